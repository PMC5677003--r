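# Preprocessing filters, systematic-error removal and history annotation.

test_that("origin filter drops near-origin responses and counts them", {
  tr <- make_trials(10)
  tr$response_eccentricity[4] <- 3.2
  out <- filter_trials(tr)
  expect_equal(nrow(out$trials), 9L)
  expect_equal(out$subjects$n_dropped_origin, 1L)
  expect_equal(out$subjects$n_dropped_3sd, 0L)
})

test_that("3-SD rule drops a gross outlier from normal errors", {
  err <- withr::with_seed(7, stats::rnorm(100, 0, 5))
  err[50] <- 40 # > 3 * SD(fixture) by direct check
  stopifnot(abs(40 - mean(err)) > 3 * stats::sd(err))
  tr <- make_trials(100, err = err)
  out <- filter_trials(tr)
  expect_equal(out$subjects$n_dropped_3sd, 1L)
  expect_false(39 %in% round(wrap_deg(out$trials$response_angle -
                                        out$trials$stimulus_angle)))
})

test_that("filtering a clean table is the identity and is idempotent", {
  # bounded uniform errors: no point can exceed 3 SD, so nothing is dropped
  tr <- make_trials(200)
  once <- filter_trials(tr)
  expect_equal(nrow(once$trials), nrow(tr))
  # with injected outliers, a second pass changes nothing further
  err <- withr::with_seed(8, stats::runif(300, -8, 8))
  err[c(10, 200)] <- c(60, -75)
  tr2 <- make_trials(300, err = err)
  first <- filter_trials(tr2)
  second <- filter_trials(first$trials)
  expect_equal(as.data.frame(second$trials), as.data.frame(first$trials))
  expect_equal(second$subjects$n_dropped_3sd, 0L)
})

test_that("subjects left with fewer than 10 trials are flagged", {
  tr <- make_trials(12)
  tr$response_eccentricity[1:4] <- 1 # origin-dropped
  out <- filter_trials(tr)
  expect_true(out$subjects$flagged_low_n)
  # flagged subjects are not fit downstream
  prep <- preprocess_trials(tr)
  expect_equal(nrow(prep$trials), 0L)
})

test_that("systematic-error estimate recovers a smooth sinusoid", {
  withr::local_seed(9)
  theta <- stats::runif(600, 0, 360)
  truth <- function(t) 2 * sin(deg2rad(t))
  y <- truth(theta) + stats::rnorm(600, 0, 1)
  fn <- estimate_systematic_error(theta, y)
  grid <- seq(0, 359.5, by = 1)
  expect_gt(stats::cor(fn(grid), truth(grid)), 0.95)
  # mean over the circle equals the mean raw error
  expect_lt(abs(mean(fn(seq(0, 359, by = 1))) - mean(y)), 1e-6)
  # periodic with period 360 (up to floating-point modulus)
  expect_equal(fn(c(12.3, 200)), fn(c(12.3 + 360, 200 + 360)),
               tolerance = 1e-12)
})

test_that("systematic-error estimate handles degenerate inputs", {
  theta <- stats::runif(100, 0, 360)
  fn0 <- estimate_systematic_error(theta, rep(0, 100))
  expect_lt(max(abs(fn0(seq(0, 359)))), 1e-9)
  expect_error(estimate_systematic_error(theta[1:30], rep(0, 30)), "50")
  expect_error(estimate_systematic_error(rep(10, 100), rep(0, 100)),
               "degenerate")
  expect_error(estimate_systematic_error(theta, rep(0, 100), span = 0), "span")
})

test_that("residualize subtracts the bias with wrapping", {
  tr <- make_trials(5)
  tr$raw_error <- c(179, 0, -10, 20, 5)
  out <- residualize(tr, bias_fn = function(t) rep(-3, length(t)))
  expect_equal(out$residual_error[1], -178) # wrap(179 - (-3)) = -178
  expect_equal(out$residual_error[2], 3)
  out0 <- residualize(tr, bias_fn = function(t) rep(0, length(t)))
  expect_equal(out0$residual_error, tr$raw_error)
  expect_equal(nrow(out), nrow(tr)) # count and order preserved
})

test_that("residualizing against the true systematic error flattens it", {
  withr::local_seed(10)
  n <- 2000
  stim <- stats::runif(n, 0, 360)
  sys <- 2 * sin(deg2rad(stim)) + 0.8 * sin(4 * deg2rad(stim) + 1)
  err <- sys + stats::rnorm(n, 0, 4)
  tr <- tibble::tibble(
    subject_id = "S1", trial_index = seq_len(n) - 1L,
    stimulus_angle = stim, response_angle = (stim + err) %% 360,
    response_eccentricity = 12, delay_s = 3, iti_s = 1
  )
  out <- residualize(tr) # per-subject LOESS estimate
  m <- stats::lm(out$residual_error ~ sin(deg2rad(stim)) + cos(deg2rad(stim)))
  expect_lt(max(abs(stats::coef(m)[-1])), 0.2)
})

test_that("subject exclusion uses a strict 10-degree threshold", {
  subj <- tibble::tibble(
    subject_id = c("A", "B", "C"),
    mean_abs_error = c(37.3, 10.0, 4.7)
  )
  out <- exclude_subjects(subj)
  expect_equal(out$excluded, c(TRUE, FALSE, FALSE))
})

test_that("history annotation wraps and never crosses subjects", {
  tr <- make_trials(2)
  tr$stimulus_angle <- c(10, 350)
  out <- annotate_history(tr)
  expect_true(is.na(out$x_prev[1]))
  expect_equal(out$x_prev[2], 20) # wrap(10 - 350)
  expect_equal(out$x_next[1], -20)
  expect_true(is.na(out$x_next[2]))

  single <- make_trials(1)
  expect_error(ann1 <- annotate_history(single), NA)
  expect_true(is.na(ann1$x_prev) && is.na(ann1$x_next))

  two <- dplyr::bind_rows(make_trials(5, subject = "A"),
                          make_trials(5, subject = "B", seed = 2))
  ann <- annotate_history(two)
  expect_true(all(is.na(ann$x_prev[ann$trial_index == 0])))

  shuffled <- tr[c(2, 1), ]
  expect_error(annotate_history(shuffled), "increasing")
})

test_that("x_next matches a brute-force recomputation", {
  tr <- make_trials(50, seed = 3)
  ann <- annotate_history(tr)
  brute <- vapply(seq_len(49), function(i) {
    wrap_deg(tr$stimulus_angle[i + 1] - tr$stimulus_angle[i])
  }, numeric(1))
  expect_equal(ann$x_next[1:49], brute)
  # x_next(i) and x_prev(i+1) describe the same stimulus pair from the two
  # trials' own reference frames, so they are sign-flipped copies
  expect_equal(ann$x_next[1:49], -ann$x_prev[2:50])
})

test_that("trials dropped by filters still donate history", {
  tr <- make_trials(60)
  tr$response_eccentricity[10] <- 2 # invalid click on trial index 9
  prep <- preprocess_trials(tr, span = 1)
  expect_false(9 %in% prep$trials$trial_index)
  t10 <- dplyr::filter(prep$trials, trial_index == 10)
  expect_equal(t10$x_prev,
               wrap_deg(tr$stimulus_angle[10] - tr$stimulus_angle[11]))
})

test_that("preprocess keeps trial counts consistent with injected nuisances", {
  cfg <- sd_config(
    n_trials_per_subject = 2000, bias_shape = "none",
    systematic_error = list(),
    outlier_rate = 0.01, origin_click_rate = 0.01,
    noise_model = "ep", noise_params = list(kappa = 131.3), seed = 61
  )
  tr <- generate_session(cfg)
  flt <- filter_trials(tr)
  n_origin_true <- sum(tr$response_eccentricity < 5)
  expect_equal(flt$subjects$n_dropped_origin, n_origin_true)
  # 3-SD drops roughly match the injected outliers (the rule also clips a
  # few genuine tail trials, and outliers inflate the SD slightly)
  expect_gt(flt$subjects$n_dropped_3sd, 5)
  expect_lt(flt$subjects$n_dropped_3sd, 60)
})
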
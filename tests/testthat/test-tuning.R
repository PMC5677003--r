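# DoG/Clifford curves, least-squares fitting, peak-to-peak, moving average,
# and the variance power-law fit.

test_that("dog_curve has the analytic peak structure", {
  expect_equal(dog_curve(0, 3, 0.02), 0)
  expect_equal(dog_curve(c(-50, 50), 3, 0.02),
               -rev(dog_curve(c(-50, 50), 3, 0.02))) # odd
  # peak height equals a at x = 1/(w sqrt(2)), confirmed on a dense grid
  for (pars in list(c(3, 0.02), c(-1.5, 0.05), c(0.7, 0.01))) {
    a <- pars[1]; w <- pars[2]
    xpk <- 1 / (w * sqrt(2))
    expect_equal(dog_curve(xpk, a, w), a, tolerance = 1e-12)
    g <- seq(-180, 180, by = 0.01)
    expect_equal(max(abs(dog_curve(g, a, w))), abs(a), tolerance = 1e-6)
  }
  expect_equal(dog_curve(seq(-180, 180, 10), 0, 0.02),
               rep(0, 37)) # a = 0 collapses the curve
})

test_that("clifford_curve satisfies its defining equation and conventions", {
  expect_equal(clifford_curve(0, 1, 0.2), 0)
  expect_equal(clifford_curve(seq(-180, 180, 5), 1, 0), rep(0, 73),
               tolerance = 1e-12) # identity mapping
  x <- seq(-180, 180, 2.5)
  y <- clifford_curve(x, 1.1, 0.25, 1)
  expect_equal(y, -rev(clifford_curve(rev(-x), 1.1, 0.25, 1)),
               tolerance = 1e-9) # odd
  expect_error(clifford_curve(10, 1, 1), "degenerate")
  expect_error(clifford_curve(10, 0.5, 0.8), "s_scale > c_center")
})

test_that("clifford_curve matches a continuous-branch numeric solve", {
  s <- 1; cc <- 0.2
  rhs <- function(x) sin(x) / sqrt((s * cos(x) - cc)^2 + sin(x)^2)
  # track the solution of sin(y + x) = rhs(x) continuously from y(0) = 0
  y_prev <- 0
  xs <- seq(0, deg2rad(45), length.out = 200)
  for (x in xs[-1]) {
    f <- function(y) sin(y + x) - rhs(x)
    y_prev <- stats::uniroot(f, c(y_prev - 0.2, y_prev + 0.2),
                             tol = 1e-12)$root
  }
  expect_equal(clifford_curve(45, s, cc, 1), rad2deg(y_prev),
               tolerance = 1e-6)
})

test_that("DoG fitting is exact on noise-free data and sign-symmetric", {
  withr::local_seed(12)
  x <- stats::runif(500, -180, 180)
  d <- tibble::tibble(x_prev = x, residual_error = dog_curve(x, 3, 0.02))
  f <- fit_tuning(d, "dog")
  expect_lt(f$sse, 1e-6)
  expect_equal(f$params$a, 3, tolerance = 1e-5)
  expect_equal(f$params$w, 0.02, tolerance = 1e-5)

  dneg <- tibble::tibble(x_prev = x, residual_error = -dog_curve(x, 3, 0.02))
  fneg <- fit_tuning(dneg, "dog")
  expect_equal(fneg$params$a, -3, tolerance = 1e-5)
  expect_lt(fneg$sse, 1e-6)

  d0 <- tibble::tibble(x_prev = x, residual_error = rep(0, 500))
  f0 <- fit_tuning(d0, "dog")
  expect_lt(abs(f0$params$a), 1e-8)
  expect_lt(abs(f0$peak_to_peak), 1e-7)

  expect_error(fit_tuning(d[1:10, ], "dog"), "20")
})

test_that("clifford fitting recovers noise-free parameters", {
  withr::local_seed(13)
  x <- stats::runif(400, -180, 180)
  for (sgn in c(1, -1)) {
    d <- tibble::tibble(x_prev = x,
                        residual_error = clifford_curve(x, 1.05, 0.2, sgn))
    f <- fit_tuning(d, "clifford")
    expect_lt(f$sse, 1e-4)
    expect_equal(f$params$s_scale, 1.05, tolerance = 0.01)
    expect_equal(f$params$c_center, 0.2, tolerance = 0.01)
  }
})

test_that("fitted tuning curves are odd in x", {
  d <- make_dog_xy(800, seed = 3)
  xg <- seq(2.5, 177.5, by = 5)
  for (model in c("dog", "clifford")) {
    f <- fit_tuning(d, model)
    cv <- tuning_curve(f)
    expect_lt(max(abs(cv(xg) + cv(-xg))), 1e-9)
  }
})

test_that("peak_to_peak matches the DoG analytic identity and conventions", {
  # 2a whenever the peaks are on-domain (1/(w sqrt 2) <= 180)
  for (pars in list(c(3, 0.02), c(-2, 0.05), c(0.5, 0.004))) {
    a <- pars[1]; w <- pars[2]
    f <- structure(list(model = "dog", params = list(a = a, w = w)),
                   class = "tuning_fit")
    expect_equal(peak_to_peak(f), 2 * a, tolerance = 1e-6)
  }
  flat <- structure(list(model = "dog", params = list(a = 0, w = 0.02)),
                    class = "tuning_fit")
  expect_equal(peak_to_peak(flat), 0)
})

test_that("noisy DoG recovery lands in the expected amplitude band", {
  hits <- vapply(1:15, function(s) {
    f <- fit_tuning(make_dog_xy(1000, seed = 100 + s), "dog")
    f$params$a
  }, numeric(1))
  expect_gte(sum(hits > 2.4 & hits < 3.6), 13) # ~+/-20% band
})

test_that("pooled group fit agrees with mean of per-subject fits", {
  fits <- vapply(1:6, function(s) {
    fit_tuning(make_dog_xy(800, seed = 200 + s), "dog")$peak_to_peak
  }, numeric(1))
  pooled <- dplyr::bind_rows(
    lapply(1:6, function(s) make_dog_xy(800, seed = 200 + s))
  )
  fp <- fit_tuning(pooled, "dog")
  expect_lt(abs(fp$peak_to_peak - mean(fits)), 3 * stats::sd(fits) / sqrt(6))
})

test_that("moving average reduces to the obvious cases", {
  d <- tibble::tibble(x_prev = seq(-179, 179, length.out = 100),
                      residual_error = rep(5, 100))
  ma <- moving_average(d, window_deg = 20)
  expect_true(all(abs(ma$mean - 5) < 1e-12, na.rm = TRUE))
  expect_true(all(ma$se[ma$n > 1] == 0))

  ma_all <- moving_average(d, window_deg = 360)
  expect_true(all(abs(ma_all$mean - mean(d$residual_error)) < 1e-12))

  # empty windows give NA, not zero
  dn <- tibble::tibble(x_prev = stats::runif(50, -10, 10),
                       residual_error = stats::rnorm(50))
  man <- moving_average(dn, window_deg = 10)
  expect_true(anyNA(man$mean))
  expect_true(all(is.na(man$mean[man$n == 0])))

  # recovers the sign of an injected bias
  db <- make_dog_xy(4000, a = 3, seed = 5)
  mab <- moving_average(db, window_deg = 30)
  near_pos <- mab$mean[mab$x > 10 & mab$x < 60]
  near_neg <- mab$mean[mab$x < -10 & mab$x > -60]
  expect_gt(mean(near_pos), 0)
  expect_lt(mean(near_neg), 0)
})

test_that("variance power law recovers a known exponent exactly", {
  d <- c(0, 1, 3, 6, 10)
  pts <- tibble::tibble(delay_s = d, variance = 10 * (d + 1)^0.47)
  f <- fit_variance_power_law(pts)
  expect_equal(f$beta, 0.47, tolerance = 1e-4)
  expect_equal(f$scale, 10, tolerance = 1e-3)
  expect_equal(f$t_offset, 1, tolerance = 1e-3)

  # the power family contains exact lines (beta = 1), so on linear data the
  # two SSEs agree
  lin <- tibble::tibble(delay_s = d, variance = 4 + 2 * d)
  fl <- fit_variance_power_law(lin)
  expect_lt(fl$sse, fl$sse_linear + 1e-9)

  cst <- tibble::tibble(delay_s = d, variance = rep(7, 5))
  fc <- fit_variance_power_law(cst)
  expect_lt(abs(fc$beta), 1e-4)

  expect_error(fit_variance_power_law(pts[1:2, ]), "3 delay levels")
  expect_error(fit_variance_power_law(
    tibble::tibble(delay_s = d, variance = c(-1, 1, 2, 3, 4))
  ), "positive")
})

test_that("variance_by_delay estimates per-condition spread with CIs", {
  withr::local_seed(14)
  d <- tibble::tibble(
    delay_s = rep(c(0, 3, 10), each = 400),
    residual_error = stats::rnorm(1200, 0, rep(c(3, 5, 8), each = 400))
  )
  v <- variance_by_delay(d, n_boot = 300, seed = 2)
  expect_equal(v$delay_s, c(0, 3, 10))
  expect_true(all(v$ci_low <= v$variance & v$variance <= v$ci_high))
  expect_equal(v$variance, c(9, 25, 64), tolerance = 0.3)
})
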
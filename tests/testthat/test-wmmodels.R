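# EP/VP/VMRW densities, the kappa <-> Fisher-information map, history
# extensions, maximum-likelihood fitting, and AICc comparison.

circle_integral <- function(dens_deg_grid, grid_deg) {
  e <- deg2rad(grid_deg)
  sum((dens_deg_grid[-1] + dens_deg_grid[-length(dens_deg_grid)]) / 2 * diff(e))
}

test_that("ep_density is a proper, unimodal circular density", {
  g <- seq(-180, 180, length.out = 1441)
  for (k in c(0.5, 5, 50)) {
    expect_equal(circle_integral(ep_density(g, k), g), 1, tolerance = 1e-6)
  }
  # uniform limit
  expect_equal(ep_density(c(-120, 0, 77), 1e-8), rep(1 / (2 * pi), 3),
               tolerance = 1e-6)
  dens <- ep_density(g, 5)
  expect_equal(which.max(dens), 721L) # mode at zero error
  expect_error(ep_density(0, -1), "kappa")
})

test_that("kappa <-> J conversion matches an independent Bessel oracle", {
  # power-series evaluation of I0 and I1, independent of besselI
  bessel_series <- function(x, nu) {
    k <- 0:40
    sum((x / 2)^(2 * k + nu) / (factorial(k) * gamma(k + nu + 1)))
  }
  J2 <- 2 * bessel_series(2, 1) / bessel_series(2, 0)
  expect_equal(kappa_to_J(2), J2, tolerance = 1e-10)
  expect_lt(kappa_to_J(1e-6), 1e-6) # J -> 0 with kappa
  expect_equal(J_to_kappa(kappa_to_J(7.3)), 7.3, tolerance = 1e-8)
  expect_equal(kappa_to_J(J_to_kappa(0.8)), 0.8, tolerance = 1e-8)
  expect_error(J_to_kappa(-1), "J")
  # the fast spline inverse used inside Monte-Carlo likelihoods agrees
  Js <- c(0.05, 0.5, 2, 9, 40)
  expect_equal(serialdep:::.phi_of_J(Js), J_to_kappa(Js), tolerance = 1e-6)
})

test_that("vp_density is normalized, symmetric, and nests EP as tau -> 0", {
  g <- seq(-180, 180, length.out = 721)
  d <- vp_density(g, J_bar = 8, tau = 4, n_mc = 10000, seed = 1)
  expect_equal(circle_integral(d, g), 1, tolerance = 0.01)
  expect_equal(as.numeric(d), rev(as.numeric(d)), tolerance = 1e-10)
  d0 <- vp_density(g, J_bar = 8, tau = 1e-6, n_mc = 2000, seed = 1)
  ep_equiv <- ep_density(g, J_to_kappa(8))
  expect_lt(max(abs(d0 - ep_equiv)), 1e-3)
  expect_error(vp_density(0, -1, 1), "J_bar")
  expect_error(vp_density(0, 1, 1, n_mc = 10), "n_mc")
})

test_that("vmrw_density is normalized and has the uniform limit", {
  g <- seq(-180, 180, length.out = 721)
  d <- vmrw_density(g, kappa = 2, xi = 10, n_mc = 2000, seed = 1)
  expect_equal(circle_integral(d, g), 1, tolerance = 0.01)
  d0 <- vmrw_density(g, kappa = 2, xi = 1e-6, n_mc = 1000, seed = 1)
  expect_equal(as.numeric(d0), rep(1 / (2 * pi), 721), tolerance = 1e-6)
  expect_error(vmrw_density(0, 0, 1), "kappa")
})

test_that("vmrw_density matches its forward-simulation histogram", {
  # scaled-down version of the full oracle check (the acceptance suite runs
  # it at 200,000 draws)
  withr::local_seed(17)
  sim <- rvmrw(40000, 2, 10)
  br <- seq(-180, 180, length.out = 73)
  counts <- graphics::hist(sim, breaks = br, plot = FALSE)$counts / 40000
  mid <- br[-73] + diff(br) / 2
  dens <- vmrw_density(mid, 2, 10, n_mc = 4000, seed = 2)
  prob <- dens * diff(deg2rad(br))
  prob <- prob / sum(prob)
  tv <- sum(abs(counts - prob)) / 2
  expect_lt(tv, 0.05)
})

test_that("vmrw_density stays accurate in the many-step regime", {
  # walks with >= 30 steps use a normal approximation to the resultant;
  # compare against the exact forward sampler at a high gain
  withr::local_seed(19)
  sim <- rvmrw(50000, 2, 140)
  br <- seq(-180, 180, length.out = 145)
  counts <- graphics::hist(sim, breaks = br, plot = FALSE)$counts / 50000
  mid <- br[-145] + diff(br) / 2
  dens <- vmrw_density(mid, 2, 140, n_mc = 4000, seed = 2)
  prob <- dens * diff(deg2rad(br))
  prob <- prob / sum(prob)
  expect_lt(sum(abs(counts - prob)) / 2, 0.03)
})

test_that("history extensions nest the base model", {
  withr::local_seed(18)
  tr <- tibble::tibble(
    residual_error = rad2deg(serialdep:::rvm_rad(500, 50)),
    x_prev = c(NA, stats::runif(499, -180, 180)),
    delay_s = 3
  )
  base <- model_loglik(tr, "ep", list(kappa = 50))
  shift0 <- model_loglik(tr, "ep", list(kappa = 50), "dog_shift",
                         list(a = 0, w = 0.02))
  swap0 <- model_loglik(tr, "ep", list(kappa = 50), "swap",
                        list(alpha = 0))
  expect_equal(shift0, base, tolerance = 1e-12)
  expect_equal(swap0, base, tolerance = 1e-12)
  expect_error(model_loglik(tr, "ep", list(kappa = 50), "swap",
                            list(alpha = 2)), "alpha")
  expect_error(model_loglik(tr, "ep", list(kappa = -1)), "invalid")
})

test_that("a full swap is detected on swap-generated data", {
  for (s in 1:3) {
    withr::with_seed(20 + s, {
      n <- 400
      x_prev <- stats::runif(n, -180, 180)
      # responses centered on the previous stimulus: shat - s = x_prev + noise
      err <- wrap_deg(x_prev + rad2deg(serialdep:::rvm_rad(n, 50)))
      tr <- tibble::tibble(residual_error = err, x_prev = x_prev, delay_s = 3)
      ll_swap <- model_loglik(tr, "ep", list(kappa = 50), "swap",
                              list(alpha = 1))
      ll_base <- model_loglik(tr, "ep", list(kappa = 50))
      expect_gt(ll_swap, ll_base)
    })
  }
})

test_that("EP concentration is recovered by maximum likelihood", {
  rel_err <- vapply(1:8, function(s) {
    withr::with_seed(30 + s, {
      tr <- tibble::tibble(
        residual_error = rad2deg(serialdep:::rvm_rad(500, 8)),
        x_prev = NA_real_, delay_s = 3
      )
      f <- fit_wm_model(tr, "ep")
      abs(f$conditions$kappa - 8) / 8
    })
  }, numeric(1))
  expect_gte(sum(rel_err < 0.15), 7)
})

test_that("VMRW parameters are recovered by maximum likelihood", {
  withr::local_seed(40)
  tr <- tibble::tibble(residual_error = rvmrw(1000, 2, 10),
                       x_prev = NA_real_, delay_s = 3)
  f <- fit_wm_model(tr, "vmrw", n_mc = 500, seed = 2)
  expect_lt(abs(f$conditions$kappa - 2) / 2, 0.25)
  expect_lt(abs(f$conditions$xi - 10) / 10, 0.25)
})

test_that("hybrid fitting recovers an injected DoG shift", {
  withr::local_seed(41)
  x <- stats::runif(1000, -180, 180)
  err <- wrap_deg(dog_curve(x, 3, 0.02) + rad2deg(serialdep:::rvm_rad(1000, 131)))
  tr <- tibble::tibble(residual_error = err, x_prev = x, delay_s = 3)
  f <- fit_wm_model(tr, "ep", "dog_shift")
  expect_gt(f$conditions$a, 2)
  expect_lt(f$conditions$a, 4)
})

test_that("separate parameter sets are fit per delay and AICc is coherent", {
  withr::local_seed(42)
  tr <- tibble::tibble(
    residual_error = rad2deg(c(serialdep:::rvm_rad(300, 20),
                               serialdep:::rvm_rad(300, 5))),
    x_prev = NA_real_,
    delay_s = rep(c(1, 10), each = 300)
  )
  f <- fit_wm_model(tr, "ep")
  expect_equal(nrow(f$conditions), 2L)
  expect_gt(f$conditions$kappa[1], f$conditions$kappa[2])
  expect_equal(f$k, 2L)
  expect_equal(f$n, 600L)
  expect_equal(f$aicc,
               2 * f$k - 2 * f$loglik + 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  # hand-checked AICc arithmetic: k = 2, n = 200, loglik = -100
  expect_equal(2 * 2 - 2 * (-100) + 2 * 2 * 3 / (200 - 2 - 1), 204.0609137,
               tolerance = 1e-7)
  expect_error(fit_wm_model(tr[1:3, ], "vp"), "too few")
})

test_that("compare_models summarizes pairwise AICc across subjects", {
  fits <- tibble::tibble(
    subject_id = rep(c("A", "B", "C"), 2),
    model = rep(c("m1", "m2"), each = 3),
    aicc = c(100, 110, 120, 104, 116, 123)
  )
  cmp <- compare_models(fits)
  expect_equal(cmp$delta_aicc_mean, mean(c(4, 6, 3))) # positive favors m1
  expect_equal(cmp$n_subjects, 3L)
  # identical model twice: delta exactly 0
  same <- dplyr::mutate(fits, aicc = rep(c(100, 110, 120), 2))
  expect_equal(compare_models(same)$delta_aicc_mean, 0)
  # missing subject excluded with warning
  expect_warning(cmp2 <- compare_models(fits[-1, ]), "missing")
  expect_equal(cmp2$n_subjects, 2L)
})
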
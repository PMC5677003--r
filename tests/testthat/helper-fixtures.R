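# Fixtures built in code: small trial tables and clean tuning datasets.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# (x, y) pairs from a known DoG bias plus Gaussian noise
make_dog_xy <- function(n, a = 3, w = 0.02, sd = 5, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::runif(n, -180, 180)
    tibble::tibble(
      x_prev = x,
      residual_error = dog_curve(x, a, w) + stats::rnorm(n, 0, sd)
    )
  })
}

# minimal hand-built trial table (uniform bounded errors by default so the
# 3-SD rule is inert unless outliers are injected explicitly)
make_trials <- function(n = 60, subject = "S1", err = NULL, ecc = 12,
                        seed = 1, delays = c(0, 1, 3, 6, 10)) {
  withr::with_seed(seed, {
    stim <- stats::runif(n, 0, 360)
    if (is.null(err)) err <- stats::runif(n, -8, 8)
    tibble::tibble(
      subject_id = subject,
      trial_index = seq_len(n) - 1L,
      stimulus_angle = stim,
      response_angle = (stim + err) %% 360,
      response_eccentricity = rep_len(ecc, n),
      delay_s = sample(delays, n, replace = TRUE),
      iti_s = 1
    )
  })
}

# von Mises CDF as a callable, for KS-style checks
vm_cdf_fun <- function(kappa) {
  th <- seq(-pi, pi, length.out = 4097)
  dens <- exp(kappa * (cos(th) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(th)))
  cdf <- cdf / cdf[length(cdf)]
  function(q) stats::approx(th, cdf, xout = q, rule = 2)$y
}
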
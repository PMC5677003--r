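#' Configuration for the synthetic session generator
#'
#' Builds and validates the parameter set from which [generate_session()]
#' simulates delayed-response sessions. Defaults emulate a variable-delay
#' spatial delayed-response experiment: ~1,000 trials per subject, retention
#' delays drawn from \{0, 1, 3, 6, 10\} s, a fixed 1-s inter-trial interval,
#' circular response noise whose variance grows sublinearly with delay
#' (equal-precision von Mises, variance 17.3 * (delay + 1)^0.47 squared
#' degrees), a delay-dependent derivative-of-Gaussian (DoG) trial-history
#' bias whose amplitude flips from repulsive at 0 s to attractive at longer
#' delays, a smooth stimulus-location-dependent systematic error, and rare
#' invalid (near-origin) and outlier responses.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_subject Trials per subject (>= 2).
#' @param delay_set Memory delays in seconds to sample from.
#' @param delay_weights Sampling weights for `delay_set` (default uniform).
#' @param iti_set Inter-trial intervals in seconds to sample from.
#' @param iti_weights Sampling weights for `iti_set` (default uniform).
#' @param noise_model One of `"ep"` (equal precision, single von Mises),
#'   `"vp"` (variable precision, gamma-mixed von Mises) or `"vmrw"`
#'   (von Mises random walk).
#' @param noise_params Named list of noise parameters. For `"ep"`: `kappa`
#'   (radian-scale concentration). For `"vp"`: `J_bar`, `tau`. For `"vmrw"`:
#'   `kappa`, `xi`. Each entry may be a scalar or a vector parallel to
#'   `delay_set` (one value per delay condition). `NULL` uses delay-calibrated
#'   EP defaults (see Details).
#' @param bias_shape Trial-history bias shape: `"dog"`, `"clifford"` or
#'   `"none"`.
#' @param bias_params For `"dog"`: list with `a` (amplitude in degrees, scalar
#'   or one per level of the conditioning variable) and `w` (width, per
#'   degree). For `"clifford"`: list with `s_scale`, `c_center`, `sign`, and
#'   `scale` (scalar or per-level multiplier applied to the curve).
#' @param bias_by Whether the bias amplitude is indexed by the current trial's
#'   `"delay"` (default) or `"iti"`.
#' @param systematic_error List of sinusoid components over stimulus angle,
#'   each a list/vector with `order` (harmonic), `amplitude` (degrees) and
#'   `phase` (degrees).
#' @param outlier_rate Probability that a trial's error is replaced by a large
#'   (> 3 SD of the noise) outlier.
#' @param origin_click_rate Probability that a response lands within 5 degrees
#'   of visual angle of the origin (an invalid click).
#' @param seed Integer seed; every subject's data are reproducible from
#'   `(seed, subject index)` alone.
#'
#' @details
#' The default DoG amplitude schedule over delays \{0, 1, 3, 6, 10\} s is
#' `c(-0.86, 0.42, 1.0, 1.7, 1.45)` degrees, i.e. peak-to-peaks of
#' `c(-1.72, 0.84, 2.0, 3.4, 2.9)` degrees: repulsion (adaptation) at a 0-s
#' delay turning into attraction (serial dependence) that peaks at 6 s.
#' The default EP concentration per delay is chosen so that total response
#' variance follows the power law 17.3 * (delay + 1)^0.47 squared degrees.
#'
#' @return A list of class `"sd_config"`.
#' @seealso [generate_session()]
#' @export
sd_config <- function(n_subjects = 1L,
                      n_trials_per_subject = 1000L,
                      delay_set = c(0, 1, 3, 6, 10),
                      delay_weights = NULL,
                      iti_set = 1,
                      iti_weights = NULL,
                      noise_model = c("ep", "vp", "vmrw"),
                      noise_params = NULL,
                      bias_shape = c("dog", "clifford", "none"),
                      bias_params = NULL,
                      bias_by = c("delay", "iti"),
                      systematic_error = list(
                        list(order = 1, amplitude = 1.5, phase = 30),
                        list(order = 4, amplitude = 0.8, phase = 100)
                      ),
                      outlier_rate = 0.002,
                      origin_click_rate = 0.002,
                      seed = 1L) {
  noise_model <- match.arg(noise_model)
  bias_shape <- match.arg(bias_shape)
  bias_by <- match.arg(bias_by)

  stopifnot(n_subjects >= 1, n_trials_per_subject >= 2)
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0, 1]")
  if (origin_click_rate < 0 || origin_click_rate > 1) {
    stop("origin_click_rate must be in [0, 1]")
  }

  norm_weights <- function(w, set, what) {
    if (is.null(w)) w <- rep(1, length(set))
    if (length(w) != length(set) || any(w < 0) || sum(w) <= 0) {
      stop("invalid ", what, " weights")
    }
    w / sum(w)
  }
  delay_weights <- norm_weights(delay_weights, delay_set, "delay")
  iti_weights <- norm_weights(iti_weights, iti_set, "iti")

  if (is.null(noise_params)) {
    # EP concentration calibrated so variance tracks a sublinear power law
    # of memory delay: var(deg^2) = 17.3 * (delay + 1)^0.47.
    var_deg2 <- 17.3 * (delay_set + 1)^0.47
    sigma_rad <- deg2rad(sqrt(var_deg2))
    defaults <- list(
      ep = list(kappa = 1 / sigma_rad^2),
      vp = list(J_bar = pmax(1 / sigma_rad^2 - 0.5, 0.5), tau = pmax(1 / sigma_rad^2, 2) / 4),
      vmrw = list(kappa = 2, xi = (1 / sigma_rad^2) / 1.3951)
    )
    noise_params <- defaults[[noise_model]]
  }

  n_levels <- if (bias_by == "delay") length(delay_set) else length(iti_set)
  if (is.null(bias_params)) {
    bias_params <- switch(bias_shape,
      dog = list(
        a = if (identical(delay_set, c(0, 1, 3, 6, 10)) && bias_by == "delay") {
          c(-0.86, 0.42, 1.0, 1.7, 1.45)
        } else {
          1.5
        },
        w = 0.02
      ),
      clifford = list(s_scale = 1, c_center = 0.2, sign = 1, scale = 1),
      none = list()
    )
  }
  if (bias_shape == "dog") {
    if (!all(c("a", "w") %in% names(bias_params)) || any(bias_params$w <= 0)) {
      stop("dog bias_params must contain a and w > 0")
    }
    if (!length(bias_params$a) %in% c(1L, n_levels)) {
      stop("dog amplitude must be scalar or one per ", bias_by, " level")
    }
  }

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_subject = as.integer(n_trials_per_subject),
      delay_set = delay_set, delay_weights = delay_weights,
      iti_set = iti_set, iti_weights = iti_weights,
      noise_model = noise_model, noise_params = noise_params,
      bias_shape = bias_shape, bias_params = bias_params, bias_by = bias_by,
      systematic_error = systematic_error,
      outlier_rate = outlier_rate, origin_click_rate = origin_click_rate,
      seed = as.integer(seed)
    ),
    class = "sd_config"
  )
}

# Parameter value for trial-level condition index (recycles scalars).
.per_level <- function(value, idx) {
  if (length(value) == 1L) rep(value, length(idx)) else value[idx]
}

# Approximate circular noise SD in degrees for a delay condition; used only
# to scale injected outliers so they exceed 3 SD of the genuine noise.
.noise_sd_deg <- function(config, level_idx) {
  p <- config$noise_params
  kappa_eff <- switch(config$noise_model,
    ep = .per_level(p$kappa, level_idx),
    vp = .phi_of_J(.per_level(p$J_bar, level_idx)),
    vmrw = {
      kap <- .per_level(p$kappa, level_idx)
      xi <- .per_level(p$xi, level_idx)
      xi * kap * vm_A1(kap)
    }
  )
  pmin(rad2deg(1 / sqrt(pmax(kappa_eff, 1e-6))), 103.9)
}

# Draw circular noise (degrees) for trials in one delay condition.
.draw_noise <- function(config, n, level_idx) {
  p <- config$noise_params
  err_rad <- switch(config$noise_model,
    ep = rvm_rad(n, .per_level(p$kappa, level_idx)[1]),
    vp = {
      J_bar <- .per_level(p$J_bar, level_idx)[1]
      tau <- .per_level(p$tau, level_idx)[1]
      J <- stats::rgamma(n, shape = J_bar / tau, scale = tau)
      kap <- .phi_of_J(J)
      vapply(kap, function(k) rvm_rad(1L, k), numeric(1))
    },
    vmrw = {
      kap <- .per_level(p$kappa, level_idx)[1]
      xi <- .per_level(p$xi, level_idx)[1]
      m <- stats::rpois(n, xi)
      steps <- rvm_rad(sum(m), kap)
      grp <- rep.int(seq_len(n), m)
      e <- numeric(n)
      if (length(steps)) {
        cs <- vapply(split(steps, factor(grp, levels = seq_len(n))), function(s) {
          atan2(sum(sin(s)), sum(cos(s)))
        }, numeric(1))
        e <- cs
      }
      e[m == 0L] <- stats::runif(sum(m == 0L), -pi, pi)
      e
    }
  )
  rad2deg(err_rad)
}

#' Simulate a synthetic delayed-response session
#'
#' Generates one trial table with the statistical structure the downstream
#' analysis assumes: uniformly random stimulus polar angles at a fixed 12-deg
#' eccentricity, randomized delays and ITIs, a trial-history bias driven by
#' the previous trial's relative location `x_prev = wrap(prev - current)`,
#' smooth stimulus-dependent systematic error, circular noise from the
#' configured generative model, and rare near-origin and outlier responses.
#' The first trial of each subject carries no history bias. Fully
#' reproducible from the config seed; subject `i` is reproducible in
#' isolation from `(seed, i)`.
#'
#' @param config An [sd_config()] object.
#' @return A tibble with one row per trial and columns `subject_id`,
#'   `trial_index` (0-based), `stimulus_angle`, `response_angle` (degrees in
#'   \[0, 360)), `response_eccentricity` (degrees of visual angle), `delay_s`,
#'   `iti_s`.
#' @examples
#' trials <- generate_session(sd_config(n_trials_per_subject = 50, seed = 2))
#' head(trials)
#' @export
generate_session <- function(config) {
  if (!inherits(config, "sd_config")) stop("config must be an sd_config object")
  purrr::map_dfr(seq_len(config$n_subjects), function(j) {
    .generate_subject(config, j)
  })
}

.generate_subject <- function(config, j) {
  n <- config$n_trials_per_subject
  withr::with_seed((config$seed + j) %% .Machine$integer.max, {
    stimulus <- stats::runif(n, 0, 360)
    delay_idx <- sample.int(length(config$delay_set), n, replace = TRUE,
                            prob = config$delay_weights)
    iti_idx <- sample.int(length(config$iti_set), n, replace = TRUE,
                          prob = config$iti_weights)
    delay_s <- config$delay_set[delay_idx]
    iti_s <- config$iti_set[iti_idx]

    # noise, drawn per delay condition
    noise <- numeric(n)
    for (k in seq_along(config$delay_set)) {
      sel <- which(delay_idx == k)
      if (length(sel)) noise[sel] <- .draw_noise(config, length(sel), k)
    }

    # systematic error over stimulus angle
    sys_err <- numeric(n)
    for (comp in config$systematic_error) {
      comp <- as.list(comp)
      sys_err <- sys_err + comp$amplitude *
        sin(comp$order * deg2rad(stimulus) + deg2rad(comp$phase))
    }

    # history bias from previous trial's relative angle
    x_prev <- wrap_deg(dplyr::lag(stimulus) - stimulus)
    lvl_idx <- if (config$bias_by == "delay") delay_idx else iti_idx
    bias <- numeric(n)
    if (config$bias_shape == "dog") {
      a <- .per_level(config$bias_params$a, lvl_idx)
      bias <- dog_curve(dplyr::coalesce(x_prev, 0), a, config$bias_params$w)
    } else if (config$bias_shape == "clifford") {
      bp <- config$bias_params
      sc <- .per_level(if (is.null(bp$scale)) 1 else bp$scale, lvl_idx)
      bias <- sc * clifford_curve(dplyr::coalesce(x_prev, 0),
                                  bp$s_scale, bp$c_center, bp$sign)
    }
    bias[1L] <- 0

    error <- wrap_deg(sys_err + bias + noise)

    # rare outliers: replace the error with one beyond 3 SD of the noise
    is_outlier <- stats::runif(n) < config$outlier_rate
    if (any(is_outlier)) {
      sd_deg <- .noise_sd_deg(config, delay_idx)[is_outlier]
      lo <- pmin(3.5 * sd_deg, 150)
      mag <- stats::runif(sum(is_outlier), lo, 180)
      error[is_outlier] <- sample(c(-1, 1), sum(is_outlier), TRUE) * mag
    }

    # rare invalid near-origin clicks; valid responses land at the stimulus
    # eccentricity of 12 degrees of visual angle
    ecc <- rep(12, n)
    is_origin <- stats::runif(n) < config$origin_click_rate
    if (any(is_origin)) ecc[is_origin] <- stats::runif(sum(is_origin), 0, 4.99)

    tibble::tibble(
      subject_id = sprintf("S%03d", j),
      trial_index = seq_len(n) - 1L,
      stimulus_angle = stimulus,
      response_angle = (stimulus + error) %% 360,
      response_eccentricity = ecc,
      delay_s = delay_s,
      iti_s = iti_s
    )
  })
}

.trial_cols <- c("subject_id", "trial_index", "stimulus_angle",
                 "response_angle", "response_eccentricity", "delay_s", "iti_s")

.validate_trials <- function(trials, require_rows = FALSE) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing)) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (require_rows && nrow(trials) == 0L) stop("trial table is empty")
  ang <- c(trials$stimulus_angle, trials$response_angle)
  if (any(!is.finite(ang)) || any(ang < 0) || any(ang >= 360)) {
    stop("angles must lie in [0, 360)")
  }
  invisible(trials)
}

#' Write / read a trial table
#'
#' Plain-CSV round trip for trial tables, with validation of the required
#' columns and angle ranges on both ends.
#'
#' @param trials A trial table as produced by [generate_session()].
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  .validate_trials(trials)
  readr::write_csv(trials[.trial_cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      trial_index = readr::col_integer(),
      stimulus_angle = readr::col_double(),
      response_angle = readr::col_double(),
      response_eccentricity = readr::col_double(),
      delay_s = readr::col_double(),
      iti_s = readr::col_double()
    )
  )
  .validate_trials(trials)
  trials
}
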
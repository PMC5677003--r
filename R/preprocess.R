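# Trial- and subject-level preprocessing: validity filters, removal of
# stimulus-location-dependent systematic error, and history annotation.

.add_raw_error <- function(trials) {
  if (!"raw_error" %in% names(trials)) {
    trials$raw_error <- wrap_deg(trials$response_angle - trials$stimulus_angle)
  }
  trials
}

#' Annotate trials with trial-history predictors
#'
#' Adds, per subject (and per `block` if such a column is present, so that
#' history never crosses block boundaries): `raw_error` (signed response
#' error, degrees, wrapped to (-180, 180]), `x_prev` (previous stimulus angle
#' minus current, wrapped; positive means the previous stimulus was
#' counterclockwise of the current one), `prev_delay_s`, and `x_next` (the
#' matching future-trial control predictor, `wrap(next - current)`). The
#' first trial of each subject/block has `NA` `x_prev`/`prev_delay_s`; the
#' last has `NA` `x_next`.
#'
#' @param trials Trial table, ordered by `trial_index` within subject.
#' @return The input tibble with history columns appended.
#' @export
annotate_history <- function(trials) {
  .validate_trials(trials, require_rows = TRUE)
  keys <- intersect(c("subject_id", "block"), names(trials))
  grouped <- dplyr::group_by(trials, dplyr::across(dplyr::all_of(keys)))
  ord_ok <- dplyr::summarise(grouped,
    ok = all(diff(.data$trial_index) > 0) || dplyr::n() == 1L,
    .groups = "drop"
  )
  if (!all(ord_ok$ok)) {
    stop("trial_index must be strictly increasing within subject/block")
  }
  out <- dplyr::mutate(.add_raw_error(grouped),
    x_prev = wrap_deg(dplyr::lag(.data$stimulus_angle) - .data$stimulus_angle),
    prev_delay_s = dplyr::lag(.data$delay_s),
    x_next = wrap_deg(dplyr::lead(.data$stimulus_angle) - .data$stimulus_angle)
  )
  dplyr::ungroup(out)
}

#' Apply trial-level validity filters
#'
#' Removes trials whose response landed within 5 degrees of visual angle of
#' the origin (invalid clicks), then, per subject, trials whose signed raw
#' error lies more than three standard deviations from that subject's mean
#' raw error. The 3-SD rule uses the mean/SD computed once on the
#' origin-filtered data (a single pass, not iterated). Dropped trials still
#' serve as history donors if [annotate_history()] was run first: only their
#' own responses are excluded.
#'
#' @param trials Trial table (annotate first to retain history columns).
#' @return A list with `trials` (surviving trials) and `subjects`, a
#'   per-subject summary tibble with columns `subject_id`, `n_trials_total`,
#'   `n_dropped_origin`, `n_dropped_3sd`, `mean_abs_error` (degrees, over
#'   surviving trials), `excluded` (all `FALSE` until
#'   [exclude_subjects()] is applied) and `flagged_low_n` (`TRUE` when fewer
#'   than 10 trials survive; such subjects should not be fit downstream).
#' @export
filter_trials <- function(trials) {
  .validate_trials(trials, require_rows = TRUE)
  trials <- .add_raw_error(trials)

  trials$.origin_drop <- trials$response_eccentricity < 5
  kept <- dplyr::filter(trials, !.data$.origin_drop)
  kept <- dplyr::mutate(
    dplyr::group_by(kept, .data$subject_id),
    .sd_drop = abs(.data$raw_error - mean(.data$raw_error)) >
      3 * stats::sd(.data$raw_error)
  )
  kept <- dplyr::ungroup(kept)
  kept$.sd_drop[is.na(kept$.sd_drop)] <- FALSE

  subjects <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id),
    n_trials_total = dplyr::n(),
    n_dropped_origin = sum(.data$.origin_drop),
    .groups = "drop"
  )
  sd_counts <- dplyr::summarise(
    dplyr::group_by(kept, .data$subject_id),
    n_dropped_3sd = sum(.data$.sd_drop),
    mean_abs_error = mean(abs(.data$raw_error[!.data$.sd_drop])),
    .groups = "drop"
  )
  subjects <- dplyr::left_join(subjects, sd_counts, by = "subject_id")
  subjects$n_dropped_3sd[is.na(subjects$n_dropped_3sd)] <- 0L
  subjects <- dplyr::mutate(subjects,
    n_surviving = .data$n_trials_total - .data$n_dropped_origin - .data$n_dropped_3sd,
    excluded = FALSE,
    flagged_low_n = .data$n_surviving < 10L
  )

  out <- dplyr::filter(kept, !.data$.sd_drop)
  out$.origin_drop <- NULL
  out$.sd_drop <- NULL
  list(trials = out, subjects = subjects)
}

#' Estimate stimulus-location-dependent systematic error
#'
#' Locally weighted regression (LOESS, degree 1) of signed raw error on
#' stimulus angle, made periodic by fitting on the data concatenated with
#' copies shifted by -360 and +360 degrees and evaluating on the central
#' copy. `span` is interpreted relative to a single copy of the data. The
#' estimate is recentred so that its mean over \[0, 360) equals the mean raw
#' error.
#'
#' @param stimulus_angles Stimulus angles in degrees, `[0, 360)`.
#' @param raw_errors Signed errors in degrees.
#' @param span LOESS span in (0, 1], fraction of the data per local fit.
#' @return A function `bias(theta)` of stimulus angle (degrees), periodic
#'   with period 360.
#' @export
estimate_systematic_error <- function(stimulus_angles, raw_errors, span = 0.3) {
  n <- length(stimulus_angles)
  if (n < 50L) stop("need at least 50 trials to estimate systematic error")
  if (length(raw_errors) != n) stop("input lengths differ")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (stats::sd(stimulus_angles) < 1e-9) {
    stop("degenerate input: all stimulus angles identical")
  }

  x3 <- c(stimulus_angles - 360, stimulus_angles, stimulus_angles + 360)
  y3 <- rep(raw_errors, 3L)
  fit <- stats::loess(y3 ~ x3, span = span / 3, degree = 1,
                      surface = "direct",
                      control = stats::loess.control(statistics = "none"))
  grid <- seq(0, 360, by = 1)
  est <- stats::predict(fit, data.frame(x3 = grid))
  est <- est - mean(est[1:360]) + mean(raw_errors)
  est[361L] <- est[1L] # exact periodic closure

  function(theta) {
    stats::approx(grid, est, xout = theta %% 360, rule = 2)$y
  }
}

#' Subtract the systematic-error estimate from each trial
#'
#' Computes `residual_error = wrap(raw_error - bias(stimulus_angle))`, the
#' quantity on which all serial-dependence statistics operate. With
#' `bias_fn = NULL` the systematic error is estimated separately for each
#' subject from that subject's own trials (ignoring trial history).
#'
#' @param trials Trial table (with `raw_error`, or it is computed).
#' @param bias_fn A function from [estimate_systematic_error()], or `NULL`.
#' @param span Passed to [estimate_systematic_error()] when `bias_fn` is
#'   `NULL`.
#' @return The input tibble, same rows and order, with `residual_error`
#'   appended.
#' @export
residualize <- function(trials, bias_fn = NULL, span = 0.3) {
  trials <- .add_raw_error(trials)
  if (!is.null(bias_fn)) {
    trials$residual_error <- wrap_deg(
      trials$raw_error - bias_fn(trials$stimulus_angle)
    )
    return(trials)
  }
  parts <- split(seq_len(nrow(trials)), trials$subject_id)
  res <- numeric(nrow(trials))
  for (idx in parts) {
    # below 50 trials the smoother is unreliable; degrade to the constant
    # (mean-error) estimate, which satisfies the same mean constraint
    fn <- if (length(idx) < 50L) {
      mu <- mean(trials$raw_error[idx])
      function(theta) rep(mu, length(theta))
    } else {
      estimate_systematic_error(trials$stimulus_angle[idx],
                                trials$raw_error[idx], span = span)
    }
    res[idx] <- wrap_deg(trials$raw_error[idx] - fn(trials$stimulus_angle[idx]))
  }
  trials$residual_error <- res
  trials
}

#' Flag subjects with poor overall performance
#'
#' Sets `excluded = TRUE` for subjects whose overall mean absolute error is
#' strictly greater than `threshold_deg` degrees of polar angle. Group-level
#' fits downstream use only non-excluded subjects.
#'
#' @param subjects Per-subject summary tibble from [filter_trials()].
#' @param threshold_deg Exclusion threshold in degrees (default 10).
#' @return The summary tibble with `excluded` updated.
#' @export
exclude_subjects <- function(subjects, threshold_deg = 10) {
  dplyr::mutate(subjects, excluded = .data$mean_abs_error > threshold_deg)
}

#' Full preprocessing chain
#'
#' Convenience wrapper: [annotate_history()] on the complete table (so that
#' trials later dropped still donate their stimulus to `x_prev` of the
#' following trial), then [filter_trials()], [residualize()] per subject and
#' [exclude_subjects()]. Trials from excluded or low-n subjects are removed
#' from the returned trial table.
#'
#' @param trials Raw trial table.
#' @param span LOESS span for the systematic-error estimate.
#' @param exclusion_threshold_deg Subject exclusion threshold in degrees.
#' @return A list with `trials` (analysis-ready annotated trials) and
#'   `subjects` (summary tibble).
#' @export
preprocess_trials <- function(trials, span = 0.3, exclusion_threshold_deg = 10) {
  ann <- annotate_history(trials)
  flt <- filter_trials(ann)
  flt$subjects <- exclude_subjects(flt$subjects, exclusion_threshold_deg)
  keep_ids <- flt$subjects$subject_id[
    !flt$subjects$excluded & !flt$subjects$flagged_low_n
  ]
  kept <- dplyr::filter(flt$trials, .data$subject_id %in% keep_ids)
  kept <- residualize(kept, span = span)
  list(trials = kept, subjects = flt$subjects)
}
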
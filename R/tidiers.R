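# broom-style tidiers for the fitted-object classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tuning-curve fit
#'
#' @param x A `tuning_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @export
tidy.tuning_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params),
                 estimate = as.numeric(unlist(x$params)))
}

#' @rdname tidy.tuning_fit
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(model = x$model, peak_to_peak = x$peak_to_peak,
                 sse = x$sse, n = x$n, converged = x$converged)
}

#' Tidy a resampling result
#'
#' @param x A `resample_result`.
#' @param ... Unused.
#' @return One-row tibble with the observed statistic, p-value and/or CI.
#' @export
tidy.resample_result <- function(x, ...) {
  tibble::tibble(kind = x$kind, model = x$model, observed = x$observed,
                 p_value = x$p_value, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_resamples = x$n_resamples, n_failed = x$n_failed,
                 seed = x$seed)
}

#' Tidy a working-memory model fit
#'
#' @param x A `wm_fit`.
#' @param ... Unused.
#' @return `tidy()`: parameter estimates in long form, one row per
#'   (condition, term); `glance()`: one row with `loglik`, `k`, `n`,
#'   `aicc`.
#' @export
tidy.wm_fit <- function(x, ...) {
  tidyr::pivot_longer(x$conditions,
                      cols = -c("delay_s", "n", "loglik", "converged"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidy.wm_fit
#' @export
glance.wm_fit <- function(x, ...) {
  tibble::tibble(model = x$model, extension = x$extension,
                 loglik = x$loglik, k = x$k, n = x$n, aicc = x$aicc)
}

#' Tidy a variance power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: SSEs of the power
#'   law and the linear comparison fit.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("scale", "t_offset", "beta"),
                 estimate = c(x$scale, x$t_offset, x$beta))
}

#' @rdname tidy.power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(sse_power = x$sse, sse_linear = x$sse_linear,
                 n = nrow(x$points))
}
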
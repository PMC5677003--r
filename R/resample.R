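# Permutation and bootstrap inference on the signed peak-to-peak statistic.

.new_resample_result <- function(observed, draws, p_value = NA_real_,
                                 ci = c(NA_real_, NA_real_), n_resamples,
                                 seed, alternative = NA_character_,
                                 model, n_failed = 0L, kind) {
  structure(
    list(
      kind = kind, model = model, observed = observed,
      null_or_boot = draws, p_value = p_value,
      ci_low = ci[1L], ci_high = ci[2L],
      n_resamples = n_resamples, n_failed = n_failed,
      seed = seed, alternative = alternative
    ),
    class = "resample_result"
  )
}

#' @export
print.resample_result <- function(x, ...) {
  cat("<resample_result>", x$kind, "of signed peak-to-peak (", x$model, "fit )\n")
  cat(sprintf("  observed = %.3f deg, %d resamples (seed %s)\n",
              x$observed, x$n_resamples, format(x$seed)))
  if (!is.na(x$p_value)) {
    shown <- if (x$p_value == 0) {
      sprintf("< %.2g", 1 / x$n_resamples)
    } else {
      sprintf("= %.4g", x$p_value)
    }
    cat(sprintf("  p %s (%s)\n", shown, x$alternative))
  }
  if (!is.na(x$ci_low)) {
    cat(sprintf("  CI = [%.3f, %.3f] deg\n", x$ci_low, x$ci_high))
  }
  invisible(x)
}

# extract complete (x, y) pairs from a data frame with tidy-eval columns
.xy_pairs <- function(data, x_quo, y_quo) {
  xv <- rlang::eval_tidy(x_quo, data)
  yv <- rlang::eval_tidy(y_quo, data)
  keep <- is.finite(xv) & is.finite(yv)
  list(x = xv[keep], y = yv[keep])
}

# signed peak-to-peak for many resampled columns at once (DoG fast path);
# clifford falls back to a per-column loop.
.p2p_many <- function(X, Y, model) {
  if (model == "dog") {
    f <- .fit_dog_profile(X, Y)
    list(p2p = .p2p_dog(f$a, f$w), failed = rep(FALSE, ncol(X)))
  } else {
    X <- as.matrix(X)
    y_is_mat <- is.matrix(Y) && ncol(Y) > 1L
    p2p <- numeric(ncol(X))
    failed <- logical(ncol(X))
    for (j in seq_len(ncol(X))) {
      yj <- if (y_is_mat) Y[, j] else Y
      fit <- tryCatch(.fit_tuning_xy(X[, j], yj, "clifford"),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        failed[j] <- TRUE
      } else {
        p2p[j] <- fit$peak_to_peak
      }
    }
    list(p2p = p2p[!failed], failed = failed)
  }
}

.perm_p <- function(observed, null, alternative) {
  switch(alternative,
    greater = mean(null >= observed),
    less = mean(null <= observed),
    two.sided = mean(abs(null) >= abs(observed)),
    auto = if (observed >= 0) mean(null >= observed) else mean(null <= observed)
  )
}

#' Permutation test of the peak-to-peak statistic
#'
#' Shuffles the relative-angle predictor `x` while leaving the errors in
#' place, refits the tuning model, and records the signed peak-to-peak of
#' each null fit. The default p-value is the proportion of null
#' peak-to-peaks greater than or equal to the observed one (a one-sided test
#' for attraction); `alternative = "less"` tests for repulsion,
#' `"two.sided"` compares magnitudes, and `"auto"` picks the tail matching
#' the sign of the observed effect (note that under the null `"auto"`
#' rejects at twice the nominal rate, since the tail is data-selected).
#'
#' @param data Data frame of trials.
#' @param model `"dog"` or `"clifford"`.
#' @param n_perm Number of permutations (values below 100 trigger a
#'   warning).
#' @param seed Integer seed; the null distribution is bit-reproducible.
#' @param alternative `"greater"` (default), `"less"`, `"two.sided"` or
#'   `"auto"`.
#' @param x,y Columns (tidy-eval), defaults `x_prev` / `residual_error`.
#' @return A `resample_result` with `observed`, the null distribution,
#'   and `p_value` (stored as the raw proportion; printed as `< 1/n_perm`
#'   when zero).
#' @export
permutation_test <- function(data, model = c("dog", "clifford"),
                             n_perm = 10000, seed = 1,
                             alternative = c("greater", "less", "two.sided", "auto"),
                             x = x_prev, y = residual_error) {
  model <- match.arg(model)
  alternative <- match.arg(alternative)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  p <- .xy_pairs(data, rlang::enquo(x), rlang::enquo(y))
  n <- length(p$x)
  if (n < 20L) stop("need at least 20 complete (x, y) pairs")

  obs <- .p2p_many(matrix(p$x, ncol = 1L), p$y, model)$p2p

  null <- numeric(0)
  n_failed <- 0L
  withr::with_seed(seed, {
    chunk <- max(1L, min(n_perm, floor(2e6 / n)))
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      idx <- vapply(seq_len(k), function(i) sample.int(n), integer(n))
      r <- .p2p_many(matrix(p$x[idx], n, k), p$y, model)
      null <- c(null, r$p2p)
      n_failed <- n_failed + sum(r$failed)
      done <- done + k
    }
  })

  .new_resample_result(
    observed = obs, draws = null,
    p_value = .perm_p(obs, null, alternative),
    n_resamples = n_perm, seed = seed, alternative = alternative,
    model = model, n_failed = n_failed, kind = "permutation test"
  )
}

#' Permutation comparison of two conditions
#'
#' For each permutation, shuffles `x` independently within each condition,
#' refits both, and records the difference of null peak-to-peaks (A minus
#' B). The default p-value is the proportion of null differences greater
#' than or equal to the empirical difference.
#'
#' @param data_a,data_b Data frames of trials for the two conditions.
#' @inheritParams permutation_test
#' @return A `resample_result`; `observed` is the empirical A - B
#'   difference.
#' @export
permutation_compare <- function(data_a, data_b, model = c("dog", "clifford"),
                                n_perm = 10000, seed = 1,
                                alternative = c("greater", "less", "two.sided", "auto"),
                                x = x_prev, y = residual_error) {
  model <- match.arg(model)
  alternative <- match.arg(alternative)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  xq <- rlang::enquo(x)
  yq <- rlang::enquo(y)
  pa <- .xy_pairs(data_a, xq, yq)
  pb <- .xy_pairs(data_b, xq, yq)
  na <- length(pa$x)
  nb <- length(pb$x)
  if (na < 20L || nb < 20L) stop("need at least 20 pairs per condition")

  obs_a <- .p2p_many(matrix(pa$x, ncol = 1L), pa$y, model)$p2p
  obs_b <- .p2p_many(matrix(pb$x, ncol = 1L), pb$y, model)$p2p
  obs <- obs_a - obs_b

  null <- numeric(0)
  n_failed <- 0L
  withr::with_seed(seed, {
    chunk <- max(1L, min(n_perm, floor(1e6 / max(na, nb))))
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      ia <- vapply(seq_len(k), function(i) sample.int(na), integer(na))
      ib <- vapply(seq_len(k), function(i) sample.int(nb), integer(nb))
      ra <- .p2p_many(matrix(pa$x[ia], na, k), pa$y, model)
      rb <- .p2p_many(matrix(pb$x[ib], nb, k), pb$y, model)
      ok <- !ra$failed & !rb$failed
      pa2 <- numeric(k); pa2[!ra$failed] <- ra$p2p
      pb2 <- numeric(k); pb2[!rb$failed] <- rb$p2p
      null <- c(null, (pa2 - pb2)[ok])
      n_failed <- n_failed + sum(!ok)
      done <- done + k
    }
  })

  .new_resample_result(
    observed = obs, draws = null,
    p_value = .perm_p(obs, null, alternative),
    n_resamples = n_perm, seed = seed, alternative = alternative,
    model = model, n_failed = n_failed, kind = "permutation comparison"
  )
}

#' Bootstrap confidence interval for the peak-to-peak
#'
#' Resamples `(x, y)` pairs jointly with replacement, refits the tuning
#' model, and returns the percentile interval of the signed peak-to-peak.
#'
#' @inheritParams permutation_test
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level in (0, 1).
#' @return A `resample_result` with `ci_low` / `ci_high`.
#' @export
bootstrap_ci <- function(data, model = c("dog", "clifford"),
                         n_boot = 10000, level = 0.95, seed = 1,
                         x = x_prev, y = residual_error) {
  model <- match.arg(model)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (n_boot < 100) warning("n_boot < 100 gives a very coarse interval")
  p <- .xy_pairs(data, rlang::enquo(x), rlang::enquo(y))
  n <- length(p$x)
  if (n < 20L) stop("need at least 20 complete (x, y) pairs")

  obs <- .p2p_many(matrix(p$x, ncol = 1L), p$y, model)$p2p

  boot <- numeric(0)
  n_failed <- 0L
  withr::with_seed(seed, {
    chunk <- max(1L, min(n_boot, floor(1e6 / n)))
    done <- 0L
    while (done < n_boot) {
      k <- min(chunk, n_boot - done)
      idx <- vapply(seq_len(k), function(i) sample.int(n, n, replace = TRUE),
                    integer(n))
      r <- .p2p_many(matrix(p$x[idx], n, k), matrix(p$y[idx], n, k), model)
      boot <- c(boot, r$p2p)
      n_failed <- n_failed + sum(r$failed)
      done <- done + k
    }
  })

  ci <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  .new_resample_result(
    observed = obs, draws = boot, ci = ci,
    n_resamples = n_boot, seed = seed, model = model,
    n_failed = n_failed, kind = "bootstrap CI"
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni(0.05, 6) # ~0.0083, i.e. the rounded 0.008 for 6 comparisons
#' @export
bonferroni <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
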
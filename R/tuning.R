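# Tuning curves for trial-history biases: derivative-of-Gaussian (DoG) and
# Clifford models, least-squares fitting, the signed peak-to-peak statistic,
# moving-average curves, and the variance-vs-delay power-law fit.

# fixed DoG normalization constant, sqrt(2)/e^{-0.5}: makes `a` the height of
# the curve peaks, which sit at x = +/- 1/(w*sqrt(2))
DOG_C <- sqrt(2) * exp(0.5)

#' Derivative-of-Gaussian tuning curve
#'
#' `y = x * a * w * c * exp(-(w x)^2)` with `c = sqrt(2) * e^{0.5}`, so that
#' the curve is odd in `x`, peaks at `x = +/- 1/(w sqrt(2))`, and the peak
#' height equals `a`. `x` is the relative angle of the previous trial in
#' degrees; `y` the predicted signed error in degrees.
#'
#' @param x Relative angle(s) of the previous stimulus, degrees.
#' @param a Signed amplitude (peak height), degrees. Positive = attraction.
#' @param w Width parameter, per degree (> 0).
#' @return Predicted bias in degrees.
#' @export
dog_curve <- function(x, a, w) {
  x * a * w * DOG_C * exp(-(w * x)^2)
}

.clifford_check <- function(s_scale, c_center) {
  if (s_scale <= 0) stop("clifford s_scale must be > 0")
  if (abs(abs(c_center) - s_scale) < 1e-12) {
    stop("degenerate clifford parameters: |c_center| == s_scale")
  }
  if (s_scale - c_center <= 0) {
    stop("clifford parameters must satisfy s_scale > c_center")
  }
}

#' Clifford tuning curve
#'
#' Adaptation-style tuning function defined implicitly by
#' `sin(y + x) = sin(x) / sqrt((s cos x - c)^2 + sin^2 x)`. The branch is
#' resolved by the vector-angle construction
#' `y = atan2(sin x, s cos x - c) - x` (continuous, odd, with `y(0) = 0`),
#' which satisfies the identity exactly. In its raw form the curve models
#' repulsive adaptation; `sign = -1` flips it to model attractive serial
#' dependence.
#'
#' @param x Relative angle(s) in degrees.
#' @param s_scale Scaling parameter `s` (> 0).
#' @param c_center Centering parameter `c` (requires `s > c` and
#'   `|c| != s`).
#' @param sign Orientation, `+1` or `-1`.
#' @return Bias in degrees.
#' @export
clifford_curve <- function(x, s_scale, c_center, sign = 1) {
  .clifford_check(s_scale, c_center)
  xr <- deg2rad(x)
  yr <- wrap_rad(atan2(sin(xr), s_scale * cos(xr) - c_center) - xr)
  sign * rad2deg(yr)
}

# ---- DoG least squares ------------------------------------------------------
#
# The DoG is linear in `a` given `w`, so the SSE is profiled exactly over a
# and minimized over w by a staged grid search on log w within
# [W_MIN, W_MAX]. Deterministic, global over the grid, and vectorizable
# across many columns at once (permutations / bootstrap replicates).

W_MIN <- 1e-4
W_MAX <- 0.2

# X: n x P matrix of predictors (each column one replicate); Y: n x P matrix
# or length-n vector of responses. Returns per-column a, w, sse.
.fit_dog_profile <- function(X, Y) {
  X <- as.matrix(X)
  n <- nrow(X)
  P <- ncol(X)
  y_is_mat <- is.matrix(Y) && ncol(Y) > 1L
  if (!y_is_mat) Y <- matrix(Y, n, 1L)
  yty <- if (y_is_mat) colSums(Y * Y) else rep(sum(Y * Y), P)

  sse_at <- function(wv) {
    # wv: length P (or 1) vector of widths; returns list(num2den, a, den)
    if (length(wv) == 1L) {
      G <- X * (wv * DOG_C) * exp(-(wv * X)^2)
    } else {
      W <- matrix(wv, n, P, byrow = TRUE)
      G <- X * W * DOG_C * exp(-(W * X)^2)
    }
    num <- if (y_is_mat) colSums(G * Y) else as.numeric(crossprod(G, Y))
    den <- colSums(G * G)
    den[den < 1e-300] <- 1e-300
    list(a = num / den, gain = num^2 / den)
  }

  lw_lo <- log(W_MIN)
  lw_hi <- log(W_MAX)
  grid1 <- exp(seq(lw_lo, lw_hi, length.out = 25L))
  best_gain <- rep(-Inf, P)
  best_w <- rep(grid1[1L], P)
  best_a <- rep(0, P)
  for (w in grid1) {
    r <- sse_at(w)
    better <- r$gain > best_gain
    if (any(better)) {
      best_gain[better] <- r$gain[better]
      best_w[better] <- w
      best_a[better] <- r$a[better]
    }
  }
  step <- (lw_hi - lw_lo) / 24
  for (stage in 1:2) {
    offs <- seq(-step, step, length.out = 15L)
    for (o in offs) {
      wv <- pmin(pmax(exp(log(best_w) + o), W_MIN), W_MAX)
      r <- sse_at(wv)
      better <- r$gain > best_gain
      if (any(better)) {
        best_gain[better] <- r$gain[better]
        best_w[better] <- wv[better]
        best_a[better] <- r$a[better]
      }
    }
    step <- step / 7
  }
  list(a = best_a, w = best_w, sse = pmax(yty - best_gain, 0))
}

# signed peak-to-peak of a DoG in closed form: the peaks sit at
# +/- 1/(w sqrt(2)) with heights +/- a whenever that location is on-domain;
# otherwise the extremes of [-180, 180] are the extrema.
.p2p_dog <- function(a, w) {
  xpk <- 1 / (w * sqrt(2))
  ifelse(xpk <= 180, 2 * a, 2 * dog_curve(180, a, w))
}

# ---- Clifford least squares -------------------------------------------------

# unconstrained parametrization guaranteeing validity: s = exp(t1),
# c = 0.999 * s * tanh(t2)  (so |c| < s always)
.clifford_untrans <- function(t) {
  s <- exp(t[1L])
  c0 <- 0.999 * s * tanh(t[2L])
  c(s, c0)
}

.fit_clifford <- function(x, y) {
  starts_s <- c(0.8, 1, 1.2)
  starts_c <- c(-0.3, 0, 0.3)
  best <- NULL
  for (sgn in c(1, -1)) {
    for (s0 in starts_s) {
      for (c0 in starts_c) {
        par0 <- c(log(s0), atanh(c0 / (0.999 * s0)))
        obj <- function(t) {
          p <- .clifford_untrans(t)
          sum((y - clifford_curve(x, p[1L], p[2L], sgn))^2)
        }
        opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-12))
        if (is.null(best) || opt$value < best$value - 1e-12) {
          best <- list(value = opt$value, par = opt$par, sign = sgn,
                       convergence = opt$convergence)
        }
      }
    }
  }
  p <- .clifford_untrans(best$par)
  list(s_scale = p[1L], c_center = p[2L], sign = best$sign,
       sse = best$value, converged = best$convergence == 0L)
}

# ---- public fitting interface ----------------------------------------------

#' Fit a tuning curve to (relative angle, residual error) pairs
#'
#' Nonlinear least squares of the DoG or Clifford tuning function. For the
#' DoG the amplitude is profiled exactly (the model is linear in `a` given
#' `w`) and the width is found by a deterministic staged grid search on
#' `[1e-4, 0.2]` per degree; the bound keeps the curve peaks on-domain. The
#' Clifford fit uses a multi-start Nelder-Mead over `(s, c)` and both
#' orientations.
#'
#' @param data A data frame of trials.
#' @param model `"dog"` or `"clifford"`.
#' @param x,y Columns holding the previous trial's relative angle and the
#'   residual error (tidy-eval; defaults `x_prev`, `residual_error`). Rows
#'   where either is `NA` are dropped.
#' @return A `tuning_fit` object: model name, parameter list, signed
#'   `peak_to_peak` (degrees), `sse`, `n`, `converged`.
#' @examples
#' d <- tibble::tibble(x = runif(200, -180, 180))
#' d$y <- dog_curve(d$x, a = 3, w = 0.02) + rnorm(200, 0, 5)
#' fit_tuning(d, "dog", x = x, y = y)
#' @export
fit_tuning <- function(data, model = c("dog", "clifford"),
                       x = x_prev, y = residual_error) {
  model <- match.arg(model)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  if (length(xv) < 20L) stop("need at least 20 complete (x, y) pairs")
  .fit_tuning_xy(xv, yv, model)
}

.fit_tuning_xy <- function(xv, yv, model) {
  if (model == "dog") {
    f <- .fit_dog_profile(matrix(xv, ncol = 1L), yv)
    # polish the width for single fits; the amplitude stays exactly profiled
    yty <- sum(yv * yv)
    prof_sse <- function(lw) {
      w <- exp(lw)
      g <- xv * (w * DOG_C) * exp(-(w * xv)^2)
      den <- sum(g * g)
      if (den < 1e-300) return(yty)
      yty - sum(g * yv)^2 / den
    }
    op <- stats::optimize(prof_sse,
                          log(pmin(pmax(c(f$w / 1.5, f$w * 1.5), W_MIN), W_MAX)),
                          tol = 1e-10)
    if (op$objective < f$sse) {
      w <- exp(op$minimum)
      g <- xv * (w * DOG_C) * exp(-(w * xv)^2)
      f <- list(a = sum(g * yv) / sum(g * g), w = w, sse = max(op$objective, 0))
    }
    fit <- list(
      model = "dog",
      params = list(a = f$a, w = f$w),
      peak_to_peak = .p2p_dog(f$a, f$w),
      sse = f$sse, n = length(xv), converged = TRUE
    )
  } else {
    f <- .fit_clifford(xv, yv)
    fit <- list(
      model = "clifford",
      params = list(s_scale = f$s_scale, c_center = f$c_center, sign = f$sign),
      peak_to_peak = NA_real_,
      sse = f$sse, n = length(xv), converged = f$converged
    )
    fit$peak_to_peak <- .p2p_curve(function(g) {
      clifford_curve(g, f$s_scale, f$c_center, f$sign)
    })
  }
  structure(fit, class = "tuning_fit")
}

#' Evaluate a fitted tuning curve
#'
#' @param fit A `tuning_fit`.
#' @return A function of the relative angle (degrees).
#' @export
tuning_curve <- function(fit) {
  stopifnot(inherits(fit, "tuning_fit"))
  p <- fit$params
  if (fit$model == "dog") {
    function(x) dog_curve(x, p$a, p$w)
  } else {
    function(x) clifford_curve(x, p$s_scale, p$c_center, p$sign)
  }
}

# grid + local refinement peak-to-peak of an arbitrary curve function.
# magnitude = max - min over [-180, 180]; sign = sign of the curve at the
# extremum closest to zero on the positive-x side (positive = attraction).
.p2p_curve <- function(fn, step = 0.05) {
  g <- seq(-180, 180, by = step)
  v <- fn(g)
  refine <- function(i, maximize) {
    lo <- g[max(i - 1L, 1L)]
    hi <- g[min(i + 1L, length(g))]
    stats::optimize(fn, c(lo, hi), maximum = maximize, tol = 1e-9)
  }
  mx <- refine(which.max(v), TRUE)$objective
  mn <- refine(which.min(v), FALSE)$objective
  mag <- mx - mn
  if (mag < 1e-12) return(0)
  # first local extremum of |curve| at x > 0
  pos <- v[g > 0]
  av <- abs(pos)
  k <- length(av)
  is_ext <- av >= c(av[-1], -Inf) & av >= c(-Inf, av[-k])
  first <- which(is_ext & av > 1e-12)[1L]
  sgn <- if (is.na(first)) sign(pos[which.max(av)]) else sign(pos[first])
  sgn * mag
}

#' Signed peak-to-peak of a fitted tuning curve
#'
#' Evaluates the fitted curve densely over \[-180, 180\] (grid step 0.05 deg
#' with local refinement of the extrema). The magnitude is max minus min;
#' the sign is that of the curve at its extremum nearest zero on the
#' positive-x side, so attraction (error pulled toward the previous
#' stimulus) is positive and repulsion negative.
#'
#' @param fit A `tuning_fit` object.
#' @return Signed peak-to-peak in degrees.
#' @export
peak_to_peak <- function(fit) {
  stopifnot(inherits(fit, "tuning_fit"))
  .p2p_curve(tuning_curve(fit))
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat("<tuning_fit>", x$model, "\n")
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 4), sep = " = ",
                         collapse = ", "), "\n")
  cat("  peak-to-peak:", signif(x$peak_to_peak, 4), "deg  (n =", x$n,
      ", sse =", signif(x$sse, 5), ")\n")
  invisible(x)
}

# ---- moving average ---------------------------------------------------------

#' Circular moving average of errors over relative angle
#'
#' Descriptive curve for plots (never used for statistics): at each grid
#' point, the mean and standard error of `y` over trials whose `x` lies in a
#' circular window. Empty windows give `NA`, not zero.
#'
#' @param data Data frame of trials.
#' @param window_deg Full window width in degrees.
#' @param by Grid step in degrees.
#' @param x,y Columns (tidy-eval), defaults `x_prev` / `residual_error`.
#' @return A tibble with `x`, `mean`, `se`, `n`.
#' @export
moving_average <- function(data, window_deg = 20, by = 2,
                           x = x_prev, y = residual_error) {
  if (window_deg <= 0) stop("window_deg must be > 0")
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]
  yv <- yv[keep]
  grid <- seq(-180, 180 - by, by = by)
  half <- min(window_deg / 2, 180)
  res <- purrr::map_dfr(grid, function(g) {
    sel <- abs(wrap_deg(xv - g)) <= half
    n <- sum(sel)
    tibble::tibble(
      x = g,
      mean = if (n > 0L) mean(yv[sel]) else NA_real_,
      se = if (n > 1L) stats::sd(yv[sel]) / sqrt(n) else NA_real_,
      n = n
    )
  })
  res
}

# ---- variance vs delay ------------------------------------------------------

#' Response-error variance by memory delay
#'
#' Variance of residual errors within each delay condition, with a
#' percentile bootstrap confidence interval (trials resampled with
#' replacement within condition).
#'
#' @param data Data frame of trials with `delay_s`.
#' @param n_boot Bootstrap replicates per condition.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param y Error column (tidy-eval), default `residual_error`.
#' @return Tibble with `delay_s`, `n`, `variance`, `ci_low`, `ci_high`.
#' @export
variance_by_delay <- function(data, n_boot = 1000, level = 0.95, seed = 1,
                              y = residual_error) {
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  d <- data$delay_s
  keep <- is.finite(yv)
  yv <- yv[keep]
  d <- d[keep]
  lev <- sort(unique(d))
  withr::with_seed(seed, {
    purrr::map_dfr(lev, function(dl) {
      e <- yv[d == dl]
      n <- length(e)
      bv <- replicate(n_boot, stats::var(e[sample.int(n, n, replace = TRUE)]))
      qs <- stats::quantile(bv, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      tibble::tibble(delay_s = dl, n = n, variance = stats::var(e),
                     ci_low = qs[1L], ci_high = qs[2L])
    })
  })
}

#' Power-law fit of variance against delay
#'
#' Least-squares fit of `variance = scale * (delay + t_offset)^beta` with
#' `t_offset > 0` (so the 0-s condition can have non-zero variance), plus an
#' ordinary linear fit for comparison. The scale is profiled exactly
#' (linear given `t_offset` and `beta`); the remaining two parameters are
#' found by multi-start Nelder-Mead.
#'
#' @param points Data frame with columns `delay_s` (or `delay`) and
#'   `variance`; at least 3 delay levels.
#' @return A `power_law_fit` object with elements `scale`, `t_offset`,
#'   `beta`, `sse`, `linear_coef`, `sse_linear`, `points`.
#' @export
fit_variance_power_law <- function(points) {
  d <- points[[if ("delay_s" %in% names(points)) "delay_s" else "delay"]]
  v <- points$variance
  if (length(unique(d)) < 3L) stop("need at least 3 delay levels")
  if (any(v <= 0)) stop("variances must be positive")

  prof <- function(t_off, beta) {
    g <- (d + t_off)^beta
    sc <- sum(v * g) / sum(g * g)
    list(scale = sc, sse = sum((v - sc * g)^2))
  }
  obj <- function(par) prof(exp(par[1L]), par[2L])$sse
  best <- NULL
  for (t0 in c(0.3, 1, 3)) {
    for (b0 in c(0.2, 0.5, 1)) {
      opt <- stats::optim(c(log(t0), b0), obj, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-14))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  t_off <- exp(best$par[1L])
  beta <- best$par[2L]
  pr <- prof(t_off, beta)
  lin <- stats::lm(v ~ d)
  structure(
    list(
      scale = pr$scale, t_offset = t_off, beta = beta, sse = pr$sse,
      linear_coef = stats::coef(lin), sse_linear = sum(stats::resid(lin)^2),
      points = tibble::tibble(delay_s = d, variance = v)
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power_law_fit> variance ~ scale * (delay + t)^beta\n")
  cat(sprintf("  scale = %.4g, t = %.4g s, beta = %.4g (SSE %.4g)\n",
              x$scale, x$t_offset, x$beta, x$sse))
  cat(sprintf("  linear comparison SSE %.4g\n", x$sse_linear))
  invisible(x)
}
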
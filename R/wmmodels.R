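# Working-memory noise models for circular recall errors: EP (equal
# precision, a single von Mises), VP (variable precision, gamma-mixed von
# Mises) and VMRW (von Mises random walk), with serial-dependence and swap
# extensions, maximum-likelihood fitting per delay condition, and AICc
# comparison. Errors are converted to radians for all densities, so kappa,
# J_bar and tau are radian-scale.

.serialdep_env <- new.env(parent = emptyenv())

#' Equal-precision (von Mises) error density
#'
#' Von Mises density with mean 0 and concentration `kappa`, evaluated at a
#' response error given in degrees. The density is per radian and integrates
#' to 1 over the circle.
#'
#' @param error_deg Signed error(s) in degrees, (-180, 180].
#' @param kappa Concentration (radian-scale), > 0.
#' @return Density per radian.
#' @export
ep_density <- function(error_deg, kappa) {
  if (kappa <= 0) stop("kappa must be > 0")
  dvm_rad(deg2rad(error_deg), kappa)
}

#' Von Mises concentration and Fisher information
#'
#' The Fisher information carried by a von Mises memory representation with
#' concentration `kappa` is `J = kappa * I1(kappa) / I0(kappa)`. The map is
#' strictly increasing; `J_to_kappa()` inverts it by monotone root-finding
#' (round-trip error below 1e-8).
#'
#' @param kappa,J Positive numeric vectors.
#' @return `kappa_to_J()` returns `J`; `J_to_kappa()` returns `kappa`.
#' @export
kappa_to_J <- function(kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0")
  kappa * vm_A1(kappa)
}

#' @rdname kappa_to_J
#' @export
J_to_kappa <- function(J) {
  if (any(J <= 0)) stop("J must be > 0")
  vapply(J, function(j) {
    hi <- max(2, j + 2, sqrt(2 * j) + 2)
    stats::uniroot(function(k) kappa_to_J(k) - j,
                   lower = 1e-10, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

# fast monotone-spline inverse of kappa -> J, cached; used inside
# Monte-Carlo likelihoods where thousands of conversions per evaluation are
# needed. Accuracy ~1e-9 relative, verified against J_to_kappa in tests.
.phi_of_J <- function(J) {
  f <- .serialdep_env$phi_spline
  if (is.null(f)) {
    lk <- seq(log(1e-4), log(1e7), length.out = 800L)
    lj <- log(kappa_to_J(exp(lk)))
    f <- stats::splinefun(lj, lk, method = "hyman")
    .serialdep_env$phi_spline <- f
  }
  exp(f(log(J)))
}

#' Variable-precision error density
#'
#' Monte-Carlo approximation of the VP density: precision `J` is drawn anew
#' on each trial from a gamma distribution with mean `J_bar` and scale
#' `tau`, converted to a von Mises concentration through the Fisher-
#' information relation, and the resulting von Mises densities are averaged.
#' Fixed uniforms (common random numbers keyed by `seed`) are transformed by
#' the gamma quantile function, so the estimate varies smoothly with the
#' parameters.
#'
#' @param error_deg Signed error(s) in degrees.
#' @param J_bar Mean Fisher information, > 0.
#' @param tau Gamma scale, > 0.
#' @param n_mc Monte-Carlo sample count (>= 100).
#' @param seed Integer seed for the common random numbers.
#' @return Density per radian, with attribute `"se"` giving the Monte-Carlo
#'   standard error pointwise.
#' @export
vp_density <- function(error_deg, J_bar, tau, n_mc = 2000, seed = 1) {
  if (J_bar <= 0 || tau <= 0) stop("J_bar and tau must be > 0")
  if (n_mc < 100) stop("n_mc must be >= 100")
  u <- withr::with_seed(seed, stats::runif(n_mc))
  J <- stats::qgamma(u, shape = J_bar / tau, scale = tau)
  J <- pmax(J, 1e-8)
  kap <- .phi_of_J(J)
  e <- deg2rad(error_deg)
  # L x n_mc matrix of von Mises densities, averaged over draws
  logc <- kap + log(besselI(kap, 0, expon.scaled = TRUE)) + log(2 * pi)
  D <- exp(outer(cos(e), kap) - matrix(logc, length(e), n_mc, byrow = TRUE))
  out <- rowMeans(D)
  attr(out, "se") <- sqrt(pmax(rowMeans(D^2) - out^2, 0) / (n_mc - 1))
  out
}

# sample VMRW resultant lengths r_i (one per Monte-Carlo draw) under common
# random numbers: m_i = qpois(u_i, xi); each walk's m_i steps have i.i.d.
# VM(0, kappa) directions obtained by inverse-CDF transform of fixed
# uniforms, so r varies smoothly with kappa and coherently with xi. Walks
# of 30 steps or more use the normal approximation to the resultant vector
# (componentwise CLT with the exact von Mises step moments), which makes
# the cost independent of xi; the crossover is validated against the exact
# forward sampler in the tests.
.vmrw_resultants <- function(kappa, xi, n_mc, seed) {
  u_m <- withr::with_seed(seed, stats::runif(n_mc))
  m <- stats::qpois(u_m, xi)
  r <- numeric(n_mc)

  small <- which(m > 0L & m < 30L)
  if (length(small)) {
    ms <- m[small]
    M <- max(ms)
    U <- withr::with_seed(seed + 1L,
                          matrix(stats::runif(n_mc * M), n_mc, M))[small, ,
                                                                   drop = FALSE]
    phi <- matrix(vm_quantile_rad(as.vector(U), kappa), length(small), M)
    mask <- col(U) <= ms
    r[small] <- sqrt(rowSums(cos(phi) * mask)^2 + rowSums(sin(phi) * mask)^2)
  }

  big <- which(m >= 30L)
  if (length(big)) {
    Z <- withr::with_seed(seed + 2L, matrix(stats::rnorm(2L * n_mc), n_mc, 2L))
    a1 <- vm_A1(kappa)
    a2 <- besselI(kappa, 2, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE)
    var_c <- pmax((1 + a2) / 2 - a1^2, 1e-12)
    var_s <- pmax((1 - a2) / 2, 1e-12)
    mb <- m[big]
    C <- mb * a1 + sqrt(mb * var_c) * Z[big, 1L]
    S <- sqrt(mb * var_s) * Z[big, 2L]
    r[big] <- sqrt(C^2 + S^2)
  }
  r
}

#' Von Mises random-walk error density
#'
#' Monte-Carlo evaluation of the VMRW density. The number of walk steps `m`
#' is Poisson-distributed with mean `xi` (the gain); the `m` step directions
#' are i.i.d. von Mises with concentration `kappa`; conditional on the
#' walk's resultant length `r`, the behavioral error is von Mises with
#' concentration `kappa * r` (a walk with `m = 0` contributes the uniform
#' density `1/(2*pi)`). The density is the average of those von Mises
#' densities over seeded draws of `r`.
#'
#' @param error_deg Signed error(s) in degrees.
#' @param kappa Per-step concentration, > 0.
#' @param xi Expected step count (gain), > 0.
#' @param n_mc Monte-Carlo walk count (>= 1000).
#' @param seed Integer seed for the common random numbers.
#' @return Density per radian, with attribute `"se"` as in [vp_density()].
#' @export
vmrw_density <- function(error_deg, kappa, xi, n_mc = 2000, seed = 1) {
  if (kappa <= 0 || xi <= 0) stop("kappa and xi must be > 0")
  if (n_mc < 1000) stop("n_mc must be >= 1000")
  r <- .vmrw_resultants(kappa, xi, n_mc, seed)
  kr <- kappa * r
  e <- deg2rad(error_deg)
  logc <- kr + log(besselI(kr, 0, expon.scaled = TRUE)) + log(2 * pi)
  D <- exp(outer(cos(e), kr) - matrix(logc, length(e), n_mc, byrow = TRUE))
  out <- rowMeans(D)
  attr(out, "se") <- sqrt(pmax(rowMeans(D^2) - out^2, 0) / (n_mc - 1))
  out
}

#' Forward-simulate VMRW errors
#'
#' Independent generative sampler for the von Mises random walk (used by the
#' generator and as a check on [vmrw_density()]): draws `m ~ Poisson(xi)`,
#' takes `m` steps with i.i.d. von Mises(0, `kappa`) directions via
#' rejection sampling, and returns the direction of the resultant vector
#' (uniform when `m = 0`).
#'
#' @param n Number of errors to draw.
#' @param kappa Per-step concentration.
#' @param xi Expected step count.
#' @return Signed errors in degrees.
#' @export
rvmrw <- function(n, kappa, xi) {
  m <- stats::rpois(n, xi)
  steps <- rvm_rad(sum(m), kappa)
  grp <- rep.int(seq_len(n), m)
  out <- stats::runif(n, -pi, pi)
  if (length(steps)) {
    cs <- rowsum(cbind(cos(steps), sin(steps)), grp)
    has <- sort(unique(grp))
    out[has] <- atan2(cs[, 2L], cs[, 1L])
  }
  rad2deg(out)
}

# ---- likelihood -------------------------------------------------------------

# log-density grid over (-180, 180] for one (model, params) pair; EP is
# exact and needs no grid. VP/VMRW use the 721-point cached grid with
# linear interpolation in between (resolution verified against the forward
# oracle in tests).
.log_density_fn <- function(model, params, n_mc, seed, grid_n = 721L) {
  if (model == "ep") {
    k <- params$kappa
    return(function(e_deg) log_dvm_rad(deg2rad(e_deg), k))
  }
  grid <- seq(-180, 180, length.out = grid_n)
  dens <- switch(model,
    vp = vp_density(grid, params$J_bar, params$tau, n_mc = max(n_mc, 100), seed = seed),
    vmrw = vmrw_density(grid, params$kappa, params$xi, n_mc = max(n_mc, 1000), seed = seed)
  )
  dens <- pmax(as.numeric(dens), 1e-300)
  function(e_deg) {
    log(stats::approx(grid, dens, xout = e_deg, rule = 2)$y)
  }
}

.valid_params <- function(model, params) {
  ok <- switch(model,
    ep = !is.null(params$kappa) && params$kappa > 0,
    vp = all(c("J_bar", "tau") %in% names(params)) &&
      params$J_bar > 0 && params$tau > 0,
    vmrw = all(c("kappa", "xi") %in% names(params)) &&
      params$kappa > 0 && params$xi > 0,
    stop("unknown model: ", model)
  )
  if (!ok) stop("invalid parameters for model ", model)
}

#' Log-likelihood of a noise model with an optional history extension
#'
#' Computes the summed log-density of the residual errors under one of the
#' base noise models, optionally extended for trial history:
#' `"none"` uses the base density as is; `"dog_shift"` slides the density
#' mean on each trial by the DoG tuning curve evaluated at that trial's
#' `x_prev` (parameters `a`, `w`); `"swap"` mixes the base density of the
#' error with the base density of the response relative to the *previous*
#' trial's stimulus, with swap probability `alpha`. Trials with undefined
#' `x_prev` contribute the base density.
#'
#' @param trials Data frame with `residual_error` and (for extensions)
#'   `x_prev`.
#' @param model `"ep"`, `"vp"` or `"vmrw"`.
#' @param params Named list of base-model parameters (see [ep_density()],
#'   [vp_density()], [vmrw_density()]).
#' @param extension `"none"`, `"dog_shift"` or `"swap"`.
#' @param ext_params Named list: `a`, `w` for `"dog_shift"`; `alpha` for
#'   `"swap"`.
#' @param n_mc,seed Monte-Carlo settings for the VP/VMRW densities (common
#'   random numbers: the same seed gives the same density surface).
#' @return The total log-likelihood (scalar). `-Inf` with a diagnostic
#'   attribute if any trial's density underflows.
#' @export
model_loglik <- function(trials, model = c("ep", "vp", "vmrw"), params,
                         extension = c("none", "dog_shift", "swap"),
                         ext_params = list(), n_mc = 1000, seed = 1) {
  model <- match.arg(model)
  extension <- match.arg(extension)
  .valid_params(model, params)
  y <- trials$residual_error
  if (any(!is.finite(y))) stop("residual_error must be finite")
  xp <- if ("x_prev" %in% names(trials)) trials$x_prev else rep(NA_real_, length(y))
  logf <- .log_density_fn(model, params, n_mc, seed)

  ll <- switch(extension,
    none = sum(logf(y)),
    dog_shift = {
      if (is.null(ext_params$a) || is.null(ext_params$w) || ext_params$w <= 0) {
        stop("dog_shift requires ext_params a and w > 0")
      }
      shift <- ifelse(is.na(xp), 0, dog_curve(dplyr::coalesce(xp, 0),
                                              ext_params$a, ext_params$w))
      sum(logf(wrap_deg(y - shift)))
    },
    swap = {
      alpha <- ext_params$alpha
      if (is.null(alpha) || alpha < 0 || alpha > 1) {
        stop("swap requires ext_params alpha in [0, 1]")
      }
      f_cur <- exp(logf(y))
      # error relative to the previous trial's stimulus: y - x_prev
      f_prev <- ifelse(is.na(xp), f_cur, exp(logf(wrap_deg(y - dplyr::coalesce(xp, 0)))))
      sum(log((1 - alpha) * f_cur + alpha * f_prev))
    }
  )
  if (!is.finite(ll)) {
    ll <- -Inf
    attr(ll, "diagnostic") <- "density underflow or invalid trial"
  }
  ll
}

# ---- fitting ----------------------------------------------------------------

# parameter transforms: positive parameters on log scale, alpha on logit;
# lo/hi are soft box bounds in the transformed space (quadratic penalty),
# keeping the simplex out of degenerate or needlessly expensive regions
.wm_par_info <- function(model, extension, kappa0) {
  base <- switch(model,
    ep = list(names = "kappa", trans = list(exp), inv = list(log),
              center = log(kappa0),
              lo = log(1e-3), hi = log(1e4)),
    vp = {
      J0 <- kappa_to_J(kappa0)
      list(names = c("J_bar", "tau"), trans = list(exp, exp),
           inv = list(log, log), center = c(log(J0), log(max(J0 / 3, 0.05))),
           lo = log(c(1e-3, 1e-4)), hi = log(c(1e4, 1e4)))
    },
    vmrw = {
      xi0 <- max(kappa0 / kappa_to_J(2), 0.5)
      list(names = c("kappa", "xi"), trans = list(exp, exp),
           inv = list(log, log), center = c(log(2), log(xi0)),
           lo = log(c(1e-3, 1e-2)), hi = log(c(1e3, 1e3)))
    }
  )
  ext <- switch(extension,
    none = list(names = character(0), trans = list(), center = numeric(0),
                lo = numeric(0), hi = numeric(0)),
    dog_shift = list(names = c("a", "w"),
                     trans = list(identity, exp),
                     center = c(1, log(0.02)),
                     lo = c(-30, log(1e-4)), hi = c(30, log(0.2))),
    swap = list(names = "alpha", trans = list(stats::plogis),
                center = stats::qlogis(0.05), lo = -15, hi = 15)
  )
  list(
    names = c(base$names, ext$names),
    trans = c(base$trans, ext$trans),
    center = c(base$center, ext$center),
    lo = c(base$lo, ext$lo), hi = c(base$hi, ext$hi),
    n_base = length(base$names)
  )
}

.wm_untransform <- function(theta, info) {
  vals <- mapply(function(f, t) f(t), info$trans, theta)
  names(vals) <- info$names
  as.list(vals)
}

#' Fit a working-memory noise model by maximum likelihood
#'
#' Derivative-free (Nelder-Mead) maximization of [model_loglik()],
#' independently for each memory delay condition (a separate parameter set
#' per delay, the default) or jointly over all trials
#' (`per_delay = FALSE`). Positive parameters are optimized on the log
#' scale and the swap probability on the logit scale; several deterministic
#' starts around a moment-based initialization guard against local optima.
#' Monte-Carlo densities reuse one seeded set of draws across optimizer
#' steps (common random numbers) so the objective is smooth.
#'
#' @param trials Annotated trials with `residual_error`, `x_prev`, and
#'   `delay_s` when `per_delay = TRUE`.
#' @param model `"ep"`, `"vp"` or `"vmrw"`.
#' @param extension `"none"`, `"dog_shift"` or `"swap"`.
#' @param per_delay Fit a separate parameter set per delay condition.
#' @param n_mc Monte-Carlo draws per density evaluation.
#' @param seed Integer seed.
#' @return A `wm_fit` object: per-condition parameter tibble, total
#'   `loglik`, parameter count `k`, trial count `n`, and `aicc`
#'   (`2k - 2 loglik + 2k(k+1)/(n-k-1)`).
#' @export
fit_wm_model <- function(trials, model = c("ep", "vp", "vmrw"),
                         extension = c("none", "dog_shift", "swap"),
                         per_delay = TRUE, n_mc = 1000, seed = 1) {
  model <- match.arg(model)
  extension <- match.arg(extension)
  if (!"residual_error" %in% names(trials)) stop("trials lack residual_error")
  groups <- if (per_delay && "delay_s" %in% names(trials)) {
    split(trials, trials$delay_s)
  } else {
    list(all = trials)
  }

  cond_fits <- purrr::imap(groups, function(g, nm) {
    e <- deg2rad(g$residual_error)
    R <- sqrt(mean(cos(e))^2 + mean(sin(e))^2)
    kappa0 <- max(vm_A1_inv(R), 0.05)
    info <- .wm_par_info(model, extension, kappa0)
    k_par <- length(info$names)
    if (nrow(g) <= k_par + 1L) {
      stop("condition ", nm, " has too few trials (", nrow(g), ") for ",
           k_par, " parameters")
    }
    negll <- function(theta) {
      excess <- pmax(theta - info$hi, 0) + pmax(info$lo - theta, 0)
      theta <- pmin(pmax(theta, info$lo), info$hi)
      p <- .wm_untransform(theta, info)
      base <- p[seq_len(info$n_base)]
      ep_ <- p[-seq_len(info$n_base)]
      ll <- tryCatch(
        model_loglik(g, model, base, extension, ep_, n_mc = n_mc, seed = seed),
        error = function(err) -Inf
      )
      if (!is.finite(ll)) 1e12 else -ll + 1e4 * sum(excess^2)
    }
    delta <- rep(0.7, k_par)
    starts <- if (extension == "none" || k_par == 1L) {
      list(info$center, info$center + delta, info$center - delta)
    } else {
      alt <- delta * rep_len(c(1, -1), k_par)
      list(info$center, info$center + alt, info$center - alt)
    }
    best <- NULL
    for (st in starts) {
      opt <- if (k_par == 1L) {
        o <- stats::optimize(function(t) negll(t), st + c(-4, 4), tol = 1e-7)
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        stats::optim(st, negll, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-7))
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    pars <- .wm_untransform(pmin(pmax(best$par, info$lo), info$hi), info)
    tibble::tibble(
      delay_s = if (identical(nm, "all")) NA_real_ else as.numeric(nm),
      n = nrow(g),
      !!!pars,
      loglik = -best$value,
      converged = best$convergence == 0L
    )
  })
  cond_tbl <- dplyr::bind_rows(cond_fits)

  k <- (ncol(cond_tbl) - 4L) * nrow(cond_tbl) # parameter columns x conditions
  n <- sum(cond_tbl$n)
  loglik <- sum(cond_tbl$loglik)
  if (n <= k + 1L) stop("too few trials for AICc (n <= k + 1)")
  aicc <- 2 * k - 2 * loglik + 2 * k * (k + 1) / (n - k - 1)

  structure(
    list(model = model, extension = extension, conditions = cond_tbl,
         loglik = loglik, k = k, n = n, aicc = aicc,
         n_mc = n_mc, seed = seed),
    class = "wm_fit"
  )
}

#' @export
print.wm_fit <- function(x, ...) {
  cat("<wm_fit>", x$model,
      if (x$extension != "none") paste0("+ ", x$extension) else "", "\n")
  cat(sprintf("  loglik = %.2f, k = %d, n = %d, AICc = %.2f\n",
              x$loglik, x$k, x$n, x$aicc))
  print(x$conditions)
  invisible(x)
}

#' Pairwise AICc model comparison across subjects
#'
#' For every pair of model labels, computes the per-subject AICc difference
#' (second-named minus first-named, so positive values favor the
#' first-named model) and summarizes it as mean +/- SEM across subjects.
#' Subjects missing a fit for either member of a pair are excluded from that
#' pair with a warning.
#'
#' @param fits A data frame with columns `subject_id`, `model` (label) and
#'   `aicc`, e.g. built by mapping [fit_wm_model()] over subjects and
#'   models and binding `glance()` rows.
#' @return Tibble with `model_a`, `model_b`, `n_subjects`,
#'   `delta_aicc_mean` (positive favors `model_a`) and `delta_aicc_sem`.
#' @export
compare_models <- function(fits) {
  stopifnot(all(c("subject_id", "model", "aicc") %in% names(fits)))
  labels <- unique(fits$model)
  if (length(labels) < 2L) stop("need at least two model labels")
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- dplyr::filter(fits, .data$model == pr[1L])
    b <- dplyr::filter(fits, .data$model == pr[2L])
    common <- intersect(a$subject_id, b$subject_id)
    dropped <- setdiff(union(a$subject_id, b$subject_id), common)
    if (length(dropped)) {
      warning("subjects missing a fit for pair ", pr[1L], " vs ", pr[2L], ": ",
              paste(dropped, collapse = ", "))
    }
    d <- b$aicc[match(common, b$subject_id)] - a$aicc[match(common, a$subject_id)]
    tibble::tibble(
      model_a = pr[1L], model_b = pr[2L], n_subjects = length(common),
      delta_aicc_mean = mean(d),
      delta_aicc_sem = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else NA_real_
    )
  })
}
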
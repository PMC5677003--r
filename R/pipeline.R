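# End-to-end orchestration: simulate or load trials, preprocess, fit tuning
# curves per condition with resampling statistics, fit the variance power
# law, and (optionally) compare working-memory noise models.

#' Configuration for a full analysis run
#'
#' @param input Either an [sd_config()] (trials are simulated), a path to a
#'   trial CSV (read with [read_trials()]), or a trial data frame.
#' @param groupings Character vector of analysis slices: any of
#'   `"pooled"` (all valid trials), `"current_delay"`, `"previous_delay"`,
#'   `"iti"`, and `"future_control"` (pooled, but with the *next* trial's
#'   relative angle `x_next` as predictor — by construction a null control).
#' @param tuning_model `"dog"`, `"clifford"`, or `"auto"`
#'   (per-condition choice by [auto_model_select()]).
#' @param n_perm,n_boot Resampling sizes.
#' @param alternative Tail convention passed to [permutation_test()].
#' @param wm_models Character vector of noise models to fit and compare
#'   (subset of `"ep"`, `"vp"`, `"vmrw"`); empty to skip.
#' @param wm_extension Extension used for the hybrid comparison fit
#'   (`"dog_shift"` by default); `"none"` fits base models only.
#' @param n_mc Monte-Carlo draws for VP/VMRW likelihoods.
#' @param span LOESS span for systematic-error removal.
#' @param out_dir Output directory for JSON/CSV results, or `NULL`.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(input,
                            groupings = c("pooled", "current_delay", "future_control"),
                            tuning_model = c("dog", "clifford", "auto"),
                            n_perm = 10000, n_boot = 10000,
                            alternative = "greater",
                            wm_models = character(0),
                            wm_extension = "dog_shift",
                            n_mc = 1000,
                            span = 0.3,
                            out_dir = NULL,
                            seed = 1L) {
  tuning_model <- match.arg(tuning_model)
  bad <- setdiff(groupings,
                 c("pooled", "current_delay", "previous_delay", "iti",
                   "future_control"))
  if (length(bad)) stop("unknown grouping(s): ", paste(bad, collapse = ", "))
  bad_wm <- setdiff(wm_models, c("ep", "vp", "vmrw"))
  if (length(bad_wm)) stop("unknown wm model(s): ", paste(bad_wm, collapse = ", "))
  structure(
    list(input = input, groupings = groupings, tuning_model = tuning_model,
         n_perm = n_perm, n_boot = n_boot, alternative = alternative,
         wm_models = wm_models, wm_extension = wm_extension, n_mc = n_mc,
         span = span, out_dir = out_dir, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Choose between the DoG and Clifford tuning models
#'
#' Fits both models and keeps the DoG unless the Clifford model's AICc
#' (computed from the SSE under a Gaussian-error equivalence, with 2 free
#' parameters each) is lower by more than `margin`. This makes the
#' "use the DoG except where it fits poorly" policy explicit and
#' reproducible; ties go to the DoG.
#'
#' @param data Data frame of trials.
#' @param margin Required AICc advantage for the Clifford model (default 2).
#' @param x,y Columns (tidy-eval).
#' @return A list with `choice` (`"dog"` or `"clifford"`), both fits, and
#'   both AICc values.
#' @export
auto_model_select <- function(data, margin = 2, x = x_prev, y = residual_error) {
  p <- .xy_pairs(data, rlang::enquo(x), rlang::enquo(y))
  if (length(p$x) < 20L) stop("need at least 20 complete (x, y) pairs")
  fits <- list(
    dog = tryCatch(.fit_tuning_xy(p$x, p$y, "dog"),
                   error = function(e) NULL),
    clifford = tryCatch(.fit_tuning_xy(p$x, p$y, "clifford"),
                        error = function(e) NULL)
  )
  if (is.null(fits$dog) && is.null(fits$clifford)) {
    stop("both tuning fits failed")
  }
  aicc_sse <- function(f, k = 2) {
    if (is.null(f)) return(Inf)
    n <- f$n
    n * log(f$sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  aicc <- c(dog = aicc_sse(fits$dog), clifford = aicc_sse(fits$clifford))
  choice <- if (aicc["clifford"] < aicc["dog"] - margin) "clifford" else "dog"
  list(choice = choice, fits = fits, aicc = aicc)
}

# deterministic sub-seed for a named stage/condition
.sub_seed <- function(seed, stage, level = 0L) {
  offs <- sum(utf8ToInt(stage)) %% 1000L
  (seed + 13L * offs + 101L * as.integer(level)) %% .Machine$integer.max
}

.grouping_slices <- function(trials, grouping) {
  switch(grouping,
    pooled = list(pooled = trials),
    future_control = list(future = trials),
    current_delay = split(trials, trials$delay_s),
    previous_delay = split(trials[!is.na(trials$prev_delay_s), ],
                           trials$prev_delay_s[!is.na(trials$prev_delay_s)]),
    iti = split(trials, trials$iti_s)
  )
}

#' Run the full serial-dependence analysis
#'
#' Simulates or loads trials, preprocesses them ([preprocess_trials()]),
#' then for every requested grouping fits the tuning curve, runs the group
#' permutation test and bootstrap CI, fits the variance-vs-delay power law,
#' and optionally fits and compares working-memory noise models per
#' subject. Deterministic given the config seed. With `out_dir` set, writes
#' `tuning.csv`, `variance.csv`, `wm_comparison.csv` and a
#' `manifest.json` recording every parameter and derived seed.
#'
#' @param config An [analysis_config()].
#' @return A list with `trials`, `subjects`, `tuning` (one row per
#'   grouping level), `variance`, `power_law`, `wm_fits`, `wm_comparison`
#'   and `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  trials <- config$input
  if (inherits(trials, "sd_config")) {
    trials <- generate_session(trials)
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }
  prep <- preprocess_trials(trials, span = config$span)

  tuning_rows <- list()
  for (grouping in config$groupings) {
    slices <- .grouping_slices(prep$trials, grouping)
    for (nm in names(slices)) {
      sl <- slices[[nm]]
      # the future-trial control swaps the predictor for x_next
      if (grouping == "future_control") sl$x_prev <- sl$x_next
      model <- config$tuning_model
      if (model == "auto") {
        sel <- auto_model_select(sl)
        model <- sel$choice
      }
      fit <- fit_tuning(sl, model)
      sseed <- .sub_seed(config$seed, paste0(grouping, nm), 1L)
      perm <- permutation_test(sl, model, n_perm = config$n_perm,
                               seed = sseed, alternative = config$alternative)
      boot <- bootstrap_ci(sl, model, n_boot = config$n_boot,
                           seed = sseed + 1L)
      tuning_rows[[paste(grouping, nm)]] <- tibble::tibble(
        grouping = grouping,
        level = nm,
        model = model,
        n = fit$n,
        peak_to_peak = fit$peak_to_peak,
        p_value = perm$p_value,
        ci_low = boot$ci_low,
        ci_high = boot$ci_high,
        seed = sseed
      )
    }
  }
  tuning_tbl <- dplyr::bind_rows(tuning_rows)

  var_tbl <- NULL
  pl_fit <- NULL
  if (length(unique(prep$trials$delay_s)) >= 3L) {
    var_tbl <- variance_by_delay(prep$trials, n_boot = min(config$n_boot, 2000),
                                 seed = .sub_seed(config$seed, "variance"))
    pl_fit <- fit_variance_power_law(var_tbl)
  }

  wm_fits <- NULL
  wm_cmp <- NULL
  if (length(config$wm_models)) {
    specs <- purrr::map(config$wm_models, function(m) list(model = m, ext = "none"))
    if (config$wm_extension != "none") {
      specs <- c(specs, purrr::map(config$wm_models, function(m) {
        list(model = m, ext = config$wm_extension)
      }))
    }
    subj_split <- split(prep$trials, prep$trials$subject_id)
    wm_fits <- purrr::map_dfr(specs, function(sp) {
      label <- if (sp$ext == "none") sp$model else paste0(sp$model, "+", sp$ext)
      purrr::imap_dfr(subj_split, function(tr, sid) {
        f <- fit_wm_model(tr, sp$model, sp$ext,
                          n_mc = config$n_mc,
                          seed = .sub_seed(config$seed, label, 2L))
        tibble::tibble(subject_id = sid, model = label,
                       loglik = f$loglik, k = f$k, n = f$n, aicc = f$aicc)
      })
    })
    wm_cmp <- compare_models(wm_fits)
  }

  manifest <- list(
    seed = config$seed,
    groupings = config$groupings,
    tuning_model = config$tuning_model,
    n_perm = config$n_perm, n_boot = config$n_boot,
    alternative = config$alternative,
    wm_models = config$wm_models, wm_extension = config$wm_extension,
    n_mc = config$n_mc, span = config$span,
    n_trials_in = nrow(trials),
    n_trials_analyzed = nrow(prep$trials),
    n_subjects_excluded = sum(prep$subjects$excluded),
    derived_seeds = stats::setNames(tuning_tbl$seed,
                                    paste(tuning_tbl$grouping, tuning_tbl$level))
  )

  out <- list(trials = prep$trials, subjects = prep$subjects,
              tuning = tuning_tbl, variance = var_tbl, power_law = pl_fit,
              wm_fits = wm_fits, wm_comparison = wm_cmp, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tuning_tbl, file.path(config$out_dir, "tuning.csv"))
    if (!is.null(var_tbl)) {
      readr::write_csv(var_tbl, file.path(config$out_dir, "variance.csv"))
    }
    if (!is.null(wm_cmp)) {
      readr::write_csv(wm_cmp, file.path(config$out_dir, "wm_comparison.csv"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
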
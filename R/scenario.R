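.all_methods <- c("sds", "boxplot", "bagplot_age_height",
                  "bagplot_height_weight", "maha_classic", "maha_mcd",
                  "maha_mve", "ddc")

# Deterministic sub-seeds so simulation, contamination and the MCD/MVE
# searches never perturb each other's random streams.
.derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Configure one simulation scenario
#'
#' @param pattern An [error_pattern()] (or its name).
#' @param prevalence Error prevalence; the study grid uses 0.02 and 0.10.
#' @param n Cohort size (default 5000).
#' @param methods Detection methods to run; any subset of
#'   `"sds"`, `"boxplot"`, `"bagplot_age_height"`,
#'   `"bagplot_height_weight"`, `"maha_classic"`, `"maha_mcd"`,
#'   `"maha_mve"`, `"ddc"`.
#' @param seed Integer master seed for the scenario.
#' @param n_trials Starting subsets for the MCD/MVE searches.
#' @param ddc A [ddc_params()] object.
#' @param tolProb Tolerance probability for the distance thresholds.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(pattern, prevalence, n = 5000,
                            methods = .all_methods, seed = 1,
                            n_trials = 500, ddc = ddc_params(),
                            tolProb = 0.99) {
  if (!inherits(pattern, "error_pattern")) pattern <- error_pattern(pattern)
  stopifnot(n > 0, all(methods %in% .all_methods))
  structure(list(pattern = pattern, prevalence = prevalence, n = n,
                 methods = methods, seed = seed, n_trials = n_trials,
                 ddc = ddc, tolProb = tolProb),
            class = "scenario_config")
}

# Run every configured detector on one contaminated cohort. Returns a list
# per method with elements `score` (NULL for threshold-only methods) and
# `flags`, or `error` when a method failed. Rowwise flags from the
# multivariable methods are attributed to the height cell, since errors are
# injected in height only.
detect_methods <- function(table, methods, n_trials = 500, seeds = NULL,
                           ddc = ddc_params(), tolProb = 0.99) {
  X <- cbind(age_months = table$age_months, height_cm = table$height_cm,
             log_weight = table$log_weight)
  if (is.null(seeds)) seeds <- c(mcd = 1L, mve = 2L)
  res <- list()
  for (m in methods) {
    res[[m]] <- tryCatch(switch(m,
      sds = {
        sc <- abs(robust_sds(table$height_cm))
        list(score = sc, flags = sc > 2)
      },
      boxplot = list(score = NULL, flags = boxplot_flags(table$height_cm)),
      bagplot_age_height = {
        xy <- X[, c("age_months", "height_cm")]
        list(score = NULL, flags = bagplot_flags(xy, build_bagplot(xy)))
      },
      bagplot_height_weight = {
        xy <- X[, c("height_cm", "log_weight")]
        list(score = NULL, flags = bagplot_flags(xy, build_bagplot(xy)))
      },
      maha_classic = {
        d <- distance_flags(mahalanobis_sq(X, classic_estimates(X)),
                            df = ncol(X), tolProb = tolProb)
        list(score = d$d2, flags = d$flags)
      },
      maha_mcd = {
        est <- mcd_estimates(X, n_trials = n_trials, seed = seeds[["mcd"]])
        d <- distance_flags(mahalanobis_sq(X, est), df = ncol(X),
                            tolProb = tolProb)
        list(score = d$d2, flags = d$flags)
      },
      maha_mve = {
        est <- mve_estimates(X, n_trials = n_trials, seed = seeds[["mve"]])
        d <- distance_flags(mahalanobis_sq(X, est), df = ncol(X),
                            tolProb = tolProb)
        list(score = d$d2, flags = d$flags)
      },
      ddc = {
        fit <- ddc_fit(X, ddc)
        list(score = abs(fit$residual[, "height_cm"]),
             flags = fit$cell_flags[, "height_cm"])
      }),
      error = function(e) list(score = NULL, flags = NULL,
                               error = conditionMessage(e)))
  }
  if ("bagplot_age_height" %in% methods && "bagplot_height_weight" %in% methods &&
      is.null(res$bagplot_age_height$error) &&
      is.null(res$bagplot_height_weight$error)) {
    res$bagplot_either <- list(
      score = NULL,
      flags = res$bagplot_age_height$flags | res$bagplot_height_weight$flags)
  }
  res
}

#' Run one scenario: simulate, contaminate, detect, evaluate
#'
#' All configured methods see the same contaminated cohort (a paired
#' comparison). Fixed-threshold metrics are computed for every method;
#' ROC summaries are computed for the continuously-scored methods (robust
#' SDS, the three Mahalanobis variants, and the cellwise detector).
#' A method that fails is reported in `errors` without aborting the run.
#'
#' @param config A [scenario_config()].
#' @param stature_table,weight_table LMS tables (default: builtin).
#' @param table Optional pre-simulated error-free cohort (so several
#'   scenarios can share one simulation, as in the study design).
#' @return A `scenario_result` list: `config`, `table` (contaminated),
#'   `mask`, `detections`, `metrics` (data frame), `auc` (data frame),
#'   `roc` (list of [roc_summary()] objects), `errors`.
#' @export
run_scenario <- function(config,
                         stature_table = builtin_lms_table("stature"),
                         weight_table = builtin_lms_table("weight"),
                         table = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- .derive_seeds(config$seed, 4)
  if (is.null(table)) {
    table <- simulate_growth(config$n, stature_table, weight_table,
                             seed = seeds[1])
  }
  cont <- contaminate(table, config$pattern, config$prevalence,
                      seed = seeds[2], stature_table = stature_table)
  det <- detect_methods(cont$table, config$methods,
                        n_trials = config$n_trials,
                        seeds = c(mcd = seeds[3], mve = seeds[4]),
                        ddc = config$ddc, tolProb = config$tolProb)
  scen <- paste0(config$pattern$name, "_", config$prevalence * 100, "pct")
  metrics <- NULL
  auc <- NULL
  roc <- list()
  errors <- list()
  for (m in names(det)) {
    if (!is.null(det[[m]]$error)) {
      errors[[m]] <- det[[m]]$error
      next
    }
    bm <- binary_metrics(confusion(det[[m]]$flags, cont$mask))
    metrics <- rbind(metrics, cbind(scenario = scen, method = m, bm))
    if (!is.null(det[[m]]$score)) {
      rs <- roc_summary(det[[m]]$score, cont$mask)
      roc[[m]] <- rs
      auc <- rbind(auc, data.frame(scenario = scen, method = m,
                                   auc = rs$auc, ci_low = rs$auc_ci[1],
                                   ci_high = rs$auc_ci[2],
                                   youden_j = rs$youden_j,
                                   youden_se = rs$youden_se,
                                   youden_sp = rs$youden_sp))
    }
  }
  structure(list(config = config, table = cont$table, mask = cont$mask,
                 detections = det, metrics = metrics, auc = auc, roc = roc,
                 errors = errors),
            class = "scenario_result")
}

#' Descriptive summary of error-free and contaminated cohorts
#'
#' Mean, SD, MAD (1.4826-scaled), minimum, the 1/5/10/25/50/75/90/95/99th
#' percentiles and maximum, for age, log weight, and the height column of
#' each supplied table.
#'
#' @param tables Named list of cohort tables; the first is taken as the
#'   reference for the age and log-weight columns.
#' @return Data frame with one row per statistic.
#' @export
descriptive_table <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("table_", seq_along(tables))
  }
  probs <- c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 0.99)
  summarize <- function(x) {
    c(mean = mean(x), sd = stats::sd(x),
      mad = stats::mad(x, constant = 1.4826), min = min(x),
      stats::quantile(x, probs), max = max(x))
  }
  ref <- tables[[1]]
  cols <- list(age_months = ref$age_months, log_weight = ref$log_weight)
  for (nm in names(tables)) cols[[paste0("height_", nm)]] <- tables[[nm]]$height_cm
  out <- data.frame(statistic = c("mean", "sd", "mad", "min",
                                  paste0("p", probs * 100), "max"))
  for (nm in names(cols)) out[[nm]] <- unname(summarize(cols[[nm]]))
  out
}

#' Run the full study grid
#'
#' Crosses the four error patterns with the two prevalences (eight
#' scenarios), runs every configured method on each, and assembles the
#' fixed-threshold metrics table, the AUC/Youden table, the descriptive
#' table (error-free plus the four patterns at 10% prevalence, as in the
#' study design) and a reproducibility manifest. Within a replicate all
#' scenarios share one error-free simulated cohort.
#'
#' @param n Cohort size (default 5000).
#' @param prevalences Error prevalences (default `c(0.02, 0.10)`).
#' @param patterns Error pattern names (default all four).
#' @param methods Methods to run (default all).
#' @param seed Master seed.
#' @param replicates Number of independent replicates (default 1).
#' @param stature_table,weight_table LMS tables (default builtin).
#' @param n_trials Starting subsets for MCD/MVE.
#' @return A `study_report` list: `metrics`, `auc`, `descriptive`,
#'   `manifest`, `scenarios` (list of `scenario_result`s).
#' @export
run_study <- function(n = 5000, prevalences = c(0.02, 0.10),
                      patterns = c("skip_last_digit", "swap_last_digits",
                                   "add_shift", "sample_first_percentile"),
                      methods = .all_methods, seed = 1, replicates = 1,
                      stature_table = builtin_lms_table("stature"),
                      weight_table = builtin_lms_table("weight"),
                      n_trials = 500) {
  grid <- expand.grid(pattern = patterns, prevalence = prevalences,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  seeds <- .derive_seeds(seed, replicates + nrow(grid))
  rep_seeds <- seeds[seq_len(replicates)]
  scen_seeds <- seeds[replicates + seq_len(nrow(grid))]

  metrics <- NULL; auc <- NULL; scenarios <- list(); manifest <- NULL
  base_tables <- lapply(rep_seeds, function(s) {
    simulate_growth(n, stature_table, weight_table, seed = s)
  })
  for (i in seq_len(nrow(grid))) {
    cfg <- scenario_config(grid$pattern[i], grid$prevalence[i], n = n,
                           methods = methods, seed = scen_seeds[i],
                           n_trials = n_trials)
    res <- run_scenario(cfg, stature_table, weight_table,
                        table = base_tables[[grid$replicate[i]]])
    key <- paste0(grid$pattern[i], "_", grid$prevalence[i] * 100, "pct",
                  if (replicates > 1) paste0("_rep", grid$replicate[i]) else "")
    scenarios[[key]] <- res
    mt <- res$metrics; mt$replicate <- grid$replicate[i]
    metrics <- rbind(metrics, mt)
    if (!is.null(res$auc)) {
      at <- res$auc; at$replicate <- grid$replicate[i]
      auc <- rbind(auc, at)
    }
    manifest <- rbind(manifest, data.frame(
      scenario = key, pattern = grid$pattern[i],
      prevalence = grid$prevalence[i], replicate = grid$replicate[i],
      n = n, seed = scen_seeds[i], sim_seed = rep_seeds[grid$replicate[i]],
      n_trials = n_trials))
  }

  desc <- NULL
  if (all(c("skip_last_digit", "swap_last_digits", "add_shift",
            "sample_first_percentile") %in% patterns) && 0.10 %in% prevalences) {
    tabs <- c(list(error_free = base_tables[[1]]),
              lapply(stats::setNames(patterns, patterns), function(p) {
                key <- paste0(p, "_10pct",
                              if (replicates > 1) "_rep1" else "")
                scenarios[[key]]$table
              }))
    desc <- descriptive_table(tabs)
  }
  structure(list(metrics = metrics, auc = auc, descriptive = desc,
                 manifest = manifest, scenarios = scenarios),
            class = "study_report")
}
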
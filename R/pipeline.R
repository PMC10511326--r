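# Formats, configuration and the staged pipeline tying generation ->
# drivers -> trajectory -> heatwave -> persistence -> scenarios into one
# reproducible run. Long-format CSV is the canonical interchange; config
# travels as YAML.

#' Read a long-format survey table
#'
#' Canonical schema: columns `reef_id`, `year`, `variable`, `value`; one
#' row per reef x year x benthic variable, percent covers bounded
#' `[0, 100]`, no duplicated reef-year-variable keys.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survey_table(x)
}

validate_survey_table <- function(x) {
  need <- c("reef_id", "year", "variable", "value")
  unknown <- setdiff(names(x), need)
  if (length(unknown)) stop_input("unknown column(s): %s", paste(unknown, collapse = ", "))
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_input("missing column(s): %s", paste(miss, collapse = ", "))
  cover_rows <- grepl("cover", x$variable)
  bad <- which(cover_rows & (x$value < 0 | x$value > 100))
  if (length(bad))
    stop_input("cover out of [0, 100] at row %d (%s, %s, %s)", bad[1],
               x$reef_id[bad[1]], x$year[bad[1]], x$variable[bad[1]])
  key <- paste(x$reef_id, x$year, x$variable)
  if (anyDuplicated(key))
    stop_input("duplicate reef-year-variable row: %s", key[anyDuplicated(key)])
  x
}

#' Write a long-format table to CSV
#'
#' @param x data.frame to write.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects stage list and module settings for a reproducible run. All
#' randomness is seeded from `seed`. `synth` holds arguments for
#' [synth_config()]; the remaining entries are module tuning parameters
#' with the package defaults.
#'
#' @param stages subset of `c("simulate", "drivers", "trajectory",
#'   "heatwave", "persistence", "scenarios")` in pipeline order.
#' @param seed integer seed for the whole run.
#' @param out_dir optional directory for stage output CSV/JSON files.
#' @param synth named list of [synth_config()] overrides.
#' @param n_perm PERMANOVA permutations.
#' @param trajectory_cutoff classification cutoff (percentage points).
#' @param max_predictors_gamm,max_predictors_ordinal dredge caps.
#' @param gamm_predictors,ordinal_predictors character vectors naming the
#'   candidate predictors for each stage (the hypothesis-driven sets after
#'   a-priori exclusions).
#' @param keep_preferences predictors preferred when pruning correlated
#'   pairs.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(stages = c("simulate", "drivers", "trajectory",
                                  "heatwave", "persistence", "scenarios"),
                       seed = 1, out_dir = NULL, synth = list(),
                       n_perm = 999, trajectory_cutoff = 3,
                       max_predictors_gamm = 5, max_predictors_ordinal = 4,
                       gamm_predictors = c("fish_total", "fish_scraper",
                                           "fish_grazer", "dhw_max",
                                           "wastewater_effluent",
                                           "urban_runoff", "chla",
                                           "sediment_input"),
                       ordinal_predictors = c("fish_total", "fish_scraper",
                                              "fish_grazer",
                                              "wastewater_effluent",
                                              "nutrient_input",
                                              "sediment_input",
                                              "urban_runoff", "wave_power",
                                              "gear_rank", "depth"),
                       keep_preferences = c("dhw_max", "rainfall_peak",
                                            "chla", "fish_scraper",
                                            "fish_grazer")) {
  order_all <- c("simulate", "drivers", "trajectory", "heatwave",
                 "persistence", "scenarios")
  unknown <- setdiff(stages, order_all)
  if (length(unknown)) stop_input("unknown stage(s): %s", paste(unknown, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  structure(list(stages = stages, seed = seed, out_dir = out_dir,
                 synth = synth, n_perm = n_perm,
                 trajectory_cutoff = trajectory_cutoff,
                 max_predictors_gamm = max_predictors_gamm,
                 max_predictors_ordinal = max_predictors_ordinal,
                 gamm_predictors = gamm_predictors,
                 ordinal_predictors = ordinal_predictors,
                 keep_preferences = keep_preferences),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [run_config()] object (`read_run_config`) or `path`
#'   (`write_run_config`).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @param config a `"run_config"`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# wide cover matrix (reef x year) for one benthic variable, rows ordered
# by reef_id so stages align with the bundle's reef table
cover_wide <- function(survey, variable = "coral_cover") {
  s <- survey[survey$variable == variable, ]
  w <- stats::reshape(s[, c("reef_id", "year", "value")], idvar = "reef_id",
                      timevar = "year", direction = "wide")
  w[order(w$reef_id), , drop = FALSE]
}

drop_constant <- function(df, log_fun = NULL) {
  sds <- vapply(df, stats::sd, numeric(1))
  drop <- names(df)[!is.finite(sds) | sds < 1e-10]
  if (length(drop) && !is.null(log_fun)) log_fun("dropped constant predictor(s)", drop)
  df[setdiff(names(df), drop)]
}

#' Run the staged land-sea analysis pipeline
#'
#' Executes the requested stages in order on a synthetic bundle:
#' `simulate` (generator), `drivers` (annual driver table), `trajectory`
#' (classification, jackknife contrasts, PERMANOVA, CAP), `heatwave`
#' (percentage-difference response, predictor preparation, coast sections,
#' AICc dredge, relative importance), `persistence` (reef-builder
#' categorization, ordinal dredge, Brant/LR/McFadden diagnostics) and
#' `scenarios` (management levers at percentile anchors of the observed
#' distributions). Later stages require the earlier ones. Every
#' exclusion (outlier, correlation prune, skipped candidate, constant
#' predictor) is appended to the result's `log`.
#'
#' @param config a [run_config()].
#' @return object of class `"reef_result_bundle"`: per-stage results,
#'   the config snapshot and the structured log.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop_input("config must be a run_config")
  res <- list(config = config, log = list())
  logit <- function(event, detail)
    res$log[[length(res$log) + 1L]] <<- list(event = event, detail = detail)
  need <- function(stage, field) {
    if (is.null(res[[field]]))
      stop_input("stage '%s' requires an earlier stage that produced '%s'",
                 stage, field)
  }

  if ("simulate" %in% config$stages) {
    scfg <- do.call(synth_config, c(config$synth, list(rng_seed = config$seed)))
    bundle <- generate_outcomes(generate_coast(scfg))
    res$bundle <- bundle
    res$survey_table <- bundle$survey_table
    res$driver_table <- bundle$driver_table
    res$synth_config <- scfg
  }

  if ("drivers" %in% config$stages) {
    need("drivers", "bundle")
    res$driver_table <- res$driver_table %||% build_driver_table(res$bundle)
  }

  scfg <- res$synth_config
  if ("trajectory" %in% config$stages) {
    need("trajectory", "driver_table")
    years <- scfg$years; hw <- scfg$heatwave_year
    cw <- cover_wide(res$survey_table)
    y_first <- min(res$survey_table$year)
    y_last <- max(res$survey_table$year[res$survey_table$year < hw])
    cls <- classify_trajectory(cw[[paste0("value.", y_first)]],
                               cw[[paste0("value.", y_last)]],
                               cutoff = config$trajectory_cutoff)
    labels <- data.frame(reef_id = cw$reef_id, delta = cls$delta,
                         class = cls$class)
    agg <- aggregate_drivers(res$driver_table, "trajectory", years, hw)
    drv <- drop_constant(agg[setdiff(names(agg), "reef_id")],
                         function(e, d) logit(e, d))
    pn <- labels$class %in% c("positive", "negative")
    x <- drv[pn, , drop = FALSE]
    lab <- droplevels(labels$class[pn])
    res$trajectory <- list(
      labels = labels,
      jackknife = jackknife_table(x, lab),
      permanova = permanova(x, lab, n_perm = config$n_perm),
      cap = cap(x, lab))
  }

  if ("heatwave" %in% config$stages) {
    need("heatwave", "driver_table")
    years <- scfg$years; hw <- scfg$heatwave_year
    cw <- cover_wide(res$survey_table)
    before <- cw[[paste0("value.", hw)]] %||% cw[[paste0("value.", hw - 1)]]
    after <- cw[[paste0("value.", hw + 1)]]
    valid <- which(before > 0)
    if (length(valid) < length(before))
      logit("zero-cover reefs excluded from the heatwave response",
            cw$reef_id[before <= 0])
    delta <- rep(NA_real_, length(before))
    delta[valid] <- percentage_difference(before[valid], after[valid])
    agg <- aggregate_drivers(res$driver_table, "heatwave", years, hw)
    agg <- agg[match(cw$reef_id, agg$reef_id), ]
    preds_raw <- drop_constant(
      agg[intersect(config$gamm_predictors, names(agg))],
      function(e, d) logit(e, d))
    preds_raw <- preds_raw[valid, , drop = FALSE]
    # outlier retention rule per predictor: drop reefs flagged anywhere
    drop_rows <- integer()
    for (v in names(preds_raw)) {
      fl <- outlier_filter_with_retention(preds_raw[[v]])
      if (length(fl$removed)) {
        logit("outlier removal", sprintf("%s: rows %s", v,
                                         paste(fl$removed, collapse = ",")))
        drop_rows <- union(drop_rows, fl$removed)
      }
    }
    keep_rows <- setdiff(seq_len(nrow(preds_raw)), drop_rows)
    sqrt_vars <- intersect(c("fish_total", "fish_scraper", "fish_grazer",
                             "fish_herbivore", "wastewater_effluent",
                             "urban_runoff", "nutrient_input", "chla",
                             "rainfall_peak"), names(preds_raw))
    fr_vars <- intersect("sediment_input", names(preds_raw))
    tp <- transform_predictors(preds_raw[keep_rows, , drop = FALSE],
                               sqrt_vars, fr_vars)
    pruned <- prune_correlated(tp, keep = config$keep_preferences)
    if (nrow(attr(pruned, "removals")))
      logit("correlation prune", attr(pruned, "removals"))
    keep_rows <- valid[keep_rows]  # back to full reef indices
    sections <- coast_sections(res$bundle$reefs$position_m[keep_rows])
    ms <- dredge_rank(delta[keep_rows], pruned, section = sections,
                      max_predictors = config$max_predictors_gamm)
    for (s in ms$skipped) logit("skipped candidate", s)
    res$heatwave <- list(response = delta, kept_rows = keep_rows,
                         predictors = pruned, sections = sections,
                         model_set = ms,
                         importance = relative_importance(ms),
                         transforms = attr(tp, "transforms"),
                         center = attr(tp, "center"), scale = attr(tp, "scale"))
  }

  if ("persistence" %in% config$stages) {
    need("persistence", "driver_table")
    years <- scfg$years; hw <- scfg$heatwave_year
    sv <- res$survey_table
    builder <- sv[sv$variable == "builder_cover" & sv$year == max(years), ]
    outcome <- categorize_cover(builder$value)
    agg <- aggregate_drivers(res$driver_table, "persistence", years, hw)
    agg <- agg[match(builder$reef_id, agg$reef_id), ]
    preds_raw <- drop_constant(
      agg[intersect(config$ordinal_predictors, names(agg))],
      function(e, d) logit(e, d))
    sqrt_vars <- intersect(c("fish_total", "wastewater_effluent",
                             "sediment_input", "nutrient_input"),
                           names(preds_raw))
    tp <- transform_predictors(preds_raw, sqrt_vars)
    pruned <- prune_correlated(tp, keep = config$keep_preferences)
    if (nrow(attr(pruned, "removals")))
      logit("correlation prune", attr(pruned, "removals"))
    ms <- dredge_ordinal(outcome, pruned,
                         max_predictors = config$max_predictors_ordinal)
    for (s in ms$skipped) logit("skipped candidate", s)
    top_fit <- ms$models[[1]]
    diagnostics <- list(
      mcfadden = ms$table$mcfadden[1],
      lr_vs_null = lr_test(fit_proportional_odds(outcome, NULL), top_fit),
      brant = if (length(top_fit$B) >= 1)
        tryCatch(brant_test(outcome,
                            pruned[, names(top_fit$B), drop = FALSE]),
                 error = function(e) conditionMessage(e)))
    res$persistence <- list(outcome = outcome, predictors = pruned,
                            raw_predictors = preds_raw, model_set = ms,
                            top_fit = top_fit, diagnostics = diagnostics,
                            transforms = attr(tp, "transforms"),
                            center = attr(tp, "center"),
                            scale = attr(tp, "scale"))
  }

  if ("scenarios" %in% config$stages) {
    need("scenarios", "persistence")
    pers <- res$persistence
    fit <- pers$top_fit
    levers <- intersect(c("fish_scraper", "wastewater_effluent"), names(fit$B))
    if (length(levers) < 1) {
      logit("scenarios skipped", "no management lever in the top model")
    } else {
      raw <- pers$raw_predictors
      anchor <- function(v, p) as.numeric(stats::quantile(raw[[v]], p, type = 7))
      hiB <- function(v) anchor(v, if (v == "fish_scraper") 0.92 else 0.95)
      loB <- function(v) anchor(v, 0.36)
      lever_hi <- vapply(levers, hiB, numeric(1))
      lever_lo <- vapply(levers, loB, numeric(1))
      good <- function(v, hi, lo) if (fit$B[[v]] > 0) hi else lo
      bad <- function(v, hi, lo) if (fit$B[[v]] > 0) lo else hi
      mk <- function(vals) stats::setNames(vals, levers)
      scen <- list(
        initial = mk(mapply(bad, levers, lever_hi, lever_lo)),
        combined = mk(mapply(good, levers, lever_hi, lever_lo)))
      if (length(levers) == 2) {
        scen$sea_only <- scen$initial; scen$sea_only[1] <- scen$combined[1]
        scen$land_only <- scen$initial; scen$land_only[2] <- scen$combined[2]
      }
      sp <- scenario_probabilities(fit, scen, pers$center, pers$scale,
                                   pers$transforms)
      folds <- if (length(levers) == 2)
        c(combined_vs_sea = fold_change(sp, "high", "combined", "sea_only"),
          combined_vs_land = fold_change(sp, "high", "combined", "land_only"))
      res$scenarios <- list(levers = levers, settings = scen, result = sp,
                            fold_high = folds)
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$survey_table))
      write_long_table(res$survey_table, file.path(config$out_dir, "survey.csv"))
    if (!is.null(res$driver_table))
      write_long_table(res$driver_table, file.path(config$out_dir, "drivers.csv"))
    if (!is.null(res$trajectory))
      write_long_table(res$trajectory$jackknife,
                       file.path(config$out_dir, "jackknife.csv"))
    if (!is.null(res$heatwave))
      write_long_table(res$heatwave$model_set$table,
                       file.path(config$out_dir, "heatwave_models.csv"))
    if (!is.null(res$persistence))
      write_long_table(res$persistence$model_set$table,
                       file.path(config$out_dir, "persistence_models.csv"))
  }
  structure(res, class = "reef_result_bundle")
}

#' @export
print.reef_result_bundle <- function(x, ...) {
  cat("reefpersist pipeline result; stages:",
      paste(x$config$stages, collapse = " -> "), "\n")
  if (!is.null(x$trajectory)) print(x$trajectory$permanova)
  if (!is.null(x$heatwave))
    cat(sprintf("heatwave: %d candidate models, top importance: %s\n",
                nrow(x$heatwave$model_set$table),
                paste(names(utils::head(x$heatwave$importance, 3)), collapse = ", ")))
  if (!is.null(x$persistence))
    cat(sprintf("persistence: top model [%s], McFadden R2 = %.3f\n",
                x$persistence$model_set$table$model[1],
                x$persistence$diagnostics$mcfadden))
  if (!is.null(x$scenarios))
    cat("scenario fold change (high):",
        paste(sprintf("%s %.2f", names(x$scenarios$fold_high),
                      x$scenarios$fold_high), collapse = ", "), "\n")
  invisible(x)
}
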
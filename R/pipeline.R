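# End-to-end orchestration: cohort (synthetic or CSV) -> exposure
# preparation -> Cox models -> lifespan and healthspan tables -> synergy ->
# composite-score minimum-dose outputs, with reproducibility metadata.

#' Pipeline configuration
#'
#' @param seed global seed; each stage draws from its own deterministic
#'   substream via [stage_seed()].
#' @param synth a [synth_config()] for synthetic input, or NULL.
#' @param cohort_csv path to a cohort CSV (the [generate_cohort()] dialect)
#'   for user-supplied input; exactly one of `synth`/`cohort_csv`.
#' @param rules an [exclusion_rules()].
#' @param covariates covariate set for all Cox models.
#' @param winsorisation `"percentile"` or `"tukey"`.
#' @param start_age life-table start age (default 65, the 5-year boundary
#'   nearest the emulated cohort's median age of 64).
#' @param calibration rate-adjustment mode, `"none"` or `"population"`.
#' @param mc_iterations,bootstrap_B Monte Carlo iterations (healthspan CIs)
#'   and bootstrap resamples (synergy CIs).
#' @param mortality_rates,disease_rates rate tables; defaults to the
#'   packaged synthetic schedules.
#' @param out_dir output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            synth = NULL,
                            cohort_csv = NULL,
                            rules = exclusion_rules(),
                            covariates = default_covariates(),
                            winsorisation = c("percentile", "tukey"),
                            start_age = 65,
                            calibration = "none",
                            mc_iterations = 10000,
                            bootstrap_B = 2000,
                            mortality_rates = NULL,
                            disease_rates = NULL,
                            out_dir = tempfile("spanlife_run")) {
  if (missing(seed)) stop_config("pipeline_config() requires a seed")
  if (is.null(synth) == is.null(cohort_csv))
    stop_config("exactly one of 'synth' or 'cohort_csv' must be given")
  winsorisation <- match.arg(winsorisation)
  structure(list(seed = as.integer(seed), synth = synth,
                 cohort_csv = cohort_csv, rules = rules,
                 covariates = covariates, winsorisation = winsorisation,
                 start_age = start_age, calibration = calibration,
                 mc_iterations = mc_iterations, bootstrap_B = bootstrap_B,
                 mortality_rates = mortality_rates %||%
                   synthetic_mortality_rates(),
                 disease_rates = disease_rates %||%
                   synthetic_disease_rates(),
                 out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL          # volatile; not part of the analytic identity
  simple <- rapply(cfg, function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace")
  jsonlite::write_json(simple, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

# Write a CSV without clobbering an existing file: versioned suffixes.
write_versioned <- function(df, path) {
  final <- path
  v <- 1
  while (file.exists(final)) {
    v <- v + 1
    final <- sub("(\\.[a-z]+)$", sprintf("_v%d\\1", v), path)
  }
  write.csv(df, final, row.names = FALSE)
  final
}

#' Run the full analysis pipeline
#'
#' Stages: synthetic cohort generation (or CSV load) -> exclusions and
#' exposure preparation -> joint-category Cox model and diagnostics ->
#' hazard-ratio table -> lifespan years-gained per category -> healthspan
#' (DFLE) years-gained with Monte Carlo CIs for selected categories ->
#' synergy indices with bootstrap CIs -> composite score, spline
#' dose-response, gain curves and minimum-dose tables.  Fully reproducible
#' from (config, seed); the config hash is recorded in the run report.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return A run report (list of class `run_report`): per-stage counts,
#'   warnings, results, and the output file manifest with MD5 checksums.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  warnings_log <- character()
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- "input"
  report <- withCallingHandlers(tryCatch({
    # -- input ---------------------------------------------------------
    cohort <- if (!is.null(config$synth)) {
      sc <- config$synth
      sc$seed <- stage_seed(config$seed, "synthgen")
      generate_cohort(sc)
    } else read.csv(config$cohort_csv)
    say("input: %d participants", nrow(cohort))

    # -- prep ----------------------------------------------------------
    stage <- "prep"
    ex <- apply_exclusions(cohort, config$rules)
    prep <- prepare_exposures(ex$cohort, mode = config$winsorisation)
    cohort <- prep$cohort
    say("prep: %d retained after exclusions; %d deaths", nrow(cohort),
        sum(cohort$death))

    # -- survmodel -----------------------------------------------------
    stage <- "survmodel"
    joint <- fit_cox_joint(cohort, covariates = config$covariates)
    hr_tab <- hazard_ratios(joint)
    diag <- ph_diagnostics(joint)
    say("survmodel: %d events; global PH p = %.3f", sum(cohort$death),
        diag$global$p)

    # -- lifetable -----------------------------------------------------
    stage <- "lifetable"
    mort <- config$mortality_rates
    gains <- years_gained_table(hr_tab, mort, start_age = config$start_age)

    # -- healthspan ----------------------------------------------------
    stage <- "healthspan"
    dis <- config$disease_rates
    mc <- mc_config(iterations = max(100, config$mc_iterations),
                    seed = stage_seed(config$seed, "healthspan"))
    hs_rows <- lapply(seq_len(nrow(hr_tab)), function(i) {
      if (is.na(hr_tab$hr[i]))
        return(data.frame(years_gained = NA, ci_low = NA, ci_high = NA))
      g <- dfle_gain_mc(hr_tab$hr[i], hr_tab$ci_low[i], hr_tab$ci_high[i],
                        mort, dis, mc, start_age = config$start_age)
      g[, c("years_gained", "ci_low", "ci_high")]
    })
    hs <- do.call(rbind, hs_rows)
    names(hs) <- paste0("healthspan_", c("years_gained", "ci_low", "ci_high"))
    gains <- cbind(gains, hs)

    # -- synergy -------------------------------------------------------
    stage <- "synergy"
    syn <- bootstrap_synergy(cohort, B = max(200, config$bootstrap_B),
                             seed = stage_seed(config$seed, "synergy"))
    say("synergy: RERI = %.3f (%.3f, %.3f)", syn$reri, syn$reri_lo,
        syn$reri_hi)

    # -- spanscore -----------------------------------------------------
    stage <- "spanscore"
    mappings <- default_mappings(prep$schemes)
    cohort$span_score <- composite_score(cohort$sleep_h, cohort$mvpa_min,
                                         cohort$dqs, mappings)
    weights <- derive_weights(hr_tab)
    spline <- fit_cox_rcs(cohort, "span_score",
                          covariates = config$covariates)
    curve <- lifespan_gain_curve(spline, mort, start_age = config$start_age)
    hs_curve <- lifespan_gain_curve(spline, mort, disease = dis,
                                    start_age = config$start_age)
    ref <- list(
      sleep = unname(quantile(cohort$sleep_h, 0.05, type = 7)),
      mvpa = unname(quantile(cohort$mvpa_min, 0.05, type = 7)),
      dqs = unname(quantile(cohort$dqs, 0.05, type = 7)))
    mdt <- minimum_dose_table(curve, weights, mappings, ref)
    mdt_hs <- minimum_dose_table(hs_curve, weights, mappings, ref)
    heat <- heatmap_grid(spline, mort, mappings,
                         fixed = list(sleep = median(cohort$sleep_h),
                                      mvpa = median(cohort$mvpa_min),
                                      dqs = median(cohort$dqs)),
                         start_age = config$start_age)
    say("spanscore: weights sleep %.2f / mvpa %.2f / dqs %.2f",
        weights[["sleep"]], weights[["mvpa"]], weights[["dqs"]])

    list(config_hash = config_hash(config), seed = config$seed,
         n_input = nrow(ex$cohort) + sum(ex$log$n_removed),
         n_analytic = nrow(cohort), n_events = sum(cohort$death),
         exclusion_log = ex$log, schemes = prep$schemes,
         hr_table = hr_tab, diagnostics = diag, gains = gains,
         synergy = syn, weights = weights, mappings = mappings,
         score_curve = curve, healthspan_curve = hs_curve,
         min_dose_lifespan = mdt, min_dose_healthspan = mdt_hs,
         heatmap = heat, reference = ref,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }, error = function(e) {
    stop_config("pipeline stage '%s' failed: %s", stage,
                conditionMessage(e))
  }), warning = function(w) { note(w); invokeRestart("muffleWarning") })
  report$warnings <- warnings_log
  class(report) <- "run_report"
  emit_outputs(report, config$out_dir)
}

#' Write pipeline outputs and the run report
#'
#' Emits the forest-plot input (per-category lifespan and healthspan
#' gains), the dose-response curves, the minimum-dose tables, the synergy
#' table, the exclusion log and a JSON run report whose manifest carries an
#' MD5 checksum per file.  Existing files are never silently overwritten;
#' rerunning into the same directory writes versioned `_v2` names.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return The report, with `$manifest` (data frame file/md5) attached.
#' @export
emit_outputs <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    if (is.null(df) || !nrow(as.data.frame(df))) return()
    files <<- c(files, write_versioned(as.data.frame(df),
                                       file.path(dir, name)))
  }
  put(report$gains, "forest_gains.csv")
  put(report$hr_table, "hr_table.csv")
  put(report$score_curve, "lifespan_dose_response.csv")
  put(report$healthspan_curve, "healthspan_dose_response.csv")
  put(report$min_dose_lifespan, "minimum_dose_lifespan.csv")
  put(report$min_dose_healthspan, "minimum_dose_healthspan.csv")
  put(report$synergy, "synergy.csv")
  put(report$exclusion_log, "exclusion_log.csv")
  put(report$heatmap, "heatmap_grid.csv")
  put(report$schemes, "tertile_schemes.csv")
  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report$manifest <- manifest
  rj <- list(config_hash = report$config_hash, seed = report$seed,
             n_input = report$n_input, n_analytic = report$n_analytic,
             n_events = report$n_events,
             weights = as.list(report$weights),
             warnings = report$warnings, manifest = manifest,
             elapsed_s = report$elapsed_s)
  jf <- file.path(dir, "run_report.json")
  v <- 1
  while (file.exists(jf)) { v <- v + 1
    jf <- file.path(dir, sprintf("run_report_v%d.json", v)) }
  jsonlite::write_json(rj, jf, auto_unbox = TRUE, digits = NA, force = TRUE)
  report$report_path <- jf
  invisible(report)
}
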
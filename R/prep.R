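# Exposure cleaning and categorisation: winsorisation, Tukey fences,
# tertiles, the 27-category joint exposure variable, and exclusion rules.

#' Winsorise a numeric series at percentile bounds
#'
#' Values below the lower percentile are replaced by the lower percentile
#' value and values above the upper percentile by the upper percentile value.
#' Sample size and ordering are preserved; nothing is dropped.  Percentiles
#' use the linear-interpolation definition (R `quantile` type 7), which the
#' bounds reported by [tertile_scheme()] inherit.
#'
#' @param x numeric vector (NAs are passed through untouched).
#' @param lower_pct,upper_pct percentile bounds in `[0, 100]`,
#'   `lower_pct < upper_pct`.  Defaults 2.5 and 97.5.
#' @return Numeric vector of the same length as `x`, with attributes
#'   `lower` and `upper` holding the replacement bounds.
#' @examples
#' winsorise(1:100)            # clamps to [3.475, 97.525]
#' winsorise(c(1, 50, 99), 0, 100)  # no-op bounds
#' @export
winsorise <- function(x, lower_pct = 2.5, upper_pct = 97.5) {
  if (!is.numeric(x) || sum(!is.na(x)) < 2L)
    stop_config("winsorise() needs at least 2 non-missing numeric values")
  if (!(lower_pct >= 0 && upper_pct <= 100 && lower_pct < upper_pct))
    stop_config("need 0 <= lower_pct < upper_pct <= 100")
  b <- quantile(x, c(lower_pct, upper_pct) / 100, na.rm = TRUE,
                names = FALSE, type = 7)
  out <- pmin(pmax(x, b[1]), b[2])
  attr(out, "lower") <- b[1]
  attr(out, "upper") <- b[2]
  out
}

#' Tukey-fence outlier bounds
#'
#' Returns `Q1 - k*IQR` and `Q3 + k*IQR`, the alternative winsorisation
#' thresholds used in sensitivity analyses.  Quartiles use the
#' linear-interpolation convention (type 7).
#'
#' @param x numeric vector with at least 4 non-missing values.
#' @param k fence multiplier, default 1.5.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
tukey_fence_bounds <- function(x, k = 1.5) {
  if (!is.numeric(x) || sum(!is.na(x)) < 4L)
    stop_config("tukey_fence_bounds() needs at least 4 non-missing values")
  if (!is.numeric(k) || k <= 0) stop_config("k must be > 0")
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  if (iqr == 0) warning("IQR is zero; fences collapse to the common quartile")
  c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
}

#' Assign tertiles to an exposure
#'
#' Cut points are the 1/3 and 2/3 percentiles (linear interpolation) of the
#' supplied values, which are expected to be already winsorised.  Values
#' exactly at a cut point go to the lower tertile.
#'
#' @param x numeric vector with at least 3 distinct non-missing values.
#' @param name exposure label recorded in the scheme.
#' @return A list with `scheme` (a one-row data frame: exposure name, the
#'   two cut points and the observed range) and `labels` (factor
#'   `low`/`medium`/`high`, NA where `x` is NA).
#' @export
assign_tertiles <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(unique(x[!is.na(x)])) < 3L)
    stop_config("assign_tertiles() needs >= 3 distinct values")
  cuts <- quantile(x, c(1, 2) / 3, na.rm = TRUE, names = FALSE, type = 7)
  if (cuts[1] >= cuts[2])
    stop_config("degenerate tertile cuts (massive ties); cannot form tertiles")
  frac_tied <- mean(x %in% cuts, na.rm = TRUE)
  if (frac_tied > 0.05)
    warning(sprintf("%.1f%% of values lie exactly on a tertile cut; ties go low",
                    100 * frac_tied))
  labels <- cut(x, breaks = c(-Inf, cuts, Inf),
                labels = c("low", "medium", "high"), right = TRUE)
  scheme <- data.frame(exposure = name,
                       cut_low_med = cuts[1], cut_med_high = cuts[2],
                       observed_min = min(x, na.rm = TRUE),
                       observed_max = max(x, na.rm = TRUE),
                       stringsAsFactors = FALSE)
  list(scheme = scheme, labels = labels)
}

#' Build the 27-category joint exposure variable
#'
#' Maps each (sleep, MVPA, diet) tertile triple to an index 1..27.  Index 1
#' is the all-low reference; index 27 is all-high.  Diet varies fastest,
#' then MVPA, then sleep: `index = 9*(sleep-1) + 3*(mvpa-1) + diet`.
#' The mapping is a bijection and round-trips via [joint_category_levels()].
#'
#' @param sleep_t,mvpa_t,diet_t tertile labels (factor or character
#'   `low`/`medium`/`high`), equal length.
#' @return Data frame with `index` (integer, NA when any label is missing —
#'   such rows are flagged for exclusion from modelling), plus the three
#'   tertile columns as factors.
#' @export
make_joint_categories <- function(sleep_t, mvpa_t, diet_t) {
  lv <- c("low", "medium", "high")
  s <- as.integer(factor(as.character(sleep_t), levels = lv))
  m <- as.integer(factor(as.character(mvpa_t), levels = lv))
  d <- as.integer(factor(as.character(diet_t), levels = lv))
  if (length(s) != length(m) || length(m) != length(d))
    stop_config("tertile label vectors must have equal length")
  idx <- 9L * (s - 1L) + 3L * (m - 1L) + d
  data.frame(index = idx,
             sleep_t = factor(lv[s], levels = lv),
             mvpa_t = factor(lv[m], levels = lv),
             diet_t = factor(lv[d], levels = lv))
}

#' Enumerate the 27 joint categories
#'
#' @return Data frame of the full index -> (sleep, mvpa, diet) mapping.
#' @export
joint_category_levels <- function() {
  lv <- c("low", "medium", "high")
  g <- expand.grid(diet_t = 1:3, mvpa_t = 1:3, sleep_t = 1:3)
  data.frame(index = 9L * (g$sleep_t - 1L) + 3L * (g$mvpa_t - 1L) + g$diet_t,
             sleep_t = factor(lv[g$sleep_t], levels = lv),
             mvpa_t = factor(lv[g$mvpa_t], levels = lv),
             diet_t = factor(lv[g$diet_t], levels = lv))[order(
               9L * (g$sleep_t - 1L) + 3L * (g$mvpa_t - 1L) + g$diet_t), ]
}

#' Exclusion rules for cohort preparation
#'
#' @param drop_death_within_years remove participants who died within this
#'   many years of follow-up start (reverse-causation guard); default 1.
#' @param drop_preexisting_disease remove participants with any of the five
#'   conditions at baseline (requires a `preexisting` 0/1 column).
#' @param drop_poor_self_rated_health requires a `poor_health` 0/1 column.
#' @param drop_underweight_bmi requires a `bmi` column; removes BMI < 18.5.
#' @param min_valid_days minimum device wear days (requires `valid_days`);
#'   default 3; set to 0 to disable.
#' @param require_weekend_day requires a `weekend_day` 0/1 column.
#' @return A list of class `exclusion_rules`.
#' @export
exclusion_rules <- function(drop_death_within_years = 1,
                            drop_preexisting_disease = FALSE,
                            drop_poor_self_rated_health = FALSE,
                            drop_underweight_bmi = FALSE,
                            min_valid_days = 0,
                            require_weekend_day = FALSE) {
  stopifnot(drop_death_within_years >= 0, min_valid_days >= 0)
  structure(list(drop_death_within_years = drop_death_within_years,
                 drop_preexisting_disease = drop_preexisting_disease,
                 drop_poor_self_rated_health = drop_poor_self_rated_health,
                 drop_underweight_bmi = drop_underweight_bmi,
                 min_valid_days = min_valid_days,
                 require_weekend_day = require_weekend_day),
            class = "exclusion_rules")
}

#' Apply exclusion rules to a cohort
#'
#' Rules are applied in a fixed, documented order: data-validity rules
#' (wear days, weekend day) first, then the early-death window, then
#' health-status rules.  The order affects only the per-rule counts in the
#' log, not the final analytic set.
#'
#' @param cohort cohort data frame (see [generate_cohort()] for the dialect).
#' @param rules an [exclusion_rules()] object.
#' @return List with `cohort` (rows retained) and `log` (data frame of rule,
#'   n_removed, n_remaining in application order).
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  stopifnot(inherits(rules, "exclusion_rules"), is.data.frame(cohort))
  need_col <- function(col, rule) {
    if (!col %in% names(cohort))
      stop_config("exclusion rule '%s' needs column '%s', which is absent",
                  rule, col)
  }
  log <- data.frame(rule = character(), n_removed = integer(),
                    n_remaining = integer(), stringsAsFactors = FALSE)
  drop_rows <- function(keep, rule) {
    n0 <- nrow(cohort)
    cohort <<- cohort[keep, , drop = FALSE]
    log <<- rbind(log, data.frame(rule = rule, n_removed = n0 - nrow(cohort),
                                  n_remaining = nrow(cohort)))
  }
  if (rules$min_valid_days > 0) {
    need_col("valid_days", "min_valid_days")
    drop_rows(cohort$valid_days >= rules$min_valid_days, "min_valid_days")
  }
  if (isTRUE(rules$require_weekend_day)) {
    need_col("weekend_day", "require_weekend_day")
    drop_rows(cohort$weekend_day == 1, "require_weekend_day")
  }
  if (rules$drop_death_within_years > 0) {
    need_col("death", "drop_death_within_years")
    need_col("followup_y", "drop_death_within_years")
    drop_rows(!(cohort$death == 1 &
                  cohort$followup_y < rules$drop_death_within_years),
              "drop_death_within_years")
  }
  if (isTRUE(rules$drop_preexisting_disease)) {
    need_col("preexisting", "drop_preexisting_disease")
    drop_rows(cohort$preexisting == 0, "drop_preexisting_disease")
  }
  if (isTRUE(rules$drop_poor_self_rated_health)) {
    need_col("poor_health", "drop_poor_self_rated_health")
    drop_rows(cohort$poor_health == 0, "drop_poor_self_rated_health")
  }
  if (isTRUE(rules$drop_underweight_bmi)) {
    need_col("bmi", "drop_underweight_bmi")
    drop_rows(cohort$bmi >= 18.5, "drop_underweight_bmi")
  }
  list(cohort = cohort, log = log)
}

#' Prepare cohort exposures for modelling
#'
#' Winsorises the three exposures (percentile bounds or Tukey fences),
#' assigns tertiles on the winsorised values (sexes pooled), and attaches
#' the 27-category joint exposure.
#'
#' @param cohort cohort data frame with `sleep_h`, `mvpa_min`, `dqs`.
#' @param mode `"percentile"` (2.5/97.5, default) or `"tukey"`.
#' @param lower_pct,upper_pct percentile bounds when `mode = "percentile"`.
#' @param tukey_k fence multiplier when `mode = "tukey"`.
#' @return List with `cohort` (winsorised exposures, `*_t` tertile columns,
#'   `joint_index`), `schemes` (per-exposure tertile schemes with
#'   winsorisation bounds) — the winsorised min/max are the endpoints of the
#'   printed tertile ranges.
#' @export
prepare_exposures <- function(cohort, mode = c("percentile", "tukey"),
                              lower_pct = 2.5, upper_pct = 97.5,
                              tukey_k = 1.5) {
  mode <- match.arg(mode)
  stopifnot(all(c("sleep_h", "mvpa_min", "dqs") %in% names(cohort)))
  wins <- function(x) {
    if (mode == "percentile") return(winsorise(x, lower_pct, upper_pct))
    b <- tukey_fence_bounds(x, tukey_k)
    out <- pmin(pmax(x, b[1]), b[2])
    attr(out, "lower") <- b[[1]]; attr(out, "upper") <- b[[2]]
    out
  }
  schemes <- list()
  for (v in c("sleep_h", "mvpa_min", "dqs")) {
    w <- wins(cohort[[v]])
    cohort[[v]] <- as.numeric(w)
    t <- assign_tertiles(as.numeric(w), name = v)
    cohort[[paste0(sub("_h$|_min$", "", v), "_t")]] <- t$labels
    sc <- t$scheme
    sc$winsor_lower <- attr(w, "lower"); sc$winsor_upper <- attr(w, "upper")
    schemes[[v]] <- sc
  }
  jc <- make_joint_categories(cohort$sleep_t, cohort$mvpa_t, cohort$dqs_t)
  cohort$joint_index <- jc$index
  list(cohort = cohort, schemes = do.call(rbind, schemes))
}
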
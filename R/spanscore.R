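# The composite lifestyle (SPAN) score: each behaviour contributes a
# 0-100/3 subscore via a piecewise-linear mapping anchored at its
# theoretically optimal value and the winsorised extremes; the three
# subscores sum to a 0-100 score.  Model-derived behaviour weights then
# invert score increments into native-unit behaviour increments, producing
# the minimum-dose tables.

#' Behaviour-to-subscore mapping
#'
#' @param optimal exposure value of maximal subscore (100/3): the mortality
#'   nadir for sleep (7.5 h/day), the curve peak for MVPA, the maximum for
#'   a monotone behaviour such as diet quality.
#' @param lower,upper winsorised exposure extremes (the subscore floor(s)).
#' @param shape `"u_shaped"`: subscore decays linearly with absolute
#'   deviation from `optimal`, reaching 0 at whichever winsorised extreme
#'   bounds that side; `"saturating"`: linear from `lower` up to `optimal`,
#'   flat (maximal) beyond; `"monotone"`: linear from `lower` to `upper`
#'   with `optimal` at `upper`.
#' @param name behaviour label.
#' @return Object of class `score_mapping`.
#' @export
score_mapping <- function(optimal, lower, upper,
                          shape = c("u_shaped", "saturating", "monotone"),
                          name = "behaviour") {
  shape <- match.arg(shape)
  if (shape == "monotone") optimal <- upper
  if (lower >= upper) stop_config("need lower < upper")
  if (optimal <= lower && shape == "u_shaped")
    stop_config("u_shaped mapping needs lower < optimal")
  if (optimal == lower) stop_config("floor equals optimal; mapping degenerate")
  structure(list(optimal = optimal, lower = lower, upper = upper,
                 shape = shape, name = name), class = "score_mapping")
}

SUBSCORE_MAX <- 100 / 3

#' Subscore of one behaviour
#'
#' @param value exposure value(s), native units.
#' @param mapping a [score_mapping()].
#' @return Subscore(s) in `[0, 100/3]`; exactly 100/3 at the optimum and 0
#'   at the winsorised floor.
#' @export
behaviour_subscore <- function(value, mapping) {
  stopifnot(inherits(mapping, "score_mapping"))
  o <- mapping$optimal
  s <- switch(mapping$shape,
    u_shaped = ifelse(value <= o,
                      SUBSCORE_MAX * (value - mapping$lower) / (o - mapping$lower),
                      SUBSCORE_MAX * (mapping$upper - value) / (mapping$upper - o)),
    saturating = ifelse(value >= o, SUBSCORE_MAX,
                        SUBSCORE_MAX * (value - mapping$lower) /
                          (o - mapping$lower)),
    monotone = SUBSCORE_MAX * (value - mapping$lower) /
      (mapping$upper - mapping$lower))
  pmin(pmax(s, 0), SUBSCORE_MAX)
}

#' Default score mappings from tertile/winsorisation schemes
#'
#' @param schemes the `schemes` data frame from [prepare_exposures()].
#' @param sleep_optimal sleep nadir, h/day (default 7.5).
#' @param mvpa_optimal MVPA peak, min/day (default 50; values beyond
#'   saturate).
#' @return Named list of [score_mapping()]s for sleep, mvpa, dqs.
#' @export
default_mappings <- function(schemes, sleep_optimal = 7.5,
                             mvpa_optimal = 50) {
  g <- function(v, col) schemes[schemes$exposure == v, col]
  list(
    sleep = score_mapping(sleep_optimal, g("sleep_h", "winsor_lower"),
                          g("sleep_h", "winsor_upper"), "u_shaped", "sleep"),
    mvpa = score_mapping(min(mvpa_optimal, g("mvpa_min", "winsor_upper")),
                         g("mvpa_min", "winsor_lower"),
                         g("mvpa_min", "winsor_upper"), "saturating", "mvpa"),
    dqs = score_mapping(g("dqs", "winsor_upper"), g("dqs", "winsor_lower"),
                        g("dqs", "winsor_upper"), "monotone", "dqs"))
}

#' Composite 0-100 score
#'
#' Sum of the three behaviour subscores (nominally equally weighted:
#' each behaviour spans a third of the scale).  All-optimal values score
#' exactly 100; all-floor values exactly 0.
#'
#' @param sleep_h,mvpa_min,dqs exposure vectors.
#' @param mappings named list with `sleep`, `mvpa`, `dqs` mappings.
#' @return Numeric score(s) in `[0, 100]`.
#' @export
composite_score <- function(sleep_h, mvpa_min, dqs, mappings) {
  if (anyNA(sleep_h) || anyNA(mvpa_min) || anyNA(dqs))
    stop_config("composite_score() requires all three behaviour values")
  behaviour_subscore(sleep_h, mappings$sleep) +
    behaviour_subscore(mvpa_min, mappings$mvpa) +
    behaviour_subscore(dqs, mappings$dqs)
}

#' Behaviour-specific weights from the joint-category hazard ratios
#'
#' For each behaviour, the marginal log-HR span is the mean absolute
#' difference between its high- and low-tertile log hazard ratios across
#' the 9 combinations of the other two behaviours' tertiles; weights are
#' the spans normalised to sum to 1.  If every span is zero the weights
#' fall back to uniform with a warning.
#'
#' @param hr_table output of [hazard_ratios()] on a `cox_joint_fit`
#'   (27 rows; missing HRs are skipped pairwise).
#' @return Named numeric vector `c(sleep, mvpa, dqs)` on the unit simplex.
#' @export
derive_weights <- function(hr_table) {
  lhr <- log(hr_table$hr)
  span_of <- function(var) {
    others <- setdiff(c("sleep_t", "mvpa_t", "diet_t"), var)
    combos <- expand.grid(a = c("low", "medium", "high"),
                          b = c("low", "medium", "high"))
    d <- mapply(function(a, b) {
      hi <- lhr[hr_table[[var]] == "high" & hr_table[[others[1]]] == a &
                  hr_table[[others[2]]] == b]
      lo <- lhr[hr_table[[var]] == "low" & hr_table[[others[1]]] == a &
                  hr_table[[others[2]]] == b]
      if (length(hi) == 1 && length(lo) == 1) abs(hi - lo) else NA_real_
    }, combos$a, combos$b)
    mean(d, na.rm = TRUE)
  }
  spans <- c(sleep = span_of("sleep_t"), mvpa = span_of("mvpa_t"),
             dqs = span_of("diet_t"))
  spans[is.na(spans)] <- 0
  if (sum(spans) == 0) {
    warning("all marginal log-HR spans are zero; falling back to uniform weights")
    return(c(sleep = 1, mvpa = 1, dqs = 1) / 3)
  }
  spans / sum(spans)
}

# Invert one behaviour's mapping: native value whose subscore is `s`,
# approached from the reference side (moving toward the optimum).
invert_subscore <- function(s, mapping, reference) {
  o <- mapping$optimal
  s <- pmin(pmax(s, 0), SUBSCORE_MAX)
  if (mapping$shape == "u_shaped" && reference > o)
    return(mapping$upper - s * (mapping$upper - o) / SUBSCORE_MAX)
  lo <- mapping$lower
  top <- if (mapping$shape == "monotone") mapping$upper else o
  lo + s * (top - lo) / SUBSCORE_MAX
}

#' Invert a composite-score increment into behaviour increments
#'
#' Allocates `delta_score * w_b` subscore points to behaviour `b`, capped
#' at each behaviour's remaining headroom above the reference (overflow is
#' reallocated to the other behaviours in proportion to their remaining
#' headroom, and logged), then converts each allocation to native units by
#' inverting that behaviour's mapping upward from the reference.  The
#' round-trip `score(reference + increments) - score(reference)` equals
#' `delta_score` to within 1e-6 whenever the total headroom allows.
#'
#' @param delta_score score points to add (>= 0).
#' @param weights a unit-simplex weight vector (`sleep`, `mvpa`, `dqs`).
#' @param mappings list of the three [score_mapping()]s.
#' @param reference named list/vector of reference exposure values
#'   (`sleep`, `mvpa`, `dqs`), typically the 5th percentiles.
#' @return One-row data frame: `delta_score`, `delta_sleep_min` (min/day),
#'   `delta_mvpa_min` (min/day), `delta_dqs` (DQS points), `reallocated`
#'   (subscore points moved due to headroom overflow).
#' @export
invert_score_increment <- function(delta_score, weights, mappings, reference) {
  if (delta_score < 0) stop_config("delta_score must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8) stop_config("weights must sum to 1")
  bs <- c(sleep = behaviour_subscore(reference[["sleep"]], mappings$sleep),
          mvpa = behaviour_subscore(reference[["mvpa"]], mappings$mvpa),
          dqs = behaviour_subscore(reference[["dqs"]], mappings$dqs))
  headroom <- SUBSCORE_MAX - bs
  if (delta_score > sum(headroom) + 1e-9)
    stop_config("delta_score %.2f exceeds total headroom %.2f above the reference",
                delta_score, sum(headroom))
  alloc <- delta_score * weights[c("sleep", "mvpa", "dqs")]
  names(alloc) <- c("sleep", "mvpa", "dqs")
  reallocated <- 0
  for (iter in 1:10) {          # redistribute overflow proportionally
    over <- pmax(alloc - headroom, 0)
    if (sum(over) < 1e-12) break
    reallocated <- reallocated + sum(over)
    alloc <- pmin(alloc, headroom)
    room <- headroom - alloc
    if (sum(room) < sum(over) - 1e-9) break
    alloc <- alloc + sum(over) * (if (sum(room) > 0) room / sum(room) else 0)
  }
  newval <- c(
    sleep = invert_subscore(bs[["sleep"]] + alloc[["sleep"]], mappings$sleep,
                            reference[["sleep"]]),
    mvpa = invert_subscore(bs[["mvpa"]] + alloc[["mvpa"]], mappings$mvpa,
                           reference[["mvpa"]]),
    dqs = invert_subscore(bs[["dqs"]] + alloc[["dqs"]], mappings$dqs,
                          reference[["dqs"]]))
  data.frame(delta_score = delta_score,
             delta_sleep_min = (newval[["sleep"]] - reference[["sleep"]]) * 60,
             delta_mvpa_min = newval[["mvpa"]] - reference[["mvpa"]],
             delta_dqs = newval[["dqs"]] - reference[["dqs"]],
             reallocated = reallocated)
}

#' Lifespan (or healthspan) gain curve over the composite score
#'
#' Evaluates the spline hazard-ratio curve on a score grid and converts
#' each point to years gained versus the reference score through the
#' hazard-ratio-adjusted life table; CIs propagate the HR confidence bounds
#' through the same monotone map.  Passing `disease` routes the same
#' machinery through the disease-free life table to give the healthspan
#' curve.
#'
#' @param spline a `cox_rcs_fit` on the composite score.
#' @param rates [baseline_rates()] mortality table.
#' @param grid score grid (default 0.5-point steps over the fitted range).
#' @param start_age life-table start age.
#' @param disease optional [disease_rates()]; when supplied the gain is in
#'   disease-free years (HR applied to both mortality and incidence).
#' @param mode prevalence handling for the healthspan path.
#' @return Data frame: `score`, `hr`, `years_gained`, `ci_low`, `ci_high`.
#' @export
lifespan_gain_curve <- function(spline, rates, grid = NULL,
                                start_age = rates$age_start[1],
                                disease = NULL, mode = "radix") {
  grid <- grid %||% seq(ceiling(spline$range[1] * 2) / 2,
                        floor(spline$range[2] * 2) / 2, by = 0.5)
  hrs <- hazard_ratios(spline, grid = grid)
  gain_at <- if (is.null(disease)) {
    e_ref <- life_expectancy(build_life_table(rates, start_age))
    function(h) life_expectancy(build_life_table(
      adjust_rates(rates, h), start_age)) - e_ref
  } else {
    d_ref <- dfle_at(1, rates, disease, start_age, mode)
    function(h) dfle_at(h, rates, disease, start_age, mode) - d_ref
  }
  out <- data.frame(score = grid, hr = hrs$hr,
                    years_gained = vapply(hrs$hr, gain_at, numeric(1)),
                    ci_low = vapply(hrs$ci_high, gain_at, numeric(1)),
                    ci_high = vapply(hrs$ci_low, gain_at, numeric(1)))
  attr(out, "reference_score") <- spline$reference_value
  out
}

#' Minimum-dose table
#'
#' The first row is the smallest grid score at which the years-gained CI
#' excludes zero (`ci_low > 0`) — the minimum dose; subsequent rows give,
#' for each requested whole-year target, the smallest score achieving it,
#' decomposed into combined behaviour increments via
#' [invert_score_increment()].  Single-behaviour equivalent columns are
#' solved on each behaviour's own gain curve when supplied; unreachable
#' targets are reported missing with the reason (mirroring empty cells).
#'
#' @param gain_curve output of [lifespan_gain_curve()].
#' @param weights,mappings,reference passed to [invert_score_increment()].
#' @param targets years-gained targets (default 1:10).
#' @param single_curves optional named list (`sleep`, `mvpa`, `dqs`) of
#'   per-behaviour gain curves, each a data frame with the behaviour's
#'   native value in column `x` and `years_gained`; used for the
#'   single-behaviour equivalent columns.  Native reference values are
#'   taken from `reference`.
#' @return Data frame of class `minimum_dose_table`; zero rows when no
#'   grid score is significant.
#' @export
minimum_dose_table <- function(gain_curve, weights, mappings, reference,
                               targets = 1:10, single_curves = NULL) {
  ref_score <- attr(gain_curve, "reference_score") %||% gain_curve$score[1]
  sig <- which(gain_curve$ci_low > 0)
  rows <- list()
  miss_row <- function(target, note)
    data.frame(target_years = target, reachable = FALSE,
               years_gained = NA, gain_ci_low = NA, gain_ci_high = NA,
               delta_score = NA, delta_sleep_min = NA, delta_mvpa_min = NA,
               delta_dqs = NA, reallocated = NA, note = note)
  add_row <- function(target, i, reachable, note = NA_character_) {
    if (!reachable) return(miss_row(target, note))
    ds <- max(gain_curve$score[i] - ref_score, 0)
    dec <- tryCatch(invert_score_increment(ds, weights, mappings, reference),
                    error = function(e) NULL)
    if (is.null(dec))
      return(miss_row(target,
                      "score increment exceeds headroom above the reference"))
    cbind(data.frame(target_years = target, reachable = TRUE,
                     years_gained = gain_curve$years_gained[i],
                     gain_ci_low = gain_curve$ci_low[i],
                     gain_ci_high = gain_curve$ci_high[i]),
          dec, data.frame(note = note))
  }
  if (length(sig) == 0)
    return(structure(data.frame(), class = c("minimum_dose_table",
                                             "data.frame")))
  i_min <- min(sig)
  rows[["min"]] <- add_row(gain_curve$years_gained[i_min], i_min, TRUE,
                           "minimum significant dose")
  for (tg in targets) {
    if (gain_curve$years_gained[i_min] >= tg) next  # below the minimum dose
    hit <- which(gain_curve$years_gained >= tg)
    if (length(hit) == 0) {
      rows[[as.character(tg)]] <-
        add_row(tg, NA, FALSE, "target unreachable on the score range")
    } else {
      rows[[as.character(tg)]] <- add_row(tg, min(hit), TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(single_curves)) {
    for (b in c("sleep", "mvpa", "dqs")) {
      cn <- paste0("single_", b)
      out[[cn]] <- NA_real_
      cv <- single_curves[[b]]
      if (is.null(cv)) next
      refv <- reference[[b]]
      for (r in seq_len(nrow(out))) {
        if (!out$reachable[r]) next
        tg <- if (is.na(out$target_years[r])) next else out$target_years[r]
        hit <- which(cv$years_gained >= tg & cv$x >= refv)
        if (length(hit)) out[[cn]][r] <- cv$x[min(hit)] - refv
      }
      if (b == "sleep") out[[cn]] <- out[[cn]] * 60   # hours -> min/day
    }
  }
  structure(out, class = c("minimum_dose_table", "data.frame"))
}

#' Years-gained heatmap grid over two behaviours
#'
#' Rectangular grid over two behaviours' winsorised ranges with the third
#' behaviour fixed at its median; each cell is the years gained versus the
#' 5th-percentile reference, obtained by scoring the cell, evaluating the
#' fitted score-HR spline and passing the HR through the life table.
#'
#' @param spline a `cox_rcs_fit` on the composite score.
#' @param rates mortality [baseline_rates()].
#' @param mappings score mappings.
#' @param vary character pair to vary, e.g. `c("sleep", "mvpa")`.
#' @param fixed named values of all three behaviours; the non-varied one is
#'   held at its value here (typically the median), the varied ones supply
#'   the reference corner.
#' @param n_grid grid resolution per axis (default 25).
#' @param start_age life-table start age.
#' @return Long-format data frame: the two varied behaviours' values,
#'   `score`, `years_gained`.
#' @export
heatmap_grid <- function(spline, rates, mappings, vary = c("sleep", "mvpa"),
                         fixed, n_grid = 25,
                         start_age = rates$age_start[1]) {
  stopifnot(length(vary) == 2, all(vary %in% c("sleep", "mvpa", "dqs")))
  rng <- function(b) c(mappings[[b]]$lower, mappings[[b]]$upper)
  g1 <- seq(rng(vary[1])[1], rng(vary[1])[2], length.out = n_grid)
  g2 <- seq(rng(vary[2])[1], rng(vary[2])[2], length.out = n_grid)
  cells <- expand.grid(v1 = g1, v2 = g2)
  vals <- list(sleep = fixed[["sleep"]], mvpa = fixed[["mvpa"]],
               dqs = fixed[["dqs"]])
  score <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    vals[[vary[1]]] <- cells$v1[i]
    vals[[vary[2]]] <- cells$v2[i]
    score[i] <- composite_score(vals$sleep, vals$mvpa, vals$dqs, mappings)
  }
  score <- pmin(pmax(score, spline$range[1]), spline$range[2])
  hrs <- hazard_ratios(spline, grid = score)
  e_ref <- life_expectancy(build_life_table(rates, start_age))
  yg <- vapply(hrs$hr, function(h) life_expectancy(
    build_life_table(adjust_rates(rates, h), start_age)) - e_ref, numeric(1))
  out <- data.frame(cells$v1, cells$v2, score = score, years_gained = yg)
  names(out)[1:2] <- vary
  out
}
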
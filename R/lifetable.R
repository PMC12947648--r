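# Period life tables: Chiang construction, hazard-ratio adjustment of
# age-specific mortality rates, and years-of-life-expectancy gained.

#' Construct a baseline age-specific rate table
#'
#' @param age_start integer vector of interval start ages, strictly
#'   increasing and contiguous (each start equals the previous start plus
#'   its width).  The final interval is open-ended.
#' @param width interval widths in years; the width of the final (open)
#'   interval is ignored and stored as `Inf`.
#' @param m mortality (or exit) rates per person-year, one per interval.
#' @param sex optional stratum label (recycled).
#' @return Data frame of class `baseline_rates`.
#' @export
baseline_rates <- function(age_start, width, m, sex = NA_character_) {
  stopifnot(length(age_start) == length(m),
            length(width) %in% c(1L, length(age_start)))
  width <- rep(width, length.out = length(age_start))
  if (is.unsorted(age_start, strictly = TRUE))
    stop_config("age_start must be strictly increasing")
  if (length(age_start) > 1L) {
    gap <- diff(age_start) - width[-length(width)]
    if (any(abs(gap) > 1e-9))
      stop_config("age intervals must be contiguous")
  }
  if (any(m < 0)) stop_config("rates must be >= 0")
  width[length(width)] <- Inf
  structure(data.frame(age_start = age_start, width = width, m = m,
                       sex = rep(sex, length.out = length(age_start)),
                       stringsAsFactors = FALSE),
            class = c("baseline_rates", "data.frame"))
}

#' Build a period life table (Chiang construction)
#'
#' Converts age-specific rates to interval death probabilities
#' `q = w*m / (1 + w*(1-a)*m)` with separation factor `a = 0.5` for closed
#' intervals, then computes survivors `l` (radix 100,000), person-years
#' `L = w*(l - d) + a*w*d`, remaining person-years `T`, and expectancy
#' `e = T/l`.  The final interval is open: `q = 1`, `L = l/m`.  With a
#' single open interval the table reduces to the constant-hazard closed
#' form `e = 1/m`.
#'
#' @param rates a [baseline_rates()] table.
#' @param start_age age at which the table starts; must equal one of the
#'   interval boundaries.  Default: the first interval.
#' @param radix survivors at `start_age` (default 100,000).
#' @return Data frame of class `life_table` with columns `age_start`,
#'   `width`, `m`, `q`, `l`, `L`, `T`, `e`.
#' @export
build_life_table <- function(rates, start_age = rates$age_start[1],
                             radix = 1e5) {
  stopifnot(inherits(rates, "baseline_rates") || is.data.frame(rates))
  i0 <- match(start_age, rates$age_start)
  if (is.na(i0)) stop_config("start_age %s is not an interval boundary",
                             format(start_age))
  r <- rates[seq(i0, nrow(rates)), , drop = FALSE]
  n <- nrow(r)
  if (r$m[n] <= 0)
    stop_config("open-ended interval has m = 0 (infinite expectancy)")
  w <- r$width
  a <- 0.5
  q <- ifelse(is.finite(w), w * r$m / (1 + w * (1 - a) * r$m), 1)
  q <- pmin(q, 1)
  l <- radix * cumprod(c(1, 1 - q[-n]))
  d <- l * q
  L <- ifelse(is.finite(w), w * (l - d) + a * w * d, l / r$m)
  Tt <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, Tt / l, 0)
  structure(data.frame(age_start = r$age_start, width = w, m = r$m,
                       q = q, l = l, L = L, T = Tt, e = e),
            class = c("life_table", "data.frame"))
}

#' Life expectancy at the table's start age
#' @param lt a [build_life_table()] result.
#' @return Expectancy in years at the first row.
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  lt$e[1]
}

#' Adjust age-specific mortality rates by a hazard ratio
#'
#' In mode `"none"` the baseline is interpreted as the reference-category
#' schedule and every rate is multiplied by `hr`.  In mode `"population"`
#' the baseline is interpreted as the whole-population schedule:
#' `m' = m * hr / sum(p_k * hr_k)` over the category prevalences `p_k`, so
#' the prevalence-weighted average of adjusted rates reproduces `m`.
#'
#' @param rates a [baseline_rates()] table.
#' @param hr hazard ratio (> 0) for the category of interest.
#' @param calibration `"none"` (default) or `"population"`.
#' @param prevalences,hrs category prevalences (summing to 1) and matching
#'   hazard ratios, required for `"population"`.
#' @return A [baseline_rates()] table with adjusted `m`.
#' @export
adjust_rates <- function(rates, hr, calibration = c("none", "population"),
                         prevalences = NULL, hrs = NULL) {
  calibration <- match.arg(calibration)
  if (!is.numeric(hr) || any(hr <= 0)) stop_config("hr must be > 0")
  scale <- hr
  if (calibration == "population") {
    if (is.null(prevalences) || is.null(hrs))
      stop_config("population calibration needs 'prevalences' and 'hrs'")
    stopifnot(length(prevalences) == length(hrs))
    scale <- hr / sum(prevalences / sum(prevalences) * hrs)
  }
  out <- rates
  out$m <- rates$m * scale
  out
}

#' Years of life expectancy gained for a hazard-ratio contrast
#'
#' `years_gained = e(start_age | m*hr) - e(start_age | m*hr_ref)`.  The
#' confidence interval is propagated by recomputing the life table at the
#' HR confidence bounds: the upper HR bound gives the lower gain bound and
#' vice versa (the map hr -> e is strictly decreasing, so the interval
#' ordering is guaranteed).
#'
#' @param hr,ci_low,ci_high hazard ratio and its 95% CI versus the
#'   reference category.
#' @param rates reference-category [baseline_rates()] (or population rates
#'   with `calibration = "population"` arguments passed through `...`).
#' @param start_age table start age.
#' @param hr_ref reference hazard ratio (default 1).
#' @param ... passed to [adjust_rates()].
#' @return One-row data frame: `years_gained`, `ci_low`, `ci_high`,
#'   `e_ref`, `e_adj`.
#' @export
years_gained <- function(hr, ci_low = hr, ci_high = hr, rates,
                         start_age = rates$age_start[1], hr_ref = 1, ...) {
  if (any(c(hr, ci_low, ci_high) <= 0)) stop_config("HRs must be > 0")
  e_at <- function(h)
    life_expectancy(build_life_table(adjust_rates(rates, h, ...), start_age))
  e_ref <- e_at(hr_ref)
  data.frame(years_gained = e_at(hr) - e_ref,
             ci_low = e_at(ci_high) - e_ref,
             ci_high = e_at(ci_low) - e_ref,
             e_ref = e_ref, e_adj = e_at(hr))
}

#' Years gained for every row of a hazard-ratio table
#'
#' @param hr_table data frame with `hr`, `ci_low`, `ci_high` (as produced
#'   by [hazard_ratios()]); rows with missing HRs yield NA gains.
#' @param rates,start_age,... passed to [years_gained()].
#' @return `hr_table` with `years_gained`, `gain_ci_low`, `gain_ci_high`
#'   appended.
#' @export
years_gained_table <- function(hr_table, rates,
                               start_age = rates$age_start[1], ...) {
  out <- hr_table
  out$years_gained <- out$gain_ci_low <- out$gain_ci_high <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (is.na(out$hr[i])) next
    g <- years_gained(out$hr[i], out$ci_low[i], out$ci_high[i],
                      rates = rates, start_age = start_age, ...)
    out$years_gained[i] <- g$years_gained
    out$gain_ci_low[i] <- g$ci_low
    out$gain_ci_high[i] <- g$ci_high
  }
  out
}

#' Sex-stratified years-gained estimates
#'
#' Computes [years_gained()] independently per stratum with that stratum's
#' own rate schedule and hazard-ratio row.
#'
#' @param hr_rows named list of one-row data frames (`hr`, `ci_low`,
#'   `ci_high`) per stratum.
#' @param rates_list named list of [baseline_rates()] per stratum; names
#'   must match `hr_rows`.
#' @param start_age table start age (shared).
#' @return Data frame with one row per stratum.
#' @export
sex_stratified_gains <- function(hr_rows, rates_list,
                                 start_age = NULL) {
  if (!setequal(names(hr_rows), names(rates_list)) ||
      is.null(names(hr_rows)))
    stop_config("strata of hr_rows and rates_list must match by name")
  out <- lapply(names(hr_rows), function(s) {
    r <- rates_list[[s]]
    sa <- start_age %||% r$age_start[1]
    g <- years_gained(hr_rows[[s]]$hr, hr_rows[[s]]$ci_low,
                      hr_rows[[s]]$ci_high, rates = r, start_age = sa)
    cbind(stratum = s, g)
  })
  do.call(rbind, out)
}
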
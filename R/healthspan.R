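# Disease-free life expectancy (healthspan): a Sullivan-style extension of
# the period life table in which the disease-free state is exited by the
# first of death or incidence of any of five chronic conditions, with
# parametric Monte Carlo propagation of rate uncertainty.

#' Construct a disease rate table
#'
#' @param age_start interval start ages (matching the mortality table grid).
#' @param condition condition label per row (long format: one row per age
#'   interval per condition).
#' @param incidence first-event rate per disease-free person-year.
#' @param prevalence proportion `[0,1]` with the condition at interval start.
#' @param incidence_se,prevalence_se standard errors (natural scale).
#' @return Data frame of class `disease_rates`.
#' @export
disease_rates <- function(age_start, condition, incidence, prevalence,
                          incidence_se = 0, prevalence_se = 0) {
  n <- length(age_start)
  condition <- rep(condition, length.out = n)
  incidence <- rep(incidence, length.out = n)
  prevalence <- rep(prevalence, length.out = n)
  if (any(incidence < 0)) stop_config("incidence must be >= 0")
  if (any(prevalence < 0 | prevalence > 1))
    stop_config("prevalence must be in [0,1]")
  structure(data.frame(age_start = age_start, condition = condition,
                       incidence = incidence, prevalence = prevalence,
                       incidence_se = rep(incidence_se, length.out = n),
                       prevalence_se = rep(prevalence_se, length.out = n),
                       stringsAsFactors = FALSE),
            class = c("disease_rates", "data.frame"))
}

#' Combined exit rates from the disease-free state
#'
#' The disease-free state is left at the first event of any type, so the
#' exit rate per interval is `hr_mortality * m + sum_c hr_c * incidence_c`.
#'
#' @param mortality a [baseline_rates()] mortality table.
#' @param disease a [disease_rates()] table on the same age grid.
#' @param hr_mortality hazard ratio applied to mortality rates.
#' @param hr_incidence scalar or named vector (by condition) of hazard
#'   ratios applied to incidence rates.
#' @return A [baseline_rates()]-style table whose `m` is the combined exit
#'   rate, with a `prevalence_any` column (`1 - prod(1 - p_c)`, assuming
#'   independent condition prevalences).
#' @export
combined_exit_rates <- function(mortality, disease, hr_mortality = 1,
                                hr_incidence = 1) {
  conds <- unique(disease$condition)
  hri <- if (length(hr_incidence) == 1L && is.null(names(hr_incidence)))
    setNames(rep(hr_incidence, length(conds)), conds) else hr_incidence
  if (!all(conds %in% names(hri)))
    stop_config("hr_incidence must be scalar or named for every condition")
  exit <- mortality$m * hr_mortality
  prev_none <- rep(1, nrow(mortality))
  for (cc in conds) {
    d <- disease[disease$condition == cc, , drop = FALSE]
    j <- match(mortality$age_start, d$age_start)
    if (any(is.na(j)))
      stop_config("disease rates for '%s' do not cover the mortality age grid",
                  cc)
    exit <- exit + hri[[cc]] * d$incidence[j]
    prev_none <- prev_none * (1 - d$prevalence[j])
  }
  out <- baseline_rates(mortality$age_start, mortality$width, exit,
                        sex = mortality$sex)
  out$prevalence_any <- 1 - prev_none
  out
}

#' Disease-free life expectancy
#'
#' Builds a life table on the combined exit rates with the starting radix
#' scaled by the disease-free proportion `1 - prevalence_any(start_age)`;
#' DFLE is the expected disease-free person-years per person *alive* at the
#' start age, i.e. `(1 - prevalence_any) * e_exit(start_age)`.  An
#' alternative Sullivan weighting mode multiplies each interval's
#' person-years by its own disease-free proportion instead.
#'
#' @param exit_rates output of [combined_exit_rates()] (must carry
#'   `prevalence_any`), or any [baseline_rates()] plus `prevalence_any`.
#' @param start_age table start age.
#' @param prevalence_any override for the disease-free scaling at
#'   `start_age`; default taken from `exit_rates`.
#' @param mode `"radix"` (default): scale the starting radix;
#'   `"sullivan"`: weight each interval's `L` by `1 - prevalence_any(age)`.
#' @return List of class `dfle` with `table` (the exit-state life table,
#'   radix-scaled), `dfle` (years) and `mode`.
#' @export
disease_free_life_expectancy <- function(exit_rates, start_age =
                                           exit_rates$age_start[1],
                                         prevalence_any = NULL,
                                         mode = c("radix", "sullivan")) {
  mode <- match.arg(mode)
  i0 <- match(start_age, exit_rates$age_start)
  if (is.na(i0)) stop_config("start_age is not an interval boundary")
  p0 <- prevalence_any %||% exit_rates$prevalence_any[i0] %||% 0
  if (is.na(p0)) p0 <- 0
  if (p0 < 0 || p0 > 1) stop_config("prevalence_any must be in [0,1]")
  lt <- build_life_table(exit_rates, start_age)
  if (mode == "radix") {
    sc <- 1 - p0
    lt$l <- lt$l * sc; lt$L <- lt$L * sc; lt$T <- lt$T * sc
    dfle <- lt$T[1] / 1e5   # per person alive at start_age (radix 100,000)
  } else {
    pa <- exit_rates$prevalence_any[seq(i0, nrow(exit_rates))]
    pa[is.na(pa)] <- 0
    lt$L <- lt$L * (1 - pa)
    lt$T <- rev(cumsum(rev(lt$L)))
    dfle <- lt$T[1] / 1e5
  }
  structure(list(table = lt, dfle = dfle, mode = mode,
                 prevalence_any = p0), class = "dfle")
}

#' Healthspan gain from an HR contrast, by construction
#'
#' Convenience point estimate: DFLE at `hr` minus DFLE at the reference.
#' @param hr hazard-ratio applied to both mortality and incidence (scalar)
#'   or a list `list(mortality =, incidence =)`.
#' @param mortality,disease rate tables; `start_age`, `mode` as in
#'   [disease_free_life_expectancy()].
#' @return Numeric years of healthspan gained.
#' @keywords internal
dfle_at <- function(hr, mortality, disease, start_age, mode = "radix") {
  if (!is.list(hr)) hr <- list(mortality = hr, incidence = hr)
  ex <- combined_exit_rates(mortality, disease, hr$mortality, hr$incidence)
  disease_free_life_expectancy(ex, start_age, mode = mode)$dfle
}

#' Monte Carlo configuration for healthspan uncertainty
#'
#' @param iterations number of parametric samples (default 10,000).
#' @param seed integer seed (mandatory for reproducibility).
#' @param include_hr_uncertainty also sample the log-HR from its fitted
#'   normal distribution (default TRUE; switch off to propagate rate
#'   uncertainty only).
#' @return List of class `mc_config`.
#' @export
mc_config <- function(iterations = 10000, seed, include_hr_uncertainty = TRUE) {
  if (iterations < 100) stop_config("iterations must be >= 100")
  if (missing(seed)) stop_config("mc_config() requires a seed")
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 include_hr_uncertainty = include_hr_uncertainty),
            class = "mc_config")
}

#' Healthspan gain with parametric Monte Carlo uncertainty
#'
#' Per iteration, incidence rates are sampled log-normally (normal on the
#' log rate, sd = se/rate by the delta method), prevalences logit-normally
#' (sd = se / (p(1-p))), and, optionally, the log hazard ratio normally
#' from its fitted standard error; the DFLE gain versus the reference
#' (HR = 1) is recomputed.  The point estimate is the gain at the central
#' values; the 95% CI is the 2.5/97.5 percentile of the iteration
#' distribution.  `mc_se` is the Monte-Carlo standard error of the mean
#' gain (sd/sqrt(iterations)).
#'
#' @param hr,ci_low,ci_high mortality/incidence hazard ratio with its 95%
#'   CI (log-HR se derived as `(log(ci_high) - log(ci_low)) / (2*1.96)`).
#' @param mortality,disease rate tables ([baseline_rates()],
#'   [disease_rates()]); `disease` must carry standard errors.
#' @param mc an [mc_config()].
#' @param start_age table start age.
#' @param mode prevalence handling, see [disease_free_life_expectancy()].
#' @return One-row data frame of class `dfle_gain`: `years_gained`,
#'   `ci_low`, `ci_high`, `mc_se`, `sd_iter`, `iterations`, `rejected`.
#' @export
dfle_gain_mc <- function(hr, ci_low = hr, ci_high = hr, mortality, disease,
                         mc, start_age = mortality$age_start[1],
                         mode = "radix") {
  stopifnot(inherits(mc, "mc_config"))
  point <- dfle_at(hr, mortality, disease, start_age, mode) -
    dfle_at(1, mortality, disease, start_age, mode)
  log_hr_se <- if (ci_high > ci_low) (log(ci_high) - log(ci_low)) / (2 * 1.96)
    else 0
  set.seed(mc$seed)
  B <- mc$iterations
  gains <- numeric(B)
  rejected <- 0L
  nr <- nrow(disease)
  sd_log_inc <- ifelse(disease$incidence > 0,
                       disease$incidence_se / disease$incidence, 0)
  p <- disease$prevalence
  sd_logit_prev <- ifelse(p > 0 & p < 1,
                          disease$prevalence_se / (p * (1 - p)), 0)
  for (b in seq_len(B)) {
    for (attempt in 1:100) {
      d <- disease
      d$incidence <- exp(log(pmax(disease$incidence, 1e-300)) +
                           rnorm(nr, 0, sd_log_inc))
      d$incidence[disease$incidence == 0] <- 0
      lp <- qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) +
        rnorm(nr, 0, sd_logit_prev)
      d$prevalence <- plogis(lp)
      d$prevalence[p == 0] <- 0
      h <- if (mc$include_hr_uncertainty)
        exp(log(hr) + rnorm(1, 0, log_hr_se)) else hr
      ok <- all(is.finite(d$incidence)) && all(d$incidence >= 0) &&
        all(d$prevalence >= 0 & d$prevalence <= 1) && is.finite(h) && h > 0
      if (ok) break
      rejected <- rejected + 1L
    }
    gains[b] <- dfle_at(h, mortality, d, start_age, mode) -
      dfle_at(1, mortality, d, start_age, mode)
  }
  if (rejected > 0.1 * B)
    warning(sprintf("%d of %d Monte Carlo draws rejected and resampled",
                    rejected, B))
  ci <- unname(quantile(gains, c(0.025, 0.975), type = 7))
  structure(data.frame(years_gained = point, ci_low = ci[1], ci_high = ci[2],
                       mc_se = sd(gains) / sqrt(B), sd_iter = sd(gains),
                       iterations = B, rejected = rejected),
            class = c("dfle_gain", "data.frame"))
}
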
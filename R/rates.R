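# Baseline age-specific mortality, prevalence and incidence schedules.
# The packaged tables are SYNTHETIC national-style schedules (smooth
# Gompertz-type curves in the range of high-income-country rates), shipped
# so that the life-table machinery runs without restricted data; real
# national life tables can be supplied by path in the same CSV dialect.

#' Synthetic age-specific mortality rate schedule
#'
#' Gompertz-type schedule `m(x) = a * exp(b * x)` over 5-year intervals
#' from age 40 to an open interval at 100, with a sex contrast around the
#' pooled curve.  Synthetic: a stand-in for national period life tables.
#'
#' @param sex `"all"`, `"male"` or `"female"`.
#' @param a,b Gompertz level and slope (defaults: a = exp(-10.4), b = 0.092,
#'   giving m(64) ~ 0.011/year).
#' @return A [baseline_rates()] table.
#' @export
synthetic_mortality_rates <- function(sex = c("all", "male", "female"),
                                      a = exp(-10.4), b = 0.092) {
  sex <- match.arg(sex)
  ages <- seq(40, 100, by = 5)
  mult <- switch(sex, all = 1, male = 1.35, female = 0.78)
  baseline_rates(ages, width = 5, m = a * exp(b * ages) * mult, sex = sex)
}

#' Synthetic age-specific disease incidence and prevalence schedule
#'
#' Per-condition first-event incidence rising exponentially with age and
#' prevalence rising logistically, on the same 5-year grid as
#' [synthetic_mortality_rates()], with standard errors set to a constant
#' coefficient of variation.  Synthetic stand-in for registry-linked
#' age-specific rates.
#'
#' @param cv coefficient of variation for the standard errors (default 0.1).
#' @return A [disease_rates()] table for cvd, cancer, t2d, copd, dementia.
#' @export
synthetic_disease_rates <- function(cv = 0.1) {
  ages <- seq(40, 100, by = 5)
  base <- c(cvd = 0.012, cancer = 0.010, t2d = 0.004, copd = 0.002,
            dementia = 0.0006)
  slope <- c(cvd = 0.055, cancer = 0.045, t2d = 0.025, copd = 0.05,
             dementia = 0.11)
  prev50 <- c(cvd = 0.10, cancer = 0.06, t2d = 0.05, copd = 0.03,
              dementia = 0.01)   # prevalence at age 70
  out <- do.call(rbind, lapply(names(base), function(cc) {
    inc <- base[[cc]] * exp(slope[[cc]] * (ages - 64))
    prev <- plogis(qlogis(prev50[[cc]]) + 0.07 * (ages - 70))
    disease_rates(ages, cc, inc, prev,
                  incidence_se = cv * inc, prevalence_se = cv * prev)
  }))
  structure(out, class = c("disease_rates", "data.frame"))
}

#' Read a mortality rate table from CSV
#'
#' Dialect: columns `age_start`, `width`, `m`, optional `sex`.
#'
#' @param path CSV path; default the packaged synthetic schedule.
#' @param sex optional stratum filter when the file holds several.
#' @return A [baseline_rates()] table.
#' @export
load_baseline_rates <- function(path = system.file("extdata",
                                  "synthetic_mortality_rates.csv",
                                  package = "spanlife"),
                                sex = NULL) {
  d <- read.csv(path)
  if (!is.null(sex)) d <- d[d$sex == sex, , drop = FALSE]
  if (!nrow(d)) stop_config("no rows in rate table (after sex filter)")
  baseline_rates(d$age_start, d$width, d$m,
                 sex = if ("sex" %in% names(d)) d$sex else NA)
}

#' Read a disease rate table from CSV
#'
#' Dialect: `age_start`, `condition`, `incidence`, `incidence_se`,
#' `prevalence`, `prevalence_se`.
#'
#' @param path CSV path; default the packaged synthetic schedule.
#' @return A [disease_rates()] table.
#' @export
load_disease_rates <- function(path = system.file("extdata",
                                 "synthetic_disease_rates.csv",
                                 package = "spanlife")) {
  d <- read.csv(path)
  disease_rates(d$age_start, d$condition, d$incidence, d$prevalence,
                d$incidence_se, d$prevalence_se)
}
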
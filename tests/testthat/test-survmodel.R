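test_that("restricted cubic spline basis matches a brute-force
           truncated-power construction and is linear in the tails", {
  knots <- c(2, 5, 7, 9)
  x <- seq(0, 12, by = 0.25)
  B <- rcs_basis(x, knots)
  # brute-force oracle, written independently from first principles
  k <- length(knots); tk <- knots[k]; tk1 <- knots[k - 1]
  pp <- function(u) ifelse(u > 0, u^3, 0)
  for (j in 1:(k - 2)) {
    oracle <- (pp(x - knots[j]) -
                 pp(x - tk1) * (tk - knots[j]) / (tk - tk1) +
                 pp(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - knots[1])^2
    expect_equal(unname(B[, j + 1]), oracle, tolerance = 1e-12)
  }
  # linearity beyond the boundary knots: second differences vanish
  lo <- x < knots[1]; hi <- x > knots[k]
  for (j in 2:(k - 1)) {
    expect_true(all(abs(diff(diff(B[lo, j]))) < 1e-9))
    expect_true(all(abs(diff(diff(B[hi, j]))) < 1e-9))
  }
  expect_error(rcs_basis(x, knots = c(1, 2)), "3 distinct")
  expect_equal(length(attr(rcs_basis(rnorm(100), n_knots = 5), "knots")), 5)
})

test_that("two-group exponential data recover the true hazard ratio", {
  coh <- exp_group_cohort(20000, rates = c(0.02, 0.04), seed = 31)
  fit <- fit_cox_joint(coh, covariates = character(0))
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr[1], 1)                       # reference row exact
  expect_identical(hr$ci_low[1], 1)
  expect_true(hr$hr[2] > 1.85 && hr$hr[2] < 2.15) # true HR 2
  expect_true(hr$ci_low[2] <= hr$hr[2] & hr$hr[2] <= hr$ci_high[2])
})

test_that("identical groups give an HR confidence interval covering 1", {
  coh <- exp_group_cohort(4000, rates = c(0.03, 0.03), seed = 33)
  hr <- hazard_ratios(fit_cox_joint(coh, covariates = character(0)))
  expect_true(hr$ci_low[2] < 1 && hr$ci_high[2] > 1)
})

test_that("hazard ratio extraction follows exp(coef +/- 1.96 se)", {
  fake <- structure(list(
    coefficients = c(.cat2 = 0.6931), covariance = matrix(0.01, 1, 1,
      dimnames = list(".cat2", ".cat2")),
    categories = c("1", "2"), reference = "1", n = c(10L, 10L),
    events = c(5L, 5L), zero_event_categories = integer(0)),
    class = "cox_joint_fit")
  hr <- hazard_ratios(fake)
  expect_equal(hr$hr[2], 2.00, tolerance = 1e-3)
  expect_equal(hr$ci_low[2], exp(0.6931 - qnorm(0.975) * 0.1),
               tolerance = 1e-9)
  expect_equal(hr$ci_high[2], exp(0.6931 + qnorm(0.975) * 0.1),
               tolerance = 1e-9)
  expect_true(hr$ci_low[2] < 1.645 && hr$ci_low[2] > 1.643)   # ~1.644
  expect_true(hr$ci_high[2] < 2.434 && hr$ci_high[2] > 2.432) # ~2.433
})

test_that("zero-event categories are reported missing, not infinite", {
  coh <- exp_group_cohort(300, rates = c(0.05, 0.05, 0.05), seed = 35)
  coh$death[coh$joint_index == 3] <- 0     # no events in group 3
  # survival additionally warns that the degenerate coefficient may be
  # infinite; that second warning is expected here and silenced
  suppressWarnings(
    expect_warning(fit <- fit_cox_joint(coh, covariates = character(0)),
                   "zero events"))
  hr <- hazard_ratios(fit)
  expect_true(is.na(hr$hr[hr$category_index == 3]))
  expect_true(all(is.finite(hr$hr[1:2])))
})

test_that("spline dose-response recovers a log-linear effect and centres
           the reference at HR 1", {
  set.seed(37)
  n <- 15000
  x <- runif(n, 0, 10)
  tt <- rexp(n, 0.03 * exp(-0.08 * x))
  coh <- data.frame(x = x, followup_y = pmin(tt, 10),
                    death = as.integer(tt <= 10))
  fit <- fit_cox_rcs(coh, "x", covariates = character(0))
  ref <- fit$reference_value
  expect_equal(unname(quantile(x, 0.05, type = 7)), ref)  # 5th pct default
  hr <- hazard_ratios(fit, grid = c(ref, 2, 5, 8))
  expect_identical(hr$hr[1], 1)                 # exact centring
  expect_identical(hr$se[1], 0)
  # fitted curve within pointwise CI of the generative log-linear truth
  truth <- exp(-0.08 * (c(2, 5, 8) - ref))
  expect_true(all(truth >= hr$ci_low[-1] & truth <= hr$ci_high[-1]))
  # monotone truth -> fitted curve monotone over the central 90% of mass
  g <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 50)
  expect_true(all(diff(hazard_ratios(fit, grid = g)$log_hr) < 0))
  expect_error(hazard_ratios(fit, grid = c(-5, 20)), "range")
  expect_error(fit_cox_rcs(coh, "death", covariates = character(0)),
               "distinct")
})

test_that("proportional-hazards diagnostics calibrate under the null and
           flag a time-varying effect", {
  # PH-true data: global test should not reject at tiny levels
  coh <- exp_group_cohort(4000, rates = c(0.03, 0.05), seed = 41)
  fit <- fit_cox_joint(coh, covariates = character(0))
  d <- ph_diagnostics(fit)
  expect_true(d$global$p > 1e-4)
  expect_s3_class(d, "ph_diagnostics")
  expect_output(print(d), "Proportional-hazards")

  # strong time-varying effect: hazard ratio flips over follow-up
  set.seed(43)
  n <- 6000
  g <- rep(0:1, n / 2)
  # group 1: high early hazard, low late hazard (piecewise exponential)
  t1 <- rexp(n, 0.30); t2 <- 2 + rexp(n, 0.02)
  tt <- ifelse(g == 1, ifelse(t1 < 2, t1, t2), rexp(n, 0.08))
  coh2 <- data.frame(joint_index = g + 1, followup_y = pmin(tt, 10),
                     death = as.integer(tt <= 10))
  d2 <- ph_diagnostics(fit_cox_joint(coh2, covariates = character(0)))
  expect_lt(d2$global$p, 0.001)
  expect_true(any(d2$schoenfeld$flagged))
})

test_that("martingale residual summary reports continuous covariates", {
  coh <- small_cohort(n = 1500, seed = 45, baseline_mortality_rate = 0.03)
  pr <- prepare_exposures(coh)$cohort
  fit <- fit_cox_joint(pr, covariates = c("age", "sex", "deprivation"))
  d <- ph_diagnostics(fit)
  expect_true(!is.null(d$martingale))
  expect_setequal(d$martingale$covariate, c("age", "deprivation"))
})
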
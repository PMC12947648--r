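# Multivariable Cox proportional-hazards models: the 27-category joint
# exposure model, restricted-cubic-spline continuous dose-response models,
# hazard-ratio extraction, and proportional-hazards diagnostics.  Partial
# likelihood maximisation and residuals are delegated to the survival
# package (Efron tie handling).

default_covariates <- function()
  c("age", "sex", "smoking", "deprivation", "alcohol", "screen_h", "lipa_min")

surv_formula <- function(time_col, event_col, terms) {
  as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time_col, event_col,
                     paste(terms, collapse = " + ")))
}

#' Fit the joint-category Cox model
#'
#' Fits a multivariable Cox proportional-hazards model with the 27-category
#' joint exposure entered as an indicator block (all-low category 1 as
#' reference) plus covariates, using the Efron approximation for ties.
#' Categories with zero events are flagged and reported as missing in the
#' hazard-ratio table rather than as infinite estimates.
#'
#' @param cohort prepared cohort (needs `joint_index` from
#'   [prepare_exposures()], the outcome columns, and the covariates).
#' @param time_col,event_col follow-up time and 0/1 event indicator columns;
#'   defaults `followup_y` / `death` (all-cause mortality).
#' @param covariates covariate column names; default
#'   age, sex, smoking, deprivation, alcohol, screen time and light PA.
#' @param category_col joint category column (default `joint_index`).
#' @return Object of class `cox_joint_fit`: coefficients, covariance,
#'   category levels, per-category n and events, the underlying
#'   `survival::coxph` fit, and zero-event categories.
#' @export
fit_cox_joint <- function(cohort, time_col = "followup_y",
                          event_col = "death",
                          covariates = default_covariates(),
                          category_col = "joint_index") {
  miss <- setdiff(c(time_col, event_col, category_col, covariates),
                  names(cohort))
  if (length(miss)) stop_config("cohort lacks columns: %s",
                                paste(miss, collapse = ", "))
  keep <- complete.cases(cohort[, c(time_col, event_col, category_col,
                                    covariates)])
  dat <- cohort[keep, , drop = FALSE]
  dat$.cat <- factor(dat[[category_col]], levels = sort(unique(dat[[category_col]])))
  counts <- table(dat$.cat)
  events <- tapply(dat[[event_col]], dat$.cat, sum)
  zero_ev <- names(events)[is.na(events) | events == 0]
  if (length(zero_ev))
    warning(sprintf("categories with zero events reported as missing: %s",
                    paste(zero_ev, collapse = ", ")))
  f <- surv_formula(time_col, event_col, c(".cat", covariates))
  fit <- survival::coxph(f, data = dat, ties = "efron", model = FALSE, x = TRUE, y = TRUE)
  if (any(!is.finite(coef(fit))))
    stop_config("Cox model did not converge (non-finite coefficient for %s)",
                paste(names(coef(fit))[!is.finite(coef(fit))], collapse = ", "))
  structure(list(coefficients = coef(fit), covariance = vcov(fit),
                 fit = fit, categories = levels(dat$.cat),
                 reference = levels(dat$.cat)[1],
                 n = as.integer(counts), events = as.integer(events),
                 zero_event_categories = as.integer(zero_ev),
                 covariates = covariates, data = dat,
                 time_col = time_col, event_col = event_col),
            class = "cox_joint_fit")
}

#' Fit a restricted-cubic-spline Cox dose-response model
#'
#' Enters an RCS basis of a continuous exposure (default 4 knots at the
#' 5/35/65/95 percentiles) into the Cox model alongside covariates.  The
#' prediction curve is centred so that the log hazard ratio is exactly zero
#' at the reference value (default: the exposure's 5th percentile).
#'
#' @param cohort cohort data frame.
#' @param exposure continuous exposure column name.
#' @param n_knots number of knots (3-5, default 4); or supply `knots`.
#' @param knots explicit knot locations (overrides `n_knots`).
#' @param covariates covariate columns (default as in [fit_cox_joint()]).
#' @param time_col,event_col outcome columns.
#' @param reference_value exposure value at which HR = 1; default the 5th
#'   percentile of the exposure.
#' @return Object of class `cox_rcs_fit` with the spline coefficient block,
#'   its covariance, knots, and the reference value.
#' @export
fit_cox_rcs <- function(cohort, exposure, n_knots = 4, knots = NULL,
                        covariates = default_covariates(),
                        time_col = "followup_y", event_col = "death",
                        reference_value = NULL) {
  miss <- setdiff(c(time_col, event_col, exposure, covariates), names(cohort))
  if (length(miss)) stop_config("cohort lacks columns: %s",
                                paste(miss, collapse = ", "))
  x <- cohort[[exposure]]
  if (length(unique(x[!is.na(x)])) < max(n_knots, length(knots)))
    stop_config("exposure '%s' has fewer distinct values than knots", exposure)
  B <- rcs_basis(x, knots = knots, n_knots = n_knots)
  knots <- attr(B, "knots")
  dat <- cbind(cohort, as.data.frame(B))
  keep <- complete.cases(dat[, c(time_col, event_col, exposure, covariates)])
  dat <- dat[keep, , drop = FALSE]
  f <- surv_formula(time_col, event_col, c(colnames(B), covariates))
  fit <- survival::coxph(f, data = dat, ties = "efron", model = FALSE, x = TRUE, y = TRUE)
  ref <- reference_value %||%
    unname(quantile(x, 0.05, na.rm = TRUE, type = 7))
  sp <- colnames(B)
  structure(list(coefficients = coef(fit)[sp],
                 covariance = vcov(fit)[sp, sp, drop = FALSE],
                 knots = knots, reference_value = ref, exposure = exposure,
                 fit = fit, range = range(x, na.rm = TRUE)),
            class = "cox_rcs_fit")
}

#' Hazard ratios with confidence intervals
#'
#' For a joint-category fit, returns the 27-row table (reference row HR
#' exactly 1 with a degenerate CI; zero-event categories NA).  For a spline
#' fit, evaluates the centred curve on a grid: the contrast is
#' `B(x) - B(ref)`, `HR = exp(contrast %*% beta)` and the CI uses the delta
#' method on the coefficient covariance (`exp(est +/- 1.96 se)`).
#'
#' @param fit a `cox_joint_fit` or `cox_rcs_fit`.
#' @param grid for spline fits, exposure values at which to evaluate
#'   (default 200 points over the fitted range).
#' @param level confidence level (fixed at 0.95 in all reported tables).
#' @param ... unused.
#' @return Data frame: for joint fits `category_index`, `sleep_t`,
#'   `mvpa_t`, `diet_t`, `hr`, `ci_low`, `ci_high`, `n`, `events`; for
#'   spline fits `x`, `log_hr`, `se`, `hr`, `ci_low`, `ci_high`.
#' @export
hazard_ratios <- function(fit, ...) UseMethod("hazard_ratios")

#' @rdname hazard_ratios
#' @export
hazard_ratios.cox_joint_fit <- function(fit, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  lv <- joint_category_levels()
  out <- lv[match(as.integer(fit$categories), lv$index), ]
  names(out)[1] <- "category_index"
  out$hr <- out$ci_low <- out$ci_high <- NA_real_
  out$n <- fit$n
  out$events <- fit$events
  out$hr[1] <- out$ci_low[1] <- out$ci_high[1] <- 1   # reference row
  for (i in seq_along(fit$categories)[-1]) {
    nm <- paste0(".cat", fit$categories[i])
    if (!nm %in% names(fit$coefficients)) next
    if (as.integer(fit$categories[i]) %in% fit$zero_event_categories) next
    b <- fit$coefficients[nm]
    se <- sqrt(fit$covariance[nm, nm])
    out$hr[i] <- exp(b)
    out$ci_low[i] <- exp(b - z * se)
    out$ci_high[i] <- exp(b + z * se)
  }
  rownames(out) <- NULL
  out
}

#' @rdname hazard_ratios
#' @export
hazard_ratios.cox_rcs_fit <- function(fit, grid = NULL, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  grid <- grid %||% seq(fit$range[1], fit$range[2], length.out = 200)
  if (any(grid < fit$range[1] - 1e-9 | grid > fit$range[2] + 1e-9))
    stop_config("grid extends beyond the fitted (winsorised) exposure range")
  Bg <- rcs_basis(grid, knots = fit$knots)
  Br <- rcs_basis(fit$reference_value, knots = fit$knots)
  C <- sweep(Bg, 2, Br[1, ])
  est <- drop(C %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((C %*% fit$covariance) * C), 0))
  data.frame(x = grid, log_hr = est, se = se, hr = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se))
}

#' Proportional-hazards and functional-form diagnostics
#'
#' Schoenfeld-residual tests of the proportional-hazards assumption per
#' term and globally (via [survival::cox.zph()]), plus a martingale-residual
#' check of linearity for continuous covariates (correlation of residuals
#' with each covariate).  Violations are flagged at `alpha`.
#'
#' @param fit a `cox_joint_fit` (or any object wrapping a coxph `fit`).
#' @param alpha flag threshold, default 0.05.
#' @param transform time transform for the Schoenfeld test (default "km").
#' @return List of class `ph_diagnostics`: `schoenfeld` (term, chisq, df,
#'   p, flagged), `global` (one row), `martingale` (covariate, cor, p,
#'   flagged).
#' @export
ph_diagnostics <- function(fit, alpha = 0.05, transform = "km") {
  cox <- if (inherits(fit, "coxph")) fit else fit$fit
  zp <- survival::cox.zph(cox, transform = transform)
  tab <- as.data.frame(zp$table)
  names(tab) <- c("chisq", "df", "p")
  tab$term <- rownames(zp$table)
  tab$flagged <- tab$p < alpha
  glob <- tab[tab$term == "GLOBAL", , drop = FALSE]
  sch <- tab[tab$term != "GLOBAL", , drop = FALSE]
  mart <- NULL
  if (!inherits(fit, "coxph") && !is.null(fit$data)) {
    res <- residuals(cox, type = "martingale")
    cont <- fit$covariates[vapply(fit$covariates, function(v)
      is.numeric(fit$data[[v]]) && length(unique(fit$data[[v]])) > 5,
      logical(1))]
    mart <- do.call(rbind, lapply(cont, function(v) {
      ct <- suppressWarnings(cor.test(fit$data[[v]], res))
      data.frame(covariate = v, cor = unname(ct$estimate), p = ct$p.value,
                 flagged = ct$p.value < alpha)
    }))
  }
  structure(list(schoenfeld = sch[, c("term", "chisq", "df", "p", "flagged")],
                 global = glob[, c("chisq", "df", "p", "flagged")],
                 martingale = mart, alpha = alpha),
            class = "ph_diagnostics")
}

#' @export
print.ph_diagnostics <- function(x, ...) {
  cat("Proportional-hazards diagnostics (alpha =", x$alpha, ")\n")
  cat("Global Schoenfeld test: chisq =", round(x$global$chisq, 2),
      "df =", x$global$df, "p =", signif(x$global$p, 3),
      if (x$global$flagged) "[FLAGGED]" else "", "\n")
  nf <- sum(x$schoenfeld$flagged)
  cat(nf, "of", nrow(x$schoenfeld), "terms flagged\n")
  invisible(x)
}

#' @importFrom stats residuals
NULL
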
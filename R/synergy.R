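# Additive-interaction indices for the three joint exposures: relative
# excess risk due to interaction (RERI), attributable proportion (AP) and
# the synergy index (S), with nonparametric bootstrap confidence intervals.
#
# Orientation: the reference is the least-favourable (all-unfavourable)
# state, so protective joint exposures appear as HR < 1 and a positive RERI
# indicates super-additive benefit relative to the sum of the single
# favourable exposures; negative values reflect a sub-additive
# (antagonistic) relationship.

#' Dichotomise the three exposures into the 8 joint states
#'
#' Default favourable definition: top two tertiles versus the bottom
#' tertile of each exposure (configurable).  The state label is a string
#' `"smd"` of 0/1 flags in (sleep, MVPA, diet) order; `"000"` (all
#' unfavourable) is the reference.
#'
#' @param cohort cohort with tertile columns `sleep_t`, `mvpa_t`, `dqs_t`
#'   (from [prepare_exposures()]).
#' @param favourable named list of functions or character vectors of
#'   favourable tertile labels per exposure; default
#'   `c("medium", "high")` for each.
#' @return List with `state` (factor with all 8 levels, reference first)
#'   and `counts` (table of state occupancy; empty states trigger a
#'   warning).
#' @export
binarize_exposures <- function(cohort,
                               favourable = list(
                                 sleep = c("medium", "high"),
                                 mvpa = c("medium", "high"),
                                 diet = c("medium", "high"))) {
  stopifnot(all(c("sleep_t", "mvpa_t", "dqs_t") %in% names(cohort)))
  s <- as.integer(cohort$sleep_t %in% favourable$sleep)
  m <- as.integer(cohort$mvpa_t %in% favourable$mvpa)
  d <- as.integer(cohort$dqs_t %in% favourable$diet)
  all_states <- apply(expand.grid(0:1, 0:1, 0:1)[, 3:1], 1, paste,
                      collapse = "")
  all_states <- sort(all_states)           # "000" first
  state <- factor(paste0(s, m, d), levels = all_states)
  counts <- table(state)
  if (any(counts == 0))
    warning(sprintf("empty joint states: %s",
                    paste(names(counts)[counts == 0], collapse = ", ")))
  list(state = state, counts = counts)
}

#' RERI, AP and S from the 8-state hazard ratios
#'
#' Joint three-exposure form:
#' `RERI = HR_111 - HR_100 - HR_010 - HR_001 + 2`,
#' `AP = RERI / HR_111`,
#' `S = (HR_111 - 1) / ((HR_100 - 1) + (HR_010 - 1) + (HR_001 - 1))`.
#' Exact additivity gives RERI = 0, AP = 0, S = 1.  S is reported missing
#' (with the reason) when its denominator is <= 0 in absolute value terms
#' relevant here: a denominator of exactly 0.
#'
#' @param hrs named numeric vector with at least `"111"`, `"100"`, `"010"`,
#'   `"001"` (hazard ratios versus the `"000"` reference).
#' @return One-row data frame: `reri`, `ap`, `s`, `s_reason` (NA unless S
#'   is undefined).
#' @export
reri_ap_s <- function(hrs) {
  need <- c("111", "100", "010", "001")
  if (!all(need %in% names(hrs)) || any(is.na(hrs[need])))
    stop_config("need hazard ratios for states %s", paste(need, collapse = ", "))
  if (any(hrs[need] <= 0)) stop_config("hazard ratios must be > 0")
  h111 <- hrs[["111"]]; h100 <- hrs[["100"]]
  h010 <- hrs[["010"]]; h001 <- hrs[["001"]]
  reri <- h111 - h100 - h010 - h001 + 2
  ap <- reri / h111
  denom <- (h100 - 1) + (h010 - 1) + (h001 - 1)
  if (denom == 0) {
    s <- NA_real_
    reason <- "synergy index undefined: single-exposure excess risks sum to 0"
  } else {
    s <- (h111 - 1) / denom
    reason <- NA_character_
  }
  data.frame(reri = reri, ap = ap, s = s, s_reason = reason,
             stringsAsFactors = FALSE)
}

# Fast 8-state Cox fit on a pre-built design matrix (used by the
# bootstrap); falls back to coxph() when coxph.fit is unavailable.
fit_state_cox <- function(X, time, status) {
  ctl <- survival::coxph.control()
  f <- tryCatch(
    survival::coxph.fit(X, survival::Surv(time, status),
                        strata = NULL, offset = NULL, init = NULL,
                        control = ctl, weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f$coefficients))) return(NULL)
  f$coefficients
}

#' Bootstrap confidence intervals for the synergy indices
#'
#' Fits the 8-state Cox model (states from [binarize_exposures()], plus
#' optional covariates) on the full cohort for the point estimates, then
#' resamples participants with replacement `B` times, refits, and takes
#' percentile 2.5/97.5 intervals of each index.  Resamples with empty
#' states or non-convergent fits are dropped and counted.
#'
#' @param cohort prepared cohort (tertiles assigned).
#' @param time_col,event_col outcome columns (default all-cause mortality).
#' @param B bootstrap resamples (default 2000; must be >= 200).
#' @param seed integer seed.
#' @param favourable passed to [binarize_exposures()].
#' @param covariates covariate columns entered linearly (default none;
#'   the index formulas condition on the fitted state HRs).
#' @return One-row data frame of class `synergy_indices`: point estimates
#'   and CIs for RERI, AP and S, `B`, `dropped_resamples`, plus the 8-state
#'   HRs as an attribute `hrs`.
#' @export
bootstrap_synergy <- function(cohort, time_col = "followup_y",
                              event_col = "death", B = 2000, seed = 1,
                              favourable = NULL, covariates = NULL) {
  if (B < 200) stop_config("B must be >= 200")
  bz <- if (is.null(favourable)) binarize_exposures(cohort)
    else binarize_exposures(cohort, favourable)
  state <- bz$state
  keep <- !is.na(state) & complete.cases(cohort[, c(time_col, event_col,
                                                    covariates)])
  state <- droplevels(state[keep])
  state <- factor(state, levels = sort(unique(c("000", levels(state)))))
  dat <- cohort[keep, , drop = FALSE]
  X <- model.matrix(~ state)[, -1, drop = FALSE]
  colnames(X) <- sub("^state", "", colnames(X))
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(dat[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  time <- dat[[time_col]]
  status <- dat[[event_col]]
  states8 <- c("100", "010", "001", "110", "101", "011", "111")
  hr_from_coef <- function(beta) {
    h <- exp(beta[intersect(states8, names(beta))])
    c("000" = 1, h)
  }
  beta0 <- fit_state_cox(X, time, status)
  if (is.null(beta0)) stop_config("8-state Cox model did not converge")
  point <- reri_ap_s(hr_from_coef(beta0))
  set.seed(seed)
  n <- length(time)
  boot <- matrix(NA_real_, B, 3)
  dropped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    st_b <- state[idx]
    if (any(table(st_b) == 0) || sum(status[idx]) == 0) {
      dropped <- dropped + 1L
      next
    }
    Xb <- X[idx, , drop = FALSE]
    beta <- fit_state_cox(Xb, time[idx], status[idx])
    if (is.null(beta)) { dropped <- dropped + 1L; next }
    r <- reri_ap_s(hr_from_coef(beta))
    boot[b, ] <- c(r$reri, r$ap, r$s)
  }
  if (dropped > 0.2 * B)
    stop_config("more than 20%% of bootstrap resamples dropped (%d of %d); increase n",
                dropped, B)
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              type = 7)
  out <- data.frame(reri = point$reri, reri_lo = ci[1, 1], reri_hi = ci[2, 1],
                    ap = point$ap, ap_lo = ci[1, 2], ap_hi = ci[2, 2],
                    s = point$s, s_lo = ci[1, 3], s_hi = ci[2, 3],
                    B = B, dropped_resamples = dropped)
  rownames(out) <- NULL
  attr(out, "hrs") <- hr_from_coef(beta0)
  attr(out, "state_counts") <- bz$counts
  class(out) <- c("synergy_indices", "data.frame")
  out
}
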
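# Shared fixtures: all built in code at test time.

# Two-group (or k-group) exponential survival data with known rate ratios.
# Returns a data frame shaped like a prepared cohort with `joint_index`
# holding the group and a constant covariate-free design.
exp_group_cohort <- function(n, rates, censor = 8, seed = 1) {
  set.seed(seed)
  k <- length(rates)
  g <- sample(rep_len(seq_len(k), n))
  t_event <- rexp(n, rates[g])
  data.frame(joint_index = g,
             followup_y = pmin(t_event, censor),
             death = as.integer(t_event <= censor))
}

# Small synthetic cohort with modest effect sizes for fast tests.
small_cohort <- function(n = 2000, seed = 1, ...) {
  generate_cohort(synth_config(n_participants = n, seed = seed, ...))
}

# A synth_config with every exposure and covariate effect switched off
# (overridable through ...).
null_config <- function(n, seed, ...) {
  nulls <- list(log_hr_sleep_quadratic = 0, log_hr_mvpa_per_min = 0,
                log_hr_dqs_per_point = 0, log_hr_age = 0,
                covariate_log_hr = c(age = 0, sex = 0, smoking = 0,
                                     deprivation = 0, alcohol = 0,
                                     screen_h = 0, lipa_min = 0))
  args <- utils::modifyList(nulls, list(...))
  do.call(synth_config, c(list(n_participants = n, seed = seed), args))
}

# Independent step-by-step life-table recursion (oracle): plain loop,
# no vectorised shortcuts shared with the implementation.
oracle_life_table_e <- function(age_start, width, m, radix = 1e5) {
  n <- length(m)
  l <- radix
  Ls <- numeric(n)
  ls <- numeric(n)
  for (i in seq_len(n)) {
    ls[i] <- l
    if (i < n) {
      q <- width[i] * m[i] / (1 + 0.5 * width[i] * m[i])
      d <- l * q
      Ls[i] <- width[i] * (l - d) + 0.5 * width[i] * d
      l <- l - d
    } else {
      Ls[i] <- l / m[i]
    }
  }
  sum(Ls) / ls[1]
}

# Fabricated spline fit with known coefficients (for curve-machinery tests).
fake_rcs_fit <- function(coefficients, knots, reference_value, range,
                         se = 1e-6) {
  structure(list(coefficients = coefficients,
                 covariance = diag(se^2, length(coefficients)),
                 knots = knots, reference_value = reference_value,
                 exposure = "score", range = range),
            class = "cox_rcs_fit")
}

# Flat-rate mortality table helpers.
flat_rates <- function(m, ages = c(65), width = 5)
  baseline_rates(ages, width, rep(m, length(ages)))
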
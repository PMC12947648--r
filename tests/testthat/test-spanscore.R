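maps_fixture <- function() list(
  sleep = score_mapping(7.5, 4.8, 9.4, "u_shaped", "sleep"),
  mvpa = score_mapping(50, 5, 103, "saturating", "mvpa"),
  dqs = score_mapping(72.5, 32.5, 72.5, "monotone", "dqs"))

test_that("behaviour subscores hit their anchors exactly", {
  m <- maps_fixture()
  expect_equal(behaviour_subscore(7.5, m$sleep), 100 / 3)   # nadir -> max
  expect_equal(behaviour_subscore(4.8, m$sleep), 0)         # floor -> 0
  expect_equal(behaviour_subscore(9.4, m$sleep), 0)
  # symmetric u-shape: equal deviation, equal subscore
  sym <- score_mapping(7.5, 6.5, 8.5, "u_shaped")
  expect_equal(behaviour_subscore(7.0, sym), behaviour_subscore(8.0, sym))
  # saturating: flat at and beyond the optimum
  expect_equal(behaviour_subscore(50, m$mvpa), 100 / 3)
  expect_equal(behaviour_subscore(103, m$mvpa), 100 / 3)
  expect_equal(behaviour_subscore(5, m$mvpa), 0)
  # monotone: linear floor -> max
  expect_equal(behaviour_subscore(72.5, m$dqs), 100 / 3)
  expect_equal(behaviour_subscore(52.5, m$dqs), 100 / 6)
  expect_error(score_mapping(5, 5, 5), "lower < upper")
})

test_that("composite score endpoints and additivity are exact", {
  m <- maps_fixture()
  expect_equal(composite_score(7.5, 50, 72.5, m), 100)
  expect_equal(composite_score(4.8, 5, 32.5, m), 0)
  expect_equal(composite_score(7.5, 5, 32.5, m), 100 / 3)  # one optimal
  expect_error(composite_score(NA, 50, 70, m), "requires")
  set.seed(2)
  v <- composite_score(runif(100, 4.8, 9.4), runif(100, 5, 103),
                       runif(100, 32.5, 72.5), m)
  expect_true(all(v >= 0 & v <= 100))
})

test_that("behaviour weights are normalised marginal log-HR spans", {
  base <- joint_category_levels()
  # constructed table with per-behaviour log-HR spans (0.2, 0.6, 0.2):
  # log hr = -0.2*(sleep high) - 0.6*(mvpa high) - 0.2*(diet high)
  lhr <- -0.2 * (base$sleep_t == "high") - 0.6 * (base$mvpa_t == "high") -
    0.2 * (base$diet_t == "high")
  tab <- cbind(base, hr = exp(lhr))
  w <- derive_weights(tab)
  expect_equal(unname(w), c(0.2, 0.6, 0.2), tolerance = 1e-12)
  # only MVPA varies -> degenerate weights
  tab2 <- cbind(base, hr = exp(-0.5 * (base$mvpa_t == "high")))
  expect_equal(unname(derive_weights(tab2)), c(0, 1, 0))
  # symmetric spans -> uniform weights
  tab3 <- cbind(base, hr = exp(-0.3 * ((base$sleep_t == "high") +
    (base$mvpa_t == "high") + (base$diet_t == "high"))))
  expect_equal(unname(derive_weights(tab3)), rep(1 / 3, 3))
  # all-null table -> uniform fallback with warning
  tab4 <- cbind(base, hr = 1)
  expect_warning(w4 <- derive_weights(tab4), "uniform")
  expect_equal(unname(w4), rep(1 / 3, 3))
})

test_that("score-increment inversion allocates by weight and round-trips", {
  m <- maps_fixture()
  ref <- list(sleep = 5.5, mvpa = 7.3, dqs = 36.9)   # 5th-percentile-style
  z <- invert_score_increment(0, c(sleep = 1, mvpa = 0, dqs = 0), m, ref)
  expect_equal(z$delta_sleep_min, 0)
  expect_equal(z$delta_mvpa_min, 0)
  expect_equal(z$delta_dqs, 0)
  only_sleep <- invert_score_increment(5, c(sleep = 1, mvpa = 0, dqs = 0),
                                       m, ref)
  expect_gt(only_sleep$delta_sleep_min, 0)
  expect_equal(only_sleep$delta_mvpa_min, 0)
  expect_equal(only_sleep$delta_dqs, 0)

  # round-trip invariant over random weights and increments
  set.seed(4)
  for (i in 1:200) {
    w <- rexp(3); w <- w / sum(w); names(w) <- c("sleep", "mvpa", "dqs")
    ds <- runif(1, 0, 40)
    dec <- invert_score_increment(ds, w, m, ref)
    s0 <- composite_score(ref$sleep, ref$mvpa, ref$dqs, m)
    s1 <- composite_score(ref$sleep + dec$delta_sleep_min / 60,
                          ref$mvpa + dec$delta_mvpa_min,
                          ref$dqs + dec$delta_dqs, m)
    expect_lt(abs((s1 - s0) - ds), 1e-6)
  }
  # headroom overflow is reallocated, and the round-trip still holds
  big <- invert_score_increment(40, c(sleep = 0.9, mvpa = 0.05, dqs = 0.05),
                                m, ref)
  expect_gt(big$reallocated, 0)
  expect_error(invert_score_increment(99, c(sleep = 1, mvpa = 0, dqs = 0),
                                      m, ref), "headroom")
})

test_that("gain curves propagate HR curves through the life table", {
  # fabricated spline with a monotone-decreasing linear log HR in score
  fit <- fake_rcs_fit(c(-0.02, 0, 0), knots = c(10, 40, 60, 90),
                      reference_value = 10, range = c(0, 100), se = 0.002)
  rates <- synthetic_mortality_rates()
  cv <- lifespan_gain_curve(fit, rates, grid = seq(10, 90, by = 0.5),
                            start_age = 65)
  expect_equal(cv$years_gained[1], 0)           # reference point
  expect_true(all(diff(cv$years_gained) > 0))   # monotone composition
  expect_true(all(cv$ci_low <= cv$years_gained &
                    cv$years_gained <= cv$ci_high))
  # healthspan routing gives smaller gains from a higher exit rate
  dis <- synthetic_disease_rates()
  hv <- lifespan_gain_curve(fit, rates, grid = seq(10, 90, by = 0.5),
                            start_age = 65, disease = dis)
  expect_equal(hv$years_gained[1], 0)
  expect_true(all(diff(hv$years_gained) > 0))
})

test_that("minimum-dose table starts at the first significant score and is
           monotone in the targets", {
  m <- maps_fixture()
  ref <- list(sleep = 5.5, mvpa = 7.3, dqs = 36.9)
  w <- c(sleep = 0.25, mvpa = 0.5, dqs = 0.25)
  fit <- fake_rcs_fit(c(-0.02, 0, 0), knots = c(10, 40, 60, 90),
                      reference_value = 10, range = c(0, 100), se = 0.004)
  rates <- synthetic_mortality_rates()
  cv <- lifespan_gain_curve(fit, rates, grid = seq(10, 95, by = 0.5),
                            start_age = 65)
  mdt <- minimum_dose_table(cv, w, m, ref, targets = 1:10)
  expect_s3_class(mdt, "minimum_dose_table")
  expect_match(mdt$note[1], "minimum significant dose")
  # first row = smallest grid score whose gain CI excludes 0
  i_min <- min(which(cv$ci_low > 0))
  expect_equal(mdt$delta_score[1], cv$score[i_min] - cv$score[1])
  # grid-search oracle for each target
  for (r in which(mdt$reachable & is.na(mdt$note))) {
    tg <- mdt$target_years[r]
    expect_equal(mdt$delta_score[r],
                 cv$score[min(which(cv$years_gained >= tg))] - cv$score[1])
  }
  expect_true(all(diff(mdt$delta_score[mdt$reachable]) >= 0))
  # unreachable targets are flagged, not dropped
  expect_true(any(!mdt$reachable) ||
                max(cv$years_gained) >= max(mdt$target_years, na.rm = TRUE))

  # flat null curve -> empty table
  null_fit <- fake_rcs_fit(c(0, 0, 0), knots = c(10, 40, 60, 90),
                           reference_value = 10, range = c(0, 100), se = 0.01)
  cv0 <- lifespan_gain_curve(null_fit, rates, grid = seq(10, 95, by = 0.5),
                             start_age = 65)
  expect_equal(nrow(minimum_dose_table(cv0, w, m, ref)), 0)

  # single-behaviour equivalents solved on their own curves
  sx <- seq(5.5, 9.4, by = 0.1)
  singles <- list(sleep = data.frame(x = sx,
                                     years_gained = 2 * (sx - 5.5)))
  mdt2 <- minimum_dose_table(cv, w, m, ref, targets = c(2),
                             single_curves = singles)
  r2 <- which(mdt2$target_years == 2)
  expect_equal(mdt2$single_sleep[r2], 60 * 1, tolerance = 6 + 1e-9)
})

test_that("heatmap grid is anchored at zero and monotone under monotone truth", {
  m <- maps_fixture()
  fit <- fake_rcs_fit(c(-0.02, 0, 0), knots = c(10, 40, 60, 90),
                      reference_value = 0, range = c(0, 100), se = 0.002)
  rates <- synthetic_mortality_rates()
  hm <- heatmap_grid(fit, rates, m, vary = c("sleep", "mvpa"),
                     fixed = list(sleep = 4.8, mvpa = 5, dqs = 32.5),
                     n_grid = 8, start_age = 65)
  # reference corner: all behaviours at floor -> score 0 = reference -> 0
  expect_equal(hm$years_gained[hm$sleep == 4.8 & hm$mvpa == 5][1], 0,
               tolerance = 1e-9)
  # monotone in MVPA at fixed sleep below the optimum
  sub <- hm[hm$sleep == unique(hm$sleep)[2], ]
  expect_true(all(diff(sub$years_gained[order(sub$mvpa)]) >= -1e-9))
})
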
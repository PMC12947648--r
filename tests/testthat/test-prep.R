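test_that("winsorisation clamps at interpolated percentiles and keeps n", {
  x <- 1:100
  w <- winsorise(x, 2.5, 97.5)
  # linear-interpolation percentile oracle on 1..100: 1 + p*(n-1)
  expect_equal(min(w), 1 + 0.025 * 99)   # 3.475
  expect_equal(max(w), 1 + 0.975 * 99)   # 97.525
  expect_length(w, 100)
  expect_true(all(diff(as.numeric(w)) >= 0))   # order preserved on sorted input

  # no-op bounds
  expect_equal(as.numeric(winsorise(x, 0, 100)), as.numeric(x))
  # re-winsorising leaves interior values untouched (the clamped tails
  # shift the interpolated percentiles slightly, so only the interior is
  # exactly stable)
  w2 <- winsorise(as.numeric(w))
  interior <- w > attr(w2, "lower") & w < attr(w2, "upper")
  expect_equal(as.numeric(w2)[interior], as.numeric(w)[interior])

  set.seed(7)
  for (i in 1:5) {
    y <- rlnorm(200, 1, 1)
    wy <- winsorise(y)
    expect_length(wy, 200)
    expect_true(all(order(wy) [!duplicated(wy[order(wy)])] %in% order(y)) ||
                  !is.unsorted(wy[order(y)]))  # monotone order-preserving
    expect_true(mean(wy) >= attr(wy, "lower") && mean(wy) <= attr(wy, "upper"))
  }
  expect_error(winsorise(numeric(0)), "non-missing")
})

test_that("Tukey fences follow Q1 - k*IQR and Q3 + k*IQR", {
  # data with quartiles exactly 10 and 20
  x <- c(10, 10, 10, 20, 20, 20)
  expect_equal(unname(tukey_fence_bounds(x, 1.5)), c(-5, 35))
  # 1..11 under the interpolation convention: Q1 = 3.5, Q3 = 8.5
  expect_equal(unname(tukey_fence_bounds(1:11, 1.5)),
               c(3.5 - 1.5 * 5, 8.5 + 1.5 * 5))  # (-4, 16)
  # symmetric data -> bounds symmetric about the median
  y <- c(-3, -1, 0, 1, 3)
  b <- tukey_fence_bounds(y)
  expect_equal(b[["lower"]] + b[["upper"]], 2 * median(y))
  expect_warning(tukey_fence_bounds(rep(5, 10)), "IQR")
})

test_that("tertile assignment cuts at the 1/3 and 2/3 percentiles", {
  t <- assign_tertiles(1:9)
  expect_equal(t$scheme$cut_low_med, 1 + 8 / 3, tolerance = 1e-10)   # 3.667
  expect_equal(t$scheme$cut_med_high, 1 + 16 / 3, tolerance = 1e-10) # 6.333
  expect_equal(as.character(t$labels),
               rep(c("low", "medium", "high"), each = 3))
  expect_error(assign_tertiles(rep(2, 10)), "distinct")
  t3 <- assign_tertiles(c(1, 2, 3))
  expect_equal(sort(as.character(unique(t3$labels))),
               c("high", "low", "medium"))
  # group sizes within 1 of n/3 for distinct values
  set.seed(1)
  tt <- assign_tertiles(runif(100))
  expect_true(all(abs(table(tt$labels) - 100 / 3) <= 1))
})

test_that("joint 27-category index is a bijection with all-low reference", {
  lv <- c("low", "medium", "high")
  full <- expand.grid(s = lv, m = lv, d = lv, stringsAsFactors = FALSE)
  jc <- make_joint_categories(full$s, full$m, full$d)
  expect_setequal(jc$index, 1:27)
  expect_equal(jc$index[full$s == "low" & full$m == "low" & full$d == "low"], 1L)
  expect_equal(jc$index[full$s == "high" & full$m == "high" & full$d == "high"],
               27L)
  # round-trip through the canonical level table
  ref <- joint_category_levels()
  m <- merge(jc, ref, by = "index")
  expect_true(all(m$sleep_t.x == m$sleep_t.y & m$mvpa_t.x == m$mvpa_t.y &
                    m$diet_t.x == m$diet_t.y))
  # missing labels flagged as NA
  expect_true(is.na(make_joint_categories("low", NA, "high")$index))
})

test_that("exclusions remove the right rows and the log reconciles", {
  toy <- data.frame(followup_y = c(0.5, 0.8, rep(5, 8)),
                    death = c(1, 1, 1, rep(0, 7)),
                    preexisting = c(1, 0, 0, 1, rep(0, 6)))
  # 2 first-year deaths, 2 preexisting of which 1 overlaps a first-year death
  res <- apply_exclusions(toy, exclusion_rules(drop_death_within_years = 1,
                                               drop_preexisting_disease = TRUE))
  expect_equal(nrow(res$cohort), 7)
  expect_equal(res$log$n_removed, c(2, 1))
  expect_equal(res$log$n_remaining[nrow(res$log)], nrow(res$cohort))

  # all rules off -> identity
  res0 <- apply_exclusions(toy, exclusion_rules(drop_death_within_years = 0))
  expect_identical(res0$cohort, toy)
  expect_equal(nrow(res0$log), 0)

  # participant who died at 0.5 y is removed by the 1-year rule
  expect_false(any(res$cohort$followup_y == 0.5 & res$cohort$death == 1))

  # absent column -> error naming it
  expect_error(apply_exclusions(toy, exclusion_rules(drop_underweight_bmi = TRUE)),
               "bmi")
})

test_that("prepare_exposures winsorises then cuts tertiles consistently", {
  coh <- small_cohort(n = 3000, seed = 11)
  pr <- prepare_exposures(coh)
  sch <- pr$schemes
  # winsorised extremes equal the observed min/max after clamping,
  # i.e. the endpoints of the printed tertile ranges
  for (v in c("sleep_h", "mvpa_min", "dqs")) {
    s <- sch[sch$exposure == v, ]
    expect_equal(s$observed_min, s$winsor_lower, tolerance = 1e-12)
    expect_equal(s$observed_max, s$winsor_upper, tolerance = 1e-12)
    expect_true(s$cut_low_med < s$cut_med_high)
  }
  expect_true(all(pr$cohort$joint_index %in% 1:27))
  # tukey mode runs and clamps harder or equal in the tails
  pr2 <- prepare_exposures(coh, mode = "tukey")
  expect_true(all(pr2$cohort$joint_index %in% 1:27))
})
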
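test_that("single open interval gives e = 1/m exactly", {
  lt <- build_life_table(flat_rates(0.05), 65)
  expect_identical(nrow(lt), 1L)
  expect_equal(lt$e, 20, tolerance = 1e-12)
  expect_error(build_life_table(flat_rates(0)), "m = 0")
})

test_that("multi-interval table matches the step-by-step recursion oracle", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    w <- sample(c(1, 5), k, replace = TRUE)
    ages <- 40 + cumsum(c(0, w[-k]))
    m <- runif(k, 0.001, 0.3)
    r <- baseline_rates(ages, w, m)
    lt <- build_life_table(r, ages[1])
    expect_equal(lt$e[1], oracle_life_table_e(ages, w, m), tolerance = 1e-10)
    # Chiang identities hold exactly per row
    wf <- lt$width[-k]
    expect_equal(lt$q[-k], wf * lt$m[-k] / (1 + 0.5 * wf * lt$m[-k]),
                 tolerance = 1e-12)
    expect_equal(lt$l[-1], (lt$l * (1 - lt$q))[-k], tolerance = 1e-9)
    expect_equal(lt$T, rev(cumsum(rev(lt$L))), tolerance = 1e-9)
    expect_equal(lt$e, lt$T / lt$l, tolerance = 1e-12)
    expect_true(all(diff(lt$l) <= 0) && all(diff(lt$T) <= 0) &&
                  all(lt$e >= 0) && all(lt$q >= 0 & lt$q <= 1))
    # doubling rates strictly lowers expectancy
    r2 <- r; r2$m <- 2 * r2$m
    expect_lt(build_life_table(r2, ages[1])$e[1], lt$e[1])
  }
})

test_that("start_age must be an interval boundary", {
  r <- baseline_rates(c(60, 65, 70), 5, c(0.01, 0.02, 0.05))
  expect_error(build_life_table(r, 63), "boundary")
  expect_equal(build_life_table(r, 70)$e, 20)
})

test_that("rate adjustment modes behave as documented", {
  r <- baseline_rates(c(60, 65, 70), 5, c(0.01, 0.02, 0.05))
  expect_equal(adjust_rates(r, 1)$m, r$m)
  expect_equal(adjust_rates(r, 2)$m, 2 * r$m)
  # population calibration: prevalence-weighted mean of adjusted rates
  # reproduces the baseline exactly
  p <- c(1, 1, 1) / 3; hrs <- c(0.5, 1, 1.5)
  adj <- sapply(hrs, function(h)
    adjust_rates(r, h, "population", prevalences = p, hrs = hrs)$m)
  expect_equal(adj %*% p, cbind(r$m), tolerance = 1e-12)
  expect_error(adjust_rates(r, 2, "population"), "prevalences")
  expect_error(adjust_rates(r, -1), "hr")
})

test_that("years gained is zero at HR 1, follows 1/m closed form, and is
           strictly decreasing in HR with ordered CIs", {
  r1 <- flat_rates(0.05)
  g <- years_gained(1, 1, 1, rates = r1, start_age = 65)
  expect_identical(g$years_gained, 0)
  expect_identical(g$ci_low, 0)
  g2 <- years_gained(0.5, rates = r1, start_age = 65)
  expect_equal(g2$years_gained, 1 / 0.025 - 1 / 0.05, tolerance = 1e-12) # +20
  # monotone and continuous in hr; CI ordering from the monotone map
  r <- synthetic_mortality_rates()
  hr_grid <- seq(0.4, 2.5, by = 0.1)
  gains <- vapply(hr_grid, function(h)
    years_gained(h, rates = r, start_age = 65)$years_gained, numeric(1))
  expect_true(all(diff(gains) < 0))
  gg <- years_gained(0.8, 0.6, 1.1, rates = r, start_age = 65)
  expect_true(gg$ci_low <= gg$years_gained && gg$years_gained <= gg$ci_high)
})

test_that("sex-stratified gains are computed independently per stratum", {
  rf <- flat_rates(0.04); rm_ <- flat_rates(0.06)
  hrr <- data.frame(hr = 0.5, ci_low = 0.4, ci_high = 0.7)
  out <- sex_stratified_gains(list(male = hrr, female = hrr),
                              list(male = rm_, female = rf), start_age = 65)
  # 1/m algebra: gain = (1/hr - 1)/m, so for hr < 1 the higher-mortality
  # stratum gains fewer absolute years
  expect_equal(out$years_gained[out$stratum == "male"], 1 / 0.03 - 1 / 0.06)
  expect_equal(out$years_gained[out$stratum == "female"], 1 / 0.02 - 1 / 0.04)
  expect_lt(out$years_gained[out$stratum == "male"],
            out$years_gained[out$stratum == "female"])
  # identical strata inputs -> identical gains
  same <- sex_stratified_gains(list(a = hrr, b = hrr),
                               list(a = rf, b = rf), start_age = 65)
  expect_equal(same$years_gained[1], same$years_gained[2])
  # hr = 1 stratum -> zero gain
  h1 <- data.frame(hr = 1, ci_low = 1, ci_high = 1)
  z <- sex_stratified_gains(list(a = h1), list(a = rf), 65)
  expect_identical(z$years_gained, 0)
  expect_error(sex_stratified_gains(list(a = hrr), list(b = rf)), "match")
})

test_that("years_gained_table maps an HR table row-wise", {
  r <- synthetic_mortality_rates()
  tab <- data.frame(hr = c(1, 0.7, NA), ci_low = c(1, 0.5, NA),
                    ci_high = c(1, 0.95, NA))
  out <- years_gained_table(tab, r, start_age = 65)
  expect_identical(out$years_gained[1], 0)
  expect_gt(out$years_gained[2], 0)
  expect_true(is.na(out$years_gained[3]))
})
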
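test_that("null dynamics leave the cohort untouched", {
  fx <- base_fixture()
  occ <- init_occupancy(fx$params, fx$settings)
  out <- step_cohort(occ, 40, no_screening_strategy(), fx$params, fx$settings,
                     null_schedules(fx$settings))
  expect_equal(out$occupancy, occ)
  expect_equal(out$events$incident, 0)
})

test_that("undetected cancer progresses one stage per year and dies after distal", {
  fx <- base_fixture()
  occ <- init_occupancy(fx$params, fx$settings)
  occ["no_cancer"] <- 0
  occ["undet_local_d0"] <- 1
  p <- dare_parameters(p_background_detect_regional = 0,
                       p_background_detect_distal = 0)
  p$p_background_detect_local <- 0   # below its published range; set directly
  sch <- null_schedules(fx$settings)
  o1 <- step_cohort(occ, 40, no_screening_strategy(), p, fx$settings, sch)
  expect_equal(o1$occupancy[["undet_regional_d0"]], 1)
  o2 <- step_cohort(o1$occupancy, 41, no_screening_strategy(), p, fx$settings, sch)
  expect_equal(o2$occupancy[["undet_distal_d0"]], 1)
  o3 <- step_cohort(o2$occupancy, 42, no_screening_strategy(), p, fx$settings, sch)
  expect_equal(o3$occupancy[["dead_cancer"]], 1)
})

test_that("three-cycle toy cohort matches hand path enumeration", {
  # incidence 0.01/yr, all background detection 0.2, no screening, no
  # other-cause mortality, detected tracks immortal; occupancy after three
  # cycles enumerated by hand following the event order:
  # detection -> progression -> incidence
  settings <- dare_settings()
  p <- dare_parameters(excess_mortality_multiplier = 0)
  p$p_background_detect_regional <- 0.2
  p$p_background_detect_distal <- 0.2
  sch <- flat_schedules(0.01, 0, settings)
  res <- run_cohort(no_screening_strategy(), p, settings, sch)
  occ3 <- res$trace[4, ]   # start of cycle 4 = state after 3 cycles

  # cycle 1: incidence only
  nc1 <- 0.99; ul1 <- 0.01
  # cycle 2: ul detected 0.2 -> det_local; rest progresses; new incidence
  detL2 <- ul1 * 0.2
  ur2 <- ul1 * 0.8
  ul2 <- nc1 * 0.01; nc2 <- nc1 * 0.99
  # cycle 3: detections from ul2 and ur2; progression; incidence
  detL3 <- ul2 * 0.2
  detR3 <- ur2 * 0.2
  ud3 <- ur2 * 0.8
  ur3 <- ul2 * 0.8
  ul3 <- nc2 * 0.01; nc3 <- nc2 * 0.99

  expect_equal(occ3[["no_cancer"]], nc3, tolerance = 1e-12)
  expect_equal(occ3[["undet_local_d0"]], ul3, tolerance = 1e-12)
  expect_equal(occ3[["undet_regional_d0"]], ur3, tolerance = 1e-12)
  expect_equal(occ3[["undet_distal_d0"]], ud3, tolerance = 1e-12)
  expect_equal(occ3[["det_local_t2"]], detL2, tolerance = 1e-12)
  expect_equal(occ3[["det_local_t1"]], detL3, tolerance = 1e-12)
  expect_equal(occ3[["det_regional_t1"]], detR3, tolerance = 1e-12)
})

test_that("excess mortality applies the Weibull survival curve to detected tracks", {
  settings <- dare_settings()
  p <- dare_parameters()
  sch <- null_schedules(settings)
  occ <- init_occupancy(p, settings)
  occ["no_cancer"] <- 0
  occ["det_regional_t0"] <- 1
  wp <- p$survival$regional
  o <- occ
  for (cyc in 1:5) {
    o <- step_cohort(o, 35 + cyc - 1, no_screening_strategy(), p, settings,
                     sch)$occupancy
  }
  surv <- sum(o[startsWith(names(o), "det_regional_")])
  expect_equal(surv, weibull_survival(weibull_params("regional", wp$shape, wp$scale), 5),
               tolerance = 1e-12)
  expect_equal(o[["det_regional_t5"]], surv, tolerance = 1e-15)
})

test_that("a cancer-free immortal cohort accrues the closed-form outcomes", {
  settings <- dare_settings(discount_rate = 0)
  p <- dare_parameters()
  res <- run_cohort(no_screening_strategy(), p, settings,
                    null_schedules(settings))
  expect_equal(res$summary$life_years, 65)
  expect_equal(res$summary$qaly, 0.76 * 65, tolerance = 1e-12)
  expect_equal(res$summary$cost, 0)
})

test_that("half-cycle discounting values payoffs at cycle midpoints", {
  expect_equal(discount(100, 0, 5), 100)
  expect_equal(discount(100, 0.03, 1), 100 * 1.03^-0.5, tolerance = 1e-12)
  expect_equal(round(discount(100, 0.03, 1), 3), 98.533)
  # a constant stream's discounted sum decreases with the rate
  sums <- vapply(c(0, 0.01, 0.03, 0.05, 0.1),
                 function(r) sum(discount(rep(1, 30), r, 1:30)), numeric(1))
  expect_true(all(diff(sums) < 0))
  expect_error(discount(1, -0.1, 1), "rate")
})

test_that("discounted outcomes never exceed undiscounted and QALYs stay below LYs", {
  fx <- base_fixture()
  for (s in list(no_screening_strategy(),
                 strategy_spec("q2 50+", screen_start_age = 50,
                               screen_end_age = 100, interval_years = 2))) {
    sm <- run_cohort(s, fx$params, fx$settings, fx$schedules,
                     trace = FALSE)$summary
    expect_lt(sm$cost_disc, sm$cost)
    expect_lt(sm$life_years_disc, sm$life_years)
    expect_lt(sm$qaly_disc, sm$qaly)
    expect_lt(sm$qaly, sm$life_years)
    expect_gte(min(sm$diagnoses), 0)
  }
})

test_that("occupancy is conserved at every cycle of a fixture run", {
  fx <- base_fixture()
  res <- run_cohort(strategy_spec("annual 50+", screen_start_age = 50,
                                  screen_end_age = 100, interval_years = 1),
                    fx$params, fx$settings, fx$schedules)
  sums <- rowSums(res$trace)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(res$trace >= 0))
})

test_that("no-screening runs have zero screening costs and events", {
  fx <- base_fixture()
  res <- run_cohort(no_screening_strategy(), fx$params, fx$settings,
                    fx$schedules, trace = FALSE)
  expect_equal(res$summary$screens, 0)
  expect_equal(res$summary$false_positives, 0)
})

test_that("validation summary normalizes and flags degenerate runs", {
  fx <- base_fixture()
  res <- run_cohort(no_screening_strategy(), fx$params, fx$settings,
                    fx$schedules, trace = FALSE)
  vs <- validation_summary(res)
  expect_equal(sum(vs$stage_distribution), 1, tolerance = 1e-12)
  expect_equal(sum(vs$age_band_distribution), 1, tolerance = 1e-12)
  expect_false(vs$degenerate)
  # zero-incidence cohort: no diagnoses is flagged, not an error
  res0 <- run_cohort(no_screening_strategy(), fx$params, fx$settings,
                     null_schedules(fx$settings), trace = FALSE)
  vs0 <- validation_summary(res0)
  expect_true(vs0$degenerate)
  expect_true(all(is.na(vs0$stage_distribution)))
})

test_that("forced early detection makes nearly all diagnoses localized", {
  fx <- base_fixture()
  p <- dare_parameters(dare_sensitivity = 1)
  p$p_background_detect_local <- 1
  res <- run_cohort(strategy_spec("annual", screen_start_age = 35,
                                  screen_end_age = 100, interval_years = 1),
                    p, fx$settings, fx$schedules, trace = FALSE)
  expect_gt(res$summary$localized_fraction, 0.999)
})

test_that("identical inputs give bit-identical outcomes", {
  fx <- base_fixture()
  s <- strategy_spec("q3 50+", screen_start_age = 50, screen_end_age = 100,
                     interval_years = 3)
  r1 <- run_cohort(s, fx$params, fx$settings, fx$schedules)
  r2 <- run_cohort(s, fx$params, fx$settings, fx$schedules)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$trace, r2$trace)
})

test_that("cohort results write cleanly to CSV", {
  fx <- base_fixture()
  res <- run_cohort(no_screening_strategy(), fx$params, fx$settings,
                    fx$schedules)
  tp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_cohort_result(res, tp, ep)
  tr <- utils::read.csv(tp, check.names = FALSE)
  expect_equal(nrow(tr), 65)
  expect_equal(tr$age[1], 35)
  ev <- utils::read.csv(ep)
  expect_true(all(c("cycle", "incident", "deaths_other") %in% names(ev)))
})
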
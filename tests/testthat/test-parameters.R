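test_that("base case carries the published values and ordered utilities", {
  bc <- base_case_parameters()
  p <- bc$params
  expect_equal(p$dare_sensitivity, 0.9)
  expect_equal(p$dare_ppv, 0.25)
  expect_equal(p$p_background_detect_local, 0.2)
  expect_equal(p$cost_screen, 16)
  expect_equal(p$cost_false_positive, 218)
  expect_equal(p$cost_workup, 1864)
  expect_equal(p$cost_treat_local, 10386)
  expect_equal(p$cost_treat_regional, 11093)
  expect_equal(p$cost_treat_distal, 14638)
  expect_equal(p$utility_no_cancer, 0.76)
  expect_equal(p$surgical_excision_fraction, 0.05)
  # utility ordering for the base case
  expect_true(p$utility_distal <= p$utility_regional)
  expect_true(p$utility_regional <= p$utility_local)
  expect_true(p$utility_local <= p$utility_no_cancer)
  s <- bc$settings
  expect_equal(s$start_age, 35L)
  expect_equal(s$max_age, 100L)
  expect_equal(s$discount_rate, 0.03)
  expect_equal(s$cycle_length, 1L)
  # every sensitivity range contains its base value
  for (nm in names(p$ranges)) {
    expect_true(p[[nm]] >= p$ranges[[nm]][1] && p[[nm]] <= p$ranges[[nm]][2],
                info = nm)
  }
})

test_that("validation rejects out-of-bound values and names the field", {
  expect_error(dare_parameters(utility_local = 1.2), "utility_local")
  expect_error(dare_parameters(dare_sensitivity = -0.1), "dare_sensitivity")
  expect_error(dare_parameters(cost_workup = -5), "cost_workup")
  expect_error(dare_parameters(progression_interval_years = 0),
               "progression_interval_years")
  expect_error(dare_parameters(cost_screen = 50), "outside its range")
  expect_error(dare_parameters(nonsense = 1), "unknown parameter")
  expect_error(dare_settings(start_age = 100, max_age = 100), "start_age")
  expect_error(dare_settings(discount_rate = -0.01), "discount_rate")
})

test_that("config round-trips losslessly and reports missing pieces", {
  bc <- base_case_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(bc$params, bc$settings, path,
              strategies = default_strategies(bc$settings))
  cfg <- load_config(path)
  expect_equal(unclass(cfg$params), unclass(bc$params), tolerance = 1e-12)
  expect_equal(unclass(cfg$settings), unclass(bc$settings))
  expect_length(cfg$strategies, 11)
  expect_equal(cfg$strategies[[1]]$label, "No screening")

  # invalid value errors name the field
  bad <- yaml::read_yaml(path)
  bad$parameters$utility_local <- 1.2
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path2)
  expect_error(load_config(path2), "utility_local")

  # schedules must come as values, csv, or a synthetic spec
  bad2 <- yaml::read_yaml(path)
  bad2$schedules <- list(mortality = list(synthetic = list(multiplier = 1)))
  path3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad2, path3)
  expect_error(load_config(path3), "incidence")
})

test_that("schedule specs expand from values, CSV, and generators", {
  bc <- base_case_parameters()
  ages <- 35:100
  inc <- age_schedule("incidence", ages, rep(0.001, length(ages)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_age_schedule(inc, csv)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(bc$params, bc$settings, path,
              schedules = list(incidence = list(csv = csv),
                               mortality = list(synthetic = list(multiplier = 0.9))))
  cfg <- load_config(path)
  expect_s3_class(cfg$schedules$incidence, "age_schedule")
  expect_equal(schedule_prob(cfg$schedules$incidence, 50), 0.001)
  expect_equal(cfg$schedules$mortality$value,
               gen_mortality_schedule(multiplier = 0.9)$value)
  # inline values survive a save/load cycle
  path2 <- withr::local_tempfile(fileext = ".yaml")
  save_config(bc$params, bc$settings, path2,
              schedules = list(incidence = inc,
                               mortality = gen_mortality_schedule(multiplier = 1)))
  cfg2 <- load_config(path2)
  expect_equal(cfg2$schedules$incidence$value, inc$value, tolerance = 1e-12)
})

test_that("age schedules are dense and bounded, and lookups fail loudly", {
  sched <- gen_mortality_schedule(multiplier = 1)
  expect_identical(sched$age, 35:100)
  expect_true(all(sched$value >= 0 & sched$value <= 1))
  expect_error(schedule_prob(sched, 20), "no value for age")
  expect_error(age_schedule("incidence", c(35, 37), c(0, 0)), "contiguous")
  expect_error(age_schedule("incidence", 35:36, c(0, 1.5)), "\\[0, 1\\]")
})

test_that("strategy specs validate their windows", {
  expect_error(strategy_spec("x", screen_start_age = 60, screen_end_age = 50,
                             interval_years = 1), "screen_start_age")
  expect_error(strategy_spec("x", screen_start_age = 35, screen_end_age = 49,
                             interval_years = 0), "interval_years")
  s <- default_strategies()
  expect_length(s, 11)
  expect_false(s[[1]]$screening)
  expect_setequal(vapply(s[-1], function(x) x$interval_years, integer(1)),
                  rep(1:5, 2))
})
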
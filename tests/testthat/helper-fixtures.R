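# Shared fixtures: built once per test run, in code.

base_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bc <- base_case_parameters()
      cache <<- list(params = bc$params, settings = bc$settings,
                     schedules = reference_schedules(1, bc$params, bc$settings))
    }
    cache
  }
})

# an immortal, cancer-free-dynamics schedule pair for closed-form checks
null_schedules <- function(settings = dare_settings()) {
  ages <- settings$start_age:settings$max_age
  list(incidence = age_schedule("incidence", ages, rep(0, length(ages))),
       mortality = age_schedule("other_cause_mortality", ages,
                                rep(0, length(ages))))
}

flat_schedules <- function(p_inc, p_mort, settings = dare_settings()) {
  ages <- settings$start_age:settings$max_age
  list(incidence = age_schedule("incidence", ages, rep(p_inc, length(ages))),
       mortality = age_schedule("other_cause_mortality", ages,
                                rep(p_mort, length(ages))))
}

band50_strategies <- function(settings = dare_settings()) {
  words <- c("year", "two years", "three years", "four years", "five years")
  c(list(no_screening_strategy()),
    lapply(1:5, function(iv) strategy_spec(
      sprintf("Age >=50 every %s", words[iv]),
      screen_start_age = 50, screen_end_age = settings$max_age,
      interval_years = iv)))
}
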
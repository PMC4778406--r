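#' Model parameters, settings, schedules and strategies
#'
#' The parameter container mirrors the base-case inputs of the evaluation:
#' test characteristics of the digital ano-rectal examination (DARE),
#' background (non-screening) detection probabilities, treatment and
#' monitoring costs in 2014 Australian dollars, and health-state utility
#' weights. Each parameter carries a sensitivity range used by the one-way
#' and probabilistic sensitivity analyses.
#'
#' @name parameters
NULL

.stages <- c("local", "regional", "distal")

#' Construct a validated parameter set
#'
#' @param ... named parameter overrides applied on top of the base case.
#' @return An object of class `dare_parameters`: a named list of model
#'   parameters (see [base_case_parameters()] for the fields and base values).
#' @export
dare_parameters <- function(...) {
  p <- .base_parameter_list()
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(p), "ranges"))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(dots)] <- dots
  p <- structure(p, class = "dare_parameters")
  validate_parameters(p)
  p
}

.base_parameter_list <- function() {
  list(
    # DARE test characteristics. `dare_ppv` is the proportion of surgical
    # referrals that turn out to be cancer; it is converted to a per-screen
    # false-positive probability at the cohort's current undetected prevalence
    # (see fp_rate_from_ppv), so the stored value matches the published input.
    dare_sensitivity = 0.9,
    dare_ppv = 0.25,
    # Annual probability an undetected cancer is diagnosed outside screening.
    # Only the localized value is study-reported. The regional/distal defaults
    # are calibrated jointly so that (i) the no-screening localized fraction
    # of diagnoses falls in the registry validation band and (ii) the
    # localized fraction rises strictly as the screening interval shrinks,
    # the stage-shift gradient screening is meant to produce.
    p_background_detect_local = 0.2,
    p_background_detect_regional = 0.15,
    p_background_detect_distal = 0.20,
    # Natural history: undetected cancer progresses one stage per interval.
    progression_interval_years = 1L,
    # Fraction of localized cancers treated by local excision instead of
    # chemoradiation.
    surgical_excision_fraction = 0.05,
    # Costs, AUD 2014.
    cost_screen = 16,
    cost_false_positive = 218,
    cost_workup = 1864,
    cost_treat_local = 10386,
    cost_treat_regional = 11093,
    cost_treat_distal = 14638,
    cost_treat_excision = 1864,
    # Post-diagnosis monitoring cost by year since diagnosis (year 1, 2, ...);
    # zero beyond the schedule's length.
    monitoring_cost_schedule = c(500, 250, 250, 250, 250),
    # Utility weights.
    utility_no_cancer = 0.76,
    utility_local = 0.71,
    utility_regional = 0.66,
    utility_distal = 0.52,
    # QALY decrement per false-positive referral (0 unless configured).
    fp_disutility = 0,
    # Years a detected cancer carries its stage utility before reverting to
    # the cancer-free utility (treated survivors remain on the excess-mortality
    # survival curve).
    treatment_utility_years = 1L,
    # Stage-specific Weibull relative-survival parameters (shape k, scale
    # lambda in years). Defaults are fitted to the packaged synthetic
    # registry-like survival curves; see gen_survival_dataset().
    survival = list(
      local = list(shape = 1.1, scale = 20),
      regional = list(shape = 1.0, scale = 10),
      distal = list(shape = 0.9, scale = 4)
    ),
    # Scenario dial: multiplies the annual excess death probabilities (scalar
    # or named per-stage vector); used by survival-shift sensitivity runs.
    excess_mortality_multiplier = 1,
    # Sensitivity ranges (low, high) containing each base value.
    ranges = list(
      dare_sensitivity = c(0.70, 1.00),
      dare_ppv = c(0.1, 0.5),
      p_background_detect_local = c(0.1, 0.55),
      cost_screen = c(10, 30),
      cost_false_positive = c(100, 500),
      cost_workup = c(1000, 3000),
      cost_treat_local = c(5000, 15000),
      cost_treat_regional = c(5000, 15000),
      cost_treat_distal = c(10000, 20000),
      utility_no_cancer = c(0.66, 0.86),
      utility_local = c(0.56, 0.76),
      utility_regional = c(0.56, 0.76),
      utility_distal = c(0.42, 0.62)
    )
  )
}

#' Model settings
#'
#' @param start_age cohort entry age in years.
#' @param max_age end of the time horizon (no cycle is run at this age).
#' @param discount_rate annual discount rate applied to costs and QALYs.
#' @param screening_uptake probability that a due screen actually occurs.
#' @param cycle_length cycle length in years (fixed at 1).
#' @return An object of class `dare_settings`.
#' @export
dare_settings <- function(start_age = 35L, max_age = 100L, discount_rate = 0.03,
                          screening_uptake = 1.0, cycle_length = 1L) {
  s <- structure(
    list(start_age = as.integer(start_age), max_age = as.integer(max_age),
         cycle_length = as.integer(cycle_length), discount_rate = discount_rate,
         screening_uptake = screening_uptake),
    class = "dare_settings"
  )
  validate_settings(s)
  s
}

#' Base-case parameters and settings
#'
#' Returns the published base-case parameter values together with the model
#' settings (35-year-old cohort followed to age 100, one-year cycles, 3%
#' annual discounting). Fields without a published value take documented
#' defaults (background detection for regional/distal disease, the monitoring
#' cost schedule, false-positive disutility, local-excision cost).
#'
#' @return A list with elements `params` ([dare_parameters()]) and
#'   `settings` ([dare_settings()]).
#' @export
#' @examples
#' bc <- base_case_parameters()
#' bc$params$dare_sensitivity
#' bc$settings$discount_rate
base_case_parameters <- function() {
  list(params = dare_parameters(), settings = dare_settings())
}

.check_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("parameter '%s' must lie in [0, 1] (got %s)", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(sprintf("parameter '%s' must be >= 0 (got %s)", name,
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
}

#' Validate a parameter set
#'
#' Checks every invariant: probabilities and utilities in \[0, 1\], costs
#' non-negative, a positive integer progression interval, positive Weibull
#' parameters, and sensitivity ranges that contain their base value. Errors
#' name the offending field.
#'
#' @param params a `dare_parameters` object.
#' @param check_ranges also require each base value to lie inside its
#'   sensitivity range? (the constructor does; sampled or scenario parameter
#'   sets legitimately leave the ranges)
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params, check_ranges = TRUE) {
  probs <- c("dare_sensitivity", "dare_ppv", "p_background_detect_local",
             "p_background_detect_regional", "p_background_detect_distal",
             "surgical_excision_fraction", "utility_no_cancer", "utility_local",
             "utility_regional", "utility_distal")
  for (nm in probs) .check_prob(params[[nm]], nm)
  costs <- c("cost_screen", "cost_false_positive", "cost_workup",
             "cost_treat_local", "cost_treat_regional", "cost_treat_distal",
             "cost_treat_excision", "monitoring_cost_schedule", "fp_disutility")
  for (nm in costs) .check_nonneg(params[[nm]], nm)
  k <- params$progression_interval_years
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 || k != round(k)) {
    stop("parameter 'progression_interval_years' must be an integer >= 1",
         call. = FALSE)
  }
  ty <- params$treatment_utility_years
  if (!is.numeric(ty) || ty < 0) {
    stop("parameter 'treatment_utility_years' must be >= 0", call. = FALSE)
  }
  .check_nonneg(params$excess_mortality_multiplier, "excess_mortality_multiplier")
  if (!length(params$excess_mortality_multiplier) %in% c(1L, 3L)) {
    stop("'excess_mortality_multiplier' must have length 1 or 3", call. = FALSE)
  }
  for (st in .stages) {
    w <- params$survival[[st]]
    if (is.null(w) || !is.numeric(w$shape) || !is.numeric(w$scale) ||
        w$shape <= 0 || w$scale <= 0) {
      stop(sprintf("parameter 'survival$%s' must have shape > 0 and scale > 0", st),
           call. = FALSE)
    }
  }
  if (check_ranges) {
    for (nm in names(params$ranges)) {
      r <- params$ranges[[nm]]
      v <- params[[nm]]
      if (length(r) != 2 || r[1] > r[2]) {
        stop(sprintf("range for '%s' must be (low, high) with low <= high", nm),
             call. = FALSE)
      }
      if (!is.null(v) && (v < r[1] || v > r[2])) {
        stop(sprintf("base value of '%s' (%s) lies outside its range [%s, %s]",
                     nm, format(v), format(r[1]), format(r[2])), call. = FALSE)
      }
    }
  }
  invisible(params)
}

#' @rdname validate_parameters
#' @param settings a `dare_settings` object.
#' @export
validate_settings <- function(settings) {
  if (settings$start_age >= settings$max_age) {
    stop("'start_age' must be < 'max_age'", call. = FALSE)
  }
  if (settings$discount_rate < 0) stop("'discount_rate' must be >= 0", call. = FALSE)
  if (settings$cycle_length != 1L) stop("'cycle_length' must be 1 year", call. = FALSE)
  .check_prob(settings$screening_uptake, "screening_uptake")
  invisible(settings)
}

# ---- Age schedules ---------------------------------------------------------

#' Age-indexed annual probability schedule
#'
#' A schedule maps every integer age in \[`start_age`, `max_age`\] to an
#' annual probability: cancer incidence or other-cause mortality.
#'
#' @param kind `"incidence"` or `"other_cause_mortality"`.
#' @param age integer ages (must be contiguous).
#' @param value annual probabilities in \[0, 1\], one per age.
#' @return An object of class `age_schedule`.
#' @export
age_schedule <- function(kind = c("incidence", "other_cause_mortality"),
                         age, value) {
  kind <- match.arg(kind)
  age <- as.integer(age)
  if (length(age) != length(value)) stop("age and value lengths differ", call. = FALSE)
  if (any(diff(age) != 1L)) stop("ages must be contiguous integers", call. = FALSE)
  .check_prob(value, paste0(kind, " schedule"))
  structure(list(kind = kind, age = age, value = as.numeric(value)),
            class = "age_schedule")
}

#' Look up a schedule's annual probability at an age
#'
#' @param schedule an [age_schedule()].
#' @param age integer age(s).
#' @return Annual probability at each requested age.
#' @export
schedule_prob <- function(schedule, age) {
  i <- match(as.integer(age), schedule$age)
  if (anyNA(i)) {
    stop(sprintf("schedule '%s' has no value for age %s", schedule$kind,
                 paste(age[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  schedule$value[i]
}

#' Read / write an age schedule as CSV (columns `age`, `value`)
#'
#' @param path file path.
#' @param kind schedule kind, see [age_schedule()].
#' @return [read_age_schedule()] returns an `age_schedule`;
#'   [write_age_schedule()] returns `path` invisibly.
#' @export
read_age_schedule <- function(path, kind = c("incidence", "other_cause_mortality")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("age", "value") %in% names(df))) {
    stop("schedule CSV must have columns 'age' and 'value'", call. = FALSE)
  }
  df <- df[order(df$age), ]
  age_schedule(kind, df$age, df$value)
}

#' @rdname read_age_schedule
#' @param schedule schedule to write.
#' @export
write_age_schedule <- function(schedule, path) {
  utils::write.csv(data.frame(age = schedule$age, value = schedule$value),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- Strategies ------------------------------------------------------------

#' Screening strategy specification
#'
#' @param label strategy name.
#' @param screening does this strategy screen at all?
#' @param screen_start_age,screen_end_age inclusive age window for screening.
#' @param interval_years years between screens (1 to 5).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(label, screening = TRUE, screen_start_age = NA,
                          screen_end_age = NA, interval_years = NA) {
  if (screening) {
    if (is.na(screen_start_age) || is.na(screen_end_age) || is.na(interval_years)) {
      stop("screening strategies need screen_start_age, screen_end_age, interval_years",
           call. = FALSE)
    }
    if (screen_start_age > screen_end_age) {
      stop("screen_start_age must be <= screen_end_age", call. = FALSE)
    }
    if (interval_years < 1 || interval_years != round(interval_years)) {
      stop("interval_years must be an integer >= 1", call. = FALSE)
    }
  }
  structure(list(label = label, screening = isTRUE(screening),
                 screen_start_age = as.integer(screen_start_age),
                 screen_end_age = as.integer(screen_end_age),
                 interval_years = as.integer(interval_years)),
            class = "strategy_spec")
}

#' @rdname strategy_spec
#' @export
no_screening_strategy <- function(label = "No screening") {
  strategy_spec(label, screening = FALSE)
}

#' The standard menu of eleven strategies
#'
#' No screening plus every combination of screening interval (1 to 5 years)
#' and age band (35 to 49, or 50 up to the model horizon).
#'
#' @param settings model settings (supplies the horizon for the >=50 band).
#' @return A list of [strategy_spec()] objects.
#' @export
default_strategies <- function(settings = dare_settings()) {
  words <- c("year", "two years", "three years", "four years", "five years")
  out <- list(no_screening_strategy())
  for (iv in 1:5) {
    out[[length(out) + 1L]] <- strategy_spec(
      sprintf("Age 35-49 every %s", words[iv]),
      screen_start_age = 35, screen_end_age = 49, interval_years = iv)
  }
  for (iv in 1:5) {
    out[[length(out) + 1L]] <- strategy_spec(
      sprintf("Age >=50 every %s", words[iv]),
      screen_start_age = 50, screen_end_age = settings$max_age,
      interval_years = iv)
  }
  out
}

# ---- Config I/O ------------------------------------------------------------

#' Write a model configuration to a YAML file
#'
#' The configuration holds the parameter set, model settings, an optional
#' strategy list, and schedule specifications (inline values, a CSV path, or
#' a synthetic-generator spec).
#'
#' @param params,settings model inputs.
#' @param strategies optional list of [strategy_spec()].
#' @param schedules optional list with elements `incidence` and `mortality`,
#'   each an [age_schedule()] (written inline) or a list spec.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, settings, path, strategies = NULL,
                        schedules = NULL) {
  ser_sched <- function(s) {
    if (inherits(s, "age_schedule")) {
      list(values = stats::setNames(as.list(s$value), s$age))
    } else {
      s
    }
  }
  cfg <- list(
    parameters = unclass(params),
    settings = unclass(settings)
  )
  if (!is.null(strategies)) cfg$strategies <- lapply(strategies, unclass)
  if (!is.null(schedules)) cfg$schedules <- lapply(schedules, ser_sched)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Load and validate a model configuration
#'
#' @param path YAML file written by [save_config()] or by hand.
#' @return A list with `params`, `settings`, `strategies` (possibly `NULL`)
#'   and `schedules` (possibly `NULL`; synthetic specs are expanded by
#'   calling the generators).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("parameters", "settings")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("config is missing required section '%s'", key), call. = FALSE)
    }
  }
  pl <- cfg$parameters
  if (!is.null(pl$monitoring_cost_schedule)) {
    pl$monitoring_cost_schedule <- as.numeric(unlist(pl$monitoring_cost_schedule))
  }
  if (!is.null(pl$ranges)) pl$ranges <- lapply(pl$ranges, as.numeric)
  params <- do.call(dare_parameters, pl)
  settings <- do.call(dare_settings, cfg$settings)
  strategies <- NULL
  if (!is.null(cfg$strategies)) {
    strategies <- lapply(cfg$strategies, function(s) do.call(strategy_spec, s))
  }
  schedules <- NULL
  if (!is.null(cfg$schedules)) {
    schedules <- .expand_schedules(cfg$schedules, params, settings, dirname(path))
  }
  list(params = params, settings = settings, strategies = strategies,
       schedules = schedules)
}

.expand_schedules <- function(spec, params, settings, base_dir = ".") {
  for (key in c("incidence", "mortality")) {
    if (is.null(spec[[key]])) {
      stop(sprintf(paste0("config section 'schedules' must provide '%s' as inline ",
                          "values, a CSV path, or a synthetic generator spec"), key),
           call. = FALSE)
    }
  }
  kind_of <- c(incidence = "incidence", mortality = "other_cause_mortality")
  out <- list()
  # mortality first: a synthetic incidence spec may calibrate against it
  for (key in c("mortality", "incidence")) {
    s <- spec[[key]]
    if (inherits(s, "age_schedule")) {
      out[[key]] <- s
    } else if (!is.null(s$values)) {
      ages <- as.integer(names(s$values))
      o <- order(ages)
      out[[key]] <- age_schedule(kind_of[[key]], ages[o],
                                 as.numeric(unlist(s$values))[o])
    } else if (!is.null(s$csv)) {
      p <- s$csv
      if (!file.exists(p)) p <- file.path(base_dir, s$csv)
      out[[key]] <- read_age_schedule(p, kind_of[[key]])
    } else if (!is.null(s$synthetic)) {
      g <- s$synthetic
      if (key == "mortality") {
        out[[key]] <- gen_mortality_schedule(
          seed = g$seed %||% 1L,
          multiplier = g$multiplier %||% 1,
          settings = settings)
      } else {
        out[[key]] <- gen_incidence_schedule(
          seed = g$seed %||% 1L,
          peak_annual_prob = g$peak_annual_prob %||% 0.004,
          target_lifetime_risk = g$target_lifetime_risk,
          mortality = out$mortality,
          params = params, settings = settings)
      }
    } else {
      stop(sprintf(paste0("schedule '%s' must provide 'values', 'csv', or a ",
                          "'synthetic' generator spec"), key), call. = FALSE)
    }
  }
  out[c("incidence", "mortality")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dare_parameters <- function(x, ...) {
  cat("<dare_parameters>\n")
  cat(sprintf("  DARE sensitivity %.2f, referral PPV %.2f\n",
              x$dare_sensitivity, x$dare_ppv))
  cat(sprintf("  background detection (local/regional/distal): %.2f/%.2f/%.2f\n",
              x$p_background_detect_local, x$p_background_detect_regional,
              x$p_background_detect_distal))
  cat(sprintf("  costs (screen/FP/workup): %g/%g/%g AUD\n",
              x$cost_screen, x$cost_false_positive, x$cost_workup))
  cat(sprintf("  utilities (none/local/regional/distal): %.2f/%.2f/%.2f/%.2f\n",
              x$utility_no_cancer, x$utility_local, x$utility_regional,
              x$utility_distal))
  invisible(x)
}

#' @export
print.strategy_spec <- function(x, ...) {
  if (x$screening) {
    cat(sprintf("<strategy> %s: ages %d-%d every %d year(s)\n", x$label,
                x$screen_start_age, x$screen_end_age, x$interval_years))
  } else {
    cat(sprintf("<strategy> %s (no screening)\n", x$label))
  }
  invisible(x)
}
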
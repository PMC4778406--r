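#' Synthetic study inputs
#'
#' The original evaluation drew its age-specific anal-cancer incidence, its
#' HIV-cohort other-cause mortality, and its stage-specific relative-survival
#' curves from registry extracts that are not distributed with this package.
#' The generators here emulate those inputs' statistical structure — an
#' age-rising incidence ramp with a roughly nine-fold ratio between ages
#' 50-64 and 35-49 and a ~3% lifetime risk of diagnosis; Gompertz-shaped
#' cohort mortality; Weibull-shaped relative survival with sampling noise —
#' so the whole pipeline runs and is testable self-contained. They are
#' synthetic fixtures, not the original registry data.
#'
#' @name synthetic_data
NULL

# logistic ramp with plateau after 65; constants chosen so the mean annual
# probability at ages 50-64 is ~9x that at ages 35-49
.incidence_shape <- function(age, midpoint = 54, steepness = 4, plateau_age = 65) {
  stats::plogis((pmin(age, plateau_age) - midpoint) / steepness) /
    stats::plogis((plateau_age - midpoint) / steepness)
}

#' Generate an age-specific anal-cancer incidence schedule
#'
#' A smooth age-rising logistic ramp over the model's age range, flat after
#' age 65, scaled so the plateau equals `peak_annual_prob`. If
#' `target_lifetime_risk` is given, a global multiplier is calibrated by
#' root-finding so that the no-screening cohort's lifetime cumulative
#' probability of diagnosis hits the target within ±0.2 percentage points
#' (the cohort engine itself is the calibration oracle).
#'
#' @param seed integer recorded with the schedule (the construction is
#'   deterministic; the seed is metadata for provenance sidecars).
#' @param peak_annual_prob plateau annual probability, in (0, 0.05\]
#'   (0 returns an all-zero schedule).
#' @param target_lifetime_risk optional lifetime diagnosis risk to calibrate
#'   to (e.g. 0.03).
#' @param mortality other-cause mortality [age_schedule()] used during
#'   calibration (default [gen_mortality_schedule()]).
#' @param params,settings model inputs used during calibration (defaults:
#'   the base case).
#' @return An `age_schedule` of kind `"incidence"`; attributes record the
#'   seed and any calibrated multiplier.
#' @export
gen_incidence_schedule <- function(seed = 1L, peak_annual_prob = 0.004,
                                   target_lifetime_risk = NULL,
                                   mortality = NULL, params = NULL,
                                   settings = NULL) {
  if (is.null(settings)) settings <- dare_settings()
  ages <- settings$start_age:settings$max_age
  if (peak_annual_prob == 0) {
    out <- age_schedule("incidence", ages, rep(0, length(ages)))
    attr(out, "seed") <- seed
    return(out)
  }
  if (peak_annual_prob < 0 || peak_annual_prob > 0.05) {
    stop("peak_annual_prob must lie in (0, 0.05]", call. = FALSE)
  }
  base <- peak_annual_prob * .incidence_shape(ages)
  mult <- 1
  if (!is.null(target_lifetime_risk)) {
    if (is.null(params)) params <- dare_parameters()
    if (is.null(mortality)) mortality <- gen_mortality_schedule(seed, settings = settings)
    risk_at <- function(m) {
      sched <- age_schedule("incidence", ages, pmin(1, m * base))
      res <- run_cohort(no_screening_strategy(), params, settings,
                        list(incidence = sched, mortality = mortality),
                        trace = FALSE)
      validation_summary(res)$lifetime_risk
    }
    m_hi <- 0.05 / peak_annual_prob   # keep calibrated probabilities <= 0.05
    if (risk_at(m_hi) < target_lifetime_risk - 0.002) {
      stop("calibration error: target lifetime risk unattainable under the ",
           "mortality schedule", call. = FALSE)
    }
    mult <- stats::uniroot(function(m) risk_at(m) - target_lifetime_risk,
                           c(0, m_hi), tol = 1e-6)$root
    achieved <- risk_at(mult)
    if (abs(achieved - target_lifetime_risk) > 0.002) {
      stop("calibration error: lifetime risk converged outside tolerance",
           call. = FALSE)
    }
  }
  out <- age_schedule("incidence", ages, pmin(1, mult * base))
  attr(out, "seed") <- seed
  attr(out, "multiplier") <- mult
  attr(out, "peak_annual_prob") <- peak_annual_prob
  out
}

#' Generate a Gompertz-shaped other-cause mortality schedule
#'
#' Annual death probabilities `min(1, multiplier * b * exp(g * (age - 35)))`
#' emulating an HIV-cohort's elevated all-cause mortality; `multiplier`
#' scales the whole schedule (0 gives a degenerate immortal cohort).
#'
#' @param seed integer recorded as metadata (construction is deterministic).
#' @param multiplier non-negative global scaling factor.
#' @param settings model settings supplying the age range.
#' @param baseline annual probability at the start age (before scaling).
#' @param log_slope Gompertz log-slope per year of age.
#' @return An `age_schedule` of kind `"other_cause_mortality"`.
#' @export
gen_mortality_schedule <- function(seed = 1L, multiplier = 1,
                                   settings = dare_settings(),
                                   baseline = 0.0012, log_slope = 0.088) {
  if (multiplier < 0) stop("multiplier must be >= 0", call. = FALSE)
  ages <- settings$start_age:settings$max_age
  p <- pmin(1, multiplier * baseline * exp(log_slope * (ages - settings$start_age)))
  out <- age_schedule("other_cause_mortality", ages, p)
  attr(out, "seed") <- seed
  attr(out, "multiplier") <- multiplier
  out
}

#' Calibrate the mortality multiplier to a discounted life expectancy
#'
#' Root-finds the [gen_mortality_schedule()] multiplier so that a cancer-free
#' cohort's discounted life expectancy at the settings' discount rate equals
#' `target_disc_le`.
#'
#' @param target_disc_le target discounted life-years.
#' @param params,settings model inputs (defaults: base case).
#' @param interval search interval for the multiplier.
#' @return The calibrated multiplier (numeric scalar).
#' @export
calibrate_mortality_multiplier <- function(target_disc_le = 24.2034,
                                           params = dare_parameters(),
                                           settings = dare_settings(),
                                           interval = c(0.05, 25)) {
  ages <- settings$start_age:settings$max_age
  zero_inc <- age_schedule("incidence", ages, rep(0, length(ages)))
  le_at <- function(m) {
    sched <- gen_mortality_schedule(multiplier = m, settings = settings)
    run_cohort(no_screening_strategy(), params, settings,
               list(incidence = zero_inc, mortality = sched),
               trace = FALSE)$summary$life_years_disc
  }
  stats::uniroot(function(m) le_at(m) - target_disc_le, interval,
                 tol = 1e-7)$root
}

.darecea_cache <- new.env(parent = emptyenv())

#' The packaged reference fixture schedules
#'
#' The calibrated synthetic schedules used throughout the package's examples
#' and tests: mortality scaled so a cancer-free cohort's discounted (3%)
#' life expectancy is ~24.2 years, and incidence calibrated so the
#' no-screening lifetime diagnosis risk is 3%. This is a documented fixture
#' emulating the original study conditions, not the original inputs.
#'
#' @param seed integer seed recorded with the schedules.
#' @param params,settings model inputs (defaults: base case).
#' @return A list with `incidence` and `mortality` schedules (plus the
#'   calibrated multipliers as attributes on each).
#' @export
reference_schedules <- function(seed = 1L, params = dare_parameters(),
                                settings = dare_settings()) {
  key <- paste0("ref_", seed, "_", settings$start_age, "_", settings$max_age)
  if (!is.null(.darecea_cache[[key]])) return(.darecea_cache[[key]])
  m <- calibrate_mortality_multiplier(params = params, settings = settings)
  mortality <- gen_mortality_schedule(seed, multiplier = m, settings = settings)
  incidence <- gen_incidence_schedule(seed, target_lifetime_risk = 0.03,
                                      mortality = mortality, params = params,
                                      settings = settings)
  out <- list(incidence = incidence, mortality = mortality)
  .darecea_cache[[key]] <- out
  out
}

#' Generate a stage-specific relative-survival dataset
#'
#' Evaluates the Weibull curve S(t) = exp(-(t/scale)^shape) on integer years
#' 0..`horizon_years`, adds truncated Gaussian noise emulating sampled
#' survival proportions, and enforces monotone non-increase by isotonic
#' clipping (running minimum). S(0) is always 1. The noise is
#' heteroscedastic, as sampled proportions are: each point's standard
#' deviation is `noise_sd` times the binomial standard error
#' `sqrt(S(1 - S)/n_at_risk)`, so far-tail points (survival near 0 or 1) are
#' measured more precisely than the middle of the curve.
#'
#' @param stage `"local"`, `"regional"` or `"distal"`.
#' @param shape,scale Weibull parameters (> 0).
#' @param horizon_years last follow-up year.
#' @param noise_sd noise level as a multiple of the binomial standard error
#'   at `n_at_risk` (0 for the exact curve; 1 emulates simple binomial
#'   sampling).
#' @param n_at_risk number at risk recorded per time point (used as fit
#'   weights by [fit_weibull()]).
#' @param seed RNG seed for the noise.
#' @return An object of classes `survival_dataset`/`data.frame` with columns
#'   `years_since_diagnosis`, `relative_survival`, `n_at_risk`; attributes
#'   record stage and generating parameters.
#' @export
gen_survival_dataset <- function(stage = c("local", "regional", "distal"),
                                 shape, scale, horizon_years = 20,
                                 noise_sd = 1, n_at_risk = 2000, seed = 1L) {
  stage <- match.arg(stage)
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0", call. = FALSE)
  t <- 0:horizon_years
  s <- exp(-(t / scale)^shape)
  if (noise_sd > 0) {
    set.seed(seed)
    se <- sqrt(s * (1 - s) / n_at_risk)
    s <- s + stats::rnorm(length(t), 0, noise_sd * se)
    s <- pmin(1, pmax(1e-8, s))
    s[1] <- 1
    s <- cummin(s)   # isotonic clipping: survival cannot increase
  }
  out <- data.frame(years_since_diagnosis = t, relative_survival = s,
                    n_at_risk = n_at_risk)
  class(out) <- c("survival_dataset", "data.frame")
  attr(out, "stage") <- stage
  attr(out, "shape") <- shape
  attr(out, "scale") <- scale
  attr(out, "seed") <- seed
  out
}

#' Write a survival dataset as CSV with a metadata sidecar
#'
#' @param data a `survival_dataset`.
#' @param path CSV output path; a `<path>.meta.json` sidecar records the
#'   stage, generating parameters and seed.
#' @return `path`, invisibly.
#' @export
write_survival_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- list(stage = attr(data, "stage"), shape = attr(data, "shape"),
               scale = attr(data, "scale"), seed = attr(data, "seed"),
               synthetic = TRUE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_survival_dataset
#' @param path CSV path written by [write_survival_dataset()]; the metadata
#'   sidecar is read when present.
#' @export
read_survival_dataset <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("years_since_diagnosis", "relative_survival") %in% names(df))) {
    stop("survival CSV needs columns 'years_since_diagnosis' and 'relative_survival'",
         call. = FALSE)
  }
  class(df) <- c("survival_dataset", "data.frame")
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(df, "stage") <- meta$stage
    attr(df, "shape") <- meta$shape
    attr(df, "scale") <- meta$scale
  }
  df
}

#' Generate a random strategy table for frontier testing
#'
#' Random positive (cost, effect) pairs with, by construction, at least one
#' strictly dominated strategy and (for n >= 3) one strategy lying strictly
#' above the chord between two others, hence removable only by extended
#' dominance.
#'
#' @param seed RNG seed.
#' @param n_strategies number of strategies, 2 to 12.
#' @return A data frame with columns `label`, `cost`, `effect`.
#' @export
gen_strategy_table <- function(seed = 1L, n_strategies = 6L) {
  n <- as.integer(n_strategies)
  if (n < 2 || n > 12) stop("n_strategies must be between 2 and 12", call. = FALSE)
  set.seed(seed)
  if (n == 2) {
    e <- stats::runif(1, 1, 10)
    c1 <- stats::runif(1, 100, 5000)
    df <- data.frame(cost = c(c1, c1 + stats::runif(1, 50, 500)),
                     effect = c(e, e))  # equal effects: costlier is dominated
  } else {
    nb <- n - 2L
    df <- data.frame(cost = stats::runif(nb, 100, 5000),
                     effect = stats::runif(nb, 1, 10))
    # strictly dominated: worse on both axes than an existing strategy
    i <- sample.int(nb, 1)
    df <- rbind(df, data.frame(cost = df$cost[i] + stats::runif(1, 50, 500),
                               effect = df$effect[i] * stats::runif(1, 0.7, 0.95)))
    # extended-dominance candidate: strictly above a chord between two others
    ij <- order(df$effect[seq_len(nb)])[c(1, nb)]
    lam <- stats::runif(1, 0.3, 0.7)
    df <- rbind(df, data.frame(
      cost = lam * df$cost[ij[1]] + (1 - lam) * df$cost[ij[2]] +
        stats::runif(1, 50, 500),
      effect = lam * df$effect[ij[1]] + (1 - lam) * df$effect[ij[2]]))
  }
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  data.frame(label = sprintf("S%02d", seq_len(n)), cost = df$cost,
             effect = df$effect, row.names = NULL)
}
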
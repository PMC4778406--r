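#' Markov cohort engine
#'
#' The cohort starts cancer-free at the entry age and is followed in one-year
#' cycles to the horizon age. Health states are: cancer-free; undetected
#' cancer in three stages (local, regional, distal), each subdivided by dwell
#' year within the progression interval; detected cancer in three stages,
#' each subdivided by a time-since-diagnosis tunnel so monitoring costs and
#' excess mortality can depend on elapsed time; and two absorbing death
#' states (cancer death, other-cause death) kept separate for validation
#' bookkeeping. Undetected cancer progresses one stage per progression
#' interval; undetected distal cancer is fatal after its interval. Treated
#' patients never return to a cancer-free state: they remain in their
#' detected track and follow the stage's relative-survival curve.
#'
#' Within a cycle events apply in order: screening detection, background
#' (symptomatic) detection, progression, incidence, mortality, and finally
#' the dwell/tunnel clock advances.
#'
#' @name markov_engine
NULL

# Precomputed state-space bookkeeping shared by the per-cycle kernel.
.state_space <- function(params, settings) {
  k <- as.integer(params$progression_interval_years)
  H <- settings$max_age - settings$start_age       # number of cycles
  Tmax <- H                                        # tunnel years 0 .. H-1
  nms <- c("no_cancer",
           unlist(lapply(.stages, function(st) paste0("undet_", st, "_d", 0:(k - 1)))),
           unlist(lapply(.stages, function(st) paste0("det_", st, "_t", 0:(Tmax - 1)))),
           "dead_cancer", "dead_other")
  idx <- seq_along(nms)
  names(idx) <- nms
  undet <- lapply(.stages, function(st) unname(idx[paste0("undet_", st, "_d", 0:(k - 1))]))
  det <- lapply(.stages, function(st) unname(idx[paste0("det_", st, "_t", 0:(Tmax - 1))]))
  names(undet) <- names(det) <- .stages
  # annual excess death probability by stage and tunnel year
  emm <- params$excess_mortality_multiplier
  if (length(emm) == 1L) emm <- stats::setNames(rep(emm, 3), .stages)
  qexc <- lapply(.stages, function(st) {
    wp <- params$survival[[st]]
    pmin(1, emm[[st]] * annual_death_prob(wp, 0:(Tmax - 1)))
  })
  names(qexc) <- .stages
  # per-state utility weight
  u <- numeric(length(nms))
  u[idx["no_cancer"]] <- params$utility_no_cancer
  ustage <- c(local = params$utility_local, regional = params$utility_regional,
              distal = params$utility_distal)
  for (st in .stages) {
    u[undet[[st]]] <- ustage[[st]]
    tu <- pmin(params$treatment_utility_years, Tmax)
    uvec <- rep(params$utility_no_cancer, Tmax)
    if (tu > 0) uvec[seq_len(tu)] <- ustage[[st]]
    u[det[[st]]] <- uvec
  }
  # per-state monitoring cost by tunnel year (treatment year t = 0 is charged
  # workup + treatment at diagnosis instead)
  mon <- numeric(length(nms))
  sched <- params$monitoring_cost_schedule
  for (st in .stages) {
    mvec <- numeric(Tmax)
    nsched <- min(length(sched), Tmax - 1)
    if (nsched > 0) mvec[1 + seq_len(nsched)] <- sched[seq_len(nsched)]
    mon[det[[st]]] <- mvec
  }
  list(names = nms, n = length(nms), idx = idx, k = k, H = H, Tmax = Tmax,
       i_nc = unname(idx["no_cancer"]), undet = undet, det = det,
       i_dc = unname(idx["dead_cancer"]), i_do = unname(idx["dead_other"]),
       qexc = qexc, utility = u, monitoring = mon,
       alive = seq_len(length(nms) - 2L))
}

# One model cycle. occ is an unnamed numeric vector over ss$names.
# Returns list(occ, ev) where ev collects the cycle's expected event counts.
.step_kernel <- function(occ, age, strategy, params, settings, schedules, ss) {
  ev <- list(screens = 0, fp = 0,
             diag_screen = c(local = 0, regional = 0, distal = 0),
             diag_bg = c(local = 0, regional = 0, distal = 0),
             deaths_cancer = 0, deaths_other = 0, incident = 0)

  # 1. screening
  if (screen_due(strategy, age) && settings$screening_uptake > 0) {
    uptake <- settings$screening_uptake
    nc <- occ[ss$i_nc]
    undet_mass <- c(local = sum(occ[ss$undet$local]),
                    regional = sum(occ[ss$undet$regional]),
                    distal = sum(occ[ss$undet$distal]))
    screened <- nc + sum(undet_mass)
    if (screened > 0) {
      prev <- sum(undet_mass) / screened
      fpr <- fp_rate_from_ppv(prev, params$dare_sensitivity, params$dare_ppv)
      ev$fp <- uptake * fpr * nc
      ev$screens <- uptake * screened
      pdet <- uptake * params$dare_sensitivity
      for (st in .stages) {
        d <- pdet * occ[ss$undet[[st]]]
        dd <- sum(d)
        if (dd > 0) {
          occ[ss$undet[[st]]] <- occ[ss$undet[[st]]] - d
          occ[ss$det[[st]][1]] <- occ[ss$det[[st]][1]] + dd
          ev$diag_screen[[st]] <- ev$diag_screen[[st]] + dd
        }
      }
    }
  }

  # 2. background (symptomatic) detection
  pbg <- c(local = params$p_background_detect_local,
           regional = params$p_background_detect_regional,
           distal = params$p_background_detect_distal)
  for (st in .stages) {
    d <- pbg[[st]] * occ[ss$undet[[st]]]
    dd <- sum(d)
    if (dd > 0) {
      occ[ss$undet[[st]]] <- occ[ss$undet[[st]]] - d
      occ[ss$det[[st]][1]] <- occ[ss$det[[st]][1]] + dd
      ev$diag_bg[[st]] <- ev$diag_bg[[st]] + dd
    }
  }

  # 3. progression: the top dwell layer of each stage moves on; the rest age
  # one dwell year. Undetected distal cancer is fatal after its interval.
  k <- ss$k
  top <- function(st) occ[ss$undet[[st]][k]]
  prog_local <- top("local"); prog_reg <- top("regional"); prog_dist <- top("distal")
  shift_dwell <- function(ix, inflow) {
    old <- occ[ix]
    if (k > 1) occ[ix[2:k]] <<- old[1:(k - 1)]
    occ[ix[1]] <<- inflow
  }
  shift_dwell(ss$undet$local, 0)
  shift_dwell(ss$undet$regional, prog_local)
  shift_dwell(ss$undet$distal, prog_reg)
  occ[ss$i_dc] <- occ[ss$i_dc] + prog_dist
  ev$deaths_cancer <- ev$deaths_cancer + prog_dist

  # 4. incidence: cancer-free -> undetected local (dwell 0)
  p_inc <- schedule_prob(schedules$incidence, age)
  inc <- p_inc * occ[ss$i_nc]
  occ[ss$i_nc] <- occ[ss$i_nc] - inc
  occ[ss$undet$local[1]] <- occ[ss$undet$local[1]] + inc
  ev$incident <- inc

  # 5. mortality: other-cause for all alive states; excess cancer mortality
  # (relative-survival curves) for detected states by tunnel year.
  p_oth <- schedule_prob(schedules$mortality, age)
  nocancer_ix <- c(ss$i_nc, unlist(ss$undet, use.names = FALSE))
  d_oth <- p_oth * sum(occ[nocancer_ix])
  occ[nocancer_ix] <- occ[nocancer_ix] * (1 - p_oth)
  dc <- 0
  for (st in .stages) {
    ix <- ss$det[[st]]
    m <- occ[ix]
    q <- ss$qexc[[st]]
    d_oth <- d_oth + p_oth * sum(m)
    dc <- dc + sum(m * (1 - p_oth) * q)
    occ[ix] <- m * (1 - p_oth) * (1 - q)
  }
  occ[ss$i_do] <- occ[ss$i_do] + d_oth
  occ[ss$i_dc] <- occ[ss$i_dc] + dc
  ev$deaths_other <- d_oth
  ev$deaths_cancer <- ev$deaths_cancer + dc

  # 6. tunnel clock: detected tracks age one year; the top layer aggregates.
  for (st in .stages) {
    ix <- ss$det[[st]]
    Tn <- length(ix)
    old <- occ[ix]
    occ[ix[2:Tn]] <- old[1:(Tn - 1)]
    occ[ix[Tn]] <- occ[ix[Tn]] + old[Tn]
    occ[ix[1]] <- 0
  }

  list(occ = occ, ev = ev)
}

#' Advance the cohort by one cycle
#'
#' Applies one year of screening, background detection, progression,
#' incidence, mortality, and clock advance to a named occupancy vector.
#'
#' @param occupancy named occupancy vector over the model's state space
#'   (see [init_occupancy()]); must sum to 1.
#' @param age integer age at the start of the cycle.
#' @param strategy a [strategy_spec()].
#' @param params a [dare_parameters()] object.
#' @param settings a [dare_settings()] object.
#' @param schedules list with [age_schedule()] elements `incidence` and
#'   `mortality`.
#' @return A list: `occupancy` (named vector after the cycle) and `events`
#'   (expected counts: screens, false positives, diagnoses by stage and
#'   route, deaths, incident cancers).
#' @export
step_cohort <- function(occupancy, age, strategy, params, settings, schedules) {
  ss <- .state_space(params, settings)
  if (!identical(names(occupancy), ss$names)) {
    occupancy <- occupancy[ss$names]
    if (anyNA(occupancy)) {
      stop("occupancy names do not match the model state space; use init_occupancy()",
           call. = FALSE)
    }
  }
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancy must sum to 1", call. = FALSE)
  }
  res <- .step_kernel(as.numeric(occupancy), age, strategy, params, settings,
                      schedules, ss)
  list(occupancy = stats::setNames(res$occ, ss$names), events = res$ev)
}

#' Initial occupancy vector (everyone cancer-free)
#'
#' @inheritParams step_cohort
#' @return Named numeric vector summing to 1.
#' @export
init_occupancy <- function(params, settings) {
  ss <- .state_space(params, settings)
  occ <- numeric(ss$n)
  occ[ss$i_nc] <- 1
  stats::setNames(occ, ss$names)
}

#' Half-cycle-corrected discounting
#'
#' Payoffs accrued during a cycle are valued at the cycle midpoint:
#' `value * (1 + rate)^-(cycle_index - 0.5)` with 1-based cycle indices.
#'
#' @param value payoff accrued in the cycle.
#' @param rate annual discount rate (>= 0).
#' @param cycle_index 1-based cycle number.
#' @return The discounted value.
#' @export
#' @examples
#' discount(100, 0.03, 1)  # 100 * 1.03^-0.5 = 98.533
discount <- function(value, rate, cycle_index) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  value * (1 + rate)^(-(cycle_index - 0.5))
}

#' Run the cohort model for one strategy
#'
#' Iterates the cohort from the entry age to the horizon, accumulating
#' undiscounted and discounted lifetime costs, life-years and QALYs with
#' half-cycle-corrected discounting. Costs comprise screening, false-positive
#' referrals, workup plus stage-specific treatment at diagnosis (a configured
#' fraction of localized cancers receives local excision instead of
#' chemoradiation), and post-diagnosis monitoring by year since diagnosis.
#' Life-years and utility weights accrue on start-of-cycle occupancy.
#'
#' @inheritParams step_cohort
#' @param trace keep the full per-cycle occupancy matrix? (`FALSE` saves
#'   memory in large sensitivity runs; events are always kept)
#' @return An object of class `cohort_result`: a list with `summary` (an
#'   `outcome_summary` row), `events` (per-cycle data frame), and `trace`
#'   (cycle-by-state occupancy matrix, or `NULL`), plus the inputs' labels.
#' @export
run_cohort <- function(strategy, params, settings, schedules, trace = TRUE) {
  validate_parameters(params, check_ranges = FALSE)
  validate_settings(settings)
  ss <- .state_space(params, settings)
  # treatment cost at diagnosis by stage (local: excision fraction)
  sef <- params$surgical_excision_fraction
  tx <- c(local = (1 - sef) * params$cost_treat_local + sef * params$cost_treat_excision,
          regional = params$cost_treat_regional,
          distal = params$cost_treat_distal)
  occ <- numeric(ss$n)
  occ[ss$i_nc] <- 1
  H <- ss$H
  r <- settings$discount_rate
  df <- (1 + r)^(-(seq_len(H) - 0.5))

  cost_c <- ly_c <- qaly_c <- numeric(H)
  ev_rows <- vector("list", H)
  tr <- if (trace) matrix(0, H, ss$n, dimnames = list(NULL, ss$names)) else NULL

  for (i in seq_len(H)) {
    age <- settings$start_age + i - 1L
    if (trace) tr[i, ] <- occ
    alive_start <- 1 - occ[ss$i_dc] - occ[ss$i_do]
    qaly_start <- sum(occ * ss$utility)
    mon_cost <- sum(occ * ss$monitoring)

    res <- .step_kernel(occ, age, strategy, params, settings, schedules, ss)
    ev <- res$ev
    occ <- res$occ
    if (abs(sum(occ) - 1) > 1e-9) {
      stop(sprintf("probability mass not conserved at cycle %d (sum %.12f)",
                   i, sum(occ)), call. = FALSE)
    }

    diag_total <- ev$diag_screen + ev$diag_bg
    cost_c[i] <- ev$screens * params$cost_screen +
      ev$fp * params$cost_false_positive +
      sum(diag_total) * params$cost_workup +
      sum(diag_total * tx[.stages]) +
      mon_cost
    ly_c[i] <- alive_start
    qaly_c[i] <- qaly_start - ev$fp * params$fp_disutility
    ev_rows[[i]] <- c(cycle = i, age = age, screens = ev$screens, fp = ev$fp,
                      diag_screen_local = ev$diag_screen[["local"]],
                      diag_screen_regional = ev$diag_screen[["regional"]],
                      diag_screen_distal = ev$diag_screen[["distal"]],
                      diag_bg_local = ev$diag_bg[["local"]],
                      diag_bg_regional = ev$diag_bg[["regional"]],
                      diag_bg_distal = ev$diag_bg[["distal"]],
                      incident = ev$incident,
                      deaths_cancer = ev$deaths_cancer,
                      deaths_other = ev$deaths_other,
                      cost = cost_c[i])
  }

  events <- as.data.frame(do.call(rbind, ev_rows))
  diag_by_stage <- c(
    local = sum(events$diag_screen_local + events$diag_bg_local),
    regional = sum(events$diag_screen_regional + events$diag_bg_regional),
    distal = sum(events$diag_screen_distal + events$diag_bg_distal))
  n_diag <- sum(diag_by_stage)
  summary <- structure(list(
    label = strategy$label,
    cost = sum(cost_c), cost_disc = sum(cost_c * df),
    life_years = sum(ly_c), life_years_disc = sum(ly_c * df),
    qaly = sum(qaly_c), qaly_disc = sum(qaly_c * df),
    diagnoses = diag_by_stage,
    diagnoses_screen = c(local = sum(events$diag_screen_local),
                         regional = sum(events$diag_screen_regional),
                         distal = sum(events$diag_screen_distal)),
    localized_fraction = if (n_diag > 0) unname(diag_by_stage["local"]) / n_diag else NA_real_,
    screens = sum(events$screens), false_positives = sum(events$fp)
  ), class = "outcome_summary")
  structure(list(summary = summary, events = events, trace = tr,
                 strategy = strategy, settings = settings),
            class = "cohort_result")
}

#' Run several strategies and collect an outcome table
#'
#' @param strategies list of [strategy_spec()] objects.
#' @inheritParams run_cohort
#' @return A data frame with one row per strategy: undiscounted and
#'   discounted cost, life-years and QALYs, the localized fraction of
#'   detected cancers, screens and false positives.
#' @export
run_strategies <- function(strategies, params, settings, schedules) {
  if (length(strategies) == 0) stop("empty strategy list", call. = FALSE)
  rows <- lapply(strategies, function(s) {
    sm <- run_cohort(s, params, settings, schedules, trace = FALSE)$summary
    data.frame(label = sm$label, cost = sm$cost, cost_disc = sm$cost_disc,
               life_years = sm$life_years, life_years_disc = sm$life_years_disc,
               qaly = sm$qaly, qaly_disc = sm$qaly_disc,
               localized_fraction = sm$localized_fraction,
               diagnoses = sum(sm$diagnoses), screens = sm$screens,
               false_positives = sm$false_positives,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Validation summaries of a completed run
#'
#' Reports the stage-at-diagnosis distribution, the lifetime cumulative
#' probability of an anal-cancer diagnosis, and the distribution of
#' diagnoses over age bands (35-44, 45-54, ..., 85+).
#'
#' @param result a `cohort_result` from [run_cohort()] (or its `events`
#'   data frame).
#' @return A list: `stage_distribution`, `lifetime_risk`,
#'   `age_band_distribution`, `n_diagnoses`, and `degenerate` (`TRUE` when
#'   there were no diagnoses, in which case distributions are `NA`).
#' @export
validation_summary <- function(result) {
  events <- if (inherits(result, "cohort_result")) result$events else result
  stage <- c(local = sum(events$diag_screen_local + events$diag_bg_local),
             regional = sum(events$diag_screen_regional + events$diag_bg_regional),
             distal = sum(events$diag_screen_distal + events$diag_bg_distal))
  total <- sum(stage)
  per_cycle <- events$diag_screen_local + events$diag_screen_regional +
    events$diag_screen_distal + events$diag_bg_local + events$diag_bg_regional +
    events$diag_bg_distal
  bands <- c("35-44" = 35, "45-54" = 45, "55-64" = 55, "65-74" = 65,
             "75-84" = 75, "85+" = 85)
  band_of <- cut(events$age, c(unname(bands), Inf), right = FALSE,
                 labels = names(bands))
  age_band <- tapply(per_cycle, band_of, sum, default = 0)
  if (total > 0) {
    list(stage_distribution = stage / total, lifetime_risk = total,
         age_band_distribution = age_band / total, n_diagnoses = total,
         degenerate = FALSE)
  } else {
    list(stage_distribution = stats::setNames(rep(NA_real_, 3), .stages),
         lifetime_risk = 0,
         age_band_distribution = stats::setNames(rep(NA_real_, length(bands)),
                                                 names(bands)),
         n_diagnoses = 0, degenerate = TRUE)
  }
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %s\n", x$label))
  cat(sprintf("  cost: %.2f (disc %.2f) AUD\n", x$cost, x$cost_disc))
  cat(sprintf("  life-years: %.4f (disc %.4f)\n", x$life_years, x$life_years_disc))
  cat(sprintf("  QALYs: %.4f (disc %.4f)\n", x$qaly, x$qaly_disc))
  cat(sprintf("  diagnoses (L/R/D): %.5f/%.5f/%.5f, localized fraction %.3f\n",
              x$diagnoses["local"], x$diagnoses["regional"], x$diagnoses["distal"],
              x$localized_fraction))
  invisible(x)
}

#' Write a cohort trace and per-cycle events to CSV
#'
#' @param result a `cohort_result`.
#' @param trace_path,events_path output files (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_cohort_result <- function(result, trace_path = NULL, events_path = NULL) {
  if (!is.null(trace_path)) {
    stopifnot(!is.null(result$trace))
    df <- data.frame(cycle = seq_len(nrow(result$trace)),
                     age = result$settings$start_age + seq_len(nrow(result$trace)) - 1L,
                     result$trace, check.names = FALSE)
    utils::write.csv(df, trace_path, row.names = FALSE)
  }
  if (!is.null(events_path)) {
    utils::write.csv(result$events, events_path, row.names = FALSE)
  }
  invisible(c(trace_path, events_path))
}
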
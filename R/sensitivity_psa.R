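#' One-way and probabilistic sensitivity analysis
#'
#' One-way analysis re-runs the full pipeline over a grid of values for a
#' single parameter, holding everything else at base. Probabilistic
#' sensitivity analysis is second-order Monte Carlo: each iteration draws
#' every varied parameter from its distribution (gamma for costs, beta for
#' utilities and probabilities, both parameterized by method of moments with
#' mean equal to the base value and SD a configurable fraction of it),
#' applies the same draw to every strategy, and records discounted cost and
#' QALYs, from which cost-effectiveness acceptability curves are built.
#'
#' @name sensitivity_psa
NULL

#' PSA settings
#'
#' @param n_iterations number of Monte Carlo iterations.
#' @param seed RNG seed.
#' @param sd_fraction default SD as a fraction of the base value (0.30).
#' @param sd_overrides named list of absolute SDs overriding the default for
#'   specific parameters (e.g. study-derived SDs).
#' @return An object of class `psa_settings`.
#' @export
psa_settings <- function(n_iterations = 10000L, seed = 1L, sd_fraction = 0.30,
                         sd_overrides = list()) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (sd_fraction <= 0) stop("sd_fraction must be > 0", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
                 sd_fraction = sd_fraction, sd_overrides = sd_overrides),
            class = "psa_settings")
}

# which parameters are varied, and with which distribution family
.psa_varied <- function() {
  c(dare_sensitivity = "beta", dare_ppv = "beta",
    p_background_detect_local = "beta",
    utility_no_cancer = "beta", utility_local = "beta",
    utility_regional = "beta", utility_distal = "beta",
    cost_screen = "gamma", cost_false_positive = "gamma",
    cost_workup = "gamma", cost_treat_local = "gamma",
    cost_treat_regional = "gamma", cost_treat_distal = "gamma")
}

# method-of-moments distribution table; beta variance clipped to feasibility
.psa_dists <- function(base, psa) {
  fam <- .psa_varied()
  rows <- lapply(names(fam), function(nm) {
    m <- base[[nm]]
    if (is.null(m) || m == 0) return(NULL)   # degenerate: left at base
    s <- psa$sd_overrides[[nm]] %||% (psa$sd_fraction * m)
    v <- s^2
    clipped <- FALSE
    if (fam[[nm]] == "beta") {
      vmax <- m * (1 - m)
      if (v >= vmax) {
        v <- 0.95 * vmax
        clipped <- TRUE
      }
      a <- m * (m * (1 - m) / v - 1)
      b <- (1 - m) * (m * (1 - m) / v - 1)
      if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
        stop(sprintf("infeasible beta moments for parameter '%s'", nm),
             call. = FALSE)
      }
      data.frame(param = nm, family = "beta", mean = m, sd = sqrt(v),
                 p1 = a, p2 = b, clipped = clipped)
    } else {
      shape <- m^2 / v
      scale <- v / m
      data.frame(param = nm, family = "gamma", mean = m, sd = s,
                 p1 = shape, p2 = scale, clipped = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Draw one sampled parameter set
#'
#' Consumes the current RNG stream (callers seed once, e.g. [run_psa()]).
#' Costs are gamma-distributed, utilities and probabilities beta-distributed,
#' each with mean equal to the base value and SD `sd_fraction` times it
#' (overridable per parameter); infeasible beta variances are clipped to 95%
#' of the maximum and flagged in the result's `"clipped"` attribute.
#'
#' @param base the base-case [dare_parameters()].
#' @param psa a [psa_settings()] object.
#' @param dists precomputed distribution table (internal use; recomputed
#'   when `NULL`).
#' @return A `dare_parameters` object with the varied fields replaced by
#'   draws; attribute `"draw"` holds the named draw vector.
#' @export
sample_parameters <- function(base, psa = psa_settings(), dists = NULL) {
  if (is.null(dists)) dists <- .psa_dists(base, psa)
  draw <- numeric(nrow(dists))
  for (i in seq_len(nrow(dists))) {
    draw[i] <- if (dists$family[i] == "beta") {
      stats::rbeta(1, dists$p1[i], dists$p2[i])
    } else {
      stats::rgamma(1, shape = dists$p1[i], scale = dists$p2[i])
    }
  }
  names(draw) <- dists$param
  out <- unclass(base)
  for (nm in names(draw)) out[[nm]] <- draw[[nm]]
  out <- structure(out, class = "dare_parameters")
  attr(out, "draw") <- draw
  attr(out, "clipped") <- dists$param[dists$clipped]
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' For each iteration one sampled parameter set is applied to all strategies
#' (common random parameters across strategies, for variance reduction and
#' because a draw represents one state of the world), the cohort model is
#' run, and discounted cost and QALYs are recorded.
#'
#' @param strategies list of [strategy_spec()] objects.
#' @param base base-case [dare_parameters()].
#' @param settings [dare_settings()].
#' @param schedules incidence/mortality schedules (see [reference_schedules()]).
#' @param psa a [psa_settings()] object.
#' @return An object of class `psa_draws`: list with `draws` (data frame
#'   `iteration`, `label`, `cost`, `qaly` — discounted), `params` (matrix of
#'   sampled parameter values, iterations by parameter), and `psa` settings.
#' @export
run_psa <- function(strategies, base, settings, schedules,
                    psa = psa_settings()) {
  dists <- .psa_dists(base, psa)
  if (any(dists$clipped)) {
    message("beta variance clipped to feasibility for: ",
            paste(dists$param[dists$clipped], collapse = ", "))
  }
  set.seed(psa$seed)
  n <- psa$n_iterations
  labs <- vapply(strategies, function(s) s$label, character(1))
  cost <- qaly <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
  pmat <- matrix(NA_real_, n, nrow(dists), dimnames = list(NULL, dists$param))
  for (it in seq_len(n)) {
    p_it <- sample_parameters(base, psa, dists)
    pmat[it, ] <- attr(p_it, "draw")
    for (j in seq_along(strategies)) {
      sm <- run_cohort(strategies[[j]], p_it, settings, schedules,
                       trace = FALSE)$summary
      cost[it, j] <- sm$cost_disc
      qaly[it, j] <- sm$qaly_disc
    }
  }
  draws <- data.frame(iteration = rep(seq_len(n), times = length(labs)),
                      label = rep(labs, each = n),
                      cost = as.vector(cost), qaly = as.vector(qaly))
  structure(list(draws = draws, params = pmat, psa = psa),
            class = "psa_draws")
}

#' Cost-effectiveness acceptability curves
#'
#' Default (pairwise) definition: for each strategy and willingness-to-pay
#' threshold, the fraction of iterations in which the strategy's net
#' monetary benefit versus the comparator is positive
#' (`wtp * dQALY - dcost > 0`). The multiway alternative reports the
#' fraction of iterations in which the strategy maximizes net monetary
#' benefit among all strategies in the draw set.
#'
#' @param draws a `psa_draws` object from [run_psa()].
#' @param comparator label of the comparator strategy.
#' @param wtp_grid willingness-to-pay thresholds (AUD per QALY), non-empty.
#' @param multiway use the maximum-net-benefit definition?
#' @return A data frame `label`, `wtp`, `probability`, of class `ceac`.
#' @export
ceac <- function(draws, comparator = "No screening",
                 wtp_grid = seq(0, 150000, by = 5000), multiway = FALSE) {
  if (length(wtp_grid) == 0) stop("willingness-to-pay grid is empty", call. = FALSE)
  d <- draws$draws
  labs <- unique(d$label)
  if (!comparator %in% labs) {
    stop(sprintf("comparator '%s' not present in draws", comparator), call. = FALSE)
  }
  cost <- do.call(cbind, split(d$cost, d$label))[, labs, drop = FALSE]
  qaly <- do.call(cbind, split(d$qaly, d$label))[, labs, drop = FALSE]
  rows <- list()
  if (multiway) {
    for (w in wtp_grid) {
      nmb <- w * qaly - cost
      best <- labs[max.col(nmb, ties.method = "first")]
      for (lb in labs) {
        rows[[length(rows) + 1L]] <-
          data.frame(label = lb, wtp = w, probability = mean(best == lb))
      }
    }
  } else {
    dc <- cost - cost[, comparator]
    dq <- qaly - qaly[, comparator]
    for (w in wtp_grid) {
      nb <- w * dq - dc
      for (lb in setdiff(labs, comparator)) {
        rows[[length(rows) + 1L]] <-
          data.frame(label = lb, wtp = w, probability = mean(nb[, lb] > 0))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ceac", "data.frame")
  out
}

#' One-way (univariate) sensitivity analysis
#'
#' Re-runs the full pipeline at each grid value of one parameter, holding
#' everything else at base, and reports the discounted per-QALY frontier
#' table at each value. Special parameter names: `"discount_rate"` (a model
#' setting) and `"progression_interval_years"` (integer-valued).
#'
#' @param parameter name of the parameter to vary.
#' @param range `(low, high)` bounds expanded to `n_points` equally spaced
#'   values (ignored when `values` is given).
#' @param n_points grid size for `range`.
#' @param strategies,base,settings,schedules as in [run_psa()].
#' @param values explicit grid values (overrides `range`).
#' @return A data frame with one row per (value, strategy): `parameter`,
#'   `value`, `label`, `status`, `icer_qaly` (discounted frontier ICER,
#'   rounded to the dollar, `NA` off-frontier), `acer_qaly`.
#' @export
owsa <- function(parameter, range = NULL, n_points = 3, strategies, base,
                 settings, schedules, values = NULL) {
  known <- c(names(unclass(base)), "discount_rate", "screening_uptake")
  if (!parameter %in% known) {
    stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  }
  if (is.null(values)) {
    if (is.null(range) || length(range) != 2 || range[1] > range[2]) {
      stop("supply 'values' or a valid (low, high) 'range'", call. = FALSE)
    }
    values <- seq(range[1], range[2], length.out = n_points)
  }
  rows <- list()
  for (v in values) {
    p <- base
    s <- settings
    if (parameter %in% c("discount_rate", "screening_uptake")) {
      s[[parameter]] <- v
    } else if (parameter == "progression_interval_years") {
      p[[parameter]] <- as.integer(v)
    } else {
      p[[parameter]] <- v
    }
    out <- run_strategies(strategies, p, s, schedules)
    tab <- base_case_table(data.frame(label = out$label, cost = out$cost_disc,
                                      life_years = out$life_years_disc,
                                      qaly = out$qaly_disc))
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = parameter, value = v, label = tab$label,
                 status = tab$status, cost = tab$cost, qaly = tab$qaly,
                 icer_qaly = tab$icer_qaly, acer_qaly = tab$acer_qaly)
  }
  do.call(rbind, rows)
}

#' Pairwise ICER between two strategies in a one-way sensitivity table
#'
#' The published one-way tables compare each screening interval with the
#' next longer one in the same age band regardless of frontier membership;
#' this helper extracts that pairwise ratio from an [owsa()] result.
#'
#' @param tab an [owsa()] result.
#' @param label,comparator strategy labels.
#' @return A data frame `parameter`, `value`, `icer` (unrounded).
#' @export
owsa_pairwise_icer <- function(tab, label, comparator) {
  out <- lapply(split(tab, tab$value), function(d) {
    a <- d[d$label == label, ]
    b <- d[d$label == comparator, ]
    data.frame(parameter = a$parameter, value = a$value,
               icer = acer(list(cost = a$cost, effect = a$qaly),
                           list(cost = b$cost, effect = b$qaly)))
  })
  out <- do.call(rbind, out)
  out[order(out$value), , drop = FALSE]
}

#' Survival-shift scenario
#'
#' Returns a parameter set whose per-stage excess mortality is rescaled so
#' that every stage's five-year relative survival moves by `delta`
#' (e.g. +0.05 for "5 percentage points better survival").
#'
#' @param params base [dare_parameters()].
#' @param delta shift in five-year survival, in probability points.
#' @return A `dare_parameters` object with `excess_mortality_multiplier` set
#'   per stage.
#' @export
scenario_survival_shift <- function(params, delta) {
  mult <- stats::setNames(numeric(3), .stages)
  for (st in .stages) {
    wp <- params$survival[[st]]
    q <- annual_death_prob(wp, 0:4)
    s5 <- weibull_survival(wp, 5)
    target <- min(max(s5 + delta, 1e-6), 1 - 1e-9)
    f <- function(m) prod(1 - pmin(1, m * q)) - target
    upper <- min(1 / max(q), 50)
    mult[st] <- stats::uniroot(f, c(1e-9, upper), tol = 1e-10)$root
  }
  p <- unclass(params)
  p$excess_mortality_multiplier <- mult
  structure(p, class = "dare_parameters")
}

#' Write PSA artifacts as CSV
#'
#' @param draws a `psa_draws`.
#' @param draws_path,ceac_path,params_path optional output paths for the
#'   cost/QALY cloud, a default CEAC, and the sampled parameter matrix.
#' @param comparator,wtp_grid passed to [ceac()] when `ceac_path` is given.
#' @return Invisibly, the paths written.
#' @export
write_psa <- function(draws, draws_path = NULL, ceac_path = NULL,
                      params_path = NULL, comparator = "No screening",
                      wtp_grid = seq(0, 150000, by = 5000)) {
  if (!is.null(draws_path)) {
    utils::write.csv(draws$draws, draws_path, row.names = FALSE)
  }
  if (!is.null(ceac_path)) {
    utils::write.csv(ceac(draws, comparator, wtp_grid), ceac_path,
                     row.names = FALSE)
  }
  if (!is.null(params_path)) {
    utils::write.csv(as.data.frame(draws$params), params_path, row.names = FALSE)
  }
  invisible(c(draws_path, ceac_path, params_path))
}
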
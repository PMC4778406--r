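#' The DARE screening test model
#'
#' Screening is a digital ano-rectal examination performed at the routine HIV
#' visit. A positive exam refers the patient to a colorectal surgeon; the
#' referral's positive predictive value (the published input, the fraction of
#' referrals that are cancer) fixes the per-screen false-positive probability
#' at the cohort's current undetected-cancer prevalence via Bayes' identity.
#'
#' @name screening_model
NULL

#' Bayesian post-test probability of cancer
#'
#' @param prior pre-test probability of cancer.
#' @param sensitivity probability a cancer is test-positive.
#' @param fp_rate probability a non-cancer is test-positive.
#' @param result `"positive"` or `"negative"`.
#' @return The posterior probability of cancer given the test result.
#' @export
#' @examples
#' posttest_probability(0.001, 0.9, 0.002703, "positive")  # ~0.25
posttest_probability <- function(prior, sensitivity, fp_rate,
                                 result = c("positive", "negative")) {
  result <- match.arg(result)
  for (v in c(prior = prior, sensitivity = sensitivity, fp_rate = fp_rate)) {
    if (v < 0 || v > 1) stop("all inputs must lie in [0, 1]", call. = FALSE)
  }
  if (result == "positive") {
    denom <- prior * sensitivity + (1 - prior) * fp_rate
    num <- prior * sensitivity
  } else {
    denom <- prior * (1 - sensitivity) + (1 - prior) * (1 - fp_rate)
    num <- prior * (1 - sensitivity)
  }
  if (denom == 0) {
    stop("undefined posterior: the observed result has probability 0",
         call. = FALSE)
  }
  num / denom
}

#' Per-screen false-positive probability implied by the referral PPV
#'
#' Solves ppv = prev * sens / (prev * sens + (1 - prev) * f) for f, the
#' probability that a cancer-free screened person is referred:
#' f = prev * sens * (1 - ppv) / (ppv * (1 - prev)). Holding the PPV fixed
#' while prevalence changes over the cohort's life keeps the ratio of
#' false-positive to true-positive referrals constant at (1 - ppv)/ppv.
#'
#' @param prevalence pre-test probability of undetected cancer among screened
#'   persons (0 returns 0: no cancers, no referrals under a fixed PPV).
#' @param sensitivity DARE sensitivity.
#' @param ppv referral positive predictive value, in (0, 1\].
#' @return Per-screen false-positive probability.
#' @export
fp_rate_from_ppv <- function(prevalence, sensitivity, ppv) {
  if (prevalence < 0 || prevalence >= 1) {
    stop("prevalence must lie in [0, 1)", call. = FALSE)
  }
  if (ppv <= 0 || ppv > 1) stop("ppv must lie in (0, 1]", call. = FALSE)
  if (sensitivity < 0 || sensitivity > 1) {
    stop("sensitivity must lie in [0, 1]", call. = FALSE)
  }
  f <- prevalence * sensitivity * (1 - ppv) / (ppv * (1 - prevalence))
  if (f > 1) {
    stop(sprintf(
      "infeasible calibration: implied false-positive probability %.3f > 1", f),
      call. = FALSE)
  }
  f
}

#' Does a strategy screen at a given age?
#'
#' A screen fires when the age falls in the strategy's window and the years
#' since the window opened are a multiple of the screening interval.
#'
#' @param strategy a [strategy_spec()].
#' @param age integer age in years.
#' @return Logical.
#' @export
screen_due <- function(strategy, age) {
  strategy$screening &&
    age >= strategy$screen_start_age && age <= strategy$screen_end_age &&
    (age - strategy$screen_start_age) %% strategy$interval_years == 0L
}

#' Screening-event quantities for one cycle
#'
#' Given start-of-cycle occupancy, computes the per-stage detection
#' probability applied to undetected cancer and the expected number of
#' false-positive referrals. Cancer-free and undetected-cancer occupants are
#' screened (patients with a detected cancer are under specialist follow-up);
#' the false-positive rate is recalibrated against the current undetected
#' prevalence so the referral PPV stays at its configured value throughout
#' the cohort's life.
#'
#' @param occupancy named occupancy vector (see [run_cohort()]), or any
#'   vector whose names include `"no_cancer"` and `"undet_<stage>_d<j>"`.
#' @param strategy a [strategy_spec()].
#' @param age integer age.
#' @param params a [dare_parameters()] object.
#' @param settings a [dare_settings()] object (supplies uptake).
#' @return A list: `fires` (did a screen happen), `detect_prob` (named per
#'   stage), `fp_rate` (per cancer-free screened person), `expected_fp`
#'   (expected false-positive referrals given the occupancy), and
#'   `screened` (expected persons screened).
#' @export
screen_event <- function(occupancy, strategy, age, params,
                         settings = dare_settings()) {
  zero <- list(fires = FALSE,
               detect_prob = stats::setNames(rep(0, 3), .stages),
               fp_rate = 0, expected_fp = 0, screened = 0)
  if (!screen_due(strategy, age)) return(zero)
  uptake <- settings$screening_uptake
  nm <- names(occupancy)
  nc <- sum(occupancy[nm == "no_cancer"])
  undet_by_stage <- vapply(.stages, function(st) {
    sum(occupancy[startsWith(nm, paste0("undet_", st, "_"))])
  }, numeric(1))
  undet <- sum(undet_by_stage)
  screened <- nc + undet
  if (screened <= 0) return(zero)
  prev <- undet / screened
  fpr <- fp_rate_from_ppv(prev, params$dare_sensitivity, params$dare_ppv)
  detect <- stats::setNames(rep(uptake * params$dare_sensitivity, 3), .stages)
  list(fires = TRUE, detect_prob = detect, fp_rate = fpr,
       expected_fp = uptake * fpr * nc, screened = uptake * screened)
}
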
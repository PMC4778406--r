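#' Weibull calibration of stage-specific relative survival
#'
#' Relative survival (observed survival of cancer patients over expected
#' survival of a comparable cancer-free population) proxies the
#' cancer-attributable excess mortality of each stage. A two-parameter
#' Weibull curve S(t) = exp(-(t/lambda)^k) is fitted per stage and converted
#' to annual conditional excess death probabilities that the cohort engine
#' applies on top of other-cause mortality.
#'
#' @name survival_calibration
NULL

#' Construct Weibull survival parameters
#'
#' @param stage `"local"`, `"regional"` or `"distal"`.
#' @param shape Weibull shape k (> 0; k > 1 means rising excess hazard).
#' @param scale Weibull scale lambda in years (> 0).
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(stage, shape, scale) {
  if (!is.numeric(shape) || shape <= 0) stop("shape must be > 0", call. = FALSE)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(stage = stage, shape = shape, scale = scale),
            class = "weibull_params")
}

#' Weibull relative survival at time t
#'
#' @param params a [weibull_params()] object (or any list with `shape`, `scale`).
#' @param t years since diagnosis (vectorized, >= 0).
#' @return S(t) = exp(-(t/scale)^shape).
#' @export
weibull_survival <- function(params, t) {
  exp(-(t / params$scale)^params$shape)
}

#' Fit a Weibull curve to a relative-survival dataset
#'
#' Uses the log(-log) linearization: log(-log S(t)) is linear in log t with
#' slope k and intercept -k log(lambda). The fit is weighted least squares
#' with inverse-variance weights proportional to the number at risk: a
#' sampled survival proportion S with denominator n has variance
#' S(1 - S)/n, which the delta method maps to variance
#' S(1 - S) / (n (S log S)^2) on the log(-log) scale. This is exactly
#' invertible on noiseless data and downweights the imprecise ends of the
#' curve on sampled data. Points at t = 0 or with survival outside (0, 1)
#' are excluded from the regression.
#'
#' @param data a `survival_dataset` (see [gen_survival_dataset()]) or any
#'   data frame with columns `years_since_diagnosis`, `relative_survival`,
#'   and optionally `n_at_risk` (default weight 1).
#' @return A [weibull_params()] object; the fitted values carry attribute
#'   `"fit"` with the underlying `lm` object.
#' @export
fit_weibull <- function(data) {
  df <- as.data.frame(data)
  stage <- attr(data, "stage") %||% "unknown"
  if (!all(c("years_since_diagnosis", "relative_survival") %in% names(df))) {
    stop("data needs columns 'years_since_diagnosis' and 'relative_survival'",
         call. = FALSE)
  }
  if (is.null(df$n_at_risk)) df$n_at_risk <- 1
  use <- df$years_since_diagnosis > 0 & df$relative_survival > 0 &
    df$relative_survival < 1
  if (all(df$relative_survival[df$years_since_diagnosis > 0] >= 1)) {
    stop("degenerate survival data: all values are 1 (no observed excess mortality)",
         call. = FALSE)
  }
  if (sum(use) < 3) {
    stop("need at least 3 usable time points with survival in (0, 1)",
         call. = FALSE)
  }
  x <- log(df$years_since_diagnosis[use])
  s <- df$relative_survival[use]
  y <- log(-log(s))
  w <- df$n_at_risk[use] * (s * log(s))^2 / (s * (1 - s))
  fit <- stats::lm(y ~ x, weights = w)
  k <- unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0) {
    stop("fitted Weibull shape is not positive; data are not Weibull-like",
         call. = FALSE)
  }
  lambda <- exp(-unname(stats::coef(fit)[1]) / k)
  out <- weibull_params(stage, k, lambda)
  attr(out, "fit") <- fit
  out
}

#' Annual excess (cancer-attributable) death probability
#'
#' The conditional probability of dying of the cancer between `years_since_dx`
#' and `years_since_dx + 1`, given alive at `years_since_dx`:
#' 1 - S(t + 1)/S(t). For shape 1 this is constant (exponential survival);
#' for shape > 1 it rises with time since diagnosis.
#'
#' @param params a [weibull_params()] object.
#' @param years_since_dx integer years since diagnosis (vectorized, >= 0).
#' @return Annual death probability in \[0, 1\].
#' @export
annual_death_prob <- function(params, years_since_dx) {
  if (any(years_since_dx < 0)) stop("years_since_dx must be >= 0", call. = FALSE)
  t <- years_since_dx
  # 1 - S(t+1)/S(t) via cumulative hazards; stable where S underflows
  h0 <- (t / params$scale)^params$shape
  h1 <- ((t + 1) / params$scale)^params$shape
  -expm1(-(h1 - h0))
}

#' Write fitted Weibull parameters as JSON records
#'
#' @param params_list a list of [weibull_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_weibull_params <- function(params_list, path) {
  recs <- lapply(params_list, function(p) {
    list(stage = p$stage, shape = p$shape, scale = p$scale)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("<weibull_params> stage %s: shape %.4f, scale %.4f years\n",
              x$stage, x$shape, x$scale))
  invisible(x)
}
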
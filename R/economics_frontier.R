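#' ACERs, dominance, and the efficiency frontier
#'
#' Strategies are ranked by increasing effectiveness. Strategies that are
#' more expensive and no more effective than another are strictly dominated
#' and removed. Then strategies whose incremental cost-effectiveness ratio
#' (ICER) against their predecessor exceeds that of a more effective
#' successor are removed by extended dominance, iterating until the frontier
#' ICERs strictly increase. ICERs are then computed between consecutive
#' frontier members; average cost-effectiveness ratios (ACERs) compare each
#' strategy with the no-intervention baseline.
#'
#' @name economics_frontier
NULL

#' Round to the nearest whole dollar, halves away from zero
#'
#' Matches the resolution at which cost-effectiveness ratios are reported;
#' internal arithmetic is never rounded.
#'
#' @param x numeric.
#' @return `x` rounded to the nearest integer, halves away from zero.
#' @export
round_dollar <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Average cost-effectiveness ratio versus a baseline
#'
#' @param strategy,baseline lists or one-row data frames with elements
#'   `cost` and `effect`.
#' @return (cost - baseline cost) / (effect - baseline effect), unrounded.
#' @export
#' @examples
#' acer(list(cost = 755, effect = 35.1225), list(cost = 373, effect = 35.1146))
acer <- function(strategy, baseline) {
  de <- strategy$effect - baseline$effect
  if (de == 0) {
    stop("undefined ratio: strategy and baseline have equal effects",
         call. = FALSE)
  }
  (strategy$cost - baseline$cost) / de
}

#' Efficiency frontier with strict and extended dominance
#'
#' @param outcomes a data frame with columns `label` (unique), `cost` (>= 0)
#'   and `effect` (QALYs or life-years — one effect scale per call).
#' @return An object of classes `frontier_result`/`data.frame`: the input
#'   rows plus `status` (`"frontier"`, `"dominated"`, or
#'   `"extended_dominated"`), `icer` (unrounded, `NA` for non-frontier rows
#'   and for the least effective frontier member), `dominated_by` (a
#'   strictly dominating label) and `ed_witness` (the "pred -> succ" pair
#'   that witnessed an extended-dominance removal).
#' @export
frontier <- function(outcomes) {
  df <- as.data.frame(outcomes)
  stopifnot(all(c("label", "cost", "effect") %in% names(df)))
  if (nrow(df) < 1) stop("need at least one strategy", call. = FALSE)
  if (anyDuplicated(df$label)) stop("strategy labels must be unique", call. = FALSE)
  if (any(df$cost < 0)) stop("costs must be >= 0", call. = FALSE)
  n <- nrow(df)
  status <- rep("frontier", n)
  dominated_by <- rep(NA_character_, n)
  ed_witness <- rep(NA_character_, n)

  # exact-tie duplicates collapse to one representative
  for (i in seq_len(n)) {
    if (status[i] != "frontier") next
    dup <- which(df$cost == df$cost[i] & df$effect == df$effect[i])
    dup <- dup[dup > i]
    status[dup] <- "dominated"
    dominated_by[dup] <- df$label[i]
  }
  # strict dominance: another strategy costs no more and achieves no less,
  # with at least one strict inequality
  for (i in seq_len(n)) {
    if (status[i] != "frontier") next
    dom <- which(df$cost <= df$cost[i] & df$effect >= df$effect[i] &
                   (df$cost < df$cost[i] | df$effect > df$effect[i]))
    dom <- dom[status[dom] != "dominated"]
    if (length(dom) > 0) {
      status[i] <- "dominated"
      dominated_by[i] <- df$label[dom[1]]
    }
  }
  # extended dominance: walk the survivors in effect order; remove the first
  # member whose ICER vs its predecessor is >= the next member's, repeat
  repeat {
    surv <- which(status == "frontier")
    surv <- surv[order(df$effect[surv], df$cost[surv])]
    if (length(surv) < 3) break
    ic <- diff(df$cost[surv]) / diff(df$effect[surv])
    bad <- which(ic[-length(ic)] >= ic[-1])
    if (length(bad) == 0) break
    j <- surv[bad[1] + 1]   # the middle strategy of the violating triple
    status[j] <- "extended_dominated"
    ed_witness[j] <- paste(df$label[surv[bad[1]]], "->",
                           df$label[surv[bad[1] + 2]])
  }
  icer <- rep(NA_real_, n)
  surv <- which(status == "frontier")
  surv <- surv[order(df$effect[surv], df$cost[surv])]
  if (length(surv) > 1) {
    icer[surv[-1]] <- diff(df$cost[surv]) / diff(df$effect[surv])
  }
  out <- df[order(df$effect, df$cost), , drop = FALSE]
  o <- order(df$effect, df$cost)
  out$status <- status[o]
  out$icer <- icer[o]
  out$dominated_by <- dominated_by[o]
  out$ed_witness <- ed_witness[o]
  rownames(out) <- NULL
  class(out) <- c("frontier_result", "data.frame")
  out
}

#' Cost-effectiveness plane coordinates versus a baseline
#'
#' @param outcomes as for [frontier()].
#' @param baseline label of the comparator (default `"No screening"`).
#' @return A data frame with `label`, `delta_cost`, `delta_effect` and the
#'   [frontier()] `status` flags.
#' @export
ce_plane <- function(outcomes, baseline = "No screening") {
  df <- as.data.frame(outcomes)
  if (!baseline %in% df$label) {
    stop(sprintf("baseline '%s' not present", baseline), call. = FALSE)
  }
  fr <- frontier(df)
  b <- df[df$label == baseline, ]
  res <- data.frame(label = fr$label,
                    delta_cost = fr$cost - b$cost,
                    delta_effect = fr$effect - b$effect,
                    status = fr$status)
  res
}

#' Base-case outcome table with frontier ICERs and ACERs
#'
#' Reproduces the published table layout: strategies ranked by QALYs,
#' dominance determined on the QALY scale, and ICERs reported between
#' consecutive frontier members on both the QALY and the life-year effect
#' scales (the life-year column shares the QALY-determined frontier
#' membership). ACERs compare every strategy with the baseline per QALY.
#' Reported ratios are rounded to the nearest dollar.
#'
#' @param outcomes a data frame with columns `label`, `cost`, `life_years`,
#'   `qaly` (e.g. from [run_strategies()], choosing either the discounted or
#'   the undiscounted columns, or a bundled reference table).
#' @param baseline label of the no-intervention strategy.
#' @return A data frame: `label`, `cost`, `life_years`, `icer_ly`, `qaly`,
#'   `icer_qaly`, `acer_qaly`, `status`.
#' @export
base_case_table <- function(outcomes, baseline = "No screening") {
  df <- as.data.frame(outcomes)
  stopifnot(all(c("label", "cost", "life_years", "qaly") %in% names(df)))
  if (!baseline %in% df$label) {
    stop(sprintf("baseline '%s' not present", baseline), call. = FALSE)
  }
  fr <- frontier(data.frame(label = df$label, cost = df$cost, effect = df$qaly))
  ord <- match(fr$label, df$label)
  out <- data.frame(label = fr$label, cost = df$cost[ord],
                    life_years = df$life_years[ord],
                    icer_ly = NA_real_, qaly = df$qaly[ord],
                    icer_qaly = round_dollar(fr$icer), acer_qaly = NA_real_,
                    status = fr$status)
  surv <- which(out$status == "frontier")
  if (length(surv) > 1) {
    out$icer_ly[surv[-1]] <- round_dollar(
      diff(out$cost[surv]) / diff(out$life_years[surv]))
  }
  b <- df[df$label == baseline, ]
  nb <- out$label != baseline
  out$acer_qaly[nb] <- round_dollar(
    (out$cost[nb] - b$cost) / (out$qaly[nb] - b$qaly))
  out
}

#' @export
print.frontier_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$icer <- ifelse(is.na(y$icer), "", format(round_dollar(y$icer),
                                             big.mark = ",", trim = TRUE))
  print.data.frame(y[, c("label", "cost", "effect", "status", "icer")],
                   row.names = FALSE)
  invisible(x)
}

#' Read / write strategy outcome tables as CSV
#'
#' @param path file with columns `label`, `cost`, `effect`.
#' @return [read_outcomes()] returns the data frame; [write_frontier()]
#'   writes a `frontier_result` and returns the path invisibly.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("label", "cost", "effect") %in% names(df)))
  df
}

#' @rdname read_outcomes
#' @param x a `frontier_result`.
#' @export
write_frontier <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Bundled reference base-case outcome tables
#'
#' The eleven-strategy lifetime outcome tables (cost, life-years, QALYs per
#' strategy; discounted at 3% or undiscounted) bundled with the package for
#' verifying the frontier arithmetic independently of the cohort engine.
#'
#' @param discounted return the discounted (3%) table? Otherwise the
#'   undiscounted one.
#' @return A data frame with columns `label`, `cost`, `life_years`, `qaly`.
#' @export
reference_outcomes <- function(discounted = TRUE) {
  f <- if (discounted) "basecase_discounted.csv" else "basecase_undiscounted.csv"
  path <- system.file("extdata", f, package = "darecea", mustWork = TRUE)
  utils::read.csv(path)
}
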
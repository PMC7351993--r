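# The dual-membrane push-pull sorter: displacement rules, the 32-scenario
# Poisson coincidence model of the throughput-purity trade-off, a
# Monte-Carlo event-stream simulator, and the evaluation metrics.
#
# Displacement rules. Every particle classified as a target triggers a
# membrane actuation at its sort-point arrival time; actuation directions
# alternate globally (+1, -1, +1, ...). An actuation at time t displaces
# every particle whose sort-point arrival time t_i satisfies |t_i - t| < tau
# by one lateral step in the actuation direction; the lateral state
# saturates at one step (a same-direction push on a displaced particle
# leaves it displaced; an opposite push returns it to the center). A
# particle leaves through a side channel (collection) iff its lateral state
# is nonzero at exit, through the center (waste) otherwise.
#
# Because directions alternate globally, the in-window actuations seen by
# any one particle alternate too, so its exit state depends only on the
# PARITY of the number of in-window actuations: odd -> side channel. The
# simulator uses that closed form.
#
# Under the alternative "self-priority" variant, a target's exit state is
# decided by its own actuation and only subsequent in-window actuations
# (its own push is never undone by an earlier one); nontargets behave as
# in the default rules.

#' Probability that an inter-event interval is shorter than tau
#'
#' For Poisson arrivals at rate lambda the interval T is exponential, so
#' P(T < tau) = 1 - exp(-lambda tau).
#'
#' @param lambda event rate, events/s (>= 0).
#' @param tau coincidence half-window, s (>= 0).
#' @return The probability p.
#' @export
intervalProb <- function(lambda, tau) {
  if (any(lambda < 0) || any(tau < 0)) stop("lambda and tau must be >= 0")
  1 - exp(-lambda * tau)
}

# number of actuation times strictly inside (t - tau, t + tau) for each t
.actCount <- function(t, actTimes, tau) {
  findInterval(t + tau, actTimes, left.open = TRUE) -
    findInterval(t - tau, actTimes)
}

# core displacement engine; decisions = actuation intents (sorter sees
# these), labels = ground truth (used only to name outcomes)
.sortDestinations <- function(times, decisions, labels, tau,
                              variant = "alternating") {
  if (is.unsorted(times, strictly = FALSE)) stop("arrival times must be sorted")
  at <- times[decisions]
  k <- .actCount(times, at, tau)
  side <- (k %% 2L) == 1L
  if (variant == "self-priority" && any(decisions)) {
    # own actuation plus strictly later in-window actuations
    kAfter <- findInterval(times + tau, at, left.open = TRUE) -
      findInterval(times, at, left.open = TRUE)
    side[decisions] <- (kAfter[decisions] %% 2L) == 1L
  }
  direction <- integer(length(times))
  direction[decisions] <- rep_len(c(1L, -1L), sum(decisions))
  destination <- ifelse(side, "collection", "waste")
  outcome <- ifelse(labels, ifelse(side, "TP", "FN"),
                    ifelse(side, "FP", "TN"))
  data.frame(time_s = times, is_target = labels, decision = decisions,
             actuated = decisions, direction = direction, n_actuations = k,
             destination = destination, outcome = outcome,
             stringsAsFactors = FALSE)
}

#' Classify one nearest-neighbor scenario
#'
#' Realizes the (previous particle, particle of interest, next particle)
#' triple with gaps of tau/2 (short) or 2 tau (long), runs the displacement
#' rules, and reports the outcome for the particle of interest. With the
#' default rules, (target, nontarget, target, short, long) reproduces the
#' narrated false positive: the preceding target's push also displaces the
#' particle of interest, no actuation occurs at its own arrival, and the
#' following target's (opposite) push is outside the window, so the
#' nontarget exits through a side channel.
#'
#' @param prevTarget,selfTarget,nextTarget logical: is each particle a
#'   target?
#' @param gapPrevShort,gapNextShort logical: is each gap shorter than tau?
#' @param tau coincidence half-window, s.
#' @param variant displacement-rule variant, "alternating" (default) or
#'   "self-priority".
#' @return One of "TP", "FP", "TN", "FN".
#' @export
classifyScenario <- function(prevTarget, selfTarget, nextTarget,
                             gapPrevShort, gapNextShort, tau = 1.5e-3,
                             variant = "alternating") {
  gp <- if (gapPrevShort) tau / 2 else 2 * tau
  gn <- if (gapNextShort) tau / 2 else 2 * tau
  lab <- c(prevTarget, selfTarget, nextTarget)
  run <- .sortDestinations(c(0, gp, gp + gn), lab, lab, tau, variant)
  run$outcome[2]
}

.scenarioGrid <- function() {
  g <- expand.grid(gap_next_short = c(TRUE, FALSE),
                   gap_prev_short = c(TRUE, FALSE),
                   next_is_target = c(TRUE, FALSE),
                   self_is_target = c(TRUE, FALSE),
                   prev_is_target = c(TRUE, FALSE))
  g[, c("prev_is_target", "self_is_target", "next_is_target",
        "gap_prev_short", "gap_next_short")]
}

# scenario outcomes depend only on the five booleans and the rule variant
# (not on the magnitudes of lambda and tau), so they are computed once
.outcomeCache <- new.env(parent = emptyenv())

.scenarioOutcomes <- function(variant) {
  if (is.null(.outcomeCache[[variant]])) {
    g <- .scenarioGrid()
    .outcomeCache[[variant]] <- vapply(seq_len(32), function(i)
      classifyScenario(g$prev_is_target[i], g$self_is_target[i],
                       g$next_is_target[i], g$gap_prev_short[i],
                       g$gap_next_short[i], 1e-3, variant),
      character(1))
  }
  .outcomeCache[[variant]]
}

#' Enumerate the 32-scenario sample space
#'
#' The five binary parameters (previous/self/next target?, preceding/
#' following gap < tau?) span 2^5 = 32 scenarios. Each particle is a target
#' with probability r, each gap is short with probability
#' \code{intervalProb(lambda, tau)}, and the scenario probability is the
#' product of the five factors; outcomes come from
#' \code{\link{classifyScenario}}.
#'
#' @param lambda event rate, events/s.
#' @param tau coincidence half-window, s.
#' @param r target fraction.
#' @param variant displacement-rule variant.
#' @return A \linkS4class{ScenarioTable}.
#' @export
enumerateScenarios <- function(lambda, tau, r, variant = "alternating") {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  p <- intervalProb(lambda, tau)
  g <- .scenarioGrid()
  g$outcome <- .scenarioOutcomes(variant)
  pr <- function(isT) ifelse(isT, r, 1 - r)
  ps <- function(short) ifelse(short, p, 1 - p)
  g$probability <- pr(g$prev_is_target) * pr(g$self_is_target) *
    pr(g$next_is_target) * ps(g$gap_prev_short) * ps(g$gap_next_short)
  g$scenario <- seq_len(32)
  rownames(g) <- NULL
  new("ScenarioTable", scenarios = g[, c("scenario", names(g)[1:7])],
      lambda = lambda, tau = tau, r = r)
}

#' Analytic sort purity from the scenario model
#'
#' Purity(lambda, tau, r) = sum(P_TP) / (sum(P_TP) + sum(P_FP)) over the
#' 32-scenario table.
#'
#' @inheritParams enumerateScenarios
#' @return Purity in [0, 1]; errors when no scenario puts mass into the
#'   collection (e.g. r = 0).
#' @export
purityAnalytic <- function(lambda, tau, r, variant = "alternating") {
  tab <- enumerateScenarios(lambda, tau, r, variant)@scenarios
  ptp <- sum(tab$probability[tab$outcome == "TP"])
  pfp <- sum(tab$probability[tab$outcome == "FP"])
  if (ptp + pfp <= 0)
    stop("purity undefined: no probability mass reaches the collection")
  ptp / (ptp + pfp)
}

#' Monte-Carlo sorter simulation over an event stream
#'
#' Applies the displacement rules event by event over the whole stream (not
#' only nearest neighbors). \code{x} may be a \linkS4class{GroundTruth}
#' (decisions default to the true labels, i.e. a perfect classifier) or a
#' numeric vector of sorted sort-point arrival times with explicit
#' \code{decisions} and \code{labels}.
#'
#' @param x arrival times or a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{SortTimingConfig} (supplies tau, the
#'   latency and the rule variant).
#' @param decisions logical actuation intents per event.
#' @param labels logical ground-truth target flags per event.
#' @param seed optional RNG seed (the rules themselves are deterministic;
#'   kept for interface symmetry).
#' @return A \linkS4class{SortRun}.
#' @export
simulateSorting <- function(x, config = sortTimingConfig(),
                            decisions = NULL, labels = NULL, seed = NULL) {
  stopifnot(is(config, "SortTimingConfig"))
  if (!is.null(seed)) set.seed(seed)
  if (is(x, "GroundTruth")) {
    times <- x@events$time_s + config@sortLatency
    if (is.null(labels)) labels <- x@events$is_target
    if (is.null(decisions)) decisions <- labels
  } else {
    times <- as.numeric(x) + config@sortLatency
    if (is.null(decisions)) stop("decisions required for a raw time vector")
    if (is.null(labels)) labels <- decisions
  }
  ev <- .sortDestinations(times, as.logical(decisions), as.logical(labels),
                          tau(config), config@variant)
  new("SortRun", events = ev, tau = tau(config), variant = config@variant)
}

#' Windowed event rate and nominal throughput
#'
#' e_i = 50 / (t_i - t_{i-50}) for i = 51 .. N. The nominal throughput is
#' the most frequent value: the median of the rates falling in the modal
#' histogram bin (default bin width 1 event/s).
#'
#' @param times strictly increasing arrival times of at least 51 events, s.
#' @param binWidth histogram bin width for the mode, events/s.
#' @return An \linkS4class{EventRateSeries}.
#' @export
eventRate <- function(times, binWidth = 1) {
  n <- length(times)
  if (n < 51) stop("need at least 51 events")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  idx <- 51:n
  rates <- 50 / (times[idx] - times[idx - 50])
  lo <- floor(min(rates) / binWidth) * binWidth
  bin <- floor((rates - lo) / binWidth)
  cnt <- tabulate(bin + 1L)
  modal <- which.max(cnt) - 1L
  nominal <- median(rates[bin == modal])
  new("EventRateSeries", index = as.integer(idx), rates = rates,
      nominalThroughput = nominal, binWidth = binWidth)
}

#' Sort purity and yield from enumeration counts
#'
#' purity = targets collected / all collected;
#' yield = targets collected / all targets.
#'
#' @param nTargetCollect,nNontargetCollect,nTargetWaste non-negative counts.
#' @return list(purity, yield); purity is NA (undefined) when the
#'   collection is empty, yield NA when there were no targets.
#' @export
purityYield <- function(nTargetCollect, nNontargetCollect, nTargetWaste) {
  counts <- c(nTargetCollect, nNontargetCollect, nTargetWaste)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  collected <- nTargetCollect + nNontargetCollect
  targets <- nTargetCollect + nTargetWaste
  list(purity = if (collected > 0) nTargetCollect / collected else NA_real_,
       yield = if (targets > 0) nTargetCollect / targets else NA_real_)
}

#' Evaluate a sort run
#'
#' @param run a \linkS4class{SortRun}.
#' @return list with the TP/FP/TN/FN confusion counts and purity/yield.
#' @export
evaluateRun <- function(run) {
  stopifnot(is(run, "SortRun"))
  out <- factor(run@events$outcome, c("TP", "FP", "TN", "FN"))
  cnt <- as.list(table(out))
  py <- purityYield(cnt$TP, cnt$FP, cnt$FN)
  c(cnt, py)
}

#' Theoretical throughput-purity curves
#'
#' Evaluates the analytic purity over a grid of event rates for one or more
#' flow speeds; tau follows from the sorting-region transit,
#' tau = sortRegionLength / flowSpeed / 2, so faster flow shortens the
#' coincidence window and raises purity at fixed throughput.
#'
#' @param lambdas event rates, events/s.
#' @param r target fraction.
#' @param flowSpeeds flow speeds, m/s.
#' @param sortRegionLength sorting-region length, um.
#' @param variant displacement-rule variant.
#' @return data.frame(flow_speed, lambda, tau, purity).
#' @export
throughputPurityCurve <- function(lambdas, r, flowSpeeds = 0.04,
                                  sortRegionLength = 120,
                                  variant = "alternating") {
  out <- expand.grid(lambda = lambdas, flow_speed = flowSpeeds)
  out$tau <- sortRegionLength * 1e-6 / out$flow_speed / 2
  out$purity <- mapply(purityAnalytic, out$lambda, out$tau,
                       MoreArgs = list(r = r, variant = variant))
  out[, c("flow_speed", "lambda", "tau", "purity")]
}

#' Gated fraction of a population, in percent
#'
#' The rare-event bookkeeping used when a small number of gated events is
#' drawn from a large population: 100 * nGated / nTotal.
#'
#' @param nGated,nTotal non-negative counts, nTotal > 0.
#' @return Percentage.
#' @export
gatedFraction <- function(nGated, nTotal) {
  if (nTotal <= 0 || nGated < 0 || nGated > nTotal)
    stop("need 0 <= nGated <= nTotal with nTotal > 0")
  100 * nGated / nTotal
}
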
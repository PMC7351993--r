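#' @rdname SpectralBasis
#' @param object,x a package object.
#' @export
setGeneric("constituentNames", function(x) standardGeneric("constituentNames"))

#' @rdname SpectralBasis
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectralBasis
#' @export
setGeneric("responses", function(x) standardGeneric("responses"))

#' @rdname SpectralBasis
#' @export
setGeneric("nColors", function(x) standardGeneric("nColors"))

#' @rdname SpectralBasis
#' @export
setGeneric("nConstituents", function(x) standardGeneric("nConstituents"))

#' @export
setMethod("constituentNames", "SpectralBasis", function(x) x@constituentNames)
#' @export
setMethod("wavenumbers", "SpectralBasis", function(x) x@wavenumbers)
#' @export
setMethod("responses", "SpectralBasis", function(x) x@responses)
#' @export
setMethod("nColors", "SpectralBasis", function(x) nrow(x@responses))
#' @export
setMethod("nConstituents", "SpectralBasis", function(x) ncol(x@responses))

setMethod("show", "SpectralBasis", function(object) {
  cat("SpectralBasis:", nColors(object), "colors x",
      nConstituents(object), "constituents\n")
  cat("  wavenumbers (cm^-1):", paste(object@wavenumbers, collapse = ", "), "\n")
  cat("  constituents:", paste(object@constituentNames, collapse = ", "), "\n")
  sv <- svd(object@responses, nu = 0, nv = 0)$d
  cat(sprintf("  condition number: %.4g\n", sv[1] / sv[length(sv)]))
})

#' Line period of an acquisition configuration
#'
#' @param x an \linkS4class{AcquisitionConfig}.
#' @return The line period 1/lineRate, seconds.
#' @export
setGeneric("linePeriod", function(x) standardGeneric("linePeriod"))

#' @rdname linePeriod
#' @export
setMethod("linePeriod", "AcquisitionConfig", function(x) 1 / x@lineRate)

#' Pixel pitches of the acquisition geometry
#'
#' \code{flowPitch} is the line-to-line advance of the specimen along the
#' flow, \code{flowSpeed / lineRate}, in um; \code{lateralPitch} is
#' \code{lateralFOV / nLateralPixels}, in um.
#'
#' @param x an \linkS4class{AcquisitionConfig}.
#' @return Pitch in um.
#' @export
setGeneric("flowPitch", function(x) standardGeneric("flowPitch"))

#' @rdname flowPitch
#' @export
setMethod("flowPitch", "AcquisitionConfig",
          function(x) x@flowSpeed / x@lineRate * 1e6)

#' @rdname flowPitch
#' @export
setGeneric("lateralPitch", function(x) standardGeneric("lateralPitch"))

#' @rdname flowPitch
#' @export
setMethod("lateralPitch", "AcquisitionConfig",
          function(x) x@lateralFOV / x@nLateralPixels)

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig: %g lines/s (%.3g us/line), %d x %d px frames, %d colors\n",
    object@lineRate, 1e6 / object@lineRate, object@frameLines,
    object@nLateralPixels, object@nColors))
  cat(sprintf("  FOV %g x %g um, flow %g m/s, noise sigma %.4g\n",
              object@flowFOV, object@lateralFOV, object@flowSpeed,
              object@noiseSigma))
})

#' Event table of a ground truth or sort run
#'
#' @param x a \linkS4class{GroundTruth} or \linkS4class{SortRun}.
#' @return The per-event data.frame.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname eventTable
#' @export
setMethod("eventTable", "GroundTruth", function(x) x@events)

#' @rdname eventTable
#' @export
setMethod("eventTable", "SortRun", function(x) x@events)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d events over %.3g s (rate %.3g /s, target fraction %.3g)\n",
    nrow(object@events), object@duration, object@rate, object@targetFraction))
})

setMethod("show", "LineScanStream", function(object) {
  d <- dim(object@samples)
  cat(sprintf("LineScanStream: %d lines x %d px x %d colors, %.4g-%.4g s\n",
              d[1], d[2], d[3],
              if (d[1]) min(object@lineTimes) else NA,
              if (d[1]) max(object@lineTimes) else NA))
})

setMethod("show", "EventFrame", function(object) {
  d <- dim(object@raw)
  cat(sprintf("EventFrame #%d at %.6g s: %d x %d x %d%s\n", object@eventId,
              object@triggerTime, d[1], d[2], d[3],
              if (object@aborted) " (aborted)" else ""))
})

#' Mask accessors
#'
#' @param x a \linkS4class{CellMask}.
#' @return \code{maskPixels}: the logical pixel matrix; \code{maskArea}: a
#'   named vector with the pixel and um^2 areas.
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))

#' @rdname maskPixels
#' @export
setMethod("maskPixels", "CellMask", function(x) x@pixels)

#' @rdname maskPixels
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname maskPixels
#' @export
setMethod("maskArea", "CellMask",
          function(x) c(px = x@areaPx, um2 = x@areaUm2))

setMethod("show", "CellMask", function(object) {
  cat(sprintf("CellMask: %d px (%.4g um^2) on a %d x %d grid\n",
              object@areaPx, object@areaUm2, nrow(object@pixels),
              ncol(object@pixels)))
})

#' Coincidence half-window of a sorter timing configuration
#'
#' @param x a \linkS4class{SortTimingConfig} or \linkS4class{SortRun}.
#' @return tau = sortWindow / 2, seconds.
#' @export
setGeneric("tau", function(x) standardGeneric("tau"))

#' @rdname tau
#' @export
setMethod("tau", "SortTimingConfig", function(x) x@sortWindow / 2)

#' @rdname tau
#' @export
setMethod("tau", "SortRun", function(x) x@tau)

setMethod("show", "SortTimingConfig", function(object) {
  cat(sprintf(
    "SortTimingConfig: window %.3g ms (tau %.3g ms), lambda %.3g /s, r %.3g\n",
    1e3 * object@sortWindow, 5e2 * object@sortWindow, object@rate,
    object@targetFraction))
  cat(sprintf("  flow %.3g m/s over a %.3g um sorting region; rules: %s\n",
              object@flowSpeed, object@sortRegionLength, object@variant))
})

#' Scenario table accessor
#'
#' @param x a \linkS4class{ScenarioTable}.
#' @return The 32-row scenario data.frame.
#' @export
setGeneric("scenarios", function(x) standardGeneric("scenarios"))

#' @rdname scenarios
#' @export
setMethod("scenarios", "ScenarioTable", function(x) x@scenarios)

setMethod("show", "ScenarioTable", function(object) {
  tab <- table(object@scenarios$outcome)
  cat(sprintf("ScenarioTable: 32 scenarios at lambda %.4g /s, tau %.4g s, r %.3g\n",
              object@lambda, object@tau, object@r))
  cat("  outcomes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SortRun", function(object) {
  tab <- table(factor(object@events$outcome, c("TP", "FP", "TN", "FN")))
  cat(sprintf("SortRun: %d events (tau %.4g s, %s rules)\n",
              nrow(object@events), object@tau, object@variant))
  cat("  ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})

#' Event-rate series accessors
#'
#' @param x an \linkS4class{EventRateSeries}.
#' @return \code{eventRates}: named numeric vector of e_i;
#'   \code{nominalThroughput}: the modal event rate (events/s).
#' @export
setGeneric("eventRates", function(x) standardGeneric("eventRates"))

#' @rdname eventRates
#' @export
setMethod("eventRates", "EventRateSeries", function(x) {
  r <- x@rates
  names(r) <- x@index
  r
})

#' @rdname eventRates
#' @export
setGeneric("nominalThroughput", function(x) standardGeneric("nominalThroughput"))

#' @rdname eventRates
#' @export
setMethod("nominalThroughput", "EventRateSeries",
          function(x) x@nominalThroughput)

setMethod("show", "EventRateSeries", function(object) {
  cat(sprintf(
    "EventRateSeries: %d rates (events %d..%d), nominal throughput %.4g /s\n",
    length(object@rates), min(object@index), max(object@index),
    object@nominalThroughput))
})
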
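#' @import methods
#' @importFrom stats approx mad median quantile rnorm rexp rbinom runif sd
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

.rankTol <- 1e-10

#' SpectralBasis: per-constituent spectral responses at the acquisition colors
#'
#' Holds the response of each chemical constituent at each acquisition
#' wavenumber ("color"). Column \code{i} of \code{responses} is the spectrum of
#' constituent \code{i} sampled at \code{wavenumbers}. Per-pixel measurements
#' are modeled as \code{d = responses \%*\% c} where \code{c} is the vector of
#' constituent concentrations; unmixing inverts this with the Moore-Penrose
#' pseudo-inverse.
#'
#' @slot constituentNames character labels, one per constituent.
#' @slot wavenumbers acquisition wavenumbers in cm^-1, all distinct.
#' @slot responses numeric matrix, n_colors x n_constituents, full column rank.
#' @export
setClass("SpectralBasis",
  slots = c(
    constituentNames = "character",
    wavenumbers = "numeric",
    responses = "matrix"
  )
)

setValidity("SpectralBasis", function(object) {
  R <- object@responses
  if (!is.numeric(R) || !all(is.finite(R)))
    return("responses must be a finite numeric matrix")
  if (nrow(R) != length(object@wavenumbers))
    return("nrow(responses) must equal length(wavenumbers)")
  if (ncol(R) != length(object@constituentNames))
    return("ncol(responses) must equal length(constituentNames)")
  if (nrow(R) < ncol(R))
    return("need at least as many colors (rows) as constituents (columns)")
  if (anyDuplicated(object@wavenumbers))
    return("wavenumbers must be distinct")
  sv <- svd(R, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= .rankTol * sv[1])
    return("responses matrix is rank deficient")
  TRUE
})

#' Construct a SpectralBasis
#'
#' @param responses numeric matrix (n_colors x n_constituents).
#' @param wavenumbers acquisition wavenumbers (cm^-1).
#' @param constituentNames labels; defaults to column names of
#'   \code{responses}.
#' @return A \linkS4class{SpectralBasis}.
#' @export
SpectralBasis <- function(responses, wavenumbers,
                          constituentNames = colnames(responses)) {
  responses <- as.matrix(responses)
  if (is.null(constituentNames))
    constituentNames <- paste0("constituent", seq_len(ncol(responses)))
  dimnames(responses) <- list(NULL, constituentNames)
  new("SpectralBasis", constituentNames = as.character(constituentNames),
      wavenumbers = as.numeric(wavenumbers), responses = responses)
}

#' AcquisitionConfig: geometry and timing of the virtual line-scan microscope
#'
#' Defaults follow the instrument operating point: 48 kHz line rate, 24
#' lateral detector pixels over a 24 um lateral field of view, 4 colors,
#' 122-line event frames nominally covering 33 um along the flow, and a
#' 0.04 m/s flow speed.
#'
#' @slot lineRate lines per second.
#' @slot nLateralPixels lateral pixels per line.
#' @slot nColors number of acquisition colors.
#' @slot lateralFOV lateral field of view, um.
#' @slot flowFOV nominal flow-direction field of view per frame, um.
#' @slot frameLines lines per event frame.
#' @slot flowSpeed particle flow speed, m/s.
#' @slot noiseSigma additive Gaussian noise SD, signal units.
#' @slot fscPulseWidth minimum forward-scatter pulse duration, seconds.
#' @slot seed RNG seed used by the renderer; NA means use the ambient RNG.
#' @export
setClass("AcquisitionConfig",
  slots = c(
    lineRate = "numeric", nLateralPixels = "integer", nColors = "integer",
    lateralFOV = "numeric", flowFOV = "numeric", frameLines = "integer",
    flowSpeed = "numeric", noiseSigma = "numeric", fscPulseWidth = "numeric",
    seed = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  pos <- c(lineRate = object@lineRate, nLateralPixels = object@nLateralPixels,
           nColors = object@nColors, lateralFOV = object@lateralFOV,
           flowFOV = object@flowFOV, frameLines = object@frameLines,
           flowSpeed = object@flowSpeed)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return(paste0("all of ", paste(names(pos), collapse = ", "),
                  " must be positive and finite"))
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@fscPulseWidth < 0) return("fscPulseWidth must be >= 0")
  TRUE
})

#' Construct an AcquisitionConfig
#'
#' @param lineRate lines per second (default 48000).
#' @param nLateralPixels lateral pixels (default 24).
#' @param nColors acquisition colors (default 4).
#' @param lateralFOV lateral field of view, um (default 24).
#' @param flowFOV nominal flow-direction FOV per frame, um (default 33).
#' @param frameLines lines per event frame (default 122).
#' @param flowSpeed flow speed, m/s (default 0.04).
#' @param noiseSigma additive noise SD in signal units; the default 1/30
#'   gives a peak signal-to-noise ratio of about 30 for unit-amplitude
#'   specimens.
#' @param fscPulseWidth minimum FSC pulse duration, s (default 0: the pulse
#'   duration is purely kinematic, 2 x radius / flowSpeed).
#' @param seed renderer RNG seed; NA (default) uses the ambient RNG stream.
#' @return An \linkS4class{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(lineRate = 48000, nLateralPixels = 24L,
                              nColors = 4L, lateralFOV = 24, flowFOV = 33,
                              frameLines = 122L, flowSpeed = 0.04,
                              noiseSigma = 1 / 30, fscPulseWidth = 0,
                              seed = NA_real_) {
  if (!length(seed)) seed <- NA_real_
  new("AcquisitionConfig", lineRate = lineRate,
      nLateralPixels = as.integer(nLateralPixels), nColors = as.integer(nColors),
      lateralFOV = lateralFOV, flowFOV = flowFOV,
      frameLines = as.integer(frameLines), flowSpeed = flowSpeed,
      noiseSigma = noiseSigma, fscPulseWidth = fscPulseWidth,
      seed = as.numeric(seed))
}

#' GroundTruth: labeled specimen arrivals of a simulated run
#'
#' @slot events data.frame with columns event_id, time_s, species, is_target,
#'   radius_um, lateral_offset_um and optionally a list column texture.
#' @slot rate Poisson arrival rate lambda, events per second.
#' @slot targetFraction target concentration r in the mixture.
#' @slot duration simulated duration, seconds.
#' @export
setClass("GroundTruth",
  slots = c(events = "data.frame", rate = "numeric",
            targetFraction = "numeric", duration = "numeric")
)

setValidity("GroundTruth", function(object) {
  ev <- object@events
  need <- c("event_id", "time_s", "species", "is_target", "radius_um",
            "lateral_offset_um")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(ev$time_s)) return("arrival times must be sorted")
  if (object@targetFraction < 0 || object@targetFraction > 1)
    return("targetFraction must lie in [0, 1]")
  if (object@rate < 0) return("rate must be >= 0")
  TRUE
})

#' LineScanStream: a simulated raw line-scan acquisition
#'
#' @slot samples 3-D array, n_lines x n_lateral_pixels x n_colors.
#' @slot lineTimes acquisition time of each line, seconds; strictly
#'   increasing with constant pitch 1/lineRate.
#' @export
setClass("LineScanStream",
  slots = c(samples = "array", lineTimes = "numeric"))

setValidity("LineScanStream", function(object) {
  d <- dim(object@samples)
  if (length(d) != 3) return("samples must be a 3-D array")
  if (d[1] != length(object@lineTimes))
    return("length(lineTimes) must equal nrow(samples)")
  if (d[1] >= 2) {
    dt <- diff(object@lineTimes)
    if (any(dt <= 0)) return("lineTimes must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(dt))
      return("lineTimes must have constant pitch")
  }
  TRUE
})

#' FSCTrace: forward-scatter intensity per line time
#'
#' @slot values non-negative scalar intensity per line.
#' @slot times time base, identical to the stream's lineTimes.
#' @export
setClass("FSCTrace", slots = c(values = "numeric", times = "numeric"))

setValidity("FSCTrace", function(object) {
  if (length(object@values) != length(object@times))
    return("values and times must have equal length")
  if (any(object@values < 0)) return("FSC values must be non-negative")
  TRUE
})

#' EventFrame: the per-event multicolor image cut from the stream
#'
#' @slot eventId unique integer id assigned in trigger order.
#' @slot triggerTime event trigger time, seconds.
#' @slot raw 3-D array frameLines x nLateralPixels x nColors.
#' @slot aborted TRUE when the stream ended before the frame completed.
#' @export
setClass("EventFrame",
  slots = c(eventId = "integer", triggerTime = "numeric", raw = "array",
            aborted = "logical"))

#' CellMask: binary specimen mask on the square-pixel grid
#'
#' @slot pixels logical matrix (rows = flow direction).
#' @slot areaPx number of set pixels.
#' @slot areaUm2 mask area in um^2 (NA if no pixel calibration was given).
#' @export
setClass("CellMask",
  slots = c(pixels = "matrix", areaPx = "numeric", areaUm2 = "numeric"))

setValidity("CellMask", function(object) {
  if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
  if (object@areaPx != sum(object@pixels))
    return("areaPx must equal the number of set pixels")
  TRUE
})

#' Gate: a sort/unsort decision region in 2-D feature space
#'
#' The boundary is inclusive: a feature point on the gate edge is sorted.
#'
#' @slot xFeature,yFeature feature names looked up in a feature record.
#' @slot vertices polygon vertex matrix (n x 2), columns (x, y).
#' @slot label meaning of the region (default "sort").
#' @export
setClass("Gate",
  slots = c(xFeature = "character", yFeature = "character",
            vertices = "matrix", label = "character"))

setValidity("Gate", function(object) {
  v <- object@vertices
  if (ncol(v) != 2 || nrow(v) < 3)
    return("vertices must be an n x 2 matrix with n >= 3")
  x <- v[, 1]; y <- v[, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (!is.finite(a) || a <= 0) return("gate region is degenerate")
  TRUE
})

#' SortTimingConfig: timing of the dual-membrane push-pull sorter
#'
#' The sort window \code{w} is the duration over which one membrane actuation
#' displaces particles at the junction; \code{tau = w/2} is the coincidence
#' half-window entering the Poisson model. Equivalently \code{tau} is half the
#' transit time of the sorting region: \code{sortRegionLength / flowSpeed / 2}.
#'
#' @slot sortLatency interrogation-to-sort-point delay, s.
#' @slot sortWindow sort window w, s.
#' @slot rate event rate lambda, events/s.
#' @slot targetFraction target concentration r.
#' @slot flowSpeed m/s.
#' @slot sortRegionLength um.
#' @slot variant displacement rule variant, "alternating" or "self-priority".
#' @export
setClass("SortTimingConfig",
  slots = c(sortLatency = "numeric", sortWindow = "numeric", rate = "numeric",
            targetFraction = "numeric", flowSpeed = "numeric",
            sortRegionLength = "numeric", variant = "character"))

setValidity("SortTimingConfig", function(object) {
  if (object@sortWindow <= 0) return("sortWindow must be > 0")
  if (object@rate < 0) return("rate must be >= 0")
  if (object@targetFraction < 0 || object@targetFraction > 1)
    return("targetFraction must lie in [0, 1]")
  if (!object@variant %in% c("alternating", "self-priority"))
    return("variant must be 'alternating' or 'self-priority'")
  TRUE
})

#' Construct a SortTimingConfig
#'
#' Give either \code{sortWindow} directly or \code{sortRegionLength} (um),
#' from which \code{sortWindow = sortRegionLength / flowSpeed} is derived
#' (so tau = sortRegionLength / flowSpeed / 2).
#'
#' @param sortWindow sort window, s (default 3e-3).
#' @param rate event rate lambda, events/s.
#' @param targetFraction target fraction r.
#' @param flowSpeed flow speed, m/s.
#' @param sortRegionLength sorting-region length, um; overrides sortWindow.
#' @param sortLatency interrogation-to-sort delay, s.
#' @param variant displacement-rule variant.
#' @return A \linkS4class{SortTimingConfig}.
#' @export
sortTimingConfig <- function(sortWindow = 3e-3, rate = 50.2,
                             targetFraction = 0.6, flowSpeed = 0.04,
                             sortRegionLength = NA_real_, sortLatency = 0,
                             variant = "alternating") {
  if (!is.na(sortRegionLength)) {
    if (sortRegionLength <= 0) stop("sortRegionLength must be > 0")
    sortWindow <- sortRegionLength * 1e-6 / flowSpeed
  } else {
    sortRegionLength <- sortWindow * flowSpeed * 1e6
  }
  new("SortTimingConfig", sortLatency = sortLatency, sortWindow = sortWindow,
      rate = rate, targetFraction = targetFraction, flowSpeed = flowSpeed,
      sortRegionLength = sortRegionLength, variant = variant)
}

#' ScenarioTable: the 32-scenario sorting-outcome sample space
#'
#' One row per combination of (previous particle target?, particle of
#' interest target?, next particle target?, preceding gap < tau?, following
#' gap < tau?), with the outcome under the displacement rules and the
#' scenario probability (product of the five factor probabilities).
#'
#' @slot scenarios data.frame with 32 rows.
#' @slot lambda,tau,r the model parameters the probabilities were computed at.
#' @export
setClass("ScenarioTable",
  slots = c(scenarios = "data.frame", lambda = "numeric", tau = "numeric",
            r = "numeric"))

setValidity("ScenarioTable", function(object) {
  if (nrow(object@scenarios) != 32) return("scenario table must have 32 rows")
  if (abs(sum(object@scenarios$probability) - 1) > 1e-12)
    return("scenario probabilities must sum to 1 within 1e-12")
  TRUE
})

#' SortRun: per-event outcomes of a Monte-Carlo sorter simulation
#'
#' @slot events data.frame with per-event time_s, is_target, decision,
#'   actuated, direction, n_actuations, destination, outcome.
#' @slot tau coincidence half-window used, s.
#' @slot variant displacement-rule variant used.
#' @export
setClass("SortRun",
  slots = c(events = "data.frame", tau = "numeric", variant = "character"))

setValidity("SortRun", function(object) {
  ev <- object@events
  if (!all(ev$destination %in% c("collection", "waste")))
    return("destinations must partition events into collection/waste")
  ok <- ifelse(ev$is_target,
               ifelse(ev$destination == "collection", "TP", "FN"),
               ifelse(ev$destination == "collection", "FP", "TN"))
  if (!identical(ok, ev$outcome))
    return("outcome inconsistent with (is_target, destination)")
  TRUE
})

#' EventRateSeries: windowed event rates and the nominal throughput
#'
#' The rate at event i (i >= 51) is 50 divided by the time spanned by the 50
#' preceding inter-event intervals; the nominal throughput is the most
#' frequent value (histogram mode).
#'
#' @slot index event indices (from 51).
#' @slot rates events per second.
#' @slot nominalThroughput modal event rate, events per second.
#' @slot binWidth histogram bin width used for the mode, events per second.
#' @export
setClass("EventRateSeries",
  slots = c(index = "integer", rates = "numeric",
            nominalThroughput = "numeric", binWidth = "numeric"))
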
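# End-to-end virtual sorting experiments: Poisson arrivals -> per-event
# rendering -> full image pipeline -> gating -> sorter simulation ->
# purity/yield.

#' Default density gate for a two-species mixture
#'
#' A rectangle in (nontarget density, target density) space placed at half
#' the expected density of a unit-concentration specimen: sort iff the
#' target-constituent density exceeds half its expected value while the
#' nontarget density stays below half of its own.
#'
#' @param basis a \linkS4class{SpectralBasis} (two constituents).
#' @param pixelArea pixel area on the normalized grid, um^2.
#' @param target target constituent name.
#' @param amplitude specimen concentration scale used in rendering.
#' @return A \linkS4class{Gate} on the density features.
#' @export
densityGate <- function(basis, pixelArea, target = "PMMA", amplitude = 1) {
  cons <- constituentNames(basis)
  nontarget <- setdiff(cons, target)[1]
  d0 <- amplitude / pixelArea   # expected density of a pure unit specimen
  rectangleGate(paste0(nontarget, "_density"), paste0(target, "_density"),
                xRange = c(-10 * d0, 0.5 * d0),
                yRange = c(0.5 * d0, 10 * d0))
}

#' Run a virtual sorting experiment
#'
#' Simulates \code{nEvents} Poisson arrivals of a binary target/nontarget
#' mixture, renders each event's acquisition window, runs the full analysis
#' chain (detection, framing, square normalization, unmixing, masking,
#' features, gating), then feeds the arrival stream and gate decisions to
#' the Monte-Carlo sorter and evaluates purity and yield against ground
#' truth.
#'
#' Events are rendered in per-event windows of frameLines + 2 margin lines
#' (their Poisson arrival times still drive the sorter), which keeps memory
#' flat at any event count.
#'
#' @param nEvents number of events.
#' @param rate arrival rate lambda, events/s.
#' @param targetFraction target fraction r.
#' @param basis a \linkS4class{SpectralBasis}.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param timing a \linkS4class{SortTimingConfig}.
#' @param gate a \linkS4class{Gate}; NULL builds \code{\link{densityGate}}.
#' @param params segmentation parameters.
#' @param amplitude specimen concentration scale.
#' @param seed RNG seed for the whole experiment.
#' @param margin specimen-free lines kept before the frame, so the
#'   background-correction margins stay clean.
#' @return list(truth, features, decisions, accuracy, maskedFraction,
#'   sortRun, metrics).
#' @export
virtualSortExperiment <- function(nEvents = 1000, rate = 50.2,
                                  targetFraction = 0.6,
                                  basis = defaultBasis(),
                                  config = acquisitionConfig(),
                                  timing = sortTimingConfig(rate = rate,
                                    targetFraction = targetFraction),
                                  gate = NULL,
                                  params = segmentationParams(),
                                  amplitude = 1, seed = 1, margin = 20L) {
  set.seed(seed)
  truth <- simulateArrivals(rate, targetFraction, nEvents = nEvents)
  ev <- truth@events
  lp <- linePeriod(config)
  L <- config@frameLines
  flowExtent <- flowPitch(config) * L
  width <- max(1L, as.integer(floor(
    config@lateralFOV / (flowExtent / L) + 0.5)))
  pixelArea <- (flowExtent / L) * (config@lateralFOV / width)
  if (is.null(gate)) gate <- densityGate(basis, pixelArea,
                                         amplitude = amplitude)
  templates <- speciesTemplates(basis)
  # fixed detector-to-camera delay that centers a typical specimen mid-frame
  rTyp <- mean(ev$radius_um)
  delay <- rTyp * 1e-6 / config@flowSpeed - (L / 2) * lp
  nLines <- L + 2L * margin
  centerTime <- (margin + L / 2) * lp
  feats <- vector("list", nEvents)
  dec <- logical(nEvents)
  masked <- logical(nEvents)
  for (i in seq_len(nEvents)) {
    one <- initialize(truth,
                      events = transform(ev[i, , drop = FALSE],
                                         time_s = centerTime, event_id = 0L),
                      duration = nLines * lp)
    acq <- renderStream(one, basis, config, templates, amplitude,
                        duration = nLines * lp)
    det <- detectEvents(acq$fsc, threshold = 1,
                        refractory = nLines * lp)
    if (!nrow(det)) {
      feats[[i]] <- NULL
      next
    }
    fr <- frameEvent(acq$stream, det$trigger_time[1], config, delay,
                     eventId = ev$event_id[i])
    norm <- normalizeSquare(fr, flowExtent, config@lateralFOV)
    dec3 <- unmixImage(norm, basis)
    ch <- which.max(apply(dec3, 3, sum))
    mask <- segment(dec3[, , ch], params, pixelArea)
    f <- extractFeatures(dec3, mask, pixelArea, eventId = ev$event_id[i])
    feats[[i]] <- f
    masked[i] <- !f$empty
    dec[i] <- decide(f, gate)
  }
  features <- do.call(rbind, feats)
  accuracy <- mean(dec == ev$is_target)
  run <- simulateSorting(truth, timing, decisions = dec,
                         labels = ev$is_target)
  metrics <- evaluateRun(run)
  if (nEvents >= 51)
    metrics$eventRate <- eventRate(ev$time_s)
  list(truth = truth, features = features,
       decisions = data.frame(event_id = ev$event_id, sort = dec,
                              is_target = ev$is_target),
       accuracy = accuracy, maskedFraction = mean(masked),
       sortRun = run, metrics = metrics)
}
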
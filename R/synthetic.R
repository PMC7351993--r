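# Synthetic flow-imaging acquisitions: Poisson particle arrivals crossing a
# multicolor line focus, rendered to a line-scan stream plus a forward-
# scatter (FSC) trace, with full ground truth retained.

#' Concentration templates for the basis species
#'
#' By default each species is a pure constituent: the template of constituent
#' i is the unit vector along i. Override to model mixed compositions.
#'
#' @param basis a \linkS4class{SpectralBasis}.
#' @return Named list of per-species concentration vectors.
#' @export
speciesTemplates <- function(basis) {
  cons <- constituentNames(basis)
  tmpl <- lapply(seq_along(cons), function(i) {
    v <- numeric(length(cons))
    names(v) <- cons
    v[i] <- 1
    v
  })
  names(tmpl) <- cons
  tmpl
}

#' Simulate Poisson particle arrivals with a binary target/nontarget mixture
#'
#' Inter-arrival times are exponential with mean 1/rate; each arrival is
#' independently a target with probability \code{targetFraction}. Specimen
#' radii default to the polymer-bead experiment (5 um PMMA targets, 6 um PS
#' nontargets); lateral offsets model residual focusing jitter as a
#' truncated Gaussian.
#'
#' @param rate arrival rate lambda, events per second (> 0).
#' @param targetFraction target concentration r in [0, 1].
#' @param duration simulated duration, seconds (> 0); ignored when
#'   \code{nEvents} is given.
#' @param seed integer RNG seed; NULL uses the ambient RNG stream.
#' @param nEvents simulate exactly this many arrivals instead of a fixed
#'   duration.
#' @param targetSpecies,nontargetSpecies species labels.
#' @param radii named radii (um) per species, or a single number.
#' @param lateralSD lateral offset SD, um.
#' @param maxOffset truncation bound for lateral offsets, um.
#' @return A \linkS4class{GroundTruth}.
#' @export
simulateArrivals <- function(rate, targetFraction, duration = NULL,
                             seed = NULL, nEvents = NULL,
                             targetSpecies = "PMMA", nontargetSpecies = "PS",
                             radii = c(PMMA = 2.5, PS = 3.0),
                             lateralSD = 1.0, maxOffset = 3.0) {
  if (rate <= 0) stop("rate must be > 0")
  if (targetFraction < 0 || targetFraction > 1)
    stop("targetFraction must lie in [0, 1]")
  if (is.null(nEvents)) {
    if (is.null(duration) || duration <= 0) stop("duration must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(nEvents)) {
    times <- cumsum(rexp(nEvents, rate))
    duration <- if (nEvents) max(times) else 0
  } else {
    # draw in blocks until the window is covered
    times <- numeric(0)
    t0 <- 0
    repeat {
      blk <- max(16, ceiling(1.5 * rate * (duration - t0)))
      times <- c(times, t0 + cumsum(rexp(blk, rate)))
      t0 <- times[length(times)]
      if (t0 > duration) break
    }
    times <- times[times <= duration]
  }
  n <- length(times)
  isTarget <- if (n) rbinom(n, 1, targetFraction) == 1 else logical(0)
  species <- ifelse(isTarget, targetSpecies, nontargetSpecies)
  if (is.null(names(radii))) {
    radius <- rep_len(radii, n)
  } else {
    radius <- unname(radii[species])
  }
  off <- if (n) pmin(pmax(rnorm(n, 0, lateralSD), -maxOffset), maxOffset)
         else numeric(0)
  ev <- data.frame(event_id = seq_len(n) - 1L, time_s = times,
                   species = as.character(species), is_target = isTarget,
                   radius_um = as.numeric(radius), lateral_offset_um = off,
                   stringsAsFactors = FALSE)
  new("GroundTruth", events = ev, rate = rate,
      targetFraction = targetFraction, duration = duration)
}

#' Attach droplet texture to specimens
#'
#' Gives every specimen \code{nDroplets} internal circular inclusions
#' (e.g. lipid droplets) in which the concentration of one constituent is
#' multiplied, producing intensity heterogeneity within the mask.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nDroplets droplets per specimen.
#' @param radiusFrac droplet radius as a fraction of the specimen radius.
#' @param multiplier concentration multiplier inside droplets.
#' @param seed optional RNG seed.
#' @return The truth with a \code{texture} list column added.
#' @export
addDroplets <- function(truth, nDroplets = 3, radiusFrac = 0.25,
                        multiplier = 3, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  if (!is.null(seed)) set.seed(seed)
  ev <- truth@events
  ev$texture <- lapply(seq_len(nrow(ev)), function(i) {
    R <- ev$radius_um[i]
    rd <- radiusFrac * R
    # droplet centers uniform in the disk that keeps droplets inside
    rho <- (R - rd) * sqrt(runif(nDroplets))
    th <- runif(nDroplets, 0, 2 * pi)
    data.frame(flow_offset_um = rho * cos(th),
               lateral_offset_um = rho * sin(th),
               radius_um = rd, multiplier = multiplier)
  })
  initialize(truth, events = ev)
}

#' Render a ground-truth arrival stream to a line-scan acquisition
#'
#' Each specimen is drawn as a disk in (time x lateral) coordinates: its
#' extent along the flow is 2 radius / flowSpeed, its per-pixel signal is
#' \code{responses(basis) \%*\% (amplitude * template)} over its support, and
#' droplet texture multiplies the template locally. Zero-mean Gaussian noise
#' of SD \code{noiseSigma} is added everywhere. The FSC trace is the summed
#' occluded chord (um) at each line time, optionally widened to the minimum
#' pulse duration \code{fscPulseWidth}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param basis a \linkS4class{SpectralBasis}.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param templates per-species concentration templates
#'   (default \code{\link{speciesTemplates}}).
#' @param amplitude global concentration scale, signal units.
#' @param startTime time of the first line, s.
#' @param duration rendered duration, s (default the truth's duration).
#' @return \code{list(stream = LineScanStream, fsc = FSCTrace)}.
#' @export
renderStream <- function(truth, basis, config,
                         templates = speciesTemplates(basis),
                         amplitude = 1, startTime = 0,
                         duration = truth@duration) {
  stopifnot(is(truth, "GroundTruth"), is(basis, "SpectralBasis"),
            is(config, "AcquisitionConfig"))
  if (config@nColors != nColors(basis))
    stop("config nColors does not match the basis")
  nLines <- max(1L, as.integer(round(duration * config@lineRate)))
  lp <- linePeriod(config)
  lineTimes <- startTime + (seq_len(nLines) - 1) * lp
  W <- config@nLateralPixels
  C <- config@nColors
  if (!is.na(config@seed)) set.seed(config@seed)
  samples <-
    if (config@noiseSigma > 0)
      array(rnorm(nLines * W * C, 0, config@noiseSigma), c(nLines, W, C))
    else array(0, c(nLines, W, C))
  fsc <- numeric(nLines)
  # lateral pixel-center coordinates, um from channel center
  latx <- (seq_len(W) - (W + 1) / 2) * lateralPitch(config)
  vum <- config@flowSpeed * 1e6                   # um/s along the flow
  ev <- truth@events
  for (i in seq_len(nrow(ev))) {
    R <- ev$radius_um[i]
    off <- ev$lateral_offset_um[i]
    if (abs(off) + R > config@lateralFOV / 2)
      stop("specimen lateral extent exceeds the field of view")
    tmpl <- templates[[ev$species[i]]]
    if (is.null(tmpl))
      stop("no concentration template for species ", ev$species[i])
    s <- drop(basis@responses %*% (amplitude * tmpl))
    t0 <- ev$time_s[i]
    # image support
    i0 <- max(1L, ceiling((t0 - R / vum - startTime) / lp) + 1L)
    i1 <- min(nLines, floor((t0 + R / vum - startTime) / lp) + 1L)
    tex <- if (!is.null(ev$texture)) ev$texture[[i]] else NULL
    if (i1 >= i0) for (li in i0:i1) {
      dy <- (lineTimes[li] - t0) * vum
      half <- sqrt(max(0, R^2 - dy^2))
      cols <- which(abs(latx - off) <= half)
      if (length(cols)) {
        samples[li, cols, ] <- samples[li, cols, ] +
          rep(s, each = length(cols))
        if (!is.null(tex) && nrow(tex)) for (k in seq_len(nrow(tex))) {
          du <- dy - tex$flow_offset_um[k]
          hx <- tex$radius_um[k]^2 - du^2
          if (hx > 0) {
            dc <- cols[abs(latx[cols] - off - tex$lateral_offset_um[k]) <=
                         sqrt(hx)]
            if (length(dc))
              samples[li, dc, ] <- samples[li, dc, ] +
                rep((tex$multiplier[k] - 1) * s, each = length(dc))
          }
        }
      }
    }
    # FSC support (possibly widened to the minimum pulse duration)
    Reff <- max(R, vum * config@fscPulseWidth / 2)
    j0 <- max(1L, ceiling((t0 - Reff / vum - startTime) / lp) + 1L)
    j1 <- min(nLines, floor((t0 + Reff / vum - startTime) / lp) + 1L)
    if (j1 >= j0) {
      dy <- (lineTimes[j0:j1] - t0) * vum * (R / Reff)
      fsc[j0:j1] <- fsc[j0:j1] + 2 * sqrt(pmax(0, R^2 - dy^2))
    }
  }
  list(stream = new("LineScanStream", samples = samples,
                    lineTimes = lineTimes),
       fsc = new("FSCTrace", values = pmax(fsc, 0), times = lineTimes))
}
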
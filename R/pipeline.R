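# The real-time analysis chain: FSC event detection, frame construction,
# square-pixel normalization, morphological masking, feature extraction and
# gating.

#' Detect events on the forward-scatter trace
#'
#' One event per upward threshold crossing; re-triggers within the
#' refractory window of an accepted event are suppressed. IDs are assigned
#' in time order starting at 0.
#'
#' @param trace an \linkS4class{FSCTrace}.
#' @param threshold trigger threshold, same units as the trace (must exceed
#'   the baseline noise).
#' @param refractory minimum time between accepted triggers, s.
#' @return data.frame(event_id, trigger_time).
#' @export
detectEvents <- function(trace, threshold, refractory = 0) {
  stopifnot(is(trace, "FSCTrace"))
  v <- trace@values
  if (!length(v)) stop("empty trace")
  above <- v >= threshold
  up <- which(above & !c(FALSE, head(above, -1)))
  tt <- trace@times[up]
  keep <- logical(length(tt))
  last <- -Inf
  for (i in seq_along(tt)) {
    if (tt[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  tt <- tt[keep]
  data.frame(event_id = seq_along(tt) - 1L, trigger_time = tt)
}

#' Cut an event frame out of the stream
#'
#' Extracts \code{frameLines} consecutive lines starting at
#' \code{triggerTime + acquisitionDelay} (the delay may be negative for
#' peri-trigger framing). If fewer lines remain in the stream the frame is
#' marked aborted and zero-padded.
#'
#' @param stream a \linkS4class{LineScanStream}.
#' @param triggerTime event trigger time, s; must fall inside the stream.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param acquisitionDelay trigger-to-first-line delay, s.
#' @param eventId id stored in the frame.
#' @return An \linkS4class{EventFrame}.
#' @export
frameEvent <- function(stream, triggerTime, config, acquisitionDelay = 0,
                       eventId = 0L) {
  stopifnot(is(stream, "LineScanStream"), is(config, "AcquisitionConfig"))
  times <- stream@lineTimes
  if (triggerTime < times[1] - 1e-12)
    stop("trigger before stream start")
  if (triggerTime > times[length(times)])
    stop("trigger beyond stream end")
  start <- triggerTime + acquisitionDelay
  startIdx <- max(1L, as.integer(ceiling((start - times[1]) / linePeriod(config) - 1e-9)) + 1L)
  L <- config@frameLines
  endIdx <- startIdx + L - 1L
  n <- length(times)
  aborted <- endIdx > n
  avail <- min(endIdx, n) - startIdx + 1L
  raw <- array(0, c(L, config@nLateralPixels, config@nColors))
  if (avail > 0)
    raw[seq_len(avail), , ] <-
      stream@samples[startIdx:(startIdx + avail - 1L), , , drop = FALSE]
  new("EventFrame", eventId = as.integer(eventId), triggerTime = triggerTime,
      raw = raw, aborted = aborted)
}

#' Normalize a frame to square pixels
#'
#' The flow-direction pitch \code{flowFOV / frameLines} is preserved; the
#' lateral axis is resampled by linear interpolation to
#' \code{round(lateralFOV / (flowFOV / frameLines))} pixels (half-up
#' rounding). A 122 x 24 frame with a 33 x 24 um field of view becomes
#' 122 x 89.
#'
#' @param frame an \linkS4class{EventFrame}, a 3-D array or a matrix.
#' @param flowFOV flow-direction extent of the frame, um.
#' @param lateralFOV lateral extent, um.
#' @return Array (or matrix) with the resampled lateral axis.
#' @export
normalizeSquare <- function(frame, flowFOV, lateralFOV) {
  if (is(frame, "EventFrame")) frame <- frame@raw
  if (flowFOV <= 0 || lateralFOV <= 0) stop("FOVs must be positive")
  isMat <- is.matrix(frame)
  if (isMat) frame <- array(frame, c(dim(frame), 1L))
  d <- dim(frame)
  if (length(d) != 3 || any(d == 0)) stop("zero-size frame")
  L <- d[1]; W <- d[2]
  pitch <- flowFOV / L
  width <- max(1L, as.integer(floor(lateralFOV / pitch + 0.5)))
  if (width == W) {
    out <- frame
  } else {
    # pixel centers, fractional index into the original lateral axis
    xOld <- (seq_len(W) - 0.5) / W
    xNew <- (seq_len(width) - 0.5) / width
    idx <- approx(xOld, seq_len(W), xout = xNew, rule = 2)$y
    lo <- pmin(floor(idx), W - 1L)
    f <- idx - lo
    out <- array(0, c(L, width, d[3]))
    for (k in seq_len(d[3]))
      out[, , k] <- frame[, lo, k] * (1 - rep(f, each = L)) +
        frame[, lo + 1L, k] * rep(f, each = L)
  }
  if (isMat) out[, , 1] else out
}

#' Segmentation parameters
#'
#' @param backgroundRows rows at each frame margin assumed specimen-free and
#'   used for per-column median background correction.
#' @param gaussianSigma Gaussian smoothing SD, px.
#' @param tophatRadius top-hat structuring disk radius, px (larger than any
#'   specimen).
#' @param cannyLow,cannyHigh Canny hysteresis thresholds as fractions of the
#'   filtered-image maximum.
#' @param closeRadius disk radius of the dilation/erosion used to close the
#'   edge contour, px.
#' @param refineFraction before taking the convex hull, restrict the
#'   component to pixels at or above this fraction of its (robust) peak
#'   intensity. For a blurred step edge the half-maximum contour coincides
#'   with the true boundary, so the default 0.5 removes the outer half of
#'   the Canny ridge that otherwise inflates the mask by about half a pixel
#'   of radius. 0 disables the refinement.
#' @param noiseFloor reject edges unless the strong Canny threshold exceeds
#'   this multiple of the background MAD of the filtered image; makes blank
#'   frames yield empty masks even though the hysteresis thresholds are
#'   relative to the image maximum.
#' @param minAreaPx components smaller than this are treated as noise.
#' @return A named list of parameters for \code{\link{segment}}.
#' @export
segmentationParams <- function(backgroundRows = 5, gaussianSigma = 1,
                               tophatRadius = 15, cannyLow = 0.1,
                               cannyHigh = 0.3, closeRadius = 2,
                               refineFraction = 0.5, noiseFloor = 3,
                               minAreaPx = 5) {
  list(backgroundRows = backgroundRows, gaussianSigma = gaussianSigma,
       tophatRadius = tophatRadius, cannyLow = cannyLow,
       cannyHigh = cannyHigh, closeRadius = closeRadius,
       refineFraction = refineFraction, noiseFloor = noiseFloor,
       minAreaPx = minAreaPx)
}

# shift a matrix by (dr, dc) with replicated borders
.shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Canny edge detection: Sobel gradients, non-maximum suppression along the
# gradient direction, hysteresis linking via connected components.
.cannyEdges <- function(img, low, high) {
  gx <- .shiftMat(img, 0, -1) - .shiftMat(img, 0, 1) +
    0.5 * (.shiftMat(img, -1, -1) - .shiftMat(img, -1, 1) +
           .shiftMat(img, 1, -1) - .shiftMat(img, 1, 1))
  gy <- .shiftMat(img, -1, 0) - .shiftMat(img, 1, 0) +
    0.5 * (.shiftMat(img, -1, -1) - .shiftMat(img, 1, -1) +
           .shiftMat(img, -1, 1) - .shiftMat(img, 1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  sector <- (round(atan2(gy, gx) / (pi / 4)) %% 4)
  nms <- mag
  for (s in 0:3) {
    d <- switch(as.character(s),
                "0" = c(0L, 1L),    # gradient along columns
                "1" = c(1L, 1L),
                "2" = c(1L, 0L),
                "3" = c(1L, -1L))
    n1 <- .shiftMat(mag, d[1], d[2])
    n2 <- .shiftMat(mag, -d[1], -d[2])
    sup <- sector == s & (mag < n1 | mag < n2)
    nms[sup] <- 0
  }
  weak <- nms >= low
  strong <- nms >= high
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lbl <- EBImage::bwlabel(weak)
  keep <- setdiff(unique(lbl[strong]), 0)
  weak & (lbl %in% keep)
}

# Fill the convex hull of a pixel set, inclusive of boundary pixels. The
# row-span fill is idempotent under chull + refill: the fill of a convex
# polygon P contains exactly the pixel centers inside P, so chull(fill(P))
# is again a convex polygon inside P with the same fill.
.fillConvex <- function(rows, cols, dm) {
  h <- grDevices::chull(cols, rows)
  vx <- cols[h]; vy <- rows[h]
  n <- length(h)
  out <- matrix(FALSE, dm[1], dm[2])
  for (y in max(1L, as.integer(ceiling(min(vy)))):
           min(dm[1], as.integer(floor(max(vy))))) {
    xs <- numeric(0)
    for (e in seq_len(n)) {
      x1 <- vx[e]; y1 <- vy[e]
      x2 <- vx[e %% n + 1]; y2 <- vy[e %% n + 1]
      if (y1 == y2) {
        if (y == y1) xs <- c(xs, x1, x2)
      } else if (y >= min(y1, y2) && y <= max(y1, y2)) {
        xs <- c(xs, x1 + (y - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs)) {
      c0 <- max(1L, as.integer(ceiling(min(xs) - 1e-9)))
      c1 <- min(dm[2], as.integer(floor(max(xs) + 1e-9)))
      if (c1 >= c0) out[y, c0:c1] <- TRUE
    }
  }
  out
}

#' Segment a normalized single-channel image into a cell mask
#'
#' Pipeline: (1) background correction by per-column median of the frame
#' margins, (2) Gaussian smoothing, (3) white top-hat, (4) Canny edge
#' detection, (5) contour closing by dilation, flood fill and erosion,
#' (6) convex hull of the largest connected component. An empty mask is a
#' valid outcome (blank frame, open contour, or sub-minimum component).
#'
#' @param image numeric matrix (rows = flow direction) on the square-pixel
#'   grid.
#' @param params see \code{\link{segmentationParams}}.
#' @param pixelArea area of one pixel, um^2 (NA leaves areaUm2 as NA).
#' @return A \linkS4class{CellMask}.
#' @export
segment <- function(image, params = segmentationParams(),
                    pixelArea = NA_real_) {
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image must be finite")
  L <- nrow(image)
  emptyMask <- function() new("CellMask",
                              pixels = matrix(FALSE, L, ncol(image)),
                              areaPx = 0, areaUm2 = if (is.na(pixelArea)) NA_real_ else 0)
  br <- min(params$backgroundRows, floor(L / 2))
  if (br > 0) {
    bgRows <- c(seq_len(br), (L - br + 1):L)
    image <- sweep(image, 2, apply(image[bgRows, , drop = FALSE], 2, median))
  }
  if (params$gaussianSigma > 0)
    image <- EBImage::gblur(image, sigma = params$gaussianSigma)
  if (params$tophatRadius > 0)
    image <- EBImage::whiteTopHat(
      image, EBImage::makeBrush(2 * params$tophatRadius + 1, "disc"))
  mx <- max(image)
  if (mx <= 0) return(emptyMask())
  if (br > 0) {
    bgMad <- mad(image[bgRows, ])
    if (params$cannyHigh * mx <= params$noiseFloor * bgMad)
      return(emptyMask())            # no edge rises above the noise floor
  }
  edges <- .cannyEdges(image, params$cannyLow * mx, params$cannyHigh * mx)
  if (!any(edges)) return(emptyMask())
  brush <- EBImage::makeBrush(2 * params$closeRadius + 1, "disc")
  closed <- EBImage::erode(
    EBImage::fillHull(EBImage::dilate(edges + 0, brush)), brush)
  lbl <- EBImage::bwlabel(closed)
  nObj <- max(lbl)
  if (nObj == 0) return(emptyMask())
  sizes <- tabulate(lbl[lbl > 0], nObj)
  big <- which.max(sizes)
  if (sizes[big] < params$minAreaPx) return(emptyMask())
  comp <- lbl == big
  if (params$refineFraction > 0) {
    vals <- image[comp]
    thr <- params$refineFraction * quantile(vals, 0.95, names = FALSE)
    keep <- comp & image >= thr
    if (sum(keep) >= params$minAreaPx) comp <- keep
  }
  px <- which(comp, arr.ind = TRUE)
  mask <- .fillConvex(px[, 1], px[, 2], dim(image))
  if (sum(mask) < params$minAreaPx) return(emptyMask())
  new("CellMask", pixels = mask, areaPx = sum(mask),
      areaUm2 = sum(mask) * pixelArea)
}

#' Extract per-event features from decomposed images
#'
#' Statistics (total, mean, maximum, SD) are computed over mask pixels for
#' each constituent; the density is the total intensity per unit mask area
#' (um^2). An empty mask yields a flagged record with NA features.
#'
#' @param decomposed 3-D array lines x lateral x constituents, as returned
#'   by \code{\link{unmixImage}}.
#' @param mask a \linkS4class{CellMask} on the same grid.
#' @param pixelArea pixel area, um^2.
#' @param eventId id copied into the record.
#' @param clipNegative clip negative concentrations to zero before computing
#'   density features (display-stage convention; the decomposition itself is
#'   never clipped).
#' @return One-row data.frame of features.
#' @export
extractFeatures <- function(decomposed, mask, pixelArea, eventId = NA_integer_,
                            clipNegative = FALSE) {
  stopifnot(is(mask, "CellMask"))
  d <- dim(decomposed)
  if (length(d) != 3 || d[1] != nrow(mask@pixels) || d[2] != ncol(mask@pixels))
    stop("mask grid does not match the decomposed image")
  cons <- dimnames(decomposed)[[3]]
  if (is.null(cons)) cons <- paste0("constituent", seq_len(d[3]))
  areaPx <- mask@areaPx
  areaUm2 <- areaPx * pixelArea
  out <- data.frame(event_id = eventId, area_px = areaPx,
                    area_um2 = areaUm2, empty = areaPx == 0)
  sel <- mask@pixels
  for (k in seq_len(d[3])) {
    v <- decomposed[, , k][sel]
    if (clipNegative) v <- pmax(v, 0)
    if (areaPx == 0) {
      st <- c(total = NA_real_, mean = NA_real_, max = NA_real_,
              sd = NA_real_, density = NA_real_)
    } else {
      st <- c(total = sum(v), mean = mean(v), max = max(v),
              sd = if (areaPx > 1) sd(v) else 0,
              density = sum(v) / areaUm2)
    }
    names(st) <- paste(cons[k], names(st), sep = "_")
    out[names(st)] <- as.list(st)
  }
  out
}

#' Rectangle and polygon gates
#'
#' @param xFeature,yFeature feature names.
#' @param xRange,yRange numeric length-2 bounds of the rectangle.
#' @param vertices n x 2 matrix of polygon vertices (x, y).
#' @param label gate meaning.
#' @return A \linkS4class{Gate}.
#' @export
rectangleGate <- function(xFeature, yFeature, xRange, yRange,
                          label = "sort") {
  new("Gate", xFeature = xFeature, yFeature = yFeature,
      vertices = cbind(x = c(xRange[1], xRange[2], xRange[2], xRange[1]),
                       y = c(yRange[1], yRange[1], yRange[2], yRange[2])),
      label = label)
}

#' @rdname rectangleGate
#' @export
polygonGate <- function(xFeature, yFeature, vertices, label = "sort") {
  new("Gate", xFeature = xFeature, yFeature = yFeature,
      vertices = as.matrix(vertices), label = label)
}

# boundary-inclusive point-in-polygon (even-odd rule plus edge test)
.pointInPolygon <- function(px, py, v, eps = 1e-12) {
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  scale <- max(abs(v), 1)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-edge check
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    cross <- dx * (py - y[i]) - dy * (px - x[i])
    if (abs(cross) <= eps * scale^2 &&
        px >= min(x[i], x[j]) - eps * scale &&
        px <= max(x[i], x[j]) + eps * scale &&
        py >= min(y[i], y[j]) - eps * scale &&
        py <= max(y[i], y[j]) + eps * scale)
      return(TRUE)
    if ((y[i] > py) != (y[j] > py) &&
        px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Apply a gate to a feature record
#'
#' Sort iff the feature point lies inside the gate region, boundary
#' inclusive. Events with empty masks are never sorted.
#'
#' @param features one-row data.frame or named list with the gate's
#'   features.
#' @param gate a \linkS4class{Gate}.
#' @return TRUE (sort) or FALSE (unsort).
#' @export
decide <- function(features, gate) {
  stopifnot(is(gate, "Gate"))
  if (!is.null(features$empty) && isTRUE(features$empty[1])) return(FALSE)
  px <- features[[gate@xFeature]]
  py <- features[[gate@yFeature]]
  if (is.null(px) || is.null(py))
    stop("gate features missing from the feature record")
  if (is.na(px) || is.na(py)) return(FALSE)
  .pointInPolygon(px[1], py[1], gate@vertices)
}

#' Process a stream end to end
#'
#' Detects events on the FSC trace, frames each, normalizes to square
#' pixels using the kinematic flow extent (flowSpeed / lineRate x
#' frameLines), decomposes spectrally, masks on the constituent channel with
#' the largest total frame signal (overridable), extracts features and
#' applies the gate. Aborted frames yield no feature record, so
#' events detected = feature rows + aborted frames.
#'
#' @param stream a \linkS4class{LineScanStream}.
#' @param fsc the matching \linkS4class{FSCTrace}.
#' @param basis a \linkS4class{SpectralBasis}.
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param gate a \linkS4class{Gate}, or NULL to skip decisions.
#' @param params segmentation parameters.
#' @param threshold FSC trigger threshold.
#' @param refractory trigger refractory window, s.
#' @param acquisitionDelay trigger-to-frame delay, s.
#' @param maskChannel constituent name to segment on; NULL selects the one
#'   with the largest total frame signal.
#' @return list(features, decisions, events, nAborted).
#' @export
processStream <- function(stream, fsc, basis, config, gate = NULL,
                          params = segmentationParams(), threshold = 1,
                          refractory = 1e-3, acquisitionDelay = 0,
                          maskChannel = NULL) {
  det <- detectEvents(fsc, threshold, refractory)
  flowExtent <- flowPitch(config) * config@frameLines
  feats <- list()
  dec <- logical(0)
  decIds <- integer(0)
  nAborted <- 0L
  for (i in seq_len(nrow(det))) {
    fr <- frameEvent(stream, det$trigger_time[i], config, acquisitionDelay,
                     eventId = det$event_id[i])
    if (fr@aborted) {
      nAborted <- nAborted + 1L
      next
    }
    norm <- normalizeSquare(fr, flowExtent, config@lateralFOV)
    pixelArea <- (flowExtent / config@frameLines) *
      (config@lateralFOV / ncol(norm))
    dec3 <- unmixImage(norm, basis)
    ch <- if (is.null(maskChannel)) {
      tot <- apply(dec3, 3, sum)
      which.max(tot)
    } else match(maskChannel, constituentNames(basis))
    mask <- segment(dec3[, , ch], params, pixelArea)
    f <- extractFeatures(dec3, mask, pixelArea, eventId = fr@eventId)
    feats[[length(feats) + 1L]] <- f
    if (!is.null(gate)) {
      dec <- c(dec, decide(f, gate))
      decIds <- c(decIds, fr@eventId)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  list(features = features,
       decisions = if (is.null(gate)) NULL
                   else data.frame(event_id = decIds, sort = dec),
       events = det, nAborted = nAborted)
}
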
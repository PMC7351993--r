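# Shared fixtures: tiny bases, disk phantoms, and an independent
# brute-force implementation of the sorter displacement rules used as the
# oracle for the scenario table and the Monte-Carlo engine.

identityBasis2 <- function()
  SpectralBasis(diag(2), c(2900, 2950), c("A", "B"))

randomFullRankBasis <- function(nColors, nConstituents, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    R <- matrix(runif(nColors * nConstituents, 0.2, 1), nColors)
    sv <- svd(R, nu = 0, nv = 0)$d
    if (sv[length(sv)] > 1e-6 * sv[1]) break
  }
  SpectralBasis(R, seq(2800, by = 10, length.out = nColors),
                paste0("C", seq_len(nConstituents)))
}

# disk phantom on an L x W grid, value inside radius r around center
diskImage <- function(L, W, r, center = c(L / 2, W / 2), value = 1,
                      noiseSigma = 0) {
  rows <- matrix(seq_len(L), L, W)
  cols <- matrix(seq_len(W), L, W, byrow = TRUE)
  img <- ifelse((rows - center[1])^2 + (cols - center[2])^2 <= r^2, value, 0)
  if (noiseSigma > 0) img <- img + rnorm(L * W, 0, noiseSigma)
  img
}

# Literal sequential implementation of the displacement rules: every
# actuation displaces all particles within the open window by one step in
# its direction, with saturating side states; side at exit -> collection.
# Directions alternate globally starting +1. Independent of the parity
# closed form used by the package.
bruteDestinations <- function(times, decisions, tau,
                              variant = "alternating") {
  at <- times[decisions]
  dirs <- rep_len(c(1, -1), length(at))
  state <- numeric(length(times))
  for (j in seq_along(at)) {
    hit <- abs(times - at[j]) < tau
    s <- state[hit]
    state[hit] <- ifelse(s == 0, dirs[j], ifelse(s == dirs[j], s, 0))
  }
  if (variant == "self-priority") {
    for (i in which(decisions)) {
      later <- which(at >= times[i] & at < times[i] + tau)
      s <- 0
      for (j in later) s <- if (s == 0) dirs[j] else
        if (s == dirs[j]) s else 0
      state[i] <- s
    }
  }
  ifelse(state != 0, "collection", "waste")
}

# single-specimen ground truth placed at a given time
oneSpecimen <- function(time_s, radius = 3, offset = 0, species = "PMMA",
                        isTarget = TRUE, duration = 0.005, rate = 50,
                        r = 0.6) {
  ev <- data.frame(event_id = 0L, time_s = time_s, species = species,
                   is_target = isTarget, radius_um = radius,
                   lateral_offset_um = offset, stringsAsFactors = FALSE)
  new("GroundTruth", events = ev, rate = rate, targetFraction = r,
      duration = duration)
}
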
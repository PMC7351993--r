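# Linear spectral decomposition of multicolor SRS measurements.
#
# Each pixel measurement d (one value per acquisition color) is modeled as
# d = S c, where column i of S is the response spectrum of constituent i
# sampled at the acquisition wavenumbers and c are the constituent
# concentrations. Unmixing multiplies by the Moore-Penrose pseudo-inverse of
# S, i.e. returns the minimum-norm least-squares solution; when S is square
# and invertible this is the exact inverse.

# Moore-Penrose pseudo-inverse via SVD; singular values below
# tol * max(singular value) are treated as zero.
.pinv <- function(A, tol = .rankTol) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Build a spectral basis by sampling constituent spectra at selected
#' wavenumbers
#'
#' Column i of the returned basis is the spectrum of constituent i, linearly
#' interpolated between its tabulated points at each selected wavenumber.
#'
#' @param spectra data.frame of tabulated spectra: the first column is the
#'   wavenumber (cm^-1), every further column one constituent's response.
#' @param selectedWavenumbers acquisition wavenumbers, cm^-1; each must lie
#'   within the tabulated range, and there must be at least as many as
#'   constituents.
#' @return A \linkS4class{SpectralBasis}; errors on a rank-deficient result.
#' @examples
#' basis <- buildBasis(referenceSpectra(), c(2899, 2954, 3006, 3034))
#' @export
buildBasis <- function(spectra, selectedWavenumbers) {
  spectra <- as.data.frame(spectra)
  if (ncol(spectra) < 2)
    stop("spectra must have a wavenumber column plus >= 1 constituent column")
  wn <- spectra[[1]]
  cons <- names(spectra)[-1]
  if (length(selectedWavenumbers) < length(cons))
    stop("need at least as many selected wavenumbers as constituents")
  if (any(selectedWavenumbers < min(wn) | selectedWavenumbers > max(wn)))
    stop("selected wavenumber outside the tabulated spectral range")
  R <- vapply(cons, function(nm)
    approx(wn, spectra[[nm]], xout = selectedWavenumbers)$y,
    numeric(length(selectedWavenumbers)))
  SpectralBasis(matrix(R, nrow = length(selectedWavenumbers),
                       dimnames = list(NULL, cons)),
                selectedWavenumbers, cons)
}

#' Unmix one pixel measurement into constituent concentrations
#'
#' Returns the minimum-norm least-squares solution of
#' \code{responses(basis) \%*\% c = d} via the pseudo-inverse. Negative
#' coefficients are retained (the decomposition is linear); clip at display
#' or feature stages if needed.
#'
#' @param d numeric vector of per-color intensities, length
#'   \code{nColors(basis)}.
#' @param basis a \linkS4class{SpectralBasis}.
#' @return Named numeric vector of concentrations, one per constituent.
#' @examples
#' b <- SpectralBasis(diag(2), c(2900, 2950), c("A", "B"))
#' unmix(c(3, 5), b)  # c(A = 3, B = 5)
#' @export
unmix <- function(d, basis) {
  stopifnot(is(basis, "SpectralBasis"))
  if (length(d) != nColors(basis))
    stop("measurement length does not match the number of basis colors")
  if (!all(is.finite(d))) stop("non-finite measurement")
  out <- drop(.pinv(basis@responses) %*% d)
  names(out) <- basis@constituentNames
  out
}

#' Unmix a multicolor image into per-constituent concentration images
#'
#' Applies \code{\link{unmix}} at every pixel of a lines x lateral x colors
#' array; the spatial grid is unchanged.
#'
#' @param image 3-D numeric array, lines x lateral x colors.
#' @param basis a \linkS4class{SpectralBasis}.
#' @return 3-D array, lines x lateral x constituents, with constituent names
#'   on the third dimension.
#' @export
unmixImage <- function(image, basis) {
  stopifnot(is(basis, "SpectralBasis"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != nColors(basis))
    stop("image color axis does not match the basis")
  P <- .pinv(basis@responses)                     # k x n_colors
  flat <- matrix(image, nrow = d[1] * d[2])       # pixels x colors
  out <- flat %*% t(P)
  array(out, dim = c(d[1], d[2], nConstituents(basis)),
        dimnames = list(NULL, NULL, basis@constituentNames))
}

#' Synthetic polystyrene / PMMA reference spectra
#'
#' Two-peak Gaussian toy spectra over the C-H stretch region, shaped like the
#' SRS spectra of polystyrene (aliphatic peak near 2904 cm^-1, aromatic peak
#' near 3054 cm^-1) and poly(methyl methacrylate) (O-CH3 peak near
#' 2954 cm^-1 with a broad high-wavenumber shoulder). They are synthetic
#' stand-ins for measured spectra, adequate for exercising basis construction
#' and unmixing.
#'
#' @param range wavenumber range, cm^-1.
#' @param step tabulation step, cm^-1.
#' @return data.frame with columns wavenumber_cm1, PS, PMMA.
#' @export
referenceSpectra <- function(range = c(2830, 3100), step = 1) {
  w <- seq(range[1], range[2], by = step)
  g <- function(mu, sig) exp(-((w - mu) / sig)^2)
  data.frame(
    wavenumber_cm1 = w,
    PS = 0.95 * g(2904, 20) + 1.0 * g(3054, 18),
    PMMA = 1.0 * g(2954, 22) + 0.45 * g(2998, 30)
  )
}

#' Default four-color PS/PMMA basis
#'
#' \code{\link{referenceSpectra}} sampled at the four acquisition wavenumbers
#' 2899, 2954, 3006 and 3034 cm^-1.
#'
#' @return A 4 x 2 \linkS4class{SpectralBasis}.
#' @export
defaultBasis <- function() {
  buildBasis(referenceSpectra(), c(2899, 2954, 3006, 3034))
}

#' Read and write tabulated spectra as CSV
#'
#' The CSV layout is one wavenumber column (first) plus one column per
#' constituent, as consumed by \code{\link{buildBasis}}.
#'
#' @param path file path.
#' @param spectra data.frame as returned by \code{\link{referenceSpectra}}.
#' @return \code{readSpectra}: the spectra data.frame.
#' @export
readSpectra <- function(path) read.csv(path, check.names = FALSE)

#' @rdname readSpectra
#' @export
writeSpectra <- function(spectra, path)
  write.csv(spectra, path, row.names = FALSE)

#' Serialize a spectral basis to/from JSON
#'
#' @param basis a \linkS4class{SpectralBasis}.
#' @param path file path.
#' @return \code{readBasis}: the reconstructed \linkS4class{SpectralBasis}.
#' @export
writeBasis <- function(basis, path) {
  stopifnot(is(basis, "SpectralBasis"))
  jsonlite::write_json(
    list(constituent_names = basis@constituentNames,
         wavenumbers_cm1 = basis@wavenumbers,
         responses = basis@responses),
    path, auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeBasis
#' @export
readBasis <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  SpectralBasis(matrix(x$responses, nrow = length(x$wavenumbers_cm1),
                       byrow = FALSE,
                       dimnames = list(NULL, x$constituent_names)),
                x$wavenumbers_cm1, x$constituent_names)
}
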
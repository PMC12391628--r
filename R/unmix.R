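#' Extract a reference spectrum from a labeled region of interest
#'
#' Averages the volume's per-wavelength intensity over the voxels carrying
#' the given label and normalizes the mean spectrum to unit maximum. This
#' is how component dictionaries are built from labeled acquisitions
#' (skin for melanin, air-bubble regions for noise, phantom test tubes for
#' the nanorod-laden cells).
#'
#' @param volume A [pa_volume].
#' @param roi Integer label array with the volume's `(slice, row, col)`
#'   grid; 0 is background.
#' @param label Label to extract (> 0).
#' @return A [pa_spectrum] with unit maximum.
#' @export
extract_reference_spectrum <- function(volume, roi, label) {
  stopifnot(inherits(volume, "pa_volume"))
  check_roi(roi, dim(volume$data)[-1L])
  sel <- roi == label
  if (!any(sel)) stop("label ", label, " is absent from the ROI mask")
  nwl <- dim(volume$data)[1L]
  means <- vapply(seq_len(nwl), function(w) {
    plane <- volume$data[w, , , ]
    mean(plane[sel])
  }, numeric(1))
  if (max(means) <= 0)
    stop("mean spectrum over label ", label,
         " is all zero and cannot be normalized")
  pa_spectrum(volume$wavelengths, means / max(means))
}

check_roi <- function(roi, grid) {
  if (!is.array(roi) || length(dim(roi)) != 3L)
    stop("ROI mask must be a 3D array")
  if (!all(dim(roi) == grid))
    stop("ROI mask grid ", paste(dim(roi), collapse = "x"),
         " does not match the volume grid ", paste(grid, collapse = "x"))
  if (any(roi < 0) || any(roi != round(roi)))
    stop("ROI labels must be non-negative integers")
  invisible(roi)
}

#' Unmix a single spectrum into non-negative component abundances
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_{a \ge 0} \| s - R a \|_2} for the spectrum s against the
#' reference dictionary R (Lawson–Hanson active-set algorithm). When the
#' unconstrained least-squares solution is element-wise non-negative the
#' result equals it.
#'
#' @param spectrum A [pa_spectrum] on the reference set's wavelength grid.
#' @param refset A `ref_spectra` dictionary.
#' @return List with `abundances` (named, >= 0) and `residual` (the
#'   minimized Euclidean norm).
#' @export
unmix_voxel <- function(spectrum, refset) {
  stopifnot(inherits(spectrum, "pa_spectrum"), inherits(refset, "ref_spectra"))
  if (!isTRUE(all.equal(spectrum$wavelengths, refset$wavelengths)))
    stop("wavelength grid mismatch between spectrum and reference set")
  a <- nnls_fit(refset$spectra, spectrum$values)
  names(a$x) <- refset$components
  list(abundances = a$x, residual = a$residual)
}

# NNLS core shared by unmix_voxel / unmix_volume. The residual is
# recomputed directly as ||d - C a||_2.
nnls_fit <- function(C, d) {
  if (all(d == 0))
    return(list(x = numeric(ncol(C)), residual = 0))
  sol <- pracma::lsqnonneg(C, d)
  x <- pmax(sol$x, 0)
  list(x = x, residual = sqrt(sum((d - C %*% x)^2)))
}

#' Unmix every voxel of a multispectral volume
#'
#' Voxel-wise application of [unmix_voxel]; voxels are independent, so
#' traversal order does not affect the result.
#'
#' @param volume A [pa_volume].
#' @param refset A `ref_spectra` dictionary on the same wavelength grid.
#' @return A [component_map] with one abundance array per component and
#'   the per-voxel residual norm.
#' @export
unmix_volume <- function(volume, refset) {
  stopifnot(inherits(volume, "pa_volume"), inherits(refset, "ref_spectra"))
  if (!isTRUE(all.equal(volume$wavelengths, refset$wavelengths)))
    stop("wavelength grid mismatch between volume and reference set")
  grid <- dim(volume$data)[-1L]
  nwl <- dim(volume$data)[1L]
  ncomp <- length(refset$components)
  smat <- matrix(volume$data, nrow = nwl)        # wavelengths x voxels
  amat <- matrix(0, nrow = ncomp, ncol = ncol(smat))
  resid <- numeric(ncol(smat))
  nonzero <- which(colSums(smat) > 0)
  for (j in nonzero) {
    f <- nnls_fit(refset$spectra, smat[, j])
    amat[, j] <- f$x
    resid[j] <- f$residual
  }
  component_map(array(amat, dim = c(ncomp, grid)),
                array(resid, dim = grid), refset$components)
}

#' Relative spectral difference between two normalized spectra
#'
#' Both spectra are normalized to unit maximum, then the per-wavelength
#' relative difference `(a_norm - b_norm) / b_norm` is returned. The
#' normalization removes global scale, so the statistic highlights
#' wavelength regions where the two spectral shapes diverge.
#'
#' @param a,b [pa_spectrum] objects on a common wavelength grid; `b` must
#'   be nonzero at every wavelength after normalization.
#' @return Numeric vector of per-wavelength relative differences.
#' @export
relative_spectral_difference <- function(a, b) {
  stopifnot(inherits(a, "pa_spectrum"), inherits(b, "pa_spectrum"))
  if (!isTRUE(all.equal(a$wavelengths, b$wavelengths)))
    stop("wavelength grid mismatch between the two spectra")
  if (max(a$values) <= 0 || max(b$values) <= 0)
    stop("cannot normalize an all-zero spectrum")
  an <- a$values / max(a$values)
  bn <- b$values / max(b$values)
  if (any(bn == 0))
    stop("reference spectrum is zero at ",
         sum(bn == 0), " wavelength(s); relative difference undefined")
  (an - bn) / bn
}
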
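#' Multispectral photoacoustic volume
#'
#' Container for a multiwavelength 3D acquisition: a 4D intensity array
#' indexed `(wavelength, slice, row, col)` plus the wavelength grid and
#' voxel spacing in micrometers.
#'
#' @param data 4D numeric array `(wavelength, slice, row, col)`, >= 0.
#' @param wavelengths Wavelengths in nm, length `dim(data)[1]`.
#' @param spacing Voxel spacing `(slice, row, col)` in µm.
#' @return A `pa_volume` object.
#' @export
pa_volume <- function(data, wavelengths, spacing = c(203, 75, 75)) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  check_wavelengths(wavelengths)
  if (dim(data)[1L] != length(wavelengths))
    stop("wavelength count (", length(wavelengths),
         ") does not match first array dimension (", dim(data)[1L], ")")
  if (any(data < 0)) stop("volume intensities must be >= 0")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 spacing = as.numeric(spacing)), class = "pa_volume")
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<pa_volume> ", d[1], " wavelengths x ", d[2], "x", d[3], "x", d[4],
      " voxels; spacing ", paste(x$spacing, collapse = "x"), " um\n",
      sep = "")
  invisible(x)
}

#' Per-component abundance maps from spectral unmixing
#'
#' @param abundance 4D array `(component, slice, row, col)`, >= 0.
#' @param residual 3D array `(slice, row, col)` of per-voxel residual
#'   norms, >= 0.
#' @param components Component names, length `dim(abundance)[1]`.
#' @return A `component_map` object.
#' @export
component_map <- function(abundance, residual, components) {
  stopifnot(is.array(abundance), length(dim(abundance)) == 4L,
            is.array(residual), length(dim(residual)) == 3L,
            dim(abundance)[1L] == length(components),
            all(dim(abundance)[-1L] == dim(residual)))
  if (any(abundance < 0)) stop("abundances must be >= 0")
  if (any(residual < 0)) stop("residuals must be >= 0")
  structure(list(abundance = abundance, residual = residual,
                 components = components), class = "component_map")
}

#' @export
print.component_map <- function(x, ...) {
  d <- dim(x$abundance)
  cat("<component_map> ", d[1], " components x ", d[2], "x", d[3], "x",
      d[4], " voxels\n  components: ",
      paste(x$components, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Axis-aligned box region (voxel index ranges, 1-based inclusive)
#' @param slices,rows,cols Length-2 integer ranges.
#' @export
region_box <- function(slices, rows, cols) {
  structure(list(kind = "box", slices = slices, rows = rows, cols = cols),
            class = "phantom_region")
}

#' Spherical region (voxel units)
#' @param center `(slice, row, col)` center.
#' @param radius Radius in voxels.
#' @export
region_sphere <- function(center, radius) {
  structure(list(kind = "sphere", center = center, radius = radius),
            class = "phantom_region")
}

region_voxel_mask <- function(region, grid) {
  m <- array(FALSE, dim = grid)
  if (region$kind == "box") {
    r <- region
    if (r$slices[1] < 1 || r$slices[2] > grid[1] ||
        r$rows[1] < 1 || r$rows[2] > grid[2] ||
        r$cols[1] < 1 || r$cols[2] > grid[3])
      stop("box region extends outside the phantom grid")
    m[r$slices[1]:r$slices[2], r$rows[1]:r$rows[2],
      r$cols[1]:r$cols[2]] <- TRUE
  } else {
    ctr <- region$center
    if (any(ctr < 1) || any(ctr > grid))
      stop("sphere center lies outside the phantom grid")
    idx <- expand.grid(s = seq_len(grid[1]), r = seq_len(grid[2]),
                       c = seq_len(grid[3]))
    d2 <- (idx$s - ctr[1])^2 + (idx$r - ctr[2])^2 + (idx$c - ctr[3])^2
    m[as.matrix(idx)] <- d2 <= region$radius^2
  }
  m
}

#' Phantom simulation configuration
#'
#' @param grid `(slices, rows, cols)` voxel counts.
#' @param spacing `(slice, row, col)` voxel spacing in µm; the default
#'   slice step is the 203 µm acquisition step.
#' @param wavelengths Acquisition wavelengths in nm (default the six
#'   in vivo wavelengths).
#' @param geometry List of elements `list(component =, region =, level =)`
#'   placing abundance `level` of `component` inside a [region_box] /
#'   [region_sphere]. Overlapping regions add.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(grid = c(16, 32, 32),
                           spacing = c(203, 75, 75),
                           wavelengths = wavelengths_in_vivo(),
                           geometry = list(),
                           noise_sd = 0, seed = 1L) {
  stopifnot(length(grid) == 3L, all(grid >= 1),
            length(spacing) == 3L, all(spacing > 0))
  check_wavelengths(wavelengths)
  if (noise_sd < 0) stop("noise sd must be >= 0")
  for (g in geometry) {
    stopifnot(is.character(g$component), inherits(g$region, "phantom_region"))
    if (is.null(g$level) || !is.numeric(g$level) || g$level < 0)
      stop("every geometry entry needs an abundance level >= 0")
  }
  structure(list(grid = as.integer(grid), spacing = as.numeric(spacing),
                 wavelengths = as.numeric(wavelengths), geometry = geometry,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Simulate a multispectral phantom volume with known ground truth
#'
#' Applies the linear mixing forward model: the voxel intensity at
#' wavelength \eqn{\lambda} is \eqn{\sum_c a_c S_c(\lambda)} plus Gaussian
#' noise, with negative post-noise intensities clipped to zero (PA
#' amplitudes are non-negative). Overlapping geometry regions add their
#' abundances, matching the linearity of the model.
#'
#' @param refset [make_reference_spectra] output; its wavelength grid must
#'   equal the config's.
#' @param config A [phantom_config].
#' @return List with `volume` (a [pa_volume]) and `truth` (a
#'   [component_map] of the generating abundances, residual 0).
#' @export
simulate_phantom_volume <- function(refset, config) {
  stopifnot(inherits(refset, "ref_spectra"), inherits(config, "phantom_config"))
  if (!isTRUE(all.equal(refset$wavelengths, config$wavelengths)))
    stop("wavelength mismatch between reference set and phantom config")
  grid <- config$grid
  ncomp <- length(refset$components)
  abundance <- array(0, dim = c(ncomp, grid))
  for (g in config$geometry) {
    k <- match(g$component, refset$components)
    if (is.na(k))
      stop("geometry component '", g$component,
           "' is not in the reference set")
    m <- region_voxel_mask(g$region, grid)
    plane <- abundance[k, , , , drop = FALSE]
    plane[1, , , ][m] <- plane[1, , , ][m] + g$level
    abundance[k, , , ] <- plane[1, , , ]
  }
  nwl <- length(config$wavelengths)
  nvox <- prod(grid)
  amat <- matrix(abundance, nrow = ncomp)        # components x voxels
  clean <- refset$spectra %*% amat               # wavelengths x voxels
  set.seed(config$seed)
  noisy <- clean
  if (config$noise_sd > 0)
    noisy <- clean + stats::rnorm(nwl * nvox, sd = config$noise_sd)
  noisy[noisy < 0] <- 0
  vol <- pa_volume(array(noisy, dim = c(nwl, grid)),
                   config$wavelengths, config$spacing)
  truth <- component_map(abundance, array(0, dim = grid), refset$components)
  list(volume = vol, truth = truth)
}
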
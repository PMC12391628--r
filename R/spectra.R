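#' Spectral shape configuration for a phantom component
#'
#' Describes the parametric shape of one component's absorption spectrum.
#' Four shape families are supported: `"lorentzian"` (a peak with a given
#' center and full width at half maximum), `"monotone"` (log-linear, i.e.
#' geometric, interpolation between positive anchor points — strictly
#' monotone whenever the anchors are), `"flat"` (constant), and
#' `"tabulated"` (piecewise-linear interpolation of arbitrary non-negative
#' anchors, clamped to the end values outside their range).
#'
#' @param component Component name, one of `"hbo2"`, `"hb"`, `"melanin"`,
#'   `"aunr_cell"`, `"noise"`.
#' @param family Shape family.
#' @param center Peak center in nm (lorentzian only); must lie in
#'   \[600, 1100\] nm.
#' @param width Full width at half maximum in nm (lorentzian only); > 0.
#' @param anchors Two-column matrix or data.frame of
#'   `(wavelength_nm, value)` anchor points (monotone / tabulated).
#' @return An object of class `spectrum_config`.
#' @examples
#' spectrum_config("aunr_cell", "lorentzian", center = 900, width = 60)
#' @export
spectrum_config <- function(component,
                            family = c("lorentzian", "monotone", "flat",
                                       "tabulated"),
                            center = NULL, width = NULL, anchors = NULL) {
  family <- match.arg(family)
  known <- c("hbo2", "hb", "melanin", "aunr_cell", "noise")
  if (!is.character(component) || length(component) != 1L ||
      !component %in% known) {
    stop("unknown component name: ", deparse(substitute(component)),
         " (expected one of ", paste(known, collapse = ", "), ")")
  }
  if (family == "lorentzian") {
    stopifnot(is.numeric(center), length(center) == 1L,
              is.numeric(width), length(width) == 1L)
    if (center < 600 || center > 1100)
      stop("peak center must lie within [600, 1100] nm, got ", center)
    if (width <= 0) stop("width must be > 0, got ", width)
  }
  if (family %in% c("monotone", "tabulated")) {
    anchors <- as.matrix(anchors)
    if (is.null(anchors) || nrow(anchors) < 2L || ncol(anchors) != 2L)
      stop("family '", family, "' needs >= 2 (wavelength, value) anchors")
    if (any(anchors[, 2L] < 0))
      stop("tabulated anchor values must be >= 0")
    if (family == "monotone" && any(anchors[, 2L] <= 0))
      stop("monotone anchors must be > 0 (geometric interpolation)")
    if (is.unsorted(anchors[, 1L], strictly = TRUE))
      stop("anchor wavelengths must be strictly increasing")
  }
  structure(list(component = component, family = family, center = center,
                 width = width, anchors = anchors),
            class = "spectrum_config")
}

#' Default spectral shapes for the five phantom components
#'
#' Parametric stand-ins with the qualitative features that make the
#' components separable over 680–970 nm: oxygenated hemoglobin rises
#' monotonically into the near infrared, deoxygenated hemoglobin has a
#' broad peak near 756 nm, melanin decays monotonically, the
#' nanorod-laden-cell spectrum is a Lorentzian centered at 900 nm (the
#' red-shifted longitudinal plasmon of intracellular aggregates), and
#' noise is spectrally flat.
#'
#' @param aunr_center Peak center of the nanorod-laden-cell spectrum (nm).
#' @param aunr_width Its full width at half maximum (nm).
#' @return Named list of [spectrum_config] objects.
#' @export
default_spectrum_configs <- function(aunr_center = 900, aunr_width = 60) {
  list(
    hbo2 = spectrum_config("hbo2", "monotone",
                           anchors = cbind(c(600, 1100), c(0.3, 1))),
    hb = spectrum_config("hb", "lorentzian", center = 756, width = 120),
    melanin = spectrum_config("melanin", "monotone",
                              anchors = cbind(c(600, 1100), c(1, 0.08))),
    aunr_cell = spectrum_config("aunr_cell", "lorentzian",
                                center = aunr_center, width = aunr_width),
    noise = spectrum_config("noise", "flat")
  )
}

# Evaluate one spectrum_config on a wavelength grid (no normalization).
eval_spectrum_config <- function(cfg, wavelengths) {
  switch(cfg$family,
    flat = rep(1, length(wavelengths)),
    lorentzian = {
      gamma <- cfg$width / 2  # FWHM -> half width at half maximum
      1 / (1 + ((wavelengths - cfg$center) / gamma)^2)
    },
    monotone = {
      a <- cfg$anchors
      lv <- stats::approx(a[, 1L], log(a[, 2L]), xout = wavelengths,
                          rule = 2)$y
      exp(lv)
    },
    tabulated = {
      a <- cfg$anchors
      stats::approx(a[, 1L], a[, 2L], xout = wavelengths, rule = 2)$y
    }
  )
}

#' Build a reference spectra set on a wavelength grid
#'
#' Evaluates each component's shape model at the acquisition wavelengths
#' and normalizes every spectrum to unit maximum, yielding the dictionary
#' that spectral unmixing solves against. Unit-max normalization makes the
#' unmixed abundances carry the intensity units of the acquisition.
#'
#' @param wavelengths Strictly increasing wavelengths in nm, non-empty.
#' @param configs List of [spectrum_config] objects (names are taken from
#'   the configs themselves).
#' @return A `ref_spectra` object: list with `wavelengths`, `components`,
#'   and `spectra` (matrix, one unit-max column per component).
#' @examples
#' rs <- make_reference_spectra(c(680, 730, 800, 924, 930, 968),
#'                              default_spectrum_configs())
#' apply(rs$spectra, 2, max)  # all exactly 1
#' @export
make_reference_spectra <- function(wavelengths, configs) {
  check_wavelengths(wavelengths)
  if (length(configs) == 0L) stop("no component configs supplied")
  comps <- unname(vapply(configs, function(c) c$component, character(1)))
  if (anyDuplicated(comps)) stop("duplicate component names in configs")
  spectra <- vapply(configs, function(cfg) {
    v <- eval_spectrum_config(cfg, wavelengths)
    m <- max(v)
    if (m <= 0) stop("component '", cfg$component,
                     "' evaluates to an all-zero spectrum on this grid")
    v / m
  }, numeric(length(wavelengths)))
  spectra <- matrix(spectra, nrow = length(wavelengths),
                    dimnames = list(NULL, comps))
  new_ref_spectra(wavelengths, comps, spectra)
}

#' Construct a reference spectra set from a matrix
#'
#' Lower-level constructor for dictionaries that do not come from shape
#' models (e.g. spectra extracted from labeled acquisitions). Columns
#' are unit-max normalized.
#'
#' @param wavelengths Strictly increasing wavelengths (nm).
#' @param components Unique component names, one per column.
#' @param spectra Non-negative matrix, one column per component.
#' @return A `ref_spectra` object.
#' @export
ref_spectra <- function(wavelengths, components, spectra) {
  check_wavelengths(wavelengths)
  if (anyDuplicated(components)) stop("component names must be unique")
  new_ref_spectra(wavelengths, components, as.matrix(spectra))
}

new_ref_spectra <- function(wavelengths, components, spectra) {
  stopifnot(nrow(spectra) == length(wavelengths),
            ncol(spectra) == length(components))
  if (any(spectra < 0)) stop("reference spectra must be non-negative")
  mx <- apply(spectra, 2L, max)
  if (any(mx <= 0)) stop("reference spectra set contains an all-zero column")
  spectra <- sweep(spectra, 2L, mx, "/")
  colnames(spectra) <- components
  structure(list(wavelengths = as.numeric(wavelengths),
                 components = components, spectra = spectra),
            class = "ref_spectra")
}

#' @export
print.ref_spectra <- function(x, ...) {
  cat("<ref_spectra> ", length(x$components), " components over ",
      length(x$wavelengths), " wavelengths [",
      min(x$wavelengths), "-", max(x$wavelengths), " nm]\n", sep = "")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  invisible(x)
}

#' A single spectrum
#'
#' @param wavelengths Strictly increasing wavelengths in nm.
#' @param values Non-negative intensities (a.u.), same length.
#' @return A `pa_spectrum` object.
#' @export
pa_spectrum <- function(wavelengths, values) {
  check_wavelengths(wavelengths)
  stopifnot(length(values) == length(wavelengths))
  if (any(!is.finite(values)) || any(values < 0))
    stop("spectrum values must be finite and >= 0")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)), class = "pa_spectrum")
}

check_wavelengths <- function(wavelengths) {
  if (length(wavelengths) == 0L) stop("wavelength list is empty")
  if (any(!is.finite(wavelengths)))
    stop("wavelengths must be finite")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (any(wavelengths < 600 | wavelengths > 1100))
    stop("wavelengths must lie within [600, 1100] nm")
  invisible(wavelengths)
}

#' Default in vivo acquisition wavelengths (nm)
#' @export
wavelengths_in_vivo <- function() c(680, 730, 800, 924, 930, 968)

#' Default in vitro spectral sweep (nm)
#' @param step Step in nm.
#' @export
wavelengths_in_vitro <- function(step = 5) seq(680, 970, by = step)
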
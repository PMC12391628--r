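# Readers/writers for pipeline artifacts: TIFF rasters with JSON
# sidecars, CSV tables, reference-spectra CSV, run manifests.
#
# TIFF planes are stored as 32-bit float scaled into [0, 1]; the scale
# factor lives in the JSON sidecar, so round trips are exact to float32
# precision.

write_planes_tiff <- function(arr3d, path, scale) {
  planes <- lapply(seq_len(dim(arr3d)[1L]), function(s)
    arr3d[s, , , drop = TRUE] / scale)
  planes <- lapply(planes, function(p) matrix(p, nrow = dim(arr3d)[2L]))
  tiff::writeTIFF(planes, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

read_planes_tiff <- function(path, scale) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  arr <- array(0, dim = c(length(planes), dim(planes[[1L]])))
  for (s in seq_along(planes)) arr[s, , ] <- planes[[s]]
  arr * scale
}

#' Write a multispectral volume as per-wavelength TIFF stacks
#'
#' One multi-page 3D TIFF per wavelength, named `<stem>_w<nm>.tif`, plus
#' a JSON sidecar `<stem>.json` recording wavelengths, voxel spacing
#' (µm), the intensity scale, and optionally seed and config hash.
#'
#' @param volume A [pa_volume].
#' @param stem Output path stem (directories are created).
#' @param seed,config_hash Optional provenance recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_volume <- function(volume, stem, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(volume, "pa_volume"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  scale <- max(volume$data, 1e-12)
  for (w in seq_along(volume$wavelengths)) {
    write_planes_tiff(array(volume$data[w, , , ],
                            dim = dim(volume$data)[-1L]),
                      sprintf("%s_w%d.tif", stem, volume$wavelengths[w]),
                      scale)
  }
  sidecar <- list(kind = "pa_volume",
                  wavelengths_nm = volume$wavelengths,
                  spacing_um = volume$spacing,
                  intensity_scale = scale,
                  seed = seed, config_hash = config_hash)
  jsonlite::write_json(sidecar, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paste0(stem, ".json"))
}

#' Read a multispectral volume written by [write_volume]
#'
#' @param stem Path stem used at write time.
#' @return A [pa_volume] with wavelengths in ascending order.
#' @export
read_volume <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path))
    stop("missing volume sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  wl <- sort(as.numeric(meta$wavelengths_nm))
  scale <- as.numeric(meta$intensity_scale)
  planes <- lapply(wl, function(w) {
    p <- sprintf("%s_w%d.tif", stem, w)
    if (!file.exists(p)) stop("missing wavelength file: ", p)
    read_planes_tiff(p, scale)
  })
  grid <- dim(planes[[1L]])
  arr <- array(0, dim = c(length(wl), grid))
  for (w in seq_along(wl)) {
    if (!all(dim(planes[[w]]) == grid))
      stop("wavelength plane count / grid mismatch in ", stem)
    arr[w, , , ] <- planes[[w]]
  }
  if (any(arr < 0)) stop("negative intensities on read from ", stem)
  pa_volume(arr, wl, as.numeric(meta$spacing_um))
}

#' Write a component map as per-component TIFF stacks
#'
#' One 3D TIFF per component (`<stem>_<component>.tif`) plus
#' `<stem>_residual.tif` and a JSON sidecar.
#'
#' @param cmap A [component_map].
#' @param stem Output path stem.
#' @return Sidecar path, invisibly.
#' @export
write_component_map <- function(cmap, stem) {
  stopifnot(inherits(cmap, "component_map"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  scale <- max(cmap$abundance, cmap$residual, 1e-12)
  for (k in seq_along(cmap$components)) {
    write_planes_tiff(array(cmap$abundance[k, , , ],
                            dim = dim(cmap$abundance)[-1L]),
                      sprintf("%s_%s.tif", stem, cmap$components[k]),
                      scale)
  }
  write_planes_tiff(cmap$residual, sprintf("%s_residual.tif", stem), scale)
  jsonlite::write_json(list(kind = "component_map",
                            components = cmap$components,
                            intensity_scale = scale),
                       paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read a component map written by [write_component_map]
#' @param stem Path stem used at write time.
#' @return A [component_map].
#' @export
read_component_map <- function(stem) {
  sidecar_path <- paste0(stem, ".json")
  if (!file.exists(sidecar_path))
    stop("missing component map sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  scale <- as.numeric(meta$intensity_scale)
  comps <- as.character(meta$components)
  maps <- lapply(comps, function(cp)
    read_planes_tiff(sprintf("%s_%s.tif", stem, cp), scale))
  resid <- read_planes_tiff(sprintf("%s_residual.tif", stem), scale)
  grid <- dim(resid)
  arr <- array(0, dim = c(length(comps), grid))
  for (k in seq_along(comps)) arr[k, , , ] <- maps[[k]]
  component_map(pmax(arr, 0), pmax(resid, 0), comps)
}

#' Write / read an integer ROI label mask as a TIFF stack
#'
#' Labels are stored scaled into \[0, 1\] (scale in the sidecar) and
#' rounded back to integers on read; 0 is background.
#'
#' @param mask 3D integer label array.
#' @param path Output TIFF path (sidecar `<path>.json` is added).
#' @return `write_mask`: the path, invisibly. `read_mask`: the label
#'   array.
#' @export
write_mask <- function(mask, path) {
  check_roi(mask, dim(mask))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  scale <- max(mask, 1)
  write_planes_tiff(mask, path, scale)
  jsonlite::write_json(list(kind = "roi_mask", label_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing mask sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  arr <- read_planes_tiff(path, as.numeric(meta$label_scale))
  round(arr)
}

#' Validate a longitudinal measurement table
#'
#' Checks the column set, the group and time-label enumerations,
#' uniqueness of `(tumor_id, time_label)`, and value finiteness.
#'
#' @param table Data frame with columns `tumor_id`, `group`,
#'   `time_label`, `day`, `pa_value`.
#' @param require_both_groups Require at least one row per group.
#' @return The validated table (invisibly unchanged).
#' @export
validate_measurement_table <- function(table,
                                       require_both_groups = FALSE) {
  need <- c("tumor_id", "group", "time_label", "day", "pa_value")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("measurement table lacks column(s): ",
         paste(miss, collapse = ", "))
  bad_grp <- setdiff(unique(table$group), c("treated", "control"))
  if (length(bad_grp) > 0L)
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         " (expected 'treated' or 'control')")
  bad_t <- setdiff(unique(table$time_label), paste0("T", 0:9))
  if (length(bad_t) > 0L)
    stop("unknown time label(s): ", paste(bad_t, collapse = ", "))
  key <- paste(table$tumor_id, table$time_label)
  if (anyDuplicated(key))
    stop("duplicate (tumor_id, time_label) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (nrow(table) > 0 && any(!is.finite(table$pa_value)))
    stop("non-finite pa_value entries")
  if (require_both_groups &&
      !all(c("treated", "control") %in% table$group))
    stop("measurement table must contain both groups")
  table
}

#' Write / read a measurement table as CSV
#'
#' Column order `tumor_id,group,time_label,day,pa_value`
#' (plus `pa_value_norm` if present) is preserved across round trips;
#' labels are validated on both directions.
#'
#' @param table Measurement table.
#' @param path CSV path.
#' @return `write_measurement_table`: path, invisibly.
#'   `read_measurement_table`: the validated table.
#' @export
write_measurement_table <- function(table, path) {
  table <- validate_measurement_table(table)
  cols <- c("tumor_id", "group", "time_label", "day", "pa_value")
  if ("pa_value_norm" %in% names(table)) cols <- c(cols, "pa_value_norm")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("missing table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(tumor_id = "character"))
  validate_measurement_table(tab)
}

#' Write / read a reference spectra set as CSV
#'
#' First column `wavelength_nm`, then one column per component.
#'
#' @param refset A `ref_spectra` object.
#' @param path CSV path.
#' @return `write_reference_spectra`: path, invisibly.
#'   `read_reference_spectra`: a `ref_spectra`.
#' @export
write_reference_spectra <- function(refset, path) {
  stopifnot(inherits(refset, "ref_spectra"))
  df <- data.frame(wavelength_nm = refset$wavelengths)
  for (cp in refset$components) df[[cp]] <- refset$spectra[, cp]
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_spectra
#' @export
read_reference_spectra <- function(path) {
  if (!file.exists(path)) stop("missing reference spectra CSV: ", path)
  df <- utils::read.csv(path)
  if (names(df)[1L] != "wavelength_nm")
    stop("first column of a reference spectra CSV must be wavelength_nm")
  comps <- names(df)[-1L]
  if (length(comps) == 0L) stop("no component columns in ", path)
  new_ref_spectra(df$wavelength_nm, comps,
                  as.matrix(df[, comps, drop = FALSE]))
}

#' Stable hash of a configuration object
#'
#' md5 of the canonical JSON encoding with recursively sorted keys, so
#' re-ordering keys does not change the hash.
#'
#' @param config Any list-like configuration.
#' @return Hex md5 string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x)) && any(names(x) != ""))
        x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  js <- jsonlite::toJSON(canon(unclass_deep(config)), auto_unbox = TRUE,
                         digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Write a run manifest for a pipeline stage
#'
#' @param stage Stage name.
#' @param seed Master seed for the run.
#' @param config The stage configuration (hashed into the manifest).
#' @param inputs,outputs Character vectors of artifact paths.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(stage, seed, config, inputs, outputs, path) {
  manifest <- list(
    tool = "paquant",
    version = as.character(utils::packageVersion("paquant")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage = stage, seed = seed,
    config_hash = config_hash(config),
    inputs = as.list(inputs), outputs = as.list(outputs))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write posterior draws and their summary to disk
#'
#' Draws as CSV (`chain`, `draw`, one column per parameter); summary as
#' JSON with posterior means, intervals, P(> 0), diagnostics, and the
#' sampler configuration echo.
#'
#' @param draws A `posterior_draws` object.
#' @param dir Output directory.
#' @param mass Credible mass for the summaries.
#' @return The summary list, invisibly.
#' @export
write_posterior <- function(draws, dir, mass = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(draws$draws)
  flat <- data.frame(chain = rep(seq_len(d[2L]), each = d[1L]),
                     draw = rep(seq_len(d[1L]), times = d[2L]))
  for (p in draws$parameters)
    flat[[p]] <- as.numeric(draws$draws[, , p])
  utils::write.csv(flat, file.path(dir, "draws.csv"), row.names = FALSE)

  eff <- delta_and_effect(draws, mass = mass)
  diag <- rhat_and_ess(draws)
  par_summ <- lapply(stats::setNames(draws$parameters,
                                     draws$parameters), function(p) {
    s <- summarize_posterior(draws_of(draws, p), mass = mass)
    list(mean = s$mean, et = s$et, hdi = s$hdi, p_gt0 = s$p_gt0)
  })
  summary <- list(
    parameters = par_summ,
    functionals = split(eff$summary, seq_len(nrow(eff$summary))) |>
      lapply(as.list) |> stats::setNames(eff$summary$functional),
    diagnostics = split(diag, seq_len(nrow(diag))) |>
      lapply(as.list) |> stats::setNames(diag$parameter),
    mass = mass,
    sampler = list(chains = draws$config$chains,
                   tune = draws$config$tune,
                   draws = draws$config$draws,
                   seed = draws$config$seed),
    sigma_sharing = draws$spec$sigma_sharing)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
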
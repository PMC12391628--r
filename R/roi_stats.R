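#' Mean of the top fraction of values (the "PA average threshold")
#'
#' The ROI summary used throughout: the mean of the k largest values in
#' the region, with k = ceiling(fraction * N). The ceiling rule
#' guarantees k >= 1 for any non-empty ROI; with `fraction = 1` the
#' statistic is the plain mean.
#'
#' @param values Non-empty numeric vector.
#' @param fraction Proportion in (0, 1\]; default 0.1 (top 10%).
#' @return Scalar mean of the k largest values.
#' @examples
#' top_decile_mean(1:10)   # 10
#' top_decile_mean(1:20)   # 19.5
#' @export
top_decile_mean <- function(values, fraction = 0.1) {
  if (length(values) == 0L) stop("values list is empty")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1], got ", fraction)
  k <- ceiling(fraction * length(values))
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

#' Cumulative component signal over a tumor ROI
#'
#' Sums the selected component abundances voxel-wise over the labeled
#' region and summarizes the sums with the top-fraction mean. This
#' "cumulative" statistic is how nanorod-laden-cell and oxygenated
#' hemoglobin signals are pooled per tumor mass. The alternative reading
#' (top-fraction mean per component, then summed) is available via
#' `combine = "top-then-sum"`.
#'
#' @param cmap A [component_map].
#' @param roi Integer label array on the map's grid.
#' @param label ROI label to summarize.
#' @param components Character vector of component names to pool.
#' @param fraction Top fraction, as in [top_decile_mean].
#' @param combine `"sum-then-top"` (default) or `"top-then-sum"`.
#' @return Scalar cumulative PA signal (a.u.).
#' @export
cumulative_component_signal <- function(cmap, roi, label, components,
                                        fraction = 0.1,
                                        combine = c("sum-then-top",
                                                    "top-then-sum")) {
  stopifnot(inherits(cmap, "component_map"))
  combine <- match.arg(combine)
  check_roi(roi, dim(cmap$abundance)[-1L])
  idx <- match(components, cmap$components)
  if (anyNA(idx))
    stop("unknown component(s): ",
         paste(components[is.na(idx)], collapse = ", "))
  sel <- roi == label
  if (!any(sel)) stop("label ", label, " is absent from the ROI mask")
  per_comp <- lapply(idx, function(k) {
    plane <- cmap$abundance[k, , , ]
    plane[sel]
  })
  if (combine == "sum-then-top") {
    top_decile_mean(Reduce(`+`, per_comp), fraction)
  } else {
    sum(vapply(per_comp, top_decile_mean, numeric(1), fraction = fraction))
  }
}

#' Normalize a longitudinal measurement table to its day-0 baseline
#'
#' Divides each tumor's values by that tumor's own T0 value, so baseline
#' rows become exactly 1 and later time points express fold change. The
#' result keeps `pa_value` untouched and adds `pa_value_norm`; applying
#' the function to its own output recomputes the same normalization
#' (idempotent).
#'
#' @param table Measurement table with columns `tumor_id`, `group`,
#'   `time_label`, `day`, `pa_value`; every tumor must have a nonzero T0
#'   row.
#' @param baseline_label Time label used as baseline (default `"T0"`).
#' @return The table with an added/replaced `pa_value_norm` column.
#' @examples
#' tab <- data.frame(tumor_id = "t1", group = "treated",
#'                   time_label = c("T0", "T1", "T2"), day = c(0, 1, 3),
#'                   pa_value = c(0.27, 0.29, 0.31))
#' normalize_to_baseline(tab)$pa_value_norm  # 1, 29/27, 31/27
#' @export
normalize_to_baseline <- function(table, baseline_label = "T0") {
  table <- validate_measurement_table(table)
  base <- table[table$time_label == baseline_label, ]
  missing <- setdiff(unique(table$tumor_id), base$tumor_id)
  if (length(missing) > 0L)
    stop("tumor(s) without a ", baseline_label, " baseline row: ",
         paste(missing, collapse = ", "))
  if (any(base$pa_value == 0))
    stop("zero ", baseline_label, " baseline for tumor(s): ",
         paste(base$tumor_id[base$pa_value == 0], collapse = ", "))
  t0 <- stats::setNames(base$pa_value, base$tumor_id)
  table$pa_value_norm <- table$pa_value / t0[table$tumor_id]
  table
}
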
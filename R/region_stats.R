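# ROI aggregation under partial-volume rules and normalised-volume
# computation. The two quantities deliberately use different conventions:
# region means include only voxels with partial-volume weight > threshold,
# whereas region volume sums every weight with no threshold.

#' Region mean of a metric map under the partial-volume inclusion rule
#'
#' Unweighted mean over voxels whose partial-volume weight is strictly
#' greater than `threshold` and whose fit is valid. Set `weighted = TRUE`
#' to weight included voxels by their partial-volume fraction instead.
#'
#' @param metric_map numeric array/vector of metric values.
#' @param weights partial-volume weights in `[0, 1]`, same shape.
#' @param threshold inclusion threshold (strict `>`; default 0.5).
#' @param valid optional logical mask of valid fits, same shape.
#' @param weighted weight included voxels by partial-volume fraction.
#' @return Scalar mean; errors on an empty region.
#' @export
aggregate_region_metric <- function(metric_map, weights, threshold = 0.5,
                                    valid = NULL, weighted = FALSE) {
  if (length(metric_map) != length(weights)) {
    stop("metric map and weight map must share a grid")
  }
  if (any(weights < 0 | weights > 1, na.rm = TRUE)) {
    stop("weights must lie in [0, 1]")
  }
  keep <- weights > threshold & is.finite(metric_map)
  if (!is.null(valid)) keep <- keep & as.logical(valid)
  if (!any(keep)) stop("empty region: no voxel passes the inclusion rule")
  if (weighted) {
    sum(metric_map[keep] * weights[keep]) / sum(weights[keep])
  } else {
    mean(metric_map[keep])
  }
}

#' Normalised region volume
#'
#' Sum of all partial-volume weights times the voxel volume, divided by the
#' total intracranial volume. All weights contribute — no threshold.
#'
#' @param weights partial-volume weights in `[0, 1]`.
#' @param voxel_volume voxel volume in mm^3.
#' @param icv total intracranial volume in mm^3 (> 0).
#' @return Dimensionless normalised volume.
#' @export
compute_normalized_volume <- function(weights, voxel_volume, icv) {
  if (!(icv > 0)) stop("icv must be positive")
  if (!(voxel_volume > 0)) stop("voxel_volume must be positive")
  if (any(weights < 0 | weights > 1, na.rm = TRUE)) {
    stop("weights must lie in [0, 1]")
  }
  sum(weights, na.rm = TRUE) * voxel_volume / icv
}

#' Summarise fitted maps over a set of regions
#'
#' Applies [aggregate_region_metric()] to every metric map and
#' [compute_normalized_volume()] to every region weight map, producing one
#' tidy row per region — the building block of the cohort table.
#'
#' @param maps a `sandi_maps` object, or a named list of numeric arrays
#'   (one per metric) plus optionally `valid`.
#' @param regions named list of partial-volume weight arrays.
#' @param voxel_volume voxel volume, mm^3.
#' @param icv intracranial volume, mm^3.
#' @param subject subject identifier copied into the output.
#' @param threshold inclusion threshold for metric means.
#' @return Tibble: one row per region with `subject`, `region`, one column
#'   per metric, `normalized_volume`, `n_voxels`.
#' @export
summarize_regions <- function(maps, regions, voxel_volume, icv,
                              subject = NA_character_, threshold = 0.5) {
  valid <- maps$valid
  metric_names <- intersect(sandi_metric_names(), names(maps))
  if (length(metric_names) == 0) {
    metric_names <- setdiff(names(maps), c("valid", "f_ec_clipped", "affine"))
  }
  rows <- lapply(names(regions), function(rn) {
    w <- regions[[rn]]
    vals <- lapply(metric_names, function(mn)
      aggregate_region_metric(maps[[mn]], w, threshold = threshold,
                              valid = valid))
    names(vals) <- metric_names
    keep <- w > threshold
    if (!is.null(valid)) keep <- keep & as.logical(valid)
    tibble::tibble(subject = subject, region = rn, !!!vals,
                   normalized_volume =
                     compute_normalized_volume(w, voxel_volume, icv),
                   n_voxels = sum(keep))
  })
  dplyr::bind_rows(rows)
}
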
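#' @name geometry_metrics
#' @title Geometric agreement metrics between candidate and reference masks
#' @description The metric battery used to compare a candidate segmentation
#'   against the gold standard: volumetric Dice, surface Dice at a distance
#'   tolerance, 95th-percentile Hausdorff distance, added path length, contour
#'   Dice, voxel confusion rates, and volume/centroid shifts. All distance
#'   computations use exact Euclidean distance transforms honoring anisotropic
#'   spacing, never index-space distances. Undefined cases (empty masks) raise
#'   classed errors rather than returning conventional values, matching the
#'   study rule that excludes structures not present in all arms before any
#'   comparison.
NULL

check_pair <- function(candidate, reference, require_nonempty = c("both", "either", "reference", "none")) {
  require_nonempty <- match.arg(require_nonempty)
  stop_unless_same_grid(candidate, reference)
  ce <- mask_is_empty(candidate); re <- mask_is_empty(reference)
  bad <- switch(require_nonempty,
                both = ce || re,
                either = ce && re,
                reference = re,
                none = FALSE)
  if (bad) seg_stop("metric undefined for empty mask input", "empty_mask")
  invisible(NULL)
}

#' Volumetric Dice similarity coefficient
#'
#' 2|A n B| / (|A| + |B|) over foreground voxel counts, in [0, 1].
#' @param candidate,reference `binary_mask` objects on one grid, not both
#'   empty.
#' @return scalar in [0, 1].
#' @export
volumetric_dice <- function(candidate, reference) {
  check_pair(candidate, reference, "either")
  a <- sum(candidate$occupancy)
  b <- sum(reference$occupancy)
  2 * sum(candidate$occupancy & reference$occupancy) / (a + b)
}

# mark face centroids of a boundary on the half-step fine lattice: fine index
# 2i on pass-through axes, 2i +/- 1 along the face axis, so every face
# centroid (and voxel center) is an exact lattice site
face_fine_indicator <- function(b) {
  ind <- array(FALSE, dim = 2L * b$grid$shape + 1L)
  if (nrow(b$face_idx)) {
    f <- 2L * b$face_idx
    sel <- cbind(seq_along(b$face_axis), b$face_axis)
    f[sel] <- f[sel] + b$face_dir
    ind[f] <- TRUE
  }
  ind
}

# distance (mm) from each face centroid of `from` to the nearest face
# centroid of `to`, via an exact EDT on the shared fine lattice
face_to_surface_dist <- function(from, to) {
  dmap <- sqrt(distance_map_sq(face_fine_indicator(to), to$grid$spacing / 2))
  f <- 2L * from$face_idx
  sel <- cbind(seq_along(from$face_axis), from$face_axis)
  f[sel] <- f[sel] + from$face_dir
  dmap[f]
}

#' Surface Dice similarity coefficient at tolerance tau
#'
#' Area-weighted fraction of the two boundaries lying within `tau` mm of each
#' other: (candidate boundary area within tau of the reference surface +
#' reference boundary area within tau of the candidate surface) / (total
#' candidate + reference boundary area). Surfaces are boundary faces with
#' centroids in mm and areas in mm^2.
#'
#' @param candidate,reference non-empty `binary_mask` objects on one grid.
#' @param tau distance tolerance(s) in mm, > 0; vectorized over `tau`.
#' @return numeric in [0, 1], one value per tolerance.
#' @export
surface_dice <- function(candidate, reference, tau) {
  check_pair(candidate, reference, "both")
  if (any(!is.finite(tau)) || any(tau <= 0))
    seg_stop("surface Dice tolerance tau must be > 0", "invalid_parameter")
  ba <- extract_boundary(candidate)
  bb <- extract_boundary(reference)
  da <- face_to_surface_dist(ba, bb)
  db <- face_to_surface_dist(bb, ba)
  tot <- sum(ba$face_areas) + sum(bb$face_areas)
  vapply(tau, function(t)
    (sum(ba$face_areas[da <= t]) + sum(bb$face_areas[db <= t])) / tot,
    numeric(1))
}

# directed nearest-neighbor distances between boundary voxel-center sets
boundary_voxel_dist <- function(from, to) {
  ind <- array(FALSE, dim = to$grid$shape)
  ind[to$voxel_idx] <- TRUE
  dmap <- sqrt(distance_map_sq(ind, to$grid$spacing))
  dmap[from$voxel_idx]
}

#' 95th-percentile Hausdorff distance
#'
#' Max of the two directed 95th percentiles, where each directed value is the
#' 95th percentile (linear interpolation between order statistics) of
#' nearest-neighbor Euclidean distances from the boundary voxel centers of one
#' mask to those of the other.
#'
#' @param candidate,reference non-empty `binary_mask` objects on one grid.
#' @param probs percentile in (0, 1]; 0.95 is the study convention.
#' @return distance in mm, >= 0.
#' @export
hausdorff95 <- function(candidate, reference, probs = 0.95) {
  check_pair(candidate, reference, "both")
  ba <- extract_boundary(candidate)
  bb <- extract_boundary(reference)
  dab <- boundary_voxel_dist(ba, bb)
  dba <- boundary_voxel_dist(bb, ba)
  max(unname(quantile(dab, probs, type = 7)),
      unname(quantile(dba, probs, type = 7)))
}

#' Added path length
#'
#' The length of reference contour that would have to be redrawn: computed
#' slice-wise in the axial plane as the count of reference boundary pixels
#' (in-plane 4-neighborhood boundary of the reference mask on each slice)
#' whose minimum 3D Euclidean distance to the candidate surface (the
#' candidate's slice-wise boundary pixel set) strictly exceeds the tolerance,
#' converted to mm by the mean in-plane pixel pitch and summed over slices. An
#' empty candidate yields the full reference path length.
#'
#' @param candidate `binary_mask` (may be empty).
#' @param reference non-empty `binary_mask` on the same grid.
#' @param tolerance distance tolerance(s) in mm, >= 0; vectorized.
#' @return length in mm, one value per tolerance.
#' @export
added_path_length <- function(candidate, reference, tolerance) {
  check_pair(candidate, reference, "reference")
  if (any(!is.finite(tolerance)) || any(tolerance < 0))
    seg_stop("APL tolerance must be >= 0", "invalid_parameter")
  sbr <- slice_boundary(reference)
  pitch <- mean(reference$grid$spacing[1:2])
  if (mask_is_empty(candidate)) {
    return(rep(nrow(sbr$idx) * pitch, length(tolerance)))
  }
  sbc <- slice_boundary(candidate)
  dmap <- sqrt(distance_map_sq(sbc$indicator, reference$grid$spacing))
  d <- dmap[sbr$idx]
  vapply(tolerance, function(t) sum(d > t) * pitch, numeric(1))
}

#' Contour Dice coefficient
#'
#' Dice overlap of boundary bands: with S_A, S_B the boundary voxel-center
#' sets and B_t(S) the set of points within `tolerance` of S, returns
#' (|S_A n B_t(S_B)| + |S_B n B_t(S_A)|) / (|S_A| + |S_B|) over voxel counts.
#'
#' @param candidate,reference non-empty `binary_mask` objects on one grid.
#' @param tolerance band half-width in mm, > 0.
#' @return scalar in [0, 1].
#' @export
contour_dice <- function(candidate, reference, tolerance) {
  check_pair(candidate, reference, "both")
  if (!is.finite(tolerance) || tolerance <= 0)
    seg_stop("contour Dice tolerance must be > 0", "invalid_parameter")
  ba <- extract_boundary(candidate)
  bb <- extract_boundary(reference)
  da <- boundary_voxel_dist(ba, bb)
  db <- boundary_voxel_dist(bb, ba)
  (sum(da <= tolerance) + sum(db <= tolerance)) / (length(da) + length(db))
}

#' Voxel-wise confusion rates
#'
#' With TP = |A n B|, FP = |A \ B|, FN = |B \ A| and TN the remaining grid
#' voxels: precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP). Undefined quotients are reported as NA, never as zeros. Note
#' TN (hence specificity) depends on the grid extent; it is computed over the
#' shared reference grid.
#'
#' @param candidate,reference `binary_mask` objects on one grid.
#' @return named list with `precision`, `sensitivity`, `specificity`.
#' @export
voxel_confusion <- function(candidate, reference) {
  check_pair(candidate, reference, "none")
  a <- candidate$occupancy
  b <- reference$occupancy
  tp <- sum(a & b)
  fp <- sum(a & !b)
  fn <- sum(!a & b)
  tn <- length(a) - tp - fp - fn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(precision = safe_div(tp, tp + fp),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp))
}

#' Signed volume difference, cc
#' @param candidate,reference `binary_mask` objects on one grid.
#' @return volume(candidate) - volume(reference) in cc (signed).
#' @export
delta_volume <- function(candidate, reference) {
  check_pair(candidate, reference, "none")
  mask_volume_cc(candidate) - mask_volume_cc(reference)
}

#' Centroid displacement, mm
#' @param candidate,reference non-empty `binary_mask` objects on one grid.
#' @return Euclidean distance between the two centroids in mm.
#' @export
delta_centroid <- function(candidate, reference) {
  check_pair(candidate, reference, "both")
  sqrt(sum((mask_centroid(candidate) - mask_centroid(reference))^2))
}

#' Default metric configuration for batch comparison
#'
#' The study battery: surface Dice at tau in {1, 1.5, 2, 3} mm, added path
#' length at tolerances {1, 2, 3, 5} mm, contour Dice at 1 mm.
#' @param sdsc_tau,apl_tol,cdc_tol tolerances in mm.
#' @param metrics optional character subset of
#'   c("VDSC","SDSC","HD95","APL","CDC","precision","sensitivity",
#'   "specificity","delta_volume","delta_centroid"); NULL means all.
#' @return list used by [compare_structure_sets()].
#' @export
metric_config <- function(sdsc_tau = c(1, 1.5, 2, 3), apl_tol = c(1, 2, 3, 5),
                          cdc_tol = 1, metrics = NULL) {
  list(sdsc_tau = sdsc_tau, apl_tol = apl_tol, cdc_tol = cdc_tol,
       metrics = metrics)
}

#' Compare two structure sets over their common structures
#'
#' Runs the full metric battery for every structure delivered and non-empty in
#' both sets; structures absent or empty in either set are skipped and logged
#' (the study compares only structures present in all arms). If the candidate
#' grid differs from the reference grid, the candidate is resampled to the
#' reference frame by nearest neighbor with a warning.
#'
#' @param candidate,reference `structure_set` objects for one case.
#' @param config a [metric_config()] list.
#' @return Long-format data.frame with columns `case`, `structure`, `arm`,
#'   `metric`, `parameter_mm`, `value`; skipped structure names in
#'   `attr(, "skipped")`.
#' @export
compare_structure_sets <- function(candidate, reference, config = metric_config()) {
  if (!identical(candidate$case_id, reference$case_id))
    seg_stop("candidate and reference must share one case id", "pairing")
  want <- function(m) is.null(config$metrics) || m %in% config$metrics
  common <- intersect(structure_names(reference), structure_names(candidate))
  rows <- list()
  skipped <- character(0)
  for (nm in c(common, setdiff(union(structure_names(reference),
                                     structure_names(candidate)), common))) {
    if (!(nm %in% common)) { skipped <- c(skipped, nm); next }
    ref <- reference$structures[[nm]]
    cand <- candidate$structures[[nm]]
    if (!structure_is_present(ref) || !structure_is_present(cand)) {
      skipped <- c(skipped, nm)
      next
    }
    if (!same_grid(cand$grid, ref$grid)) {
      seg_warn(sprintf("structure %s: candidate resampled to reference grid", nm),
               "grid_resampled")
      cand <- resample_nearest(cand, ref$grid)
      if (mask_is_empty(cand)) { skipped <- c(skipped, nm); next }
    }
    add <- function(metric, parameter_mm, value) {
      rows[[length(rows) + 1L]] <<- data.frame(
        case = reference$case_id, structure = nm, arm = candidate$arm,
        metric = metric, parameter_mm = parameter_mm, value = value,
        stringsAsFactors = FALSE)
    }
    if (want("VDSC")) add("VDSC", NA_real_, volumetric_dice(cand, ref))
    if (want("SDSC")) add("SDSC", config$sdsc_tau, surface_dice(cand, ref, config$sdsc_tau))
    if (want("HD95")) add("HD95", NA_real_, hausdorff95(cand, ref))
    if (want("APL")) add("APL", config$apl_tol, added_path_length(cand, ref, config$apl_tol))
    if (want("CDC")) add("CDC", config$cdc_tol, contour_dice(cand, ref, config$cdc_tol))
    if (any(vapply(c("precision", "sensitivity", "specificity"), want, logical(1)))) {
      cf <- voxel_confusion(cand, ref)
      for (m in c("precision", "sensitivity", "specificity"))
        if (want(m)) add(m, NA_real_, cf[[m]])
    }
    if (want("delta_volume")) add("delta_volume", NA_real_, delta_volume(cand, ref))
    if (want("delta_centroid")) add("delta_centroid", NA_real_, delta_centroid(cand, ref))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case = character(0), structure = character(0), arm = character(0),
               metric = character(0), parameter_mm = numeric(0), value = numeric(0))
  if (length(skipped))
    message(sprintf("case %s arm %s: skipped %d structure(s) not present in both sets: %s",
                    reference$case_id, candidate$arm, length(skipped),
                    paste(sort(unique(skipped)), collapse = ", ")))
  attr(out, "skipped") <- sort(unique(skipped))
  out
}
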
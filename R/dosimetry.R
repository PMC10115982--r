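#' Scalar dose field on a voxel grid
#' @param grid a `voxel_grid`.
#' @param dose numeric array (Gy) with dim equal to `grid$shape`; must be
#'   finite and non-negative.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(grid, dose) {
  if (!inherits(grid, "voxel_grid")) seg_stop("grid must be a voxel_grid", "invalid_geometry")
  dose <- as.array(dose)
  storage.mode(dose) <- "double"
  if (!identical(as.integer(dim(dose)), grid$shape))
    seg_stop("dose dim must equal grid shape", "invalid_geometry")
  if (any(!is.finite(dose)) || any(dose < 0))
    seg_stop("dose must be finite and >= 0 everywhere", "invalid_geometry")
  structure(list(grid = grid, dose = dose), class = "dose_grid")
}

#' Write / read a dose field as NIfTI (Gy, float)
#' @param dose a `dose_grid`.
#' @param path NIfTI file path.
#' @return `path` (write) or a `dose_grid` (read).
#' @export
write_dose_nifti <- function(dose, path) {
  aff <- diag(4)
  diag(aff)[1:3] <- dose$grid$spacing
  aff[1:3, 4] <- dose$grid$origin
  nii <- RNifti::asNifti(dose$dose)
  RNifti::sform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_dose_nifti
#' @export
read_dose_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  dose_grid(nifti_grid(nii), array(as.array(nii), dim = dim(nii)[1:3]))
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid: %d x %d x %d voxels, dose range %.2f-%.2f Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$dose), max(x$dose)))
  invisible(x)
}

# trilinear interpolation of the dose field at world points (n x 3 mm);
# points outside the dose extent clamp to the edge sample. Dose is a smooth
# field, so interpolation (not nearest neighbor) avoids aliasing DVH tails.
interp_dose_at <- function(dose, points) {
  g <- dose$grid
  out <- numeric(nrow(points))
  t <- sweep(sweep(points, 2, g$origin, `-`), 2, g$spacing, `/`)
  t <- pmax(pmin(t, matrix(rep(g$shape - 1L, each = nrow(t)), ncol = 3)), 0)
  i0 <- pmin(floor(t), matrix(rep(g$shape - 2L, each = nrow(t)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- t - i0
  d <- dose$dose
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    acc <- acc + w * d[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  }
  acc
}

# dose values at the foreground voxel centers of a region mask; exact lookup
# when the grids coincide, trilinear interpolation otherwise
region_doses <- function(region, dose) {
  if (same_grid(region$grid, dose$grid)) {
    dose$dose[region$occupancy]
  } else {
    interp_dose_at(dose, mask_voxel_centers(region))
  }
}

#' Expand a CTV into a PTV
#'
#' Isotropic Euclidean expansion in mm (a voxel joins the PTV when its center
#' lies within `margin` of any CTV foreground voxel center), cropped to the
#' body mask — the standard uniform-margin PTV construction.
#'
#' @param ctv clinical target volume, `binary_mask`.
#' @param margin expansion margin in mm, >= 0 (study default 3 mm).
#' @param body patient body mask on the same grid.
#' @return PTV as a `binary_mask`.
#' @export
expand_ptv <- function(ctv, margin, body) {
  stop_unless_same_grid(ctv, body)
  if (!is.finite(margin) || margin < 0)
    seg_stop("PTV margin must be >= 0 mm", "invalid_parameter")
  if (margin == 0 || mask_is_empty(ctv)) {
    return(mask_boolean(ctv, body, "intersect"))
  }
  d2 <- distance_map_sq(ctv$occupancy, ctv$grid$spacing)
  exp_occ <- d2 <= margin^2 + 1e-9
  binary_mask(ctv$grid, exp_occ & body$occupancy)
}

#' Dosimetric evaluation region of an OAR
#'
#' The OAR minus the union of the PTVs. If the remaining volume is below
#' `min_cc` (study rule: 0.1 cc) the structure is excluded from dosimetric
#' analysis and an explicit excluded marker is returned instead of a mask.
#'
#' @param oar `binary_mask`.
#' @param ptvs list of PTV `binary_mask` objects on the same grid (may be
#'   empty).
#' @param min_cc exclusion threshold in cc.
#' @return A `binary_mask`, or an object of class `excluded_region` whose
#'   `reason` attribute records the residual volume.
#' @export
oar_eval_region <- function(oar, ptvs = list(), min_cc = 0.1) {
  region <- oar
  for (p in ptvs) region <- mask_boolean(region, p, "subtract")
  v <- mask_volume_cc(region)
  if (v < min_cc) {
    return(structure(list(volume_cc = v), class = "excluded_region",
                     reason = sprintf("residual volume %.4f cc < %.2f cc", v, min_cc)))
  }
  region
}

#' Is a region the excluded marker?
#' @param x result of [oar_eval_region()].
#' @return logical scalar.
#' @export
is_excluded <- function(x) inherits(x, "excluded_region")

#' Exact cumulative dose-volume histogram
#'
#' Every foreground voxel contributes its voxel volume at its dose value; the
#' cumulative curve (volume in cc receiving at least dose d) is evaluated on
#' the sorted voxel-dose samples with no binning loss. The curve value at d = 0
#' equals the total region volume.
#'
#' @param region non-empty `binary_mask`.
#' @param dose a `dose_grid` (interpolated to the region voxel centers if the
#'   grids differ).
#' @param structure optional structure name carried on the curve.
#' @return An object of class `dvh_curve`: sorted dose samples (Gy), uniform
#'   per-sample volume (cc) and the total volume.
#' @export
cumulative_dvh <- function(region, dose, structure = NA_character_) {
  if (mask_is_empty(region))
    seg_stop("DVH of an empty region is undefined", "empty_mask")
  d <- sort(region_doses(region, dose))
  vv_mm3 <- voxel_volume_mm3(region$grid)
  # same arithmetic as mask_volume_cc so conservation is exact to the bit
  structure(list(structure = structure, dose_sorted = d,
                 sample_volume_cc = vv_mm3 / 1000, voxel_mm3 = vv_mm3,
                 total_cc = length(d) * vv_mm3 / 1000),
            class = "dvh_curve")
}

#' Evaluate the cumulative DVH: volume (cc) receiving >= dose d
#' @param curve a `dvh_curve`.
#' @param d dose level(s), Gy.
#' @return volume(s) in cc.
#' @export
dvh_volume_at <- function(curve, d) {
  vapply(d, function(x) sum(curve$dose_sorted >= x) * curve$voxel_mm3 / 1000,
         numeric(1))
}

#' DVH statistic extraction
#'
#' Supported statistics: `"Dmean"` (volume-weighted mean dose), `"Dxcc"` for
#' any x (e.g. `"D0.03cc"`: minimum dose received by the hottest x cc, by
#' linear interpolation on the sorted voxel-dose profile — no histogram
#' binning), and `"VxGy"` (volume in cc at or above x Gy).
#'
#' @param curve a `dvh_curve`.
#' @param statistic statistic string.
#' @return dose in Gy (D-type) or volume in cc (V-type).
#' @export
dose_stat <- function(curve, statistic) {
  if (identical(statistic, "Dmean")) return(mean(curve$dose_sorted))
  m <- regmatches(statistic, regexec("^D([0-9.]+)cc$", statistic))[[1]]
  if (length(m) == 2L) {
    x <- as.numeric(m[2])
    if (x > curve$total_cc + 1e-12)
      seg_stop(sprintf("D%scc queried beyond total volume %.4f cc", m[2], curve$total_cc),
               "invalid_query")
    d <- rev(curve$dose_sorted)                 # hottest first
    cumv <- seq_along(d) * curve$sample_volume_cc
    if (x <= cumv[1]) return(d[1])
    return(approx(cumv, d, xout = min(x, cumv[length(cumv)]))$y)
  }
  m <- regmatches(statistic, regexec("^V([0-9.]+)Gy$", statistic))[[1]]
  if (length(m) == 2L) return(dvh_volume_at(curve, as.numeric(m[2])))
  seg_stop(sprintf("unrecognized DVH statistic '%s'", statistic), "invalid_query")
}

#' A single plan-quality objective
#'
#' One DVH-objective scoring rule: a statistic on a structure, a comparison
#' direction, a full-credit threshold and optional linear partial credit down
#' to a zero-credit threshold (which must lie on the failing side).
#'
#' @param structure structure name the objective applies to.
#' @param statistic DVH statistic string as in [dose_stat()].
#' @param direction `"<="` (limit, OAR-style) or `">="` (goal, target-style).
#' @param threshold full-credit threshold (Gy or cc).
#' @param points point value > 0.
#' @param zero_threshold optional zero-credit threshold enabling a linear
#'   credit ramp between the two thresholds.
#' @param target if TRUE the statistic is evaluated on the structure mask
#'   itself; otherwise on the OAR evaluation region (minus PTVs, with the
#'   0.1 cc exclusion rule).
#' @return An object of class `pqm_objective`.
#' @export
pqm_objective <- function(structure, statistic, direction = c("<=", ">="),
                          threshold, points = 1, zero_threshold = NULL,
                          target = FALSE) {
  direction <- match.arg(direction)
  if (!is.finite(points) || points <= 0)
    seg_stop("objective point value must be > 0", "invalid_parameter")
  if (!is.null(zero_threshold)) {
    ok <- if (direction == "<=") zero_threshold > threshold else zero_threshold < threshold
    if (!ok)
      seg_stop("zero-credit threshold must lie on the failing side of the full-credit threshold",
               "invalid_parameter")
  }
  structure(list(structure = structure, statistic = statistic,
                 direction = direction, threshold = threshold,
                 points = points, zero_threshold = zero_threshold,
                 target = target),
            class = "pqm_objective")
}

#' Plan-quality scoring template
#' @param objectives list of [pqm_objective()] rules, at least one.
#' @param id template identifier.
#' @return An object of class `pqm_template`.
#' @export
pqm_template <- function(objectives, id = "template") {
  if (length(objectives) == 0L)
    seg_stop("a PQM template needs at least one objective", "empty_template")
  for (o in objectives) if (!inherits(o, "pqm_objective"))
    seg_stop("objectives must be pqm_objective entries", "invalid_parameter")
  structure(list(objectives = objectives, id = id), class = "pqm_template")
}

#' Read a PQM template from a YAML file
#'
#' Expected form: a top-level `id` and a list `objectives`, each with
#' `structure`, `statistic`, `direction`, `threshold`, and optionally
#' `points`, `zero_threshold`, `target`. See
#' `system.file("extdata", "pqm_hn_example.yaml", package = "segeval")`.
#' @param path YAML file.
#' @return A `pqm_template`.
#' @export
read_pqm_template <- function(path) {
  y <- yaml::read_yaml(path)
  objs <- lapply(y$objectives, function(o)
    pqm_objective(o$structure, o$statistic,
                  direction = if (is.null(o$direction)) "<=" else o$direction,
                  threshold = o$threshold,
                  points = if (is.null(o$points)) 1 else o$points,
                  zero_threshold = o$zero_threshold,
                  target = isTRUE(o$target)))
  pqm_template(objs, id = if (is.null(y$id)) "template" else y$id)
}

score_objective <- function(obj, value) {
  met <- if (obj$direction == "<=") value <= obj$threshold else value >= obj$threshold
  if (met) return(obj$points)
  if (is.null(obj$zero_threshold)) return(0)
  frac <- (obj$zero_threshold - value) / (obj$zero_threshold - obj$threshold)
  obj$points * min(1, max(0, frac))
}

#' Score a structure set against a plan-quality template
#'
#' Per objective: full points when the DVH statistic satisfies the comparison
#' at the full-credit threshold, zero at or beyond the zero-credit threshold,
#' linear in between when a ramp is configured. Objectives whose structure is
#' absent, empty, or excluded by the evaluation-region rule contribute to
#' neither achieved nor maximum — this is what makes the normalized score
#' comparable across cases with different structure rosters.
#'
#' @param structset a `structure_set`.
#' @param dose a `dose_grid`.
#' @param template a `pqm_template`.
#' @param ptvs list of PTV masks used for the OAR evaluation-region rule.
#' @return list with `achieved`, `maximum`, and a per-objective data.frame
#'   `detail` (structure, statistic, value, score, max, status).
#' @export
pqm_score <- function(structset, dose, template, ptvs = list()) {
  rows <- list()
  achieved <- 0; maximum <- 0
  for (obj in template$objectives) {
    s <- structset$structures[[obj$structure]]
    status <- "scored"; value <- NA_real_; sc <- NA_real_; mx <- NA_real_
    if (is.null(s) || !structure_is_present(s)) {
      status <- "absent"
    } else {
      region <- if (obj$target) s else oar_eval_region(s, ptvs)
      if (is_excluded(region)) {
        status <- "excluded"
      } else {
        value <- dose_stat(cumulative_dvh(region, dose, obj$structure), obj$statistic)
        sc <- score_objective(obj, value)
        mx <- obj$points
        achieved <- achieved + sc
        maximum <- maximum + mx
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      structure = obj$structure, statistic = obj$statistic, value = value,
      score = sc, max = mx, status = status, stringsAsFactors = FALSE)
  }
  if (maximum == 0)
    seg_stop("no scorable objectives: template references only absent or excluded structures",
             "empty_template")
  list(achieved = achieved, maximum = maximum, detail = do.call(rbind, rows))
}

#' Normalized plan quality metric
#'
#' 100 x achieved / maximum plan-quality points, the maximum taken over the
#' objectives whose structures are present (and not excluded), in [0, 100].
#'
#' @inheritParams pqm_score
#' @return percentage in [0, 100].
#' @export
npqm <- function(structset, dose, template, ptvs = list()) {
  s <- pqm_score(structset, dose, template, ptvs)
  100 * s$achieved / s$maximum
}

#' Dosimetric agreement of an arm with the gold standard
#'
#' For every structure with a valid evaluation region in both sets, the
#' absolute differences |dDmean| and |dD0.03cc| (Gy) computed on the one
#' shared reference dose grid, plus the case-level |dNPQM| in percentage
#' points. Structures excluded (or absent/empty) in either set are skipped
#' and listed in `attr(, "skipped")`.
#'
#' @param arm,gs `structure_set` objects on the GS grid.
#' @param dose the reference `dose_grid`.
#' @param ptvs list of PTV masks.
#' @param template a `pqm_template` for the NPQM comparison.
#' @param hot_cc hot-spot volume for the near-maximum dose statistic (cc).
#' @return list with `structures` (data.frame: structure, delta_dmean_gy,
#'   delta_dhot_gy) and `delta_npqm_pct`.
#' @export
dosimetric_deltas <- function(arm, gs, dose, ptvs = list(), template = NULL,
                              hot_cc = 0.03) {
  hot <- sprintf("D%gcc", hot_cc)
  common <- intersect(structure_names(gs, present_only = TRUE),
                      structure_names(arm, present_only = TRUE))
  rows <- list(); skipped <- character(0)
  for (nm in common) {
    rg <- oar_eval_region(gs$structures[[nm]], ptvs)
    ra <- oar_eval_region(arm$structures[[nm]], ptvs)
    if (is_excluded(rg) || is_excluded(ra)) { skipped <- c(skipped, nm); next }
    cg <- cumulative_dvh(rg, dose, nm)
    ca <- cumulative_dvh(ra, dose, nm)
    hot_ok <- min(cg$total_cc, ca$total_cc) >= hot_cc
    rows[[length(rows) + 1L]] <- data.frame(
      structure = nm,
      delta_dmean_gy = abs(dose_stat(ca, "Dmean") - dose_stat(cg, "Dmean")),
      delta_dhot_gy = if (hot_ok) abs(dose_stat(ca, hot) - dose_stat(cg, hot)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  dn <- if (is.null(template)) NA_real_ else
    abs(npqm(arm, dose, template, ptvs) - npqm(gs, dose, template, ptvs))
  skipped <- c(skipped, setdiff(union(structure_names(gs), structure_names(arm)), common))
  if (length(skipped))
    message(sprintf("case %s arm %s: %d structure(s) skipped in dosimetric deltas: %s",
                    gs$case_id, arm$arm, length(sort(unique(skipped))),
                    paste(sort(unique(skipped)), collapse = ", ")))
  out <- list(structures = if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0), delta_dmean_gy = numeric(0),
               delta_dhot_gy = numeric(0)),
    delta_npqm_pct = dn)
  attr(out, "skipped") <- sort(unique(skipped))
  out
}
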
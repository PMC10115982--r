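#' Absent-structure marker
#'
#' A structure that was never delivered in a structure set. Distinct from a
#' delivered-but-empty mask: absence is what the presence contingency counts,
#' while an empty delivered mask still blocks geometric metrics (which require
#' non-empty input). An empty delivered mask is treated as absent for presence
#' accounting.
#' @return An object of class `absent_structure`.
#' @export
absent_structure <- function() structure(list(), class = "absent_structure")

#' Is a structure entry the absent marker?
#' @param x a structure entry (`binary_mask` or `absent_structure`).
#' @return logical scalar.
#' @export
is_absent <- function(x) inherits(x, "absent_structure")

# delivered and non-empty: the presence criterion used by the contingency
# analysis and by the all-arms eligibility rule
structure_is_present <- function(x) {
  !is_absent(x) && !mask_is_empty(x)
}

#' Named structure set for one case and one arm
#'
#' Bundles the masks delivered by one contour source ("arm": the gold standard
#' GS, the unrevised model DL, the physician-revised model DL+RO, the revised
#' manual arm MDA+RO, or any user label) for one case. All masks share one
#' grid; structures may be explicitly absent.
#'
#' @param case_id case identifier (coerced to character).
#' @param arm arm label.
#' @param structures named list whose elements are `binary_mask` objects or
#'   `absent_structure()` markers; names must be unique.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(case_id, arm, structures) {
  if (is.null(names(structures)) || any(names(structures) == "") ||
      anyDuplicated(names(structures)))
    seg_stop("structures must be uniquely named", "invalid_geometry")
  grid <- NULL
  for (s in structures) {
    if (is_absent(s)) next
    if (!inherits(s, "binary_mask"))
      seg_stop("structure entries must be binary_mask or absent_structure", "invalid_geometry")
    if (is.null(grid)) grid <- s$grid
    else if (!same_grid(grid, s$grid))
      seg_stop("all masks in a structure set must share one grid", "grid_mismatch")
  }
  structure(list(case_id = as.character(case_id), arm = as.character(arm),
                 structures = structures, grid = grid),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  pres <- vapply(x$structures, structure_is_present, logical(1))
  cat(sprintf("structure_set: case %s, arm %s, %d structures (%d present, %d absent/empty)\n",
              x$case_id, x$arm, length(x$structures), sum(pres), sum(!pres)))
  invisible(x)
}

#' Names of structures in a set
#' @param set a `structure_set`.
#' @param present_only if TRUE, only delivered non-empty structures.
#' @return character vector.
#' @export
structure_names <- function(set, present_only = FALSE) {
  nm <- names(set$structures)
  if (present_only) nm[vapply(set$structures, structure_is_present, logical(1))] else nm
}

#' Write a binary mask as NIfTI
#'
#' World axes map to NIfTI i/j/k with the grid spacing in pixdim and the grid
#' origin in the affine translation. Values are 0/1 uint8.
#' @param mask a `binary_mask`.
#' @param path output file (".nii" or ".nii.gz").
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- array(as.integer(mask$occupancy), dim = mask$grid$shape)
  aff <- diag(4)
  diag(aff)[1:3] <- mask$grid$spacing
  aff[1:3, 4] <- mask$grid$origin
  nii <- RNifti::asNifti(img)
  RNifti::sform(nii) <- structure(aff, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

nifti_grid <- function(nii) {
  aff <- RNifti::xform(nii)
  voxel_grid(origin = aff[1:3, 4], spacing = abs(diag(aff)[1:3]),
             shape = dim(nii)[1:3])
}

#' Read a NIfTI label/mask volume as a binary mask
#' @param path NIfTI file; nonzero voxels become foreground.
#' @return A `binary_mask`.
#' @export
read_mask_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  binary_mask(nifti_grid(nii), array(as.array(nii) != 0, dim = dim(nii)[1:3]))
}

#' Write a structure set as NIfTI masks plus a JSON manifest
#'
#' One NIfTI file per delivered structure plus `manifest.json` recording case,
#' arm, grid, and the present/absent status of every structure.
#' @param set a `structure_set`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_structure_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (nm in names(set$structures)) {
    s <- set$structures[[nm]]
    if (is_absent(s)) { files[[nm]] <- NA_character_; next }
    f <- paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nii.gz")
    write_mask_nifti(s, file.path(dir, f))
    files[[nm]] <- f
  }
  manifest <- list(case_id = set$case_id, arm = set$arm, structures = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a structure set written by [write_structure_set()]
#' @param dir directory containing `manifest.json` and the NIfTI masks.
#' @return A `structure_set`.
#' @export
read_structure_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  structures <- lapply(manifest$structures, function(f) {
    if (is.null(f) || is.na(f)) absent_structure()
    else read_mask_nifti(file.path(dir, f))
  })
  structure_set(manifest$case_id, manifest$arm, structures)
}
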
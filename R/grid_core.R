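#' Axis-aligned anisotropic voxel grid
#'
#' The geometric substrate of every mask, metric and dose field: a
#' world-aligned 3D raster. World coordinates are millimetres; the grid origin
#' is the world position of the center of voxel (1,1,1); anisotropic spacing
#' (e.g. the typical planning-CT voxel of 1.27 x 1.27 x 2 mm) is fully
#' supported. Axis 3 is the slicing (axial) direction.
#'
#' @param origin numeric(3), world position (mm) of the first voxel center.
#' @param spacing numeric(3), strictly positive voxel size per axis (mm).
#' @param shape integer(3), strictly positive voxel counts per axis.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(0, 0, 0), c(1.27, 1.27, 2), c(64, 64, 40))
#' voxel_volume_mm3(g)
#' @export
voxel_grid <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || length(spacing) != 3L || length(shape) != 3L)
    seg_stop("origin, spacing and shape must each have length 3", "invalid_geometry")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    seg_stop("grid spacing must be strictly positive on all axes", "invalid_geometry")
  if (any(is.na(shape)) || any(shape <= 0L))
    seg_stop("grid shape must be strictly positive on all axes", "invalid_geometry")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid a `voxel_grid`.
#' @return scalar, product of the three spacings (mm^3).
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$spacing)

#' World coordinates of voxel centers along one axis
#' @param grid a `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of length `grid$shape[axis]` (mm).
#' @export
grid_axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Do two grids coincide?
#' @param a,b `voxel_grid` objects.
#' @param tol positional tolerance in mm.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

stop_unless_same_grid <- function(a, b) {
  if (!same_grid(a$grid, b$grid))
    seg_stop("masks are not on the same grid; resample first", "grid_mismatch")
}

#' Binary occupancy mask on a voxel grid
#'
#' @param grid a `voxel_grid`.
#' @param occupancy logical array with dim equal to `grid$shape`; defaults to
#'   all-background. Empty masks are valid objects; operations that need a
#'   non-empty mask raise classed errors instead of inventing values.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, occupancy = NULL) {
  if (!inherits(grid, "voxel_grid")) seg_stop("grid must be a voxel_grid", "invalid_geometry")
  if (is.null(occupancy)) {
    occupancy <- array(FALSE, dim = grid$shape)
  } else {
    occupancy <- as.array(occupancy)
    storage.mode(occupancy) <- "logical"
    if (!identical(as.integer(dim(occupancy)), grid$shape))
      seg_stop("occupancy dim must equal grid shape", "invalid_geometry")
    if (anyNA(occupancy)) seg_stop("occupancy must not contain NA", "invalid_geometry")
  }
  structure(list(grid = grid, occupancy = occupancy), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d foreground voxels (%.3f cc) on %d x %d x %d grid\n",
              sum(x$occupancy), mask_volume_cc(x),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

mask_is_empty <- function(mask) !any(mask$occupancy)

#' Foreground voxel centers in world mm
#' @param mask a `binary_mask`.
#' @return n x 3 matrix of world coordinates (mm) of foreground voxel centers.
#' @export
mask_voxel_centers <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  idx_to_world(idx, mask$grid)
}

idx_to_world <- function(idx, grid) {
  if (length(idx) == 0L) return(matrix(numeric(0), ncol = 3))
  sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Planar contour on an axial slice
#'
#' The DICOM-RT-style planar polygon: an ordered, implicitly-closed vertex
#' loop at a fixed position along the slicing axis.
#'
#' @param z slice position (mm) along the slicing (third) axis.
#' @param vertices n x 2 matrix of in-plane (x, y) vertices in mm, n >= 3.
#' @return An object of class `contour_slice`.
#' @export
contour_slice <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L)
    seg_stop("a contour needs >= 3 planar (x, y) vertices", "invalid_geometry")
  if (!is.finite(z) || anyNA(vertices))
    seg_stop("contour coordinates must be finite", "invalid_geometry")
  structure(list(z = as.numeric(z), vertices = unname(vertices)),
            class = "contour_slice")
}

#' Rasterize planar contours onto a grid
#'
#' A voxel becomes foreground iff its center lies inside an odd number of the
#' polygons on its slice (even-odd rule, strict interior with a deterministic
#' half-open tie rule). Contours are assigned to the nearest grid slice;
#' contours falling outside the slicing extent are clipped away, and in-plane
#' geometry outside the grid is clipped by construction.
#'
#' @param contours list of `contour_slice` objects (may be empty).
#' @param grid target `voxel_grid`.
#' @return A `binary_mask` on `grid`.
#' @examples
#' g <- voxel_grid(c(-4.5, -4.5, 0), c(1, 1, 2), c(10, 10, 3))
#' sq <- contour_slice(2, cbind(c(-5, 5, 5, -5), c(-5, -5, 5, 5)))
#' sum(rasterize_contours(list(sq), g)$occupancy)  # 100
#' @export
rasterize_contours <- function(contours, grid) {
  if (!inherits(grid, "voxel_grid")) seg_stop("grid must be a voxel_grid", "invalid_geometry")
  occ <- array(FALSE, dim = grid$shape)
  if (length(contours) == 0L) return(binary_mask(grid, occ))
  for (ct in contours) {
    if (!inherits(ct, "contour_slice"))
      seg_stop("contours must be contour_slice objects (axial planes only)",
               "unsupported_orientation")
  }
  zs <- vapply(contours, function(ct) ct$z, numeric(1))
  # nearest slice, ties toward the lower index
  k <- ceiling((zs - grid$origin[3]) / grid$spacing[3] - 0.5) + 1
  keep <- k >= 1 & k <= grid$shape[3]
  xs <- grid_axis_coords(grid, 1)
  ys <- grid_axis_coords(grid, 2)
  px <- rep(xs, times = grid$shape[2])
  py <- rep(ys, each = grid$shape[1])
  for (slice in unique(k[keep])) {
    cross <- integer(length(px))
    for (ct in contours[keep & k == slice]) {
      cross <- cross + pip_crossings_cpp(px, py, ct$vertices[, 1], ct$vertices[, 2])
    }
    occ[, , slice] <- occ[, , slice] | matrix(cross %% 2L == 1L, grid$shape[1], grid$shape[2])
  }
  binary_mask(grid, occ)
}

#' Nearest-neighbor resampling of a mask onto another grid
#'
#' Each output voxel takes the occupancy of the input voxel whose center is
#' nearest to the output voxel center (per-axis nearest; ties toward the lower
#' index). Output centers outside the input grid become background, so
#' disjoint domains yield an empty mask. Resampling onto the identical grid is
#' the identity.
#'
#' @param mask a `binary_mask`.
#' @param target a `voxel_grid`.
#' @return A `binary_mask` on `target`.
#' @export
resample_nearest <- function(mask, target) {
  if (same_grid(mask$grid, target)) return(binary_mask(target, mask$occupancy))
  maps <- lapply(1:3, function(a) {
    x <- grid_axis_coords(target, a)
    i <- ceiling((x - mask$grid$origin[a]) / mask$grid$spacing[a] - 0.5) + 1
    i[i < 1L | i > mask$grid$shape[a]] <- NA_integer_
    i
  })
  valid <- !is.na(maps[[1]])
  occ <- array(FALSE, dim = target$shape)
  i1 <- maps[[1]][valid]
  v2 <- !is.na(maps[[2]]); v3 <- !is.na(maps[[3]])
  if (any(valid) && any(v2) && any(v3)) {
    occ[valid, v2, v3] <- mask$occupancy[i1, maps[[2]][v2], maps[[3]][v3], drop = FALSE]
  }
  binary_mask(target, occ)
}

# occupancy of the neighbor in direction dir (+1/-1) along axis; FALSE beyond edge
shift_occ <- function(occ, axis, dir) {
  d <- dim(occ)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (n == 1L) return(out)
  src <- if (dir > 0) 2:n else 1:(n - 1)
  dst <- if (dir > 0) 1:(n - 1) else 2:n
  ix <- list(1:d[1], 1:d[2], 1:d[3])
  ixs <- ix; ixs[[axis]] <- src
  ixd <- ix; ixd[[axis]] <- dst
  out[ixd[[1]], ixd[[2]], ixd[[3]]] <- occ[ixs[[1]], ixs[[2]], ixs[[3]]]
  out
}

#' Extract the boundary of a binary mask
#'
#' Returns both surface representations used by the agreement metrics:
#' boundary faces (faces between a foreground voxel and a background voxel or
#' the grid edge, with centroid in mm and area in mm^2 given by the product of
#' the two in-plane spacings) and boundary voxel centers (foreground voxels
#' with at least one exposed face). An empty mask yields empty sets.
#'
#' @param mask a `binary_mask`.
#' @return An object of class `mask_boundary`: list with `face_centers` (f x 3
#'   mm), `face_areas` (mm^2), `face_axis`, `face_dir`, `face_idx` (f x 3 voxel
#'   indices), `voxel_centers` (b x 3 mm), `voxel_idx` (b x 3), and `grid`.
#' @export
extract_boundary <- function(mask) {
  occ <- mask$occupancy
  grid <- mask$grid
  face_idx <- vector("list", 6)
  face_axis <- integer(0); face_dir <- integer(0)
  fi <- list(); fa <- integer(0); fd <- integer(0)
  bvox <- array(FALSE, dim = dim(occ))
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      exposed <- occ & !shift_occ(occ, axis, dir)
      bvox <- bvox | exposed
      idx <- which(exposed, arr.ind = TRUE)
      if (nrow(idx)) {
        fi[[length(fi) + 1L]] <- idx
        fa <- c(fa, rep(axis, nrow(idx)))
        fd <- c(fd, rep(dir, nrow(idx)))
      }
    }
  }
  if (length(fi)) {
    face_idx <- do.call(rbind, fi)
    face_centers <- idx_to_world(face_idx, grid)
    for (axis in 1:3) {
      sel <- fa == axis
      face_centers[sel, axis] <- face_centers[sel, axis] +
        fd[sel] * grid$spacing[axis] / 2
    }
    face_areas <- prod(grid$spacing) / grid$spacing[fa]
  } else {
    face_idx <- matrix(integer(0), ncol = 3)
    face_centers <- matrix(numeric(0), ncol = 3)
    face_areas <- numeric(0)
  }
  vidx <- which(bvox, arr.ind = TRUE)
  structure(list(face_centers = face_centers, face_areas = face_areas,
                 face_axis = fa, face_dir = fd, face_idx = face_idx,
                 voxel_centers = idx_to_world(vidx, grid), voxel_idx = vidx,
                 grid = grid),
            class = "mask_boundary")
}

# slice-wise in-plane (4-neighborhood) boundary pixels, as an indicator array
# and voxel indices; used by the added-path-length metric
slice_boundary <- function(mask) {
  occ <- mask$occupancy
  b <- occ & !(shift_occ(occ, 1, -1) & shift_occ(occ, 1, 1) &
                 shift_occ(occ, 2, -1) & shift_occ(occ, 2, 1))
  list(indicator = b, idx = which(b, arr.ind = TRUE))
}

#' Mask volume in cc
#' @param mask a `binary_mask`.
#' @return foreground voxel count times voxel volume, converted mm^3 -> cc.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$occupancy) * voxel_volume_mm3(mask$grid) / 1000
}

#' Mask centroid in world mm
#' @param mask a non-empty `binary_mask`.
#' @return numeric(3), unweighted mean of foreground voxel centers (mm).
#' @export
mask_centroid <- function(mask) {
  if (mask_is_empty(mask))
    seg_stop("centroid of an empty mask is undefined", "empty_mask")
  unname(colMeans(mask_voxel_centers(mask)))
}

#' Voxel-wise boolean combination of two masks
#' @param a,b `binary_mask` objects on one shared grid.
#' @param op one of "union", "intersect", "subtract" (a minus b).
#' @return A `binary_mask` on the shared grid.
#' @export
mask_boolean <- function(a, b, op = c("union", "intersect", "subtract")) {
  op <- match.arg(op)
  stop_unless_same_grid(a, b)
  occ <- switch(op,
    union     = a$occupancy | b$occupancy,
    intersect = a$occupancy & b$occupancy,
    subtract  = a$occupancy & !b$occupancy)
  binary_mask(a$grid, occ)
}

#' Squared Euclidean distance map to a voxel set
#'
#' Exact separable distance transform honoring anisotropic spacing: for every
#' voxel center, the squared distance (mm^2) to the nearest `TRUE` voxel
#' center of `indicator`. All-`FALSE` input yields +Inf everywhere.
#'
#' @param indicator logical 3D array.
#' @param spacing numeric(3) voxel spacing (mm).
#' @return numeric array of squared distances, same dim as `indicator`.
#' @export
distance_map_sq <- function(indicator, spacing) {
  edt_sq_cpp(indicator, as.numeric(spacing))
}
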
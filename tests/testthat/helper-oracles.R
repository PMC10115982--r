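# Brute-force oracles, independent of the package's distance-transform path.
# Distances accumulate squared offsets in axis order x, y, z so that exact
# lattice distances agree bit-for-bit with the separable transform.

# minimum Euclidean distance from each row of A (n x 3, mm) to the point set B
bf_min_dists <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i) {
    dx <- A[i, 1] - B[, 1]
    dy <- A[i, 2] - B[, 2]
    dz <- A[i, 3] - B[, 3]
    sqrt(min(dx * dx + dy * dy + dz * dz))
  }, numeric(1))
}

# boundary voxels and faces by an explicit 6-neighborhood scan (nested loops)
bf_boundary_scan <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  g <- mask$grid
  vox <- NULL
  n_faces <- 0L
  area <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!occ[i, j, k]) next
    exposed <- FALSE
    for (step in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                      c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
      ii <- i + step[1]; jj <- j + step[2]; kk <- k + step[3]
      outside <- ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]
      if (outside || !occ[ii, jj, kk]) {
        exposed <- TRUE
        n_faces <- n_faces + 1L
        ax <- which(step != 0)
        area <- area + prod(g$spacing) / g$spacing[ax]
      }
    }
    if (exposed) vox <- rbind(vox, c(i, j, k))
  }
  list(n_faces = n_faces, total_area = area,
       voxel_idx = if (is.null(vox)) matrix(integer(0), ncol = 3) else vox)
}

bf_face_set <- function(mask) {
  b <- extract_boundary(mask)
  list(centers = b$face_centers, areas = b$face_areas)
}

bf_voxel_centers <- function(mask) extract_boundary(mask)$voxel_centers

bf_surface_dice <- function(candidate, reference, tau) {
  fa <- bf_face_set(candidate)
  fb <- bf_face_set(reference)
  da <- bf_min_dists(fa$centers, fb$centers)
  db <- bf_min_dists(fb$centers, fa$centers)
  (sum(fa$areas[da <= tau]) + sum(fb$areas[db <= tau])) /
    (sum(fa$areas) + sum(fb$areas))
}

bf_hausdorff95 <- function(candidate, reference, probs = 0.95) {
  pa <- bf_voxel_centers(candidate)
  pb <- bf_voxel_centers(reference)
  max(unname(quantile(bf_min_dists(pa, pb), probs, type = 7)),
      unname(quantile(bf_min_dists(pb, pa), probs, type = 7)))
}

# slice-wise in-plane 4-neighborhood boundary pixels, world mm
bf_slice_boundary_centers <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  g <- mask$grid
  out <- NULL
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!occ[i, j, k]) next
    edge <- i == 1 || i == d[1] || j == 1 || j == d[2] ||
      !occ[i - 1, j, k] || !occ[i + 1, j, k] ||
      !occ[i, j - 1, k] || !occ[i, j + 1, k]
    if (edge) out <- rbind(out, c(i, j, k))
  }
  if (is.null(out)) return(matrix(numeric(0), ncol = 3))
  sweep(sweep(out - 1, 2, g$spacing, `*`), 2, g$origin, `+`)
}

bf_added_path_length <- function(candidate, reference, tolerance) {
  pr <- bf_slice_boundary_centers(reference)
  pitch <- mean(reference$grid$spacing[1:2])
  if (!any(candidate$occupancy)) return(nrow(pr) * pitch)
  pc <- bf_slice_boundary_centers(candidate)
  d <- bf_min_dists(pr, pc)
  sum(d > tolerance) * pitch
}

bf_contour_dice <- function(candidate, reference, tolerance) {
  pa <- bf_voxel_centers(candidate)
  pb <- bf_voxel_centers(reference)
  da <- bf_min_dists(pa, pb)
  db <- bf_min_dists(pb, pa)
  (sum(da <= tolerance) + sum(db <= tolerance)) / (length(da) + length(db))
}
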
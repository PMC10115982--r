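# In-code fixtures: small grids, shapes and random blob masks.

iso_grid <- function(n = 20, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_grid(origin, spacing, rep(n, length.out = 3))
}

aniso_grid <- function(n = 20, spacing = c(1.27, 1.27, 2)) {
  voxel_grid(c(0, 0, 0), spacing, rep(n, length.out = 3))
}

cube_mask <- function(grid, from, to) {
  occ <- array(FALSE, dim = grid$shape)
  occ[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  binary_mask(grid, occ)
}

sphere_mask <- function(grid, center, r) {
  primitive_mask(grid, "sphere", center, r)
}

# voxel-aligned translation by integer voxel steps (exact, no resampling)
translate_mask <- function(mask, steps) {
  occ <- mask$occupancy
  d <- dim(occ)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- steps[a]
    if (abs(s) >= d[a]) return(binary_mask(mask$grid, out))
    src[[a]] <- if (s >= 0) 1:(d[a] - s) else (1 - s):d[a]
    dst[[a]] <- if (s >= 0) (1 + s):d[a] else 1:(d[a] + s)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  binary_mask(mask$grid, out)
}

# random non-empty blob: union of a few random balls, clipped to the grid
random_blob_mask <- function(grid, n_balls = 3) {
  half <- (grid$shape - 1) * grid$spacing / 2
  ctr0 <- grid$origin + half
  occ <- array(FALSE, dim = grid$shape)
  for (b in seq_len(n_balls)) {
    c_ <- ctr0 + runif(3, -0.6, 0.6) * half
    r <- runif(1, 0.15, 0.45) * min(half)
    occ <- occ | primitive_mask(grid, "sphere", c_, r)$occupancy
  }
  if (!any(occ)) occ[ceiling(grid$shape / 2)[1],
                     ceiling(grid$shape / 2)[2],
                     ceiling(grid$shape / 2)[3]] <- TRUE
  binary_mask(grid, occ)
}

# tiny presence-only structure set: every named structure shares one 2-voxel mask
presence_set <- function(case_id, arm, present, absent = character(0)) {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  occ <- array(FALSE, dim = c(2, 2, 2)); occ[1, 1, 1] <- TRUE
  m <- binary_mask(g, occ)
  st <- c(setNames(replicate(length(present), m, simplify = FALSE), present),
          setNames(replicate(length(absent), absent_structure(), simplify = FALSE),
                   absent))
  structure_set(case_id, arm, st)
}
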
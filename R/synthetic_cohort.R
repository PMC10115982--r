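#' @name synthetic_cohort
#' @title Synthetic phantom cohorts with analytically known answers
#' @description Generates fully synthetic study inputs — anisotropic phantom
#'   grids, a 42-name gold-standard organ-at-risk roster built from geometric
#'   primitives, perturbed "arm" structure sets (translation, dilation or
#'   erosion, correlated boundary noise, slice dropout, absence sampling),
#'   dose fields, and per-case timing records — so that every evaluation
#'   module is testable without patient data, and every applied ground-truth
#'   parameter is recoverable by the corresponding metric.
NULL

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

outer3 <- function(a, b, c) outer(outer(a, b, `+`), c, `+`)

#' Rasterize a geometric primitive onto a grid
#'
#' Primitives: `sphere` (p1 = radius), `ellipsoid` (p1..p3 = semi-axes),
#' `tube` (circular cylinder along the slicing axis; p1 = radius, p2 = half
#' length), `box` (p1..p3 = half sizes), `ring` (annular cylinder; p1 = inner
#' radius, p2 = outer radius, p3 = half length), `ecylinder` (elliptical
#' cylinder; p1, p2 = in-plane semi-axes, p3 = half length). A voxel is
#' foreground when its center lies inside or on the primitive.
#'
#' @param grid a `voxel_grid`.
#' @param primitive primitive name.
#' @param center numeric(3) center, mm.
#' @param size numeric parameter vector p1..p3, mm.
#' @return A `binary_mask`.
#' @export
primitive_mask <- function(grid, primitive, center, size) {
  dx <- grid_axis_coords(grid, 1) - center[1]
  dy <- grid_axis_coords(grid, 2) - center[2]
  dz <- grid_axis_coords(grid, 3) - center[3]
  inz <- function(hz) abs(dz) <= hz
  occ <- switch(primitive,
    sphere = outer3(dx^2, dy^2, dz^2) <= size[1]^2,
    ellipsoid = outer3((dx / size[1])^2, (dy / size[2])^2, (dz / size[3])^2) <= 1,
    tube = outer3(dx^2, dy^2, rep(0, length(dz))) <= size[1]^2 &
      outer3(rep(0, length(dx)), rep(0, length(dy)), ifelse(inz(size[2]), 0, Inf)) <= 0,
    box = outer3(ifelse(abs(dx) <= size[1], 0, Inf),
                 ifelse(abs(dy) <= size[2], 0, Inf),
                 ifelse(abs(dz) <= size[3], 0, Inf)) <= 0,
    ring = {
      rho2 <- outer3(dx^2, dy^2, rep(0, length(dz)))
      rho2 >= size[1]^2 & rho2 <= size[2]^2 &
        outer3(rep(0, length(dx)), rep(0, length(dy)),
               ifelse(inz(size[3]), 0, Inf)) <= 0
    },
    ecylinder = outer3((dx / size[1])^2, (dy / size[2])^2, rep(0, length(dz))) <= 1 &
      outer3(rep(0, length(dx)), rep(0, length(dy)),
             ifelse(inz(size[3]), 0, Inf)) <= 0,
    seg_stop(sprintf("unknown primitive '%s'", primitive), "spec"))
  binary_mask(grid, occ)
}

rep_x <- function(v, shape) array(rep(v, times = shape[2] * shape[3]), dim = shape)
rep_y <- function(v, shape) array(rep(rep(v, each = shape[1]), times = shape[3]), dim = shape)
rep_z <- function(v, shape) array(rep(v, each = shape[1] * shape[2]), dim = shape)

# corner-rounded combination of two orthogonal 1D/2D signed distances
sdf_corner <- function(q1, q2) {
  pmin(pmax(q1, q2), 0) + sqrt(pmax(q1, 0)^2 + pmax(q2, 0)^2)
}

#' Continuum signed distance field of a primitive
#'
#' Signed Euclidean distance (mm, negative inside) from every voxel center to
#' the continuum surface of the primitive — exact for spheres, boxes, tubes
#' and rings; the standard first-order approximation for ellipsoids and
#' elliptical cylinders (exact on their axes, small error elsewhere). The
#' perturbation model operates on this field, so dilation and translation of
#' generated structures are continuum-faithful rather than lattice
#' morphology.
#'
#' @inheritParams primitive_mask
#' @return numeric array of signed distances with dim `grid$shape`.
#' @export
primitive_sdf <- function(grid, primitive, center, size) {
  shape <- grid$shape
  dx <- grid_axis_coords(grid, 1) - center[1]
  dy <- grid_axis_coords(grid, 2) - center[2]
  dz <- grid_axis_coords(grid, 3) - center[3]
  switch(primitive,
    sphere = sqrt(outer3(dx^2, dy^2, dz^2)) - size[1],
    box = {
      qx <- rep_x(abs(dx) - size[1], shape)
      qy <- rep_y(abs(dy) - size[2], shape)
      qz <- rep_z(abs(dz) - size[3], shape)
      sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2) +
        pmin(pmax(qx, pmax(qy, qz)), 0)
    },
    tube = {
      rho <- sqrt(outer(dx^2, dy^2, `+`))
      q1 <- array(rep(rho - size[1], times = shape[3]), dim = shape)
      q2 <- rep_z(abs(dz) - size[2], shape)
      sdf_corner(q1, q2)
    },
    ring = {
      rho <- sqrt(outer(dx^2, dy^2, `+`))
      rc <- (size[1] + size[2]) / 2
      q1 <- array(rep(abs(rho - rc) - (size[2] - size[1]) / 2,
                      times = shape[3]), dim = shape)
      q2 <- rep_z(abs(dz) - size[3], shape)
      sdf_corner(q1, q2)
    },
    ellipsoid = {
      k0 <- sqrt(outer3((dx / size[1])^2, (dy / size[2])^2, (dz / size[3])^2))
      k1 <- sqrt(outer3((dx / size[1]^2)^2, (dy / size[2]^2)^2, (dz / size[3]^2)^2))
      out <- k0 * (k0 - 1) / pmax(k1, 1e-12)
      out[k1 < 1e-12] <- -min(size[1:3])
      out
    },
    ecylinder = {
      k0 <- sqrt(outer((dx / size[1])^2, (dy / size[2])^2, `+`))
      k1 <- sqrt(outer((dx / size[1]^2)^2, (dy / size[2]^2)^2, `+`))
      sd2 <- k0 * (k0 - 1) / pmax(k1, 1e-12)
      sd2[k1 < 1e-12] <- -min(size[1:2])
      q1 <- array(rep(sd2, times = shape[3]), dim = shape)
      q2 <- rep_z(abs(dz) - size[3], shape)
      sdf_corner(q1, q2)
    },
    seg_stop(sprintf("unknown primitive '%s'", primitive), "spec"))
}

primitive_volume_mm3 <- function(primitive, size) {
  switch(primitive,
    sphere = 4 / 3 * pi * size[1]^3,
    ellipsoid = 4 / 3 * pi * size[1] * size[2] * size[3],
    tube = pi * size[1]^2 * 2 * size[2],
    box = 8 * size[1] * size[2] * size[3],
    ring = pi * (size[2]^2 - size[1]^2) * 2 * size[3],
    ecylinder = pi * size[1] * size[2] * 2 * size[3])
}

primitive_extent <- function(primitive, size) {
  switch(primitive,
    sphere = rep(size[1], 3),
    ellipsoid = size[1:3],
    tube = c(size[1], size[1], size[2]),
    box = size[1:3],
    ring = c(size[2], size[2], size[3]),
    ecylinder = size[1:3])
}

roster_row <- function(name, primitive, cx, cy, cz, p1, p2 = NA, p3 = NA,
                       organ_class = "serial", limit_gy = 50) {
  data.frame(name = name, primitive = primitive, cx = cx, cy = cy, cz = cz,
             p1 = p1, p2 = p2, p3 = p3, organ_class = organ_class,
             limit_gy = limit_gy, stringsAsFactors = FALSE)
}

bilateral <- function(name, primitive, cx, cy, cz, p1, p2 = NA, p3 = NA,
                      organ_class = "serial", limit_gy = 50) {
  rbind(roster_row(paste0(name, "_L"), primitive, -cx, cy, cz, p1, p2, p3, organ_class, limit_gy),
        roster_row(paste0(name, "_R"), primitive, cx, cy, cz, p1, p2, p3, organ_class, limit_gy))
}

#' The 42-structure head-and-neck OAR roster of the phantom
#'
#' A standardized-nomenclature roster of 42 head-and-neck organs-at-risk, each
#' with a shape primitive, center and size (mm) laid out in a head-shaped
#' phantom (x lateral, y anterior, z superior), an organ class driving the
#' default plan-quality objective (serial organs scored on the near-maximum
#' dose D0.03cc, parallel organs on the mean dose), and an illustrative dose
#' limit in Gy. The anatomy is schematic: positions and sizes are plausible,
#' not atlas-derived.
#'
#' @param structures optional character vector to subset the roster by name.
#' @return data.frame with 42 rows (or the requested subset).
#' @export
hn_oar_roster <- function(structures = NULL) {
  r <- rbind(
    roster_row("Brain", "ellipsoid", 0, 5, 55, 45, 52, 28, "parallel", 54),
    roster_row("Brainstem", "tube", 0, -15, 25, 8, 22, NA, "serial", 54),
    roster_row("SpinalCord", "tube", 0, -25, -30, 4.5, 52, NA, "serial", 45),
    roster_row("OpticChiasm", "box", 0, 5, 38, 10, 3, 2, "serial", 54),
    bilateral("OpticNrv", "box", 15, 12, 38, 8, 2, 2, "serial", 54),
    bilateral("Eye", "sphere", 28, 42, 38, 11, NA, NA, "serial", 45),
    bilateral("Lens", "sphere", 28, 52, 38, 4, NA, NA, "serial", 10),
    bilateral("Retina", "ring", 28, 42, 38, 9, 11, 8, "serial", 45),
    bilateral("Glnd_Lacrimal", "sphere", 38, 48, 42, 5, NA, NA, "parallel", 25),
    bilateral("Cochlea", "sphere", 42, -5, 18, 3.5, NA, NA, "serial", 35),
    bilateral("EAC", "box", 52, -5, 18, 6, 3, 3, "serial", 35),
    bilateral("Mastoid", "ellipsoid", 48, -15, 12, 7, 8, 10, "parallel", 35),
    bilateral("Parotid", "ellipsoid", 45, 0, -5, 8, 14, 18, "parallel", 26),
    bilateral("Glnd_Submand", "ellipsoid", 20, 25, -18, 8, 10, 9, "parallel", 35),
    roster_row("Cavity_Oral", "ellipsoid", 0, 35, 5, 22, 20, 12, "parallel", 30),
    roster_row("Lips", "box", 0, 58, 5, 18, 4, 8, "parallel", 20),
    roster_row("Mandible", "ring", 0, 30, -8, 24, 30, 8, "serial", 70),
    roster_row("Larynx", "ellipsoid", 0, 20, -35, 12, 12, 14, "parallel", 40),
    roster_row("Glnd_Thyroid", "ellipsoid", 0, 18, -55, 14, 6, 10, "parallel", 45),
    roster_row("Esophagus", "tube", 0, -12, -62, 5, 22, NA, "serial", 34),
    roster_row("Trachea", "tube", 0, 8, -60, 6, 24, NA, "serial", 40),
    roster_row("Musc_Constrict_S", "box", 0, 0, -18, 10, 3, 6, "parallel", 50),
    roster_row("Musc_Constrict_M", "box", 0, 0, -30, 10, 3, 6, "parallel", 50),
    roster_row("Musc_Constrict_I", "box", 0, 0, -42, 10, 3, 6, "parallel", 50),
    roster_row("Cricopharyngeus", "box", 0, 5, -48, 8, 3, 3, "parallel", 45),
    bilateral("BrachialPlex", "box", 30, -15, -60, 16, 4, 10, "serial", 66),
    bilateral("A_Carotid", "tube", 28, 5, -40, 4, 40, NA, "serial", 70),
    roster_row("Pituitary", "sphere", 0, 0, 34, 4, NA, NA, "serial", 45),
    bilateral("TMJ", "sphere", 45, 10, 10, 5, NA, NA, "serial", 70)
  )
  rownames(r) <- NULL
  if (!is.null(structures)) {
    missing <- setdiff(structures, r$name)
    if (length(missing))
      seg_stop(paste("unknown roster structures:", paste(missing, collapse = ", ")), "spec")
    r <- r[match(structures, r$name), , drop = FALSE]
  }
  r
}

#' Phantom specification
#'
#' Grid geometry plus the structure roster and target layout the generator
#' realizes. Defaults emulate the study conditions: the typical planning-CT
#' voxel of 1.27 x 1.27 x 2 mm, the 42-OAR roster, and a small rate of
#' genuinely missing structures.
#'
#' @param spacing voxel spacing, mm.
#' @param shape grid shape (the grid is centered on the world origin).
#' @param roster structure roster data.frame as from [hn_oar_roster()].
#' @param n_targets number of CTV target volumes (1-3).
#' @param gs_absence_prob per-structure probability that a structure is
#'   genuinely missing from the case (absent in the gold standard).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = c(1.27, 1.27, 2), shape = c(110, 110, 90),
                         roster = hn_oar_roster(), n_targets = 2,
                         gs_absence_prob = 0.026) {
  grid <- voxel_grid(-(shape - 1) * spacing / 2, spacing, shape)
  half_extent <- (shape - 1) * spacing / 2
  for (i in seq_len(nrow(roster))) {
    ext <- primitive_extent(roster$primitive[i],
                            c(roster$p1[i], roster$p2[i], roster$p3[i]))
    ctr <- c(roster$cx[i], roster$cy[i], roster$cz[i])
    if (any(abs(ctr) + ext > half_extent + 1e-9))
      seg_stop(sprintf("structure %s does not fit within the phantom grid", roster$name[i]),
               "spec")
  }
  if (!n_targets %in% 1:3) seg_stop("n_targets must be 1, 2 or 3", "spec")
  if (gs_absence_prob < 0 || gs_absence_prob > 1)
    seg_stop("gs_absence_prob must be in [0, 1]", "spec")
  structure(list(grid = grid, roster = roster, n_targets = n_targets,
                 gs_absence_prob = gs_absence_prob),
            class = "phantom_spec")
}

#' Compact phantom specification for small-scale experiments
#'
#' `n_structures` small spheres and ellipsoids arranged on a ring inside a
#' compact grid — the same machinery as the full head phantom at a fraction of
#' the cost, with analytic truth.
#'
#' @param n_structures number of structures (named Struct01, ...).
#' @param spacing,shape grid geometry.
#' @param gs_absence_prob per-structure missingness probability.
#' @return A `phantom_spec`.
#' @export
demo_phantom_spec <- function(n_structures = 6, spacing = c(1.27, 1.27, 2),
                              shape = c(48, 48, 28), gs_absence_prob = 0) {
  half <- (shape - 1) * spacing / 2
  ring_r <- 0.55 * min(half[1:2])
  ang <- 2 * pi * (seq_len(n_structures) - 1) / n_structures
  rows <- lapply(seq_len(n_structures), function(i) {
    if (i %% 2 == 1)
      roster_row(sprintf("Struct%02d", i), "sphere",
                 ring_r * cos(ang[i]), ring_r * sin(ang[i]), 0,
                 0.28 * min(half), NA, NA,
                 if (i %% 4 == 1) "serial" else "parallel", 40)
    else
      roster_row(sprintf("Struct%02d", i), "ellipsoid",
                 ring_r * cos(ang[i]), ring_r * sin(ang[i]), 0,
                 0.3 * min(half), 0.22 * min(half), 0.26 * min(half),
                 if (i %% 4 == 2) "serial" else "parallel", 40)
  })
  phantom_spec(spacing = spacing, shape = shape, roster = do.call(rbind, rows),
               n_targets = 1, gs_absence_prob = gs_absence_prob)
}

default_targets <- function(grid) {
  half <- (grid$shape - 1) * grid$spacing / 2
  s <- min(half) / 90  # scale relative to the full head phantom
  list(CTV1 = list(center = c(25, 20, -10) * s, radius = max(3, 16 * s)),
       CTV2 = list(center = c(-20, 10, -30) * s, radius = max(2.5, 12 * s)),
       CTV3 = list(center = c(0, -5, -50) * s, radius = max(2, 10 * s)))
}

#' Generate the gold-standard case from a phantom specification
#'
#' Deterministic given the seed (randomness enters only through absence
#' sampling). Returns the GS structure set, the body mask, the CTV masks, and
#' the analytic truth (volume and centroid of every primitive) for oracle
#' checks.
#'
#' @param spec a `phantom_spec`.
#' @param case_id case identifier.
#' @param seed integer seed for absence sampling.
#' @return list with `gs` (a `structure_set`, arm "GS"), `body`, `ctvs`
#'   (named list of masks), `truth` (data.frame: name, volume_cc, cx, cy, cz,
#'   absent), `grid`.
#' @export
generate_gs_case <- function(spec, case_id = "case01", seed = 1) {
  grid <- spec$grid
  half <- (grid$shape - 1) * grid$spacing / 2
  body <- primitive_mask(grid, "ecylinder", c(0, 0, 0),
                         c(0.95 * half[1], 0.97 * half[2], 0.97 * half[3]))
  absent <- with_seed(seed, runif(nrow(spec$roster)) < spec$gs_absence_prob)
  structures <- list()
  truth <- spec$roster[, "name", drop = FALSE]
  truth$volume_cc <- NA_real_
  truth$cx <- spec$roster$cx; truth$cy <- spec$roster$cy; truth$cz <- spec$roster$cz
  truth$absent <- absent
  for (i in seq_len(nrow(spec$roster))) {
    r <- spec$roster[i, ]
    if (absent[i]) {
      structures[[r$name]] <- absent_structure()
      next
    }
    structures[[r$name]] <- primitive_mask(grid, r$primitive,
                                           c(r$cx, r$cy, r$cz),
                                           c(r$p1, r$p2, r$p3))
    truth$volume_cc[i] <- primitive_volume_mm3(r$primitive, c(r$p1, r$p2, r$p3)) / 1000
  }
  tg <- default_targets(grid)[seq_len(spec$n_targets)]
  ctvs <- lapply(tg, function(t) primitive_mask(grid, "sphere", t$center, t$radius))
  list(gs = structure_set(case_id, "GS", structures), body = body,
       ctvs = ctvs, truth = truth, grid = grid, roster = spec$roster)
}

#' Per-arm perturbation specification
#'
#' The statistical model of one contour source's disagreement with the gold
#' standard. Per structure and case the generator draws an isotropic normal
#' translation, applies a fixed dilation (positive) or erosion (negative),
#' adds a smooth correlated radial boundary displacement (band-limited noise
#' on the signed distance, so surface metrics degrade gracefully and
#' monotonically in the amplitude), drops whole slices, and samples absence:
#' structures present in the GS are missed with `miss_prob`; structures
#' absent from the GS are hallucinated with `false_presence_prob`.
#'
#' @param translation_sd_mm per-axis SD of the random translation, mm.
#' @param dilation_mm fixed dilation (+) or erosion (-) radius, mm.
#' @param noise_amp_mm SD of the boundary displacement field, mm.
#' @param noise_corr_mm correlation length of the displacement field, mm.
#' @param slice_dropout_prob per-slice dropout probability.
#' @param miss_prob probability of omitting a GS-present structure.
#' @param false_presence_prob probability of delivering a GS-absent structure.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(translation_sd_mm = 1, dilation_mm = 0, noise_amp_mm = 1,
                     noise_corr_mm = 20, slice_dropout_prob = 0,
                     miss_prob = 0, false_presence_prob = 0) {
  probs <- c(slice_dropout_prob, miss_prob, false_presence_prob)
  if (any(probs < 0) || any(probs > 1))
    seg_stop("probabilities must be in [0, 1]", "spec")
  if (translation_sd_mm < 0 || noise_amp_mm < 0 || noise_corr_mm <= 0)
    seg_stop("amplitudes must be >= 0 and correlation length > 0", "spec")
  structure(list(translation_sd_mm = translation_sd_mm, dilation_mm = dilation_mm,
                 noise_amp_mm = noise_amp_mm, noise_corr_mm = noise_corr_mm,
                 slice_dropout_prob = slice_dropout_prob, miss_prob = miss_prob,
                 false_presence_prob = false_presence_prob),
            class = "arm_spec")
}

# smooth standard-normal random field at the voxel centers of `grid`:
# iid N(0,1) on a coarse lattice with pitch = the correlation length,
# trilinearly interpolated
smooth_field <- function(grid, corr_mm) {
  n <- pmax(2L, as.integer(ceiling((grid$shape - 1) * grid$spacing / corr_mm)) + 1L)
  coarse <- array(rnorm(prod(n)), dim = n)
  tpos <- lapply(1:3, function(a) {
    x <- (grid_axis_coords(grid, a) - grid$origin[a]) / corr_mm
    pmin(pmax(x, 0), n[a] - 1 - 1e-9)
  })
  i0 <- lapply(tpos, floor)
  f <- lapply(1:3, function(a) tpos[[a]] - i0[[a]])
  out <- array(0, dim = grid$shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx) f[[1]] else 1 - f[[1]]
    wy <- if (dy) f[[2]] else 1 - f[[2]]
    wz <- if (dz) f[[3]] else 1 - f[[3]]
    vals <- coarse[cbind(rep(i0[[1]] + dx + 1, times = prod(grid$shape[2:3])),
                         rep(rep(i0[[2]] + dy + 1, each = grid$shape[1]),
                             times = grid$shape[3]),
                         rep(i0[[3]] + dz + 1, each = prod(grid$shape[1:2])))]
    out <- out + array(vals, dim = grid$shape) * outer3_w(wx, wy, wz)
  }
  out
}

outer3_w <- function(wx, wy, wz) {
  array(outer(outer(wx, wy, `*`), wz, `*`), dim = c(length(wx), length(wy), length(wz)))
}

signed_distance <- function(occ, spacing) {
  d_out <- sqrt(distance_map_sq(occ, spacing))      # 0 inside, dist outside
  d_in <- sqrt(distance_map_sq(!occ, spacing))      # 0 outside, dist inside
  d_out - d_in
}

#' Perturb one mask with the arm disagreement model
#'
#' Applies, in order: translation (exact for voxel-multiple shifts),
#' dilation/erosion by a Euclidean radius, correlated boundary displacement
#' (threshold shift of the signed distance by a smooth field), and slice
#' dropout. Deterministic given the current RNG state.
#'
#' @param mask a `binary_mask`.
#' @param translation numeric(3) translation, mm.
#' @param dilation_mm Euclidean dilation (+) / erosion (-) radius, mm.
#' @param noise_amp_mm,noise_corr_mm boundary displacement SD and correlation
#'   length, mm.
#' @param slice_dropout_prob per-slice dropout probability.
#' @return A perturbed `binary_mask` on the same grid.
#' @export
perturb_mask <- function(mask, translation = c(0, 0, 0), dilation_mm = 0,
                         noise_amp_mm = 0, noise_corr_mm = 20,
                         slice_dropout_prob = 0) {
  grid <- mask$grid
  occ <- mask$occupancy
  if (any(translation != 0)) {
    shifted <- binary_mask(voxel_grid(grid$origin + translation, grid$spacing,
                                      grid$shape), occ)
    occ <- resample_nearest(shifted, grid)$occupancy
  }
  if (dilation_mm > 0 && any(occ)) {
    occ <- distance_map_sq(occ, grid$spacing) <= dilation_mm^2 + 1e-9
  } else if (dilation_mm < 0 && any(occ)) {
    occ <- occ & (distance_map_sq(!occ, grid$spacing) > dilation_mm^2 + 1e-9)
  }
  if (noise_amp_mm > 0 && any(occ)) {
    g <- smooth_field(grid, noise_corr_mm)
    occ <- signed_distance(occ, grid$spacing) <= noise_amp_mm * g
  }
  if (slice_dropout_prob > 0 && any(occ)) {
    zs <- which(apply(occ, 3, any))
    drop <- zs[runif(length(zs)) < slice_dropout_prob]
    occ[, , drop] <- FALSE
  }
  binary_mask(grid, occ)
}

#' Realize a perturbed primitive directly from its signed distance field
#'
#' The structure-level perturbation used by the cohort generator: translation
#' moves the continuum primitive, dilation (+) / erosion (-) shifts the
#' signed-distance threshold, and correlated boundary noise displaces the
#' threshold by a smooth random field — all applied before rasterization, so
#' a dilation by r of a sphere of radius R is a sphere of radius R + r up to
#' pure voxelization error, and a voxel-multiple translation is exact. Slice
#' dropout is applied on the raster. Uses the current RNG state.
#'
#' @inheritParams primitive_mask
#' @inheritParams perturb_mask
#' @return A `binary_mask`.
#' @export
perturb_primitive <- function(grid, primitive, center, size,
                              translation = c(0, 0, 0), dilation_mm = 0,
                              noise_amp_mm = 0, noise_corr_mm = 20,
                              slice_dropout_prob = 0) {
  sd <- primitive_sdf(grid, primitive, center + translation, size)
  thr <- dilation_mm
  if (noise_amp_mm > 0) {
    thr <- thr + noise_amp_mm * smooth_field(grid, noise_corr_mm)
  }
  occ <- sd <= thr
  if (slice_dropout_prob > 0 && any(occ)) {
    zs <- which(apply(occ, 3, any))
    drop <- zs[runif(length(zs)) < slice_dropout_prob]
    occ[, , drop] <- FALSE
  }
  binary_mask(grid, occ)
}

#' Perturb a gold-standard case into one arm's structure set
#'
#' Draws per-structure perturbation parameters from the arm specification and
#' applies them; records every applied ground-truth parameter for recovery
#' testing.
#'
#' @param gs_case a case bundle from [generate_gs_case()].
#' @param spec an `arm_spec`.
#' @param arm arm label for the returned set.
#' @param seed integer seed.
#' @return A `structure_set`; the applied parameters in `attr(, "applied")`
#'   (data.frame: structure, tx, ty, tz, dilation_mm, noise_amp_mm, absent).
#' @export
perturb_case <- function(gs_case, spec, arm = "ARM", seed = 1) {
  gs <- gs_case$gs
  roster <- gs_case$roster
  with_seed(seed, {
    structures <- list()
    rows <- list()
    for (nm in names(gs$structures)) {
      s <- gs$structures[[nm]]
      r <- roster[roster$name == nm, ]
      tr <- c(0, 0, 0); absent_out <- FALSE
      deliver <- if (is_absent(s)) runif(1) < spec$false_presence_prob
                 else runif(1) >= spec$miss_prob
      if (deliver) {
        tr <- rnorm(3, 0, spec$translation_sd_mm)
        structures[[nm]] <- perturb_primitive(
          gs_case$grid, r$primitive, c(r$cx, r$cy, r$cz), c(r$p1, r$p2, r$p3),
          translation = tr, dilation_mm = spec$dilation_mm,
          noise_amp_mm = spec$noise_amp_mm, noise_corr_mm = spec$noise_corr_mm,
          slice_dropout_prob = spec$slice_dropout_prob)
      } else {
        structures[[nm]] <- absent_structure()
        absent_out <- TRUE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        structure = nm, tx = tr[1], ty = tr[2], tz = tr[3],
        dilation_mm = spec$dilation_mm, noise_amp_mm = spec$noise_amp_mm,
        absent = absent_out, stringsAsFactors = FALSE)
    }
    out <- structure_set(gs$case_id, arm, structures)
    attr(out, "applied") <- do.call(rbind, rows)
    out
  })
}

#' Dose-model specification
#'
#' `uniform`: the first prescription everywhere. `ramp`: linear in z from 0
#' to the maximum prescription across the grid (slab mean doses analytically
#' known). `blobs`: one Gaussian falloff per target, full prescription inside
#' the CTV (monotone in distance from each target).
#'
#' @param model "blobs", "uniform" or "ramp".
#' @param prescriptions_gy per-target prescription levels, Gy (study range
#'   54-72 Gy).
#' @param sigma_mm Gaussian falloff scale for the blob model.
#' @return An object of class `dose_model_spec`.
#' @export
dose_model_spec <- function(model = c("blobs", "uniform", "ramp"),
                            prescriptions_gy = c(70, 60), sigma_mm = 15) {
  model <- match.arg(model)
  if (any(prescriptions_gy < 0)) seg_stop("prescriptions must be >= 0", "spec")
  structure(list(model = model, prescriptions_gy = prescriptions_gy,
                 sigma_mm = sigma_mm),
            class = "dose_model_spec")
}

#' Generate a dose field for a case
#' @param gs_case a case bundle from [generate_gs_case()].
#' @param spec a `dose_model_spec`; prescriptions are recycled/truncated to
#'   the case's targets.
#' @return A `dose_grid` on the case grid.
#' @export
generate_dose <- function(gs_case, spec = dose_model_spec()) {
  grid <- gs_case$grid
  presc <- rep(spec$prescriptions_gy, length.out = length(gs_case$ctvs))
  d <- switch(spec$model,
    uniform = array(spec$prescriptions_gy[1], dim = grid$shape),
    ramp = {
      z <- grid_axis_coords(grid, 3)
      zr <- (z - z[1]) / (z[length(z)] - z[1])
      array(rep(max(spec$prescriptions_gy) * zr,
                each = prod(grid$shape[1:2])), dim = grid$shape)
    },
    blobs = {
      acc <- array(0, dim = grid$shape)
      for (i in seq_along(gs_case$ctvs)) {
        dist <- sqrt(distance_map_sq(gs_case$ctvs[[i]]$occupancy, grid$spacing))
        acc <- acc + presc[i] * exp(-dist^2 / (2 * spec$sigma_mm^2))
      }
      acc
    })
  dose_grid(grid, d)
}

#' Timing model for the contouring workflow
#'
#' Standard-arm initial and revision durations are lognormal with the stated
#' means (hours); the experimental arm takes the standard total scaled by
#' 1 - s/100, where the per-case savings s follows a normal distribution
#' truncated above at `max_savings_pct` (durations must stay positive), with
#' its location solved so that the true mean savings equals
#' `true_savings_pct` exactly.
#'
#' @param std_initial_mean_h,std_revision_mean_h standard-arm mean durations.
#' @param std_initial_sdlog,std_revision_sdlog lognormal shape parameters.
#' @param true_savings_pct,savings_sd_pct mean and pre-truncation SD of the
#'   per-case savings, %.
#' @param max_savings_pct upper truncation of per-case savings, %.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(std_initial_mean_h = 2.3, std_initial_sdlog = 0.2,
                         std_revision_mean_h = 1.1, std_revision_sdlog = 0.5,
                         true_savings_pct = 76, savings_sd_pct = 24,
                         max_savings_pct = 99) {
  if (true_savings_pct >= max_savings_pct)
    seg_stop("true_savings_pct must lie below max_savings_pct", "spec")
  trunc_mean <- function(mu) {
    a <- (max_savings_pct - mu) / savings_sd_pct
    mu - savings_sd_pct * stats::dnorm(a) / stats::pnorm(a)
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - true_savings_pct,
                       c(true_savings_pct, max_savings_pct + 6 * savings_sd_pct),
                       tol = 1e-10)$root
  structure(list(std_initial_mean_h = std_initial_mean_h,
                 std_initial_sdlog = std_initial_sdlog,
                 std_revision_mean_h = std_revision_mean_h,
                 std_revision_sdlog = std_revision_sdlog,
                 true_savings_pct = true_savings_pct,
                 savings_sd_pct = savings_sd_pct,
                 max_savings_pct = max_savings_pct,
                 mu_pct = mu),
            class = "timing_model")
}

#' True mean of the per-case savings distribution
#' @param tm a `timing_model`.
#' @return true mean per-case savings, percent (equals the requested
#'   `true_savings_pct` by construction).
#' @export
timing_true_mean_savings <- function(tm) {
  a <- (tm$max_savings_pct - tm$mu_pct) / tm$savings_sd_pct
  tm$mu_pct - tm$savings_sd_pct * stats::dnorm(a) / stats::pnorm(a)
}

rtrunc_upper <- function(n, mean, sd, upper) {
  stats::qnorm(runif(n) * stats::pnorm((upper - mean) / sd)) * sd + mean
}

generate_timing <- function(tm, case_ids, std_arm = "MDA+RO", exp_arm = "DL+RO") {
  n <- length(case_ids)
  mlog <- function(m, s) log(m) - s^2 / 2
  init <- rlnorm(n, mlog(tm$std_initial_mean_h, tm$std_initial_sdlog), tm$std_initial_sdlog)
  rev_ <- rlnorm(n, mlog(tm$std_revision_mean_h, tm$std_revision_sdlog), tm$std_revision_sdlog)
  s <- rtrunc_upper(n, tm$mu_pct, tm$savings_sd_pct, tm$max_savings_pct)
  std_total <- init + rev_
  exp_total <- std_total * (1 - s / 100)
  rbind(
    do.call(rbind, lapply(seq_len(n), function(i)
      timing_record(case_ids[i], std_arm, init[i], rev_[i]))),
    do.call(rbind, lapply(seq_len(n), function(i)
      timing_record(case_ids[i], exp_arm, 0, exp_total[i]))))
}

default_arm_specs <- function() {
  list(
    "DL" = arm_spec(translation_sd_mm = 0.6, noise_amp_mm = 0.8,
                    miss_prob = 0, false_presence_prob = 0.32),
    "DL+RO" = arm_spec(translation_sd_mm = 0.8, noise_amp_mm = 1.0,
                       miss_prob = 0, false_presence_prob = 0.1),
    "MDA+RO" = arm_spec(translation_sd_mm = 1.8, dilation_mm = -0.5,
                        noise_amp_mm = 2.2, miss_prob = 0.02,
                        false_presence_prob = 0.05))
}

#' Generate a full synthetic study cohort
#'
#' Per case: the gold-standard structure set, one perturbed structure set per
#' arm with independently drawn perturbations, a dose field, and timing
#' records; plus the pooled ground-truth perturbation table for recovery
#' testing. Fully deterministic given the seed. The default arm ordering
#' (unrevised model closest to GS, revised model close, manual arm farthest)
#' mirrors the study design the cohort emulates.
#'
#' @param n_cases number of cases (study default 19 analyzable cases).
#' @param phantom a `phantom_spec`.
#' @param arms named list of `arm_spec` objects.
#' @param dose a `dose_model_spec`.
#' @param timing a `timing_model`.
#' @param seed integer master seed.
#' @return An object of class `synthetic_cohort`: list with `cases` (each:
#'   `case_id`, `gs_case`, `arms`, `dose`), `timing`, `truth`, `phantom`,
#'   `arm_specs`.
#' @export
generate_cohort <- function(n_cases = 19, phantom = phantom_spec(),
                            arms = default_arm_specs(),
                            dose = dose_model_spec(), timing = timing_model(),
                            seed = 1) {
  if (n_cases < 1) seg_stop("n_cases must be >= 1", "spec")
  case_ids <- sprintf("case%02d", seq_len(n_cases))
  cases <- vector("list", n_cases)
  truth_rows <- list()
  for (i in seq_len(n_cases)) {
    gsc <- generate_gs_case(phantom, case_ids[i], seed = seed + 1000L * i)
    gsc$roster <- phantom$roster
    arm_sets <- list()
    for (j in seq_along(arms)) {
      nm <- names(arms)[j]
      arm_sets[[nm]] <- perturb_case(gsc, arms[[j]], arm = nm,
                                     seed = seed + 1000L * i + j)
      ap <- attr(arm_sets[[nm]], "applied")
      ap$case <- case_ids[i]; ap$arm <- nm
      truth_rows[[length(truth_rows) + 1L]] <- ap
    }
    cases[[i]] <- list(case_id = case_ids[i], gs_case = gsc, arms = arm_sets,
                       dose = generate_dose(gsc, dose))
  }
  timing_tab <- with_seed(seed + 777L, generate_timing(timing, case_ids))
  structure(list(cases = cases, timing = timing_tab,
                 truth = do.call(rbind, truth_rows), phantom = phantom,
                 arm_specs = arms, timing_spec = timing, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d cases, %d structures, arms: %s\n",
              length(x$cases), nrow(x$phantom$roster),
              paste(names(x$arm_specs), collapse = ", ")))
  invisible(x)
}

#' Geometric metric table for a whole cohort
#' @param cohort a `synthetic_cohort`.
#' @param config a [metric_config()].
#' @return long-format data.frame over all cases, arms and structures.
#' @export
cohort_metric_table <- function(cohort, config = metric_config()) {
  rows <- lapply(cohort$cases, function(cs) {
    do.call(rbind, lapply(cs$arms, function(a)
      suppressMessages(compare_structure_sets(a, cs$gs_case$gs, config))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dosimetric delta table for a whole cohort
#'
#' PTVs are built from the CTVs with the uniform margin cropped to the body;
#' the default plan-quality template is derived from the roster's organ
#' classes and limits plus one goal objective per target.
#'
#' @param cohort a `synthetic_cohort`.
#' @param template optional `pqm_template`; defaults to
#'   [default_hn_pqm_template()] for the cohort roster and prescriptions.
#' @param ptv_margin_mm uniform CTV-to-PTV margin, mm.
#' @return long data.frame: case, structure, arm, metric, value (structure NA
#'   for the case-level NPQM delta).
#' @export
cohort_dose_table <- function(cohort, template = NULL, ptv_margin_mm = 3) {
  if (is.null(template))
    template <- default_hn_pqm_template(
      cohort$phantom$roster,
      targets = setNames(
        rep(60, cohort$phantom$n_targets),
        paste0("CTV", seq_len(cohort$phantom$n_targets))))
  rows <- list()
  for (cs in cohort$cases) {
    gsc <- cs$gs_case
    ptvs <- lapply(gsc$ctvs, expand_ptv, margin = ptv_margin_mm, body = gsc$body)
    for (nm in names(cs$arms)) {
      dd <- suppressMessages(
        dosimetric_deltas(augment_targets(cs$arms[[nm]], gsc$ctvs),
                          augment_targets(gsc$gs, gsc$ctvs),
                          cs$dose, ptvs, template))
      if (nrow(dd$structures)) {
        rows[[length(rows) + 1L]] <- data.frame(
          case = cs$case_id, structure = dd$structures$structure, arm = nm,
          metric = "delta_dmean_gy", value = dd$structures$delta_dmean_gy,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          case = cs$case_id, structure = dd$structures$structure, arm = nm,
          metric = "delta_dhot_gy", value = dd$structures$delta_dhot_gy,
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        case = cs$case_id, structure = NA_character_, arm = nm,
        metric = "delta_npqm_pct", value = dd$delta_npqm_pct,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# target volumes are shared across arms (taken from the delivered plan), so
# NPQM differences between arms come from the OARs alone
augment_targets <- function(set, ctvs) {
  st <- set$structures
  for (nm in names(ctvs)) st[[nm]] <- ctvs[[nm]]
  out <- structure_set(set$case_id, set$arm, st)
  out
}

#' Default head-and-neck plan-quality template
#'
#' One objective per roster OAR — serial organs capped on the near-maximum
#' dose D0.03cc, parallel organs on the mean dose, at the roster's
#' illustrative limit — plus one goal objective per target (mean dose at
#' least 98% of prescription, weighted 4 points). Illustrative, not an
#' institutional protocol.
#'
#' @param roster roster data.frame with `name`, `organ_class`, `limit_gy`.
#' @param targets named numeric vector of target prescriptions (Gy); names
#'   must match target structure names.
#' @param ramp_gy optional width of a linear partial-credit ramp beyond each
#'   OAR limit (NULL for binary scoring, the default).
#' @return A `pqm_template`.
#' @export
default_hn_pqm_template <- function(roster = hn_oar_roster(), targets = NULL,
                                    ramp_gy = NULL) {
  objs <- lapply(seq_len(nrow(roster)), function(i) {
    stat <- if (roster$organ_class[i] == "serial") "D0.03cc" else "Dmean"
    pqm_objective(roster$name[i], stat, "<=", roster$limit_gy[i], points = 1,
                  zero_threshold = if (is.null(ramp_gy)) NULL else
                    roster$limit_gy[i] + ramp_gy)
  })
  if (!is.null(targets)) {
    objs <- c(objs, lapply(names(targets), function(nm)
      pqm_objective(nm, "Dmean", ">=", 0.98 * targets[[nm]], points = 4,
                    target = TRUE)))
  }
  pqm_template(objs, id = "hn-default")
}
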
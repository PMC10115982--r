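test_that("volumetric Dice matches trivial and closed-form lens values", {
  g <- iso_grid(12)
  m <- cube_mask(g, c(3, 3, 3), c(8, 8, 8))
  expect_equal(volumetric_dice(m, m), 1.0)
  far <- cube_mask(g, c(10, 10, 10), c(12, 12, 12))
  expect_equal(volumetric_dice(m, far), 0.0)
  expect_error(volumetric_dice(binary_mask(g), binary_mask(g)),
               class = "segeval_empty_mask")

  # equal spheres R = 10 mm, centers d = 5 mm apart, 1 mm grid: the lens
  # (spherical-cap intersection) volume gives DSC = 2*Vcap/(2V) = 0.6328
  gs <- voxel_grid(c(-14, -14, -14), c(1, 1, 1), c(34, 34, 34))
  a <- sphere_mask(gs, c(0, 0, 0), 10)
  b <- sphere_mask(gs, c(5, 0, 0), 10)
  R <- 10; d <- 5
  lens <- pi / 12 * (4 * R + d) * (2 * R - d)^2
  dsc_analytic <- 2 * lens / (2 * 4 / 3 * pi * R^3)
  expect_equal(dsc_analytic, 0.6328, tolerance = 1e-4)
  expect_lt(abs(volumetric_dice(a, b) - dsc_analytic), 0.01)
})

test_that("surface Dice: identity, separation, and exact agreement with all-pairs", {
  g <- iso_grid(16)
  cube <- cube_mask(g, c(4, 4, 4), c(13, 13, 13))
  expect_equal(surface_dice(cube, cube, 1), 1.0)
  expect_equal(surface_dice(cube, cube, 0.25), 1.0)
  gbig <- iso_grid(24)
  a <- cube_mask(gbig, c(1, 1, 1), c(4, 4, 4))
  b <- cube_mask(gbig, c(18, 18, 18), c(22, 22, 22))
  expect_equal(surface_dice(a, b, 2), 0.0)
  expect_error(surface_dice(cube, cube, 0), class = "segeval_invalid_parameter")
  expect_error(surface_dice(cube, binary_mask(g), 1), class = "segeval_empty_mask")

  # 10-voxel cube vs itself translated 2 voxels, tau = 1 mm: the
  # distance-transform value must equal the brute-force all-pairs value
  shifted <- translate_mask(cube, c(2, 0, 0))
  expect_identical(surface_dice(shifted, cube, 1), bf_surface_dice(shifted, cube, 1))
})

test_that("HD95: trivial distances and percentile definition", {
  g <- iso_grid(10)
  m <- cube_mask(g, c(3, 3, 3), c(7, 7, 7))
  expect_equal(hausdorff95(m, m), 0.0)
  a <- cube_mask(g, c(2, 2, 2), c(2, 2, 2))
  b <- cube_mask(g, c(5, 2, 2), c(5, 2, 2))
  expect_equal(hausdorff95(a, b), 3.0)
  expect_error(hausdorff95(m, binary_mask(g)), class = "segeval_empty_mask")
  # HD95 never exceeds the exact Hausdorff (100th percentile)
  set.seed(31)
  gg <- aniso_grid(14)
  x <- random_blob_mask(gg); y <- random_blob_mask(gg)
  expect_lte(hausdorff95(x, y), hausdorff95(x, y, probs = 1))
})

test_that("APL: identity, empty candidate, and shifted-ring brute force", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(16, 16, 5))
  ring_occ <- array(FALSE, dim = g$shape)
  ring_occ[4:13, 4:13, 3] <- TRUE
  ring_occ[5:12, 5:12, 3] <- FALSE   # 10 x 10 px square ring, one slice
  ring <- binary_mask(g, ring_occ)
  expect_equal(added_path_length(ring, ring, 1), 0.0)
  expect_equal(added_path_length(ring, ring, 0), 0.0)
  # empty candidate: full reference path length = 36 boundary px * 1 mm
  expect_equal(added_path_length(binary_mask(g), ring, 1), 36.0)
  expect_error(added_path_length(ring, binary_mask(g), 1),
               class = "segeval_empty_mask")
  shifted <- translate_mask(ring, c(2, 0, 0))
  expect_identical(added_path_length(shifted, ring, 1),
                   bf_added_path_length(shifted, ring, 1))
  # APL is reference-anchored, not symmetric in general
  g2 <- iso_grid(14)
  a <- cube_mask(g2, c(3, 3, 3), c(10, 10, 10))
  b <- sphere_mask(g2, c(6.5, 6.5, 6.5), 5)
  expect_false(isTRUE(all.equal(added_path_length(a, b, 1),
                                added_path_length(b, a, 1))))
})

test_that("contour Dice: identity, separation, dilated-cube brute force", {
  g <- iso_grid(16)
  cube <- cube_mask(g, c(5, 5, 5), c(11, 11, 11))
  expect_equal(contour_dice(cube, cube, 1), 1.0)
  a <- cube_mask(g, c(1, 1, 1), c(3, 3, 3))
  b <- cube_mask(g, c(12, 12, 12), c(15, 15, 15))
  expect_equal(contour_dice(a, b, 1), 0.0)
  dil <- cube_mask(g, c(4, 4, 4), c(12, 12, 12))
  expect_identical(contour_dice(dil, cube, 1), bf_contour_dice(dil, cube, 1))
  expect_error(contour_dice(cube, cube, 0), class = "segeval_invalid_parameter")
})

test_that("voxel confusion: identity, containment, hand-counted toy masks", {
  g <- iso_grid(8)
  m <- cube_mask(g, c(3, 3, 3), c(6, 6, 6))
  cf <- voxel_confusion(m, m)
  expect_equal(unlist(cf), c(precision = 1, sensitivity = 1, specificity = 1))

  sup <- cube_mask(g, c(2, 2, 2), c(7, 7, 7))  # superset of m
  cf2 <- voxel_confusion(sup, m)
  expect_equal(cf2$sensitivity, 1)
  expect_lt(cf2$precision, 1)

  # hand count: candidate 2x2x2 at corner, reference 2x2x2 overlapping 1 voxel
  a <- cube_mask(g, c(1, 1, 1), c(2, 2, 2))
  b <- cube_mask(g, c(2, 2, 2), c(3, 3, 3))
  cf3 <- voxel_confusion(a, b)  # TP = 1, FP = 7, FN = 7, TN = 497
  expect_equal(cf3$precision, 1 / 8)
  expect_equal(cf3$sensitivity, 1 / 8)
  expect_equal(cf3$specificity, 497 / (497 + 7))

  # degenerate cases yield NA markers, not zeros
  empty <- binary_mask(g)
  cf4 <- voxel_confusion(empty, m)
  expect_true(is.na(cf4$precision))
  expect_equal(cf4$sensitivity, 0)
})

test_that("volume and centroid deltas are signed/metric as specified", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(20, 20, 20))
  m <- cube_mask(g, c(4, 4, 4), c(13, 13, 13))
  expect_equal(delta_volume(m, m), 0)
  expect_equal(delta_centroid(m, m), 0)
  # 500 extra 1x1x2 mm voxels = +1.0 cc
  extra <- m$occupancy
  extra[1:5, 14:18, 1:20] <- TRUE  # 500 voxels, disjoint from m in y
  big <- binary_mask(g, extra | m$occupancy)
  expect_equal(delta_volume(big, m), 500 * 2 / 1000)
  expect_lt(delta_volume(m, big), 0)
  shifted <- translate_mask(m, c(3, 4, 0))  # (3, 4, 0) voxel steps = (3, 4, 0) mm
  expect_equal(delta_centroid(shifted, m), 5.0)  # 3-4-5 triangle
  expect_error(delta_centroid(binary_mask(g), m), class = "segeval_empty_mask")
})

test_that("metric battery: symmetry, monotonicity, translation invariance", {
  set.seed(41)
  for (rep in 1:4) {
    g <- aniso_grid(12)
    a <- random_blob_mask(g)
    b <- random_blob_mask(g)
    tau <- runif(1, 0.8, 3)
    expect_equal(volumetric_dice(a, b), volumetric_dice(b, a))
    expect_equal(surface_dice(a, b, tau), surface_dice(b, a, tau))
    expect_equal(hausdorff95(a, b), hausdorff95(b, a))
    expect_equal(contour_dice(a, b, tau), contour_dice(b, a, tau))
    # monotonicity in tolerance
    taus <- c(0.5, 1, 2, 4)
    expect_true(all(diff(surface_dice(a, b, taus)) >= 0))
    expect_true(all(diff(added_path_length(a, b, taus)) <= 0))
    # joint voxel-aligned translation leaves every metric unchanged
    st <- c(2, 1, 1)
    at <- translate_mask(a, st); bt <- translate_mask(b, st)
    near_edge <- sum(at$occupancy) != sum(a$occupancy) ||
      sum(bt$occupancy) != sum(b$occupancy)
    if (!near_edge) {
      expect_equal(volumetric_dice(at, bt), volumetric_dice(a, b))
      expect_equal(surface_dice(at, bt, tau), surface_dice(a, b, tau))
      expect_equal(hausdorff95(at, bt), hausdorff95(a, b))
      expect_equal(added_path_length(at, bt, tau), added_path_length(a, b, tau))
    }
  }
})

test_that("compare_structure_sets filters to common present structures and matches single ops", {
  set.seed(51)
  g <- aniso_grid(14)
  ref_masks <- setNames(lapply(1:5, function(i) random_blob_mask(g)),
                        paste0("S", 1:5))
  cand_masks <- lapply(ref_masks, function(m)
    perturb_mask(m, translation = c(1.27, 0, 0)))
  names(cand_masks) <- names(ref_masks)
  ref <- structure_set("c1", "GS", ref_masks)

  # candidate missing 2 of 5 structures: exactly 3 structures emitted
  cand3 <- structure_set("c1", "DL",
                         c(cand_masks[1:3],
                           list(S4 = absent_structure(), S5 = absent_structure())))
  res <- suppressMessages(compare_structure_sets(cand3, ref))
  expect_setequal(unique(res$structure), c("S1", "S2", "S3"))
  expect_setequal(attr(res, "skipped"), c("S4", "S5"))

  # self-comparison: all Dice-family metrics 1, all distances 0
  self <- suppressMessages(compare_structure_sets(
    structure_set("c1", "GS2", ref_masks), ref))
  expect_true(all(self$value[self$metric %in% c("VDSC", "SDSC", "CDC")] == 1))
  expect_true(all(self$value[self$metric %in%
                               c("HD95", "APL", "delta_centroid", "delta_volume")] == 0))

  # battery values match the single-operation calls
  full <- suppressMessages(compare_structure_sets(
    structure_set("c1", "DL", cand_masks), ref))
  s2 <- full[full$structure == "S2", ]
  expect_equal(s2$value[s2$metric == "VDSC"],
               volumetric_dice(cand_masks$S2, ref_masks$S2))
  expect_equal(s2$value[s2$metric == "SDSC" & s2$parameter_mm == 2],
               surface_dice(cand_masks$S2, ref_masks$S2, 2))
  expect_equal(s2$value[s2$metric == "HD95"],
               hausdorff95(cand_masks$S2, ref_masks$S2))
  expect_equal(s2$value[s2$metric == "APL" & s2$parameter_mm == 3],
               added_path_length(cand_masks$S2, ref_masks$S2, 3))
  # default battery: SDSC at 4 taus, APL at 4 tolerances, CDC at 1 mm
  expect_equal(sum(s2$metric == "SDSC"), 4)
  expect_equal(sum(s2$metric == "APL"), 4)
  expect_equal(s2$parameter_mm[s2$metric == "CDC"], 1)
})
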
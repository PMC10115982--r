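test_that("PTV expansion is Euclidean, cropped to body, and margin-0 is intersection", {
  g <- iso_grid(24)
  body_all <- binary_mask(g, array(TRUE, dim = g$shape))
  ctv <- cube_mask(g, c(8, 8, 8), c(17, 17, 17))  # 10 mm cube
  expect_identical(expand_ptv(ctv, 0, body_all)$occupancy, ctv$occupancy)

  ptv <- expand_ptv(ctv, 3, body_all)
  # brute-force Euclidean dilation oracle
  centers <- mask_voxel_centers(ctv)
  grid_pts <- mask_voxel_centers(body_all)
  d <- bf_min_dists(grid_pts, centers)
  expect_equal(sum(ptv$occupancy), sum(d <= 3 + 1e-9))
  # bounding extent grows by exactly 3 voxels per side on a 1 mm grid
  idx <- which(ptv$occupancy, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(5, 20))

  # cropping: body that cuts the expansion
  body_half <- binary_mask(g, array(rep(c(TRUE, FALSE), c(12, 12)), dim = g$shape))
  ptv2 <- expand_ptv(ctv, 3, body_half)
  expect_identical(ptv2$occupancy, ptv$occupancy & body_half$occupancy)
  expect_error(expand_ptv(ctv, -1, body_all), class = "segeval_invalid_parameter")
})

test_that("OAR evaluation region applies the 0.1 cc exclusion rule", {
  g <- iso_grid(20)
  oar <- cube_mask(g, c(2, 2, 2), c(6, 6, 6))
  far_ptv <- cube_mask(g, c(14, 14, 14), c(18, 18, 18))
  r <- oar_eval_region(oar, list(far_ptv))
  expect_identical(r$occupancy, oar$occupancy)

  covering <- cube_mask(g, c(1, 1, 1), c(8, 8, 8))
  expect_true(is_excluded(oar_eval_region(oar, list(covering))))

  # 0.25 cc OAR with 0.20 cc overlapped: 0.05 cc residue < 0.1 cc -> excluded
  oar2 <- cube_mask(g, c(1, 1, 1), c(5, 5, 10))   # 250 voxels = 0.25 cc
  ptv2 <- cube_mask(g, c(1, 1, 1), c(5, 5, 8))    # overlaps 200 voxels
  r2 <- oar_eval_region(oar2, list(ptv2))
  expect_true(is_excluded(r2))
  expect_equal(r2$volume_cc, 0.05)
})

test_that("DVH is exact, conserving, and statistics match hand constructions", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(10, 10, 10))
  uni <- dose_grid(g, array(60, dim = g$shape))
  region <- cube_mask(g, c(2, 2, 2), c(7, 7, 7))
  cv <- cumulative_dvh(region, uni)
  expect_equal(cv$total_cc, mask_volume_cc(region))
  expect_equal(dvh_volume_at(cv, 0), cv$total_cc)
  expect_equal(dvh_volume_at(cv, 60), cv$total_cc)
  expect_equal(dvh_volume_at(cv, 60.01), 0)
  expect_equal(dose_stat(cv, "Dmean"), 60)
  expect_equal(dose_stat(cv, "D0.03cc"), 60)

  # two-voxel region, doses 10 and 20 Gy, 2 mm^3 voxels
  occ <- array(FALSE, dim = g$shape); occ[1, 1, 1] <- TRUE; occ[2, 1, 1] <- TRUE
  dd <- array(0, dim = g$shape); dd[1, 1, 1] <- 10; dd[2, 1, 1] <- 20
  cv2 <- cumulative_dvh(binary_mask(g, occ), dose_grid(g, dd))
  expect_equal(dvh_volume_at(cv2, 10), 0.004)
  expect_equal(dvh_volume_at(cv2, 20), 0.002)

  # hottest voxel 70 Gy occupying 0.05 cc (25 voxels of 2 mm^3): D0.03cc = 70
  occ3 <- array(FALSE, dim = g$shape); occ3[1:10, 1:5, 1] <- TRUE
  d3 <- array(0, dim = g$shape); d3[occ3] <- 30; d3[1:5, 1:5, 1] <- 70
  cv3 <- cumulative_dvh(binary_mask(g, occ3), dose_grid(g, d3))
  expect_equal(dose_stat(cv3, "D0.03cc"), 70)
  expect_error(dose_stat(cv3, "D5cc"), class = "segeval_invalid_query")
  expect_error(cumulative_dvh(binary_mask(g), uni), class = "segeval_empty_mask")

  # linear ramp 0 -> 60 Gy across a slab: Dmean = midpoint within one step
  gr <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(8, 8, 30))
  z <- grid_axis_coords(gr, 3)
  ramp <- dose_grid(gr, array(rep(60 * (z - z[1]) / (z[30] - z[1]),
                                  each = 64), dim = gr$shape))
  slab <- binary_mask(gr, array(TRUE, dim = gr$shape))
  cvr <- cumulative_dvh(slab, ramp)
  expect_lt(abs(dose_stat(cvr, "Dmean") - 30), 60 / 29)
  # Dxcc non-increasing in x; Dmean invariant under dose permutation
  expect_true(dose_stat(cvr, "D0.03cc") >= dose_stat(cvr, "D1cc"))
  set.seed(61)
  dp <- array(sample(as.numeric(ramp$dose)), dim = gr$shape)
  expect_equal(dose_stat(cumulative_dvh(slab, dose_grid(gr, dp)), "Dmean"),
               dose_stat(cvr, "Dmean"))
})

test_that("PQM scoring: full credit, zero, linear ramp midpoint, NPQM normalization", {
  g <- iso_grid(16)
  m1 <- cube_mask(g, c(2, 2, 2), c(7, 7, 7))
  m2 <- cube_mask(g, c(9, 9, 9), c(14, 14, 14))
  dd <- array(20, dim = g$shape); dd[9:14, 9:14, 9:14] <- 50
  dose <- dose_grid(g, dd)
  ss <- structure_set("c1", "GS", list(A = m1, B = m2))

  tmpl_ok <- pqm_template(list(pqm_objective("A", "Dmean", "<=", 30),
                               pqm_objective("B", "Dmean", "<=", 60)))
  s <- pqm_score(ss, dose, tmpl_ok)
  expect_equal(s$achieved, s$maximum)
  expect_equal(npqm(ss, dose, tmpl_ok), 100)

  tmpl_bad <- pqm_template(list(pqm_objective("A", "Dmean", "<=", 10),
                                pqm_objective("B", "Dmean", "<=", 10)))
  expect_equal(pqm_score(ss, dose, tmpl_bad)$achieved, 0)

  # half the equal-weighted objectives met -> NPQM 50
  tmpl_half <- pqm_template(list(pqm_objective("A", "Dmean", "<=", 30),
                                 pqm_objective("B", "Dmean", "<=", 10)))
  expect_equal(npqm(ss, dose, tmpl_half), 50)

  # ramped objective exactly midway between thresholds earns half its points
  tmpl_ramp <- pqm_template(list(
    pqm_objective("A", "Dmean", "<=", 10, points = 2, zero_threshold = 30)))
  expect_equal(pqm_score(ss, dose, tmpl_ramp)$achieved, 1)

  # absent structure drops from numerator and denominator
  ss_missing <- structure_set("c1", "DL", list(A = m1, B = absent_structure()))
  expect_equal(npqm(ss_missing, dose, tmpl_ok), 100)
  tmpl_only_b <- pqm_template(list(pqm_objective("B", "Dmean", "<=", 60)))
  expect_error(npqm(ss_missing, dose, tmpl_only_b), class = "segeval_empty_template")
  expect_error(pqm_template(list()), class = "segeval_empty_template")
  expect_error(pqm_objective("A", "Dmean", "<=", 30, zero_threshold = 20),
               class = "segeval_invalid_parameter")
})

test_that("PQM YAML template round-trip", {
  shipped <- read_pqm_template(system.file("extdata", "pqm_hn_example.yaml",
                                           package = "segeval"))
  expect_length(shipped$objectives, 6)
  expect_equal(shipped$objectives[[5]]$zero_threshold, 50)

  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "id: demo",
    "objectives:",
    "  - {structure: Cord, statistic: D0.03cc, direction: '<=', threshold: 45}",
    "  - {structure: Parotid_L, statistic: Dmean, direction: '<=', threshold: 26, points: 2}",
    "  - {structure: CTV1, statistic: Dmean, direction: '>=', threshold: 58.8, target: true}"
  ), path)
  t <- read_pqm_template(path)
  expect_length(t$objectives, 3)
  expect_equal(t$objectives[[2]]$points, 2)
  expect_true(t$objectives[[3]]$target)
  expect_equal(t$objectives[[3]]$direction, ">=")
})

test_that("dose NIfTI round-trip preserves grid and values", {
  g <- aniso_grid(8)
  set.seed(9)
  d <- dose_grid(g, array(runif(prod(g$shape), 0, 70), dim = g$shape))
  tmp <- tempfile(fileext = ".nii.gz")
  write_dose_nifti(d, tmp)
  back <- read_dose_nifti(tmp)
  expect_true(same_grid(back$grid, g, tol = 1e-4))
  expect_equal(back$dose, d$dose, tolerance = 1e-6)
})

test_that("dosimetric deltas: self-comparison zero, ramp shift recovered, exclusions skipped", {
  gr <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(20, 20, 30))
  z <- grid_axis_coords(gr, 3)
  grad <- 1.0  # Gy per mm along z
  ramp <- dose_grid(gr, array(rep(grad * (z - z[1]), each = 400), dim = gr$shape))
  oar <- cube_mask(gr, c(5, 5, 8), c(14, 14, 15))
  ss <- structure_set("c1", "GS", list(A = oar))
  tmpl <- pqm_template(list(pqm_objective("A", "Dmean", "<=", 40)))

  self <- suppressMessages(
    dosimetric_deltas(structure_set("c1", "DL", list(A = oar)), ss, ramp,
                      template = tmpl))
  expect_equal(self$structures$delta_dmean_gy, 0)
  expect_equal(self$structures$delta_dhot_gy, 0)
  expect_equal(self$delta_npqm_pct, 0)

  # shift 3 slices = 6 mm into higher dose: |dDmean| = 6 mm * 1 Gy/mm
  shifted <- structure_set("c1", "DL", list(A = translate_mask(oar, c(0, 0, 3))))
  dd <- suppressMessages(dosimetric_deltas(shifted, ss, ramp, template = tmpl))
  expect_equal(dd$structures$delta_dmean_gy, 6, tolerance = 1e-9)

  # structure excluded in one set only: absent from output, listed as skipped
  tiny <- cube_mask(gr, c(1, 1, 1), c(2, 2, 2))  # 0.016 cc < 0.1 cc
  arm2 <- structure_set("c1", "DL", list(A = oar, B = tiny))
  gs2 <- structure_set("c1", "GS", list(A = oar, B = oar))
  dd2 <- suppressMessages(dosimetric_deltas(arm2, gs2, ramp, template = tmpl))
  expect_identical(dd2$structures$structure, "A")
  expect_true("B" %in% attr(dd2, "skipped"))
})
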
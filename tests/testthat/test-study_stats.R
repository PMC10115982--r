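test_that("presence contingency counts delivery, and rates follow the counts", {
  # candidate identical in presence to GS: no false positives or negatives
  gs <- presence_set("c1", "GS", present = c("A", "B", "C"), absent = "D")
  same <- presence_set("c1", "DL", present = c("A", "B", "C"), absent = "D")
  ct <- presence_contingency(same, gs)
  expect_equal(ct$fp, 0)
  expect_equal(ct$fn, 0)
  expect_equal(ct$tp, 3)
  expect_equal(ct$tn, 1)

  # one case, 42 expected names, 40 delivered matching 40 GS-present
  nm <- sprintf("S%02d", 1:42)
  gs42 <- presence_set("c1", "GS", present = nm[1:40], absent = nm[41:42])
  dl42 <- presence_set("c1", "DL", present = nm[1:40], absent = nm[41:42])
  ct42 <- presence_contingency(dl42, gs42, expected = nm)
  expect_equal(ct42$tp, 40)
  expect_equal(ct42$tn, 2)
  # counts always sum to cases x expected structures
  expect_equal(ct42$tp + ct42$fp + ct42$tn + ct42$fn, 42)

  # delivered-but-empty counts as absent for presence accounting
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  gs_e <- structure_set("c1", "GS", list(A = presence_set("c1", "x", "A")$structures$A))
  cand_e <- structure_set("c1", "DL", list(A = binary_mask(g)))
  expect_equal(presence_contingency(cand_e, gs_e)$fn, 1)
})

test_that("sensitivity and specificity follow the printed-count conventions", {
  expect_equal(sens_spec(contingency_table(818, 7, 15, 0)),
               c(sensitivity = 100, specificity = 68))
  r <- sens_spec(contingency_table(0, 0, 5, 0))
  expect_true(is.na(r["sensitivity"]))
  expect_equal(unname(r["specificity"]), 100)
  expect_equal(sens_spec(contingency_table(1, 1, 1, 1)),
               c(sensitivity = 50, specificity = 50))
  expect_equal(unname(sens_spec(contingency_table(818, 7, 15, 0), digits = NULL)[2]),
               100 * 15 / 22)
})

test_that("mean_ci matches the textbook t-quantile and always contains the mean", {
  ci <- mean_ci(c(1, 2, 3))
  expect_equal(ci$mean, 2)
  expect_equal(ci$lower, 2 - 4.302653 * (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(ci$upper, 2 + 4.302653 * (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(mean_ci(rep(5, 4))$lower, 5)
  expect_error(mean_ci(1), class = "segeval_insufficient_data")
  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(sample(3:30, 1))
    ci <- mean_ci(x)
    expect_true(ci$lower <= ci$mean && ci$mean <= ci$upper)
  }
})

test_that("paired t-test matches an independent computation and flags degenerate cases", {
  # oracle: textbook t statistic on the stated differences
  d <- c(0.5, 1.5, 1.0, 2.0, 0.0)
  b <- rnorm(5)
  a <- b + d
  res <- paired_ttest(a, b)
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * pt(-abs(t_oracle), 4)
  expect_equal(res$mean_diff, mean(d))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_true(res$ci_lower <= res$mean_diff && res$mean_diff <= res$ci_upper)

  same <- paired_ttest(b, b)
  expect_equal(same$p_value, 1)
  expect_equal(same$flag, "no-difference")
  expect_false(same$significant)

  degen <- paired_ttest(b + 1, b)
  expect_equal(degen$flag, "degenerate-variance")
  expect_true(degen$significant)

  expect_error(paired_ttest(1:3, 1:4), class = "segeval_pairing")
  # shift invariance: adding a constant to both arms changes nothing
  res2 <- paired_ttest(a + 10, b + 10)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$mean_diff, res$mean_diff)
})

test_that("mean_ci and paired_ttest agree with stats::t.test on random vectors", {
  set.seed(81)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- x + rnorm(n, mean = runif(1, -1, 1))
    tt <- t.test(x)
    ci <- mean_ci(x)
    expect_equal(c(ci$lower, ci$upper), as.numeric(tt$conf.int), tolerance = 1e-9)
    pt_ <- paired_ttest(x, y)
    ref <- t.test(x - y)
    expect_equal(pt_$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(c(pt_$ci_lower, pt_$ci_upper), as.numeric(ref$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("time savings: arithmetic, zero-width CI, negative savings allowed", {
  mk <- function(arm, totals, init = 0) do.call(rbind, lapply(seq_along(totals),
    function(i) timing_record(sprintf("c%d", i), arm, init, totals[i] - init)))
  std <- mk("MDA+RO", rep(4, 5), init = 2)
  exp_ <- mk("DL+RO", rep(1, 5))
  ts <- time_savings(std, exp_)
  expect_equal(ts$mean, 75)
  expect_equal(ts$lower, 75)
  expect_equal(ts$upper, 75)
  expect_true(ts$significant)  # degenerate-variance case: all savings identical

  same <- time_savings(std, std)
  expect_equal(same$mean, 0)

  slower <- time_savings(mk("MDA+RO", c(2, 2.5, 3)), mk("DL+RO", c(3, 3.5, 2)))
  expect_lt(slower$mean, 50)
  expect_true(any(slower$per_case$savings_pct < 0))

  expect_error(timing_record("c1", "DL", -1, 2), class = "segeval_invalid_parameter")
})

test_that("time-savings power follows the noncentral t and its boundary/monotonicity", {
  # at the null boundary the power equals the one-sided alpha
  expect_equal(power_sample_size(30, 20, 20, margin = 30), 0.025, tolerance = 1e-9)
  # noncentral-t oracle at the study's planning values
  p <- power_sample_size(50, 20, 20, margin = 30)
  ncp <- (50 - 30) / 20 * sqrt(20)
  oracle <- 1 - pt(qt(0.975, 19), 19, ncp)
  expect_equal(p, oracle, tolerance = 1e-12)
  # monotone in n
  ns <- c(5, 10, 20, 40)
  pw <- vapply(ns, function(n) power_sample_size(50, 20, n), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(power_sample_size(50, 0, 20), class = "segeval_invalid_parameter")
})

test_that("OAR threshold counting and eligibility arithmetic", {
  v <- setNames(c(rep(0.9, 32), rep(0.5, 10)), sprintf("o%02d", 1:42))
  r <- count_oars_above(v, threshold = 0.8)
  expect_equal(r$count, 32)
  expect_equal(r$pct, 76)
  df <- data.frame(structure = names(v), metric = "VDSC", mean_value = v)
  expect_equal(count_oars_above(df, "VDSC", 0.8)$pct, 76)
  expect_equal(count_oars_above(numeric(0))$count, 0)
  expect_equal(count_oars_above(numeric(0))$pct, 0)

  nm <- sprintf("S%02d", 1:5)
  sets <- list(
    list(presence_set("c1", "GS", nm),
         presence_set("c1", "DL", nm),
         presence_set("c1", "DL+RO", nm[1:4], absent = nm[5]),
         presence_set("c1", "MDA+RO", nm)),
    list(presence_set("c2", "GS", nm),
         presence_set("c2", "DL", nm),
         presence_set("c2", "DL+RO", nm),
         presence_set("c2", "MDA+RO", nm)))
  el <- eligible_structures(sets)
  expect_equal(el$n_structures, 4 + 5)
  expect_equal(el$n_contours, 9 * 4)
})

test_that("study_report classifies constructed effect directions and handles ties", {
  set.seed(91)
  n_cases <- 12
  structs <- c("P1", "P2")
  rows <- list()
  for (cs in sprintf("c%02d", 1:n_cases)) for (s in structs) {
    base <- runif(1, 0.7, 0.9)
    rows[[length(rows) + 1L]] <- data.frame(
      case = cs, structure = s,
      arm = c("A", "B"), metric = "VDSC", parameter_mm = NA_real_,
      value = c(base, base - 0.12 + rnorm(1, 0, 0.01)))
  }
  tab <- do.call(rbind, rows)
  rep_ <- study_report(metric_table = tab, reference_arm = "A")
  # arm A is a strictly smaller perturbation: favored everywhere
  expect_true(all(rep_$per_oar$B$detail$classification == "favor-A"))
  pooled <- rep_$pooled
  expect_gt(pooled$mean[pooled$arm == "A"], pooled$mean[pooled$arm == "B"])
  expect_true(pooled$significant[pooled$arm == "B"])

  # identical arms: every comparison no-difference
  tab2 <- tab; tab2$value[tab2$arm == "B"] <- tab2$value[tab2$arm == "A"]
  rep2 <- study_report(metric_table = tab2, reference_arm = "A")
  expect_true(all(rep2$per_oar$B$detail$classification == "no-difference"))

  # row counts: one row per metric x arm
  expect_equal(nrow(pooled), length(unique(tab$arm)) * length(unique(tab$metric)))
})
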
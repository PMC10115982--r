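#' Structure-presence contingency table
#'
#' Counts of structure-presence agreement between candidate sets and the gold
#' standard, pooled over cases and the expected structure roster: TP = present
#' in both, FN = present in GS only, FP = present in candidate only, TN =
#' present in neither. "Present" means delivered and non-empty.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts)))
    seg_stop("contingency counts must be non-negative", "invalid_parameter")
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Presence contingency of candidate structure sets against the gold standard
#'
#' Pools over all cases and all expected structure names. A structure counts
#' as present when delivered and non-empty; a delivered-but-empty structure is
#' counted as absent (the contingency counts delivery, not geometry).
#'
#' @param candidates list of candidate `structure_set` objects (or one set).
#' @param references list of GS `structure_set` objects paired with
#'   `candidates` by position (or one set).
#' @param expected character vector of expected structure names; defaults to
#'   the union of names seen in the paired sets.
#' @return A `contingency_table`.
#' @export
presence_contingency <- function(candidates, references, expected = NULL) {
  if (inherits(candidates, "structure_set")) candidates <- list(candidates)
  if (inherits(references, "structure_set")) references <- list(references)
  if (length(candidates) != length(references))
    seg_stop("candidates and references must pair one-to-one by case", "pairing")
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(candidates)) {
    cs <- candidates[[i]]; rs <- references[[i]]
    exp_i <- if (is.null(expected))
      union(structure_names(cs), structure_names(rs)) else expected
    for (nm in exp_i) {
      pc <- !is.null(cs$structures[[nm]]) && structure_is_present(cs$structures[[nm]])
      pr <- !is.null(rs$structures[[nm]]) && structure_is_present(rs$structures[[nm]])
      if (pc && pr) tp <- tp + 1L
      else if (pc && !pr) fp <- fp + 1L
      else if (!pc && pr) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  contingency_table(tp, fp, tn, fn)
}

#' Sensitivity and specificity of structure-presence detection
#'
#' 100*TP/(TP+FN) and 100*TN/(TN+FP), rounded to the nearest integer percent
#' (the study reporting convention; set `digits = NULL` for unrounded values).
#' Zero denominators yield NA.
#'
#' @param table a `contingency_table`.
#' @param digits rounding digits for the percentages, or NULL for none.
#' @return named numeric: `sensitivity`, `specificity` (percent).
#' @export
sens_spec <- function(table, digits = 0) {
  sens <- if (table$tp + table$fn > 0) 100 * table$tp / (table$tp + table$fn) else NA_real_
  spec <- if (table$tn + table$fp > 0) 100 * table$tn / (table$tn + table$fp) else NA_real_
  out <- c(sensitivity = sens, specificity = spec)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Sample mean with a t-based 95% confidence interval
#' @param values numeric vector, n >= 2.
#' @param conf confidence level.
#' @return list with `mean`, `lower`, `upper`, `n`.
#' @export
mean_ci <- function(values, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) seg_stop("mean_ci needs at least 2 values", "insufficient_data")
  m <- mean(values)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(values) / sqrt(n)
  list(mean = m, lower = m - half, upper = m + half, n = n)
}

#' Two-sided paired t-test between matched measurements
#'
#' Pairs by position; the test statistic is formed on the differences with
#' n - 1 degrees of freedom. Degenerate difference vectors are reported
#' descriptively instead of with fabricated p-values: all-zero differences
#' yield p = 1 with flag `"no-difference"`; zero-variance nonzero differences
#' are flagged `"degenerate-variance"` and marked significant.
#'
#' @param a_values,b_values equal-length paired numeric vectors (n >= 2).
#' @param metric,arms optional labels carried on the result.
#' @param alpha significance level for the flag.
#' @return An object of class `paired_comparison`: mean difference (a - b),
#'   95% CI, two-sided p, `significant`, `flag`, `n`.
#' @export
paired_ttest <- function(a_values, b_values, metric = NA_character_,
                         arms = c(NA_character_, NA_character_), alpha = 0.05) {
  if (length(a_values) != length(b_values))
    seg_stop("paired vectors must have equal length", "pairing")
  keep <- !(is.na(a_values) | is.na(b_values))
  d <- a_values[keep] - b_values[keep]
  n <- length(d)
  if (n < 2L) seg_stop("paired t-test needs at least 2 complete pairs", "insufficient_data")
  flag <- "ok"
  if (sd(d) == 0) {
    if (all(d == 0)) {
      flag <- "no-difference"; p <- 1; ci <- c(0, 0)
    } else {
      flag <- "degenerate-variance"; p <- 0; ci <- c(mean(d), mean(d))
    }
    md <- mean(d)
  } else {
    tt <- stats::t.test(a_values[keep], b_values[keep], paired = TRUE)
    md <- unname(tt$estimate); p <- tt$p.value; ci <- as.numeric(tt$conf.int)
  }
  structure(list(metric = metric, arms = arms, differences = d,
                 mean_diff = md, ci_lower = ci[1], ci_upper = ci[2],
                 p_value = p, significant = p < alpha, flag = flag, n = n),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired_comparison%s: mean diff %.4g (95%% CI %.4g to %.4g), p = %.3g%s, n = %d\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$mean_diff, x$ci_lower, x$ci_upper, x$p_value,
              if (x$flag != "ok") paste0(" (", x$flag, ")") else "", x$n))
  invisible(x)
}

#' Per-case timing record
#' @param case_id case identifier.
#' @param arm arm label.
#' @param initial_h initial-contouring duration in hours (0 when the arm has
#'   no human initial contouring, e.g. model-generated contours).
#' @param revision_h physician revision duration in hours.
#' @return one-row data.frame with `total_h = initial_h + revision_h`.
#' @export
timing_record <- function(case_id, arm, initial_h, revision_h) {
  if (any(c(initial_h, revision_h) < 0))
    seg_stop("durations must be >= 0", "invalid_parameter")
  data.frame(case = as.character(case_id), arm = as.character(arm),
             initial_h = initial_h, revision_h = revision_h,
             total_h = initial_h + revision_h, stringsAsFactors = FALSE)
}

#' Relative contouring time savings of the experimental arm
#'
#' Per-case relative savings 100 * (standard total - experimental total) /
#' standard total, matched on case; mean with t-based 95% CI; and a one-sided
#' one-sample t-test of mean savings > `margin` (study margin 30%, one-sided
#' alpha 0.025). Cases with zero standard total are excluded with a warning.
#' Negative savings (experimental slower) are permitted.
#'
#' @param standard,experimental data.frames of [timing_record()] rows covering
#'   the same cases.
#' @param margin clinically significant savings margin, percent.
#' @param alpha one-sided significance level.
#' @return list with `per_case` (case, savings_pct), `mean`, `lower`, `upper`,
#'   `n`, `margin`, `p_value`, `significant`.
#' @export
time_savings <- function(standard, experimental, margin = 30, alpha = 0.025) {
  std <- stats::aggregate(total_h ~ case, data = standard, FUN = sum)
  exp_ <- stats::aggregate(total_h ~ case, data = experimental, FUN = sum)
  merged <- merge(std, exp_, by = "case", suffixes = c("_std", "_exp"))
  if (nrow(merged) == 0L) seg_stop("no shared cases between arms", "pairing")
  zero <- merged$total_h_std == 0
  if (any(zero)) {
    seg_warn(sprintf("%d case(s) with zero standard-arm time excluded", sum(zero)),
             "zero_denominator")
    merged <- merged[!zero, , drop = FALSE]
  }
  sav <- 100 * (merged$total_h_std - merged$total_h_exp) / merged$total_h_std
  ci <- mean_ci(sav)
  tstat <- (ci$mean - margin) / (sd(sav) / sqrt(ci$n))
  p <- pt(tstat, ci$n - 1, lower.tail = FALSE)
  list(per_case = data.frame(case = merged$case, savings_pct = sav,
                             stringsAsFactors = FALSE),
       mean = ci$mean, lower = ci$lower, upper = ci$upper, n = ci$n,
       margin = margin, p_value = p, significant = p < alpha)
}

#' Power of the one-sided time-savings test
#'
#' Power of the one-sided, one-sample t-test that mean savings exceeds
#' `margin`, under the alternative `assumed_savings`, via the noncentral t
#' distribution.
#'
#' @param assumed_savings assumed true mean savings, percent.
#' @param sd assumed standard deviation of per-case savings, percent.
#' @param n number of cases (>= 2).
#' @param margin savings margin being tested, percent.
#' @param alpha one-sided significance level.
#' @return power in [0, 1].
#' @export
power_sample_size <- function(assumed_savings, sd, n, margin = 30, alpha = 0.025) {
  if (!is.finite(sd) || sd <= 0) seg_stop("sd must be > 0", "invalid_parameter")
  if (!is.finite(n) || n < 2) seg_stop("n must be >= 2", "invalid_parameter")
  ncp <- (assumed_savings - margin) / sd * sqrt(n)
  pt(qt(1 - alpha, n - 1), n - 1, ncp = ncp, lower.tail = FALSE)
}

#' Count OARs whose arm-mean metric exceeds a threshold
#'
#' E.g. the number (and percentage of the expected roster) of OARs with mean
#' volumetric Dice above 0.8 for one arm.
#'
#' @param per_oar_means data.frame with columns `structure`, `metric`,
#'   `mean_value` (one row per OAR for the arm of interest), or a named
#'   numeric vector of per-OAR means.
#' @param metric metric name to filter on (ignored for a named vector).
#' @param threshold threshold; strictly-greater comparison.
#' @param roster_size size of the full expected OAR roster (study roster: 42).
#' @return list with `count` and `pct` (rounded to integer percent of the
#'   roster).
#' @export
count_oars_above <- function(per_oar_means, metric = "VDSC", threshold = 0.8,
                             roster_size = 42) {
  if (is.data.frame(per_oar_means)) {
    v <- per_oar_means$mean_value[per_oar_means$metric == metric]
  } else {
    v <- as.numeric(per_oar_means)
  }
  count <- sum(v > threshold, na.rm = TRUE)
  list(count = count, pct = round(100 * count / roster_size))
}

#' Structures eligible for comparison across all arms
#'
#' The study rule: a structure of a case enters the comparison only if it is
#' present (delivered, non-empty) in every contour set for that case
#' (gold standard and all arms). Returns the eligible count and the total
#' number of contours it represents (eligible structures x number of sets).
#'
#' @param sets_by_case list over cases; each element a list of the case's
#'   `structure_set` objects (GS plus every arm).
#' @return list with `n_structures`, `n_sets`, `n_contours`, and the per-case
#'   eligible names `by_case`.
#' @export
eligible_structures <- function(sets_by_case) {
  by_case <- lapply(sets_by_case, function(sets) {
    Reduce(intersect, lapply(sets, structure_names, present_only = TRUE))
  })
  n_sets <- if (length(sets_by_case)) length(sets_by_case[[1]]) else 0L
  n_structures <- sum(lengths(by_case))
  list(n_structures = n_structures, n_sets = n_sets,
       n_contours = n_structures * n_sets, by_case = by_case)
}
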
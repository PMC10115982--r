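#' @name study_report
#' @title Study report tables
#' @description Aggregates the long-format metric, dosimetry and timing tables
#'   into the report shapes used by contouring validation studies: pooled
#'   per-arm means with 95% CIs and paired significance against a reference
#'   arm; per-OAR favored-arm classification; dosimetric delta summaries;
#'   timing summary with the time-savings endpoint; and the structure-presence
#'   contingency summary.
NULL

# which direction means better agreement with the gold standard
metric_orientation <- function(metric) {
  switch(metric,
         VDSC = , SDSC = , CDC = , precision = , sensitivity = ,
         specificity = "higher",
         delta_volume = "abs_lower",
         "lower")
}

# report rounding convention: unitless metric means to 2 decimals,
# mm/Gy/percent quantities to 1 decimal
metric_round_digits <- function(metric) {
  if (metric %in% c("VDSC", "SDSC", "CDC", "precision", "sensitivity", "specificity")) 2L else 1L
}

metric_key <- function(tab) {
  param <- ifelse(is.na(tab$parameter_mm), "", paste0("-", tab$parameter_mm, "mm"))
  paste0(tab$metric, param)
}

pair_values <- function(tab, arm_a, arm_b, unit_cols) {
  a <- tab[tab$arm == arm_a, c(unit_cols, "value")]
  b <- tab[tab$arm == arm_b, c(unit_cols, "value")]
  m <- merge(a, b, by = unit_cols, suffixes = c("_a", "_b"))
  m
}

#' Pooled per-arm comparison of one long-format metric table
#'
#' Means with 95% CIs per arm for every metric/tolerance, with two-sided
#' paired t-tests against the reference arm, paired at the case x structure
#' level.
#'
#' @param metric_table long data.frame from [compare_structure_sets()].
#' @param reference_arm arm every other arm is tested against.
#' @return data.frame: metric, parameter_mm, arm, n, mean, ci_lower, ci_upper,
#'   p_vs_reference, significant.
#' @export
pooled_metric_report <- function(metric_table, reference_arm = "DL+RO") {
  tab <- metric_table
  tab$key <- metric_key(tab)
  rows <- list()
  for (k in unique(tab$key)) {
    sub <- tab[tab$key == k, , drop = FALSE]
    for (arm in unique(sub$arm)) {
      v <- sub$value[sub$arm == arm]
      v <- v[!is.na(v)]
      ci <- if (length(v) >= 2) mean_ci(v) else list(mean = mean(v), lower = NA, upper = NA, n = length(v))
      p <- NA_real_
      if (arm != reference_arm && reference_arm %in% sub$arm) {
        m <- pair_values(sub, arm, reference_arm, c("case", "structure"))
        if (nrow(m) >= 2 && !all(is.na(m$value_a - m$value_b))) {
          p <- paired_ttest(m$value_a, m$value_b)$p_value
        }
      }
      dg <- metric_round_digits(sub$metric[1])
      rows[[length(rows) + 1L]] <- data.frame(
        metric = sub$metric[1], parameter_mm = sub$parameter_mm[1], arm = arm,
        n = ci$n, mean = round(ci$mean, dg), ci_lower = round(ci$lower, dg),
        ci_upper = round(ci$upper, dg), p_vs_reference = p,
        significant = !is.na(p) & p < 0.05, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-OAR favored-arm classification
#'
#' For every structure and metric, a two-sided paired t-test (paired at the
#' case level) between an arm and the reference arm, classified as
#' "no-difference" or as favoring whichever arm agrees better with the gold
#' standard given the metric's orientation (overlap metrics: higher is
#' better; distances and path lengths: lower; volume shift: smaller
#' magnitude).
#'
#' @inheritParams pooled_metric_report
#' @param arm the comparison arm.
#' @return list with `detail` (structure x metric classification) and
#'   `summary` (counts per metric).
#' @export
per_oar_report <- function(metric_table, arm, reference_arm = "DL+RO") {
  tab <- metric_table
  tab$key <- metric_key(tab)
  detail <- list()
  for (k in unique(tab$key)) {
    sub <- tab[tab$key == k, , drop = FALSE]
    for (s in unique(sub$structure)) {
      ss <- sub[sub$structure == s, , drop = FALSE]
      m <- pair_values(ss, arm, reference_arm, "case")
      if (nrow(m) < 2) next
      orient <- metric_orientation(ss$metric[1])
      va <- m$value_a; vb <- m$value_b
      if (orient == "abs_lower") { va <- abs(va); vb <- abs(vb) }
      cls <- "no-difference"
      if (sd(va - vb) > 0 || any(va != vb)) {
        tt <- paired_ttest(va, vb)
        if (tt$significant) {
          a_better <- if (orient == "higher") tt$mean_diff > 0 else tt$mean_diff < 0
          cls <- if (a_better) paste0("favor-", arm) else paste0("favor-", reference_arm)
        }
      }
      detail[[length(detail) + 1L]] <- data.frame(
        metric = k, structure = s, classification = cls, n = nrow(m),
        stringsAsFactors = FALSE)
    }
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(metric = character(0), structure = character(0),
               classification = character(0), n = integer(0))
  summary <- as.data.frame(table(metric = detail$metric,
                                 classification = detail$classification),
                           stringsAsFactors = FALSE)
  list(detail = detail, summary = summary)
}

#' Timing summary table
#'
#' Per-arm means with 95% CIs of initial, revision and total hours, plus the
#' time-savings endpoint of the experimental vs the standard arm.
#'
#' @param timing_table data.frame of [timing_record()] rows.
#' @param standard_arm,experimental_arm arm labels for the savings endpoint.
#' @return list with `by_arm` and `savings` (from [time_savings()], or NULL
#'   when either arm is missing).
#' @export
timing_report <- function(timing_table, standard_arm = "MDA+RO",
                          experimental_arm = "DL+RO") {
  rows <- list()
  for (arm in unique(timing_table$arm)) {
    sub <- timing_table[timing_table$arm == arm, , drop = FALSE]
    f <- function(x) {
      ci <- mean_ci(x)
      sprintf("%.1f (%.1f - %.1f)", ci$mean, ci$lower, ci$upper)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, n = nrow(sub),
      initial_h = f(sub$initial_h), revision_h = f(sub$revision_h),
      total_h = f(sub$total_h), stringsAsFactors = FALSE)
  }
  arms <- unique(timing_table$arm)
  savings <- NULL
  if (all(c(standard_arm, experimental_arm) %in% arms)) {
    savings <- time_savings(timing_table[timing_table$arm == standard_arm, ],
                            timing_table[timing_table$arm == experimental_arm, ])
  }
  list(by_arm = do.call(rbind, rows), savings = savings)
}

#' Full study report
#'
#' Emits the five report components from the long-format module outputs. Any
#' missing input yields an explicit NULL component rather than a failure; the
#' number of paired tests performed is recorded because no multiple-testing
#' correction is applied (per-metric alpha 0.05).
#'
#' @param metric_table long data.frame of geometric metrics (or NULL).
#' @param dose_table long data.frame with columns case, structure, arm,
#'   metric, value for the dosimetric deltas (or NULL).
#' @param timing_table data.frame of timing records (or NULL).
#' @param contingency a `contingency_table` (or NULL).
#' @param reference_arm reference arm for paired comparisons.
#' @param comparison_arms arms classified against the reference per OAR;
#'   default all non-reference arms in `metric_table`.
#' @return An object of class `study_report` (list of report tables).
#' @export
study_report <- function(metric_table = NULL, dose_table = NULL,
                         timing_table = NULL, contingency = NULL,
                         reference_arm = "DL+RO", comparison_arms = NULL) {
  pooled <- NULL; per_oar <- NULL; dose <- NULL
  if (!is.null(metric_table) && nrow(metric_table)) {
    pooled <- pooled_metric_report(metric_table, reference_arm)
    if (is.null(comparison_arms))
      comparison_arms <- setdiff(unique(metric_table$arm), reference_arm)
    per_oar <- lapply(setNames(comparison_arms, comparison_arms),
                      per_oar_report, metric_table = metric_table,
                      reference_arm = reference_arm)
  }
  if (!is.null(dose_table) && nrow(dose_table)) {
    dose <- pooled_metric_report(
      data.frame(case = dose_table$case, structure = dose_table$structure,
                 arm = dose_table$arm, metric = dose_table$metric,
                 parameter_mm = NA_real_, value = dose_table$value,
                 stringsAsFactors = FALSE),
      reference_arm)
  }
  timing <- if (!is.null(timing_table) && nrow(timing_table))
    timing_report(timing_table) else NULL
  conting <- if (!is.null(contingency))
    list(table = contingency, rates = sens_spec(contingency)) else NULL
  n_tests <- sum(!is.na(pooled$p_vs_reference)) +
    sum(vapply(per_oar, function(p) nrow(p$detail), integer(1))) +
    if (!is.null(dose)) sum(!is.na(dose$p_vs_reference)) else 0L
  structure(list(pooled = pooled, per_oar = per_oar, dose = dose,
                 timing = timing, contingency = conting,
                 n_tests = n_tests, reference_arm = reference_arm),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (reference arm:", x$reference_arm, ")\n")
  if (!is.null(x$pooled)) {
    cat("\nPooled metric means (95% CI), paired vs reference:\n")
    print(x$pooled, row.names = FALSE)
  }
  if (!is.null(x$per_oar)) {
    for (arm in names(x$per_oar)) {
      cat("\nPer-OAR classification,", arm, "vs", x$reference_arm, ":\n")
      print(x$per_oar[[arm]]$summary, row.names = FALSE)
    }
  }
  if (!is.null(x$dose)) {
    cat("\nDosimetric deltas:\n")
    print(x$dose, row.names = FALSE)
  }
  if (!is.null(x$timing)) {
    cat("\nTiming (hours):\n")
    print(x$timing$by_arm, row.names = FALSE)
    if (!is.null(x$timing$savings))
      cat(sprintf("Time savings: %.0f%% (95%% CI %.0f%% - %.0f%%), p(>%g%%) = %.3g\n",
                  x$timing$savings$mean, x$timing$savings$lower,
                  x$timing$savings$upper, x$timing$savings$margin,
                  x$timing$savings$p_value))
  }
  if (!is.null(x$contingency)) {
    cat("\nStructure presence: ")
    print(x$contingency$table)
    cat(sprintf("  sensitivity %g%%, specificity %g%%\n",
                x$contingency$rates["sensitivity"], x$contingency$rates["specificity"]))
  }
  cat(sprintf("\n%d paired tests performed (no multiple-testing correction).\n", x$n_tests))
  invisible(x)
}
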
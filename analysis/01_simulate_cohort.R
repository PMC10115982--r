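#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a synthetic contouring-trial cohort: per case a gold-standard
# structure set built from geometric primitives, three candidate arms (an
# unrevised model arm "DL", a lightly revised "DL+RO" arm, and a manual
# "MDA+RO" arm with larger disagreement), a Gaussian-blob dose field around
# the targets, and per-case timing records whose per-case savings distribution
# is centered on the study's 76% with the spread its confidence interval
# implies. A compact 8-structure phantom keeps the downstream geometry
# tractable on a laptop; the full 42-OAR head phantom (hn_oar_roster()) plugs
# in unchanged.

suppressPackageStartupMessages(library(segeval))

seed <- 42
n_cases <- 10
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

phantom <- demo_phantom_spec(n_structures = 8, shape = c(48, 48, 28),
                             gs_absence_prob = 0.03)
cohort <- generate_cohort(
  n_cases = n_cases, phantom = phantom,
  dose = dose_model_spec("blobs", prescriptions_gy = 66),
  seed = seed)

saveRDS(cohort, "scratch/cohort.rds")
write.csv(cohort$timing, "results/timing_records.csv", row.names = FALSE)
write.csv(cohort$truth, "results/ground_truth_perturbations.csv", row.names = FALSE)

n_present <- sum(!cohort$truth$absent)
cat(sprintf("Simulated %d cases x %d structures x %d arms (seed %d).\n",
            n_cases, nrow(phantom$roster), length(cohort$arm_specs), seed))
cat(sprintf("%d of %d arm-structure deliveries present; %d timing records.\n",
            n_present, nrow(cohort$truth), nrow(cohort$timing)))
cat("Cohort saved to scratch/cohort.rds; timing and ground truth under results/.\n")
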
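#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates the study design: 11 fibromyalgia (FM) cases vs 10 controls, 1212
# miRNA probes + 100 blank spots per array, a 5-miRNA signature implanted at
# 6.31-13.47-fold downregulation, ~20% of probes downregulated 2-4x, 30% of
# probes absent, clinical severity scores at the published case-group
# means/SDs, and qPCR Ct values consistent with the implanted folds.
# Writes results/cohort/ (scan TSVs, sample sheet, qPCR table, truth JSON).

suppressPackageStartupMessages(library(mirscreen))

seed <- 1
cfg <- simulation_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat(sprintf("seed %d: wrote %d scans (%d FM, %d control) to results/cohort\n",
            seed, length(cohort$scans),
            sum(cohort$sample_sheet$group == "FM"),
            sum(cohort$sample_sheet$group == "control")))
cat(sprintf("implanted signature: %s\n",
            paste(sprintf("%s (%.2fx)", cohort$truth$signature,
                          cohort$truth$folds[cohort$truth$signature]),
                  collapse = ", ")))
cat(sprintf("%d probes absent, %d broadly downregulated 2-4x\n",
            length(cohort$truth$absent), length(cohort$truth$broad)))
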
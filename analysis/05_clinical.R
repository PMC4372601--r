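#!/usr/bin/env Rscript
# Stage 5: clinical-score statistics.
#
# Spearman rank correlation of validated signature miRNA levels (qPCR
# relative expression, case group only) against the FIQ total and the five
# MFI fatigue subscales, with pairwise-complete deletion; the small-RNA
# fraction comparison between groups; and the extreme mental-fatigue outlier
# report. Writes correlations.tsv, small_rna.json and outlier_report.json
# under results/.

suppressPackageStartupMessages(library(mirscreen))

cohort <- read_cohort("results/cohort")
sheet <- cohort$sample_sheet
sig <- jsonlite::read_json("results/signature.json", simplifyVector = TRUE)
em <- read_expression_matrix("results/expression_matrix.tsv")

# per-sample relative expression of the signature assays, FM group only
rel <- relative_expression(cohort$qpcr$ct, cohort$qpcr$ct_reference)
expr <- data.frame(sample_id = cohort$qpcr$sample_id, check.names = FALSE)
expr <- cbind(expr, setNames(list(rel), "rel"))
wide <- reshape(cbind(expr, mirna_id = cohort$qpcr$mirna_id),
                idvar = "sample_id", timevar = "mirna_id",
                direction = "wide")
names(wide) <- sub("^rel\\.", "", names(wide))
fm_expr <- wide[wide$sample_id %in% sheet$sample_id[sheet$group == "FM"],
                c("sample_id", intersect(sig$members, names(wide)))]

correlations <- correlate_clinical(fm_expr, sheet)
write.table(correlations, "results/correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("correlations: %d cells, %d with p < 0.05\n",
            nrow(correlations),
            sum(correlations$p_value < 0.05, na.rm = TRUE)))

sr <- compare_small_rna_fractions(sheet[, c("sample_id", "small_rna_fraction")],
                                  sheet)
cat(sprintf("small RNA fraction: control %.1f%% +/- %.1f%%, FM %.1f%% +/- %.1f%% (p = %.2f)\n",
            100 * sr$summary$mean[1], 100 * sr$summary$sd[1],
            100 * sr$summary$mean[2], 100 * sr$summary$sd[2], sr$p_value))
jsonlite::write_json(list(summary = sr$summary, u = sr$u,
                          p_value = sr$p_value),
                     "results/small_rna.json", auto_unbox = TRUE, digits = NA)

outlier <- flag_outlier_patient(em, sheet, sig$members)
cat(sprintf("case with lowest mental-fatigue score: %s (MF = %g); highest FM-group level for %d of %d signature miRNAs; exceeds the lowest control level for %d\n",
            outlier$sample_id, outlier$mf_score, outlier$n_highest_in_fm,
            length(sig$members), outlier$n_exceed))
jsonlite::write_json(list(sample_id = outlier$sample_id,
                          mf_score = outlier$mf_score,
                          n_exceed = outlier$n_exceed,
                          n_highest_in_fm = outlier$n_highest_in_fm,
                          per_mirna = outlier$per_mirna),
                     "results/outlier_report.json", auto_unbox = TRUE,
                     digits = NA)
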
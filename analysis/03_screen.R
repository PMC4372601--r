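#!/usr/bin/env Rscript
# Stage 3: fold-change screening.
#
# Filters the matrix to miRNAs whose control OR case group mean exceeds 5,
# computes per-miRNA group means and control/case ratios, counts the 2x/4x
# downregulation and 1.5x induction census, and selects the >= 6-fold
# downregulated signature. Writes group_summary.tsv, census.json and
# signature.json under results/.

suppressPackageStartupMessages(library(mirscreen))

em <- read_expression_matrix("results/expression_matrix.tsv")
filtered <- heatmap_filter(em, min_group_mean = 5)
cat(sprintf("group-mean filter: %d of %d miRNAs retained\n",
            nrow(filtered$values), nrow(em$values)))

summary <- summarize_groups(filtered)
cen <- census(summary)
print(cen)
cat(sprintf("as a share of the %d probes on the array: %.1f%% down >= 2-fold\n",
            nrow(em$values), 100 * cen$n_down_2x / nrow(em$values)))

sig <- select_signature(summary, min_fold = 6)
cat("signature (>= 6-fold downregulated in cases):\n")
print(format_group_summary(summary[summary$mirna_id %in% sig$mirna_id, ]))

write.table(format_group_summary(summary), "results/group_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(unclass(cen), "results/census.json",
                     auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(min_fold = 6, members = sig$mirna_id,
                          ratio = sig$ratio),
                     "results/signature.json", auto_unbox = TRUE, digits = NA)

# optional figure: clustered heatmap of the filtered matrix
if (requireNamespace("pheatmap", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  plot_expression_heatmap(filtered, filename = "results/figures/heatmap.png")
  cat("wrote results/figures/heatmap.png\n")
}
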
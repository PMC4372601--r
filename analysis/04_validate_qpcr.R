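#!/usr/bin/env Rscript
# Stage 4: RT-qPCR validation of the screened panel.
#
# Converts Ct tables to relative expression against the U6 reference
# (2^-dCt) and compares FM vs control per miRNA with the two-sided
# Mann-Whitney U test at alpha 0.05, uncorrected. Writes
# results/validation.tsv.

suppressPackageStartupMessages(library(mirscreen))

cohort <- read_cohort("results/cohort")
sig <- jsonlite::read_json("results/signature.json", simplifyVector = TRUE)

validation <- validate_mirnas(cohort$qpcr, cohort$sample_sheet, alpha = 0.05)
print(validation)
write.table(validation, "results/validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

confirmed <- validation$mirna_id[validation$significant &
                                   validation$direction == "down_in_FM"]
cat(sprintf("signature members confirmed by qPCR: %d of %d\n",
            sum(sig$members %in% confirmed), length(sig$members)))
not_sig <- validation$mirna_id[!validation$significant]
if (length(not_sig)) {
  cat(sprintf("not significant (p >= 0.05): %s\n",
              paste(not_sig, collapse = ", ")))
}
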
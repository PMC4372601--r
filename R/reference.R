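## Published reference inputs carried with the package.
##
## These are the study's printed screening averages and assay annotation:
## the group-mean table of the eight microarray-screened miRNAs (normalized
## fluorescence units, global median 25), the qPCR primer panel, and the
## case-group clinical-score summaries. They serve as fixed inputs for
## signature selection on the printed data and as defaults for the
## synthetic-cohort generator.

#' Printed microarray group averages of the screened miRNAs
#'
#' Control and case (FM) group means after global median normalization for
#' the eight miRNAs taken to qPCR validation: the five strongly downregulated
#' signature candidates, one intermediate (~4-fold) miRNA, and two
#' near-unchanged controls.
#'
#' @return Data frame with `mirna_id`, `control_mean`, `fm_mean`.
#' @export
reference_group_averages <- function() {
  data.frame(
    mirna_id = c("hsa-miR-223-3p", "hsa-miR-451a", "hsa-miR-338-3p",
                 "hsa-miR-143-3p", "hsa-miR-145-5p", "hsa-miR-21-5p",
                 "hsa-miR-1908-5p", "hsa-miR-1260b"),
    control_mean = c(66736.98, 4830.07, 374.20, 506.26, 546.05,
                     5470.04, 762.60, 23676.19),
    fm_mean = c(10577.74, 358.62, 32.22, 45.42, 52.58,
                1409.50, 660.45, 17356.79),
    stringsAsFactors = FALSE
  )
}

#' qPCR primer panel annotation
#'
#' Forward-primer metadata for the validated assays (reverse primer is the
#' kit's universal primer; U6 is the reference gene). Annotation only --
#' never used in computation.
#'
#' @return Data frame with `mirna_id`, `accession`, `mature_sequence`,
#'   `primer_sequence`, `tm_c`.
#' @export
qpcr_primer_annotation <- function() {
  data.frame(
    mirna_id = c("hsa-miR-223-3p", "hsa-miR-451a", "hsa-miR-338-3p",
                 "hsa-miR-143-3p", "hsa-miR-145-5p", "hsa-miR-21-5p",
                 "hsa-miR-1908-5p", "hsa-miR-1260b"),
    accession = c("MIMAT0000280", "MIMAT0001631", "MIMAT0000763",
                  "MIMAT0000437", "MIMAT0000435", "MIMAT0000076",
                  "MIMAT0007881", "MIMAT0015041"),
    mature_sequence = c("UGUCAGUUUGUCAAAUACCCCA", "AAACCGUUACCAUUACUGAGUU",
                        "UCCAGCAUCAGUGAUUUUGUUG", "UGAGAUGAAGCACUGUAGCUC",
                        "GUCCAGUUUUCCCAGGAAUCCCU", "UAGCUUAUCAGACUGAUGUUGA",
                        "CGGCGGGGACGGCGAUUGGUC", "AUCCCACCACUGCCACCAU"),
    primer_sequence = c("TGTCAGTTTGTCAAATACCC", "AAACCGTTACCATTACTGAG",
                        "TCCAGCATCAGTGATTTTGT", "TGAGATGAAGCACTGTAGC",
                        "GTCCAGTTTTCCCAGGAATCC", "TAGCTTATCAGACTGATGTT",
                        "CGGCGGGGACGGCGATTGG", "ATCCCACCACTGCCACC"),
    tm_c = c(50.3, 49.8, 52.1, 51.9, 55.7, 47.9, 66.9, 57.9),
    stringsAsFactors = FALSE
  )
}

## Signature folds = printed control/case ratios of the five members; the
## three extra assayed miRNAs carry their printed ratios too.
default_signature_folds <- function() {
  ref <- reference_group_averages()
  folds <- round(ref$control_mean / ref$fm_mean, 2)
  names(folds) <- ref$mirna_id
  folds[c("hsa-miR-451a", "hsa-miR-338-3p", "hsa-miR-143-3p",
          "hsa-miR-145-5p", "hsa-miR-223-3p")]
}

default_extra_folds <- function() {
  ref <- reference_group_averages()
  folds <- round(ref$control_mean / ref$fm_mean, 2)
  names(folds) <- ref$mirna_id
  folds[c("hsa-miR-21-5p", "hsa-miR-1908-5p", "hsa-miR-1260b")]
}

#' Case-group clinical score summaries
#'
#' Printed mean and SD of the FM group's severity instruments: FIQ total
#' (0-100) and the MFI subscales (0-20). RA and RM summaries were not
#' printed; the values used here are plausible mid-range defaults consistent
#' with the printed subscales and are configurable in the generator.
#'
#' @return Named list of `c(mean, sd)` pairs for FIQ, GF, PF, MF, RA, RM.
#' @export
reference_clinical_summaries <- function() {
  list(FIQ = c(mean = 74.11, sd = 13.32),
       GF = c(mean = 18.64, sd = 1.63),
       PF = c(mean = 17.64, sd = 1.50),
       MF = c(mean = 14.27, sd = 2.90),
       RA = c(mean = 14.00, sd = 3.00),
       RM = c(mean = 13.00, sd = 3.50))
}

#' Small-RNA fraction summaries per group
#'
#' Printed relative small-RNA abundance: mean and SD per group, as
#' proportions.
#'
#' @return Named list with `control` and `FM` entries of `c(mean, sd)`.
#' @export
reference_small_rna_summaries <- function() {
  list(control = c(mean = 0.140, sd = 0.034),
       FM = c(mean = 0.161, sd = 0.102))
}
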
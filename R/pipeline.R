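## End-to-end orchestration.
##
## run_all() chains the stages: normalize every scan -> assemble the
## expression matrix -> group-mean filter -> group summary, census and
## signature selection -> qPCR validation of the assayed panel -> clinical
## correlation of validated miRNA levels (case group) -> small-RNA fraction
## comparison -> outlier-patient flag. Stage outputs are written to disk when
## an output directory is given, and the returned run report is recomputable
## from those files.

#' Pipeline configuration
#'
#' Aggregates the stage constants. The defaults reproduce the standard
#' parameterization end to end: 5% blank trim, mean + 2 SD detection, median
#' target 25, group-mean filter at 5, downregulation census at 2x and 4x,
#' induction at 1.5x, signature membership at 6-fold, two-sided testing at
#' alpha 0.05 with no multiplicity correction.
#'
#' @param normalization A [normalization_config()].
#' @param min_group_mean Group-mean filter threshold.
#' @param down_thresholds Census downregulation fold thresholds.
#' @param up_threshold Census induction threshold.
#' @param min_fold Signature membership fold threshold.
#' @param alpha qPCR validation significance level.
#' @param p_adjust Multiplicity correction for validation p-values.
#' @param max_cycles Ct validity bound.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(normalization = normalization_config(),
                            min_group_mean = 5,
                            down_thresholds = c(2, 4), up_threshold = 1.5,
                            min_fold = 6, alpha = 0.05, p_adjust = "none",
                            max_cycles = 45) {
  structure(list(normalization = normalization,
                 min_group_mean = min_group_mean,
                 down_thresholds = down_thresholds,
                 up_threshold = up_threshold, min_fold = min_fold,
                 alpha = alpha, p_adjust = p_adjust,
                 max_cycles = max_cycles),
            class = "pipeline_config")
}

## qPCR relative expression per sample for a set of miRNAs, wide layout.
qpcr_expression_table <- function(qpcr, mirna_ids, max_cycles = 45) {
  sub <- qpcr[qpcr$mirna_id %in% mirna_ids, , drop = FALSE]
  agg <- stats::aggregate(sub[, c("ct", "ct_reference")],
                          by = list(sample_id = sub$sample_id,
                                    mirna_id = sub$mirna_id),
                          FUN = mean)
  agg$rel_expr <- relative_expression(agg$ct, agg$ct_reference,
                                      max_cycles = max_cycles)
  wide <- stats::reshape(agg[, c("sample_id", "mirna_id", "rel_expr")],
                         idvar = "sample_id", timevar = "mirna_id",
                         direction = "wide")
  names(wide) <- sub("^rel_expr\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Run the complete analysis
#'
#' @param cohort A `synthetic_cohort` (or any list with `scans`,
#'   `sample_sheet`, and optional `qpcr`), or `NULL` when `input_dir` is
#'   given.
#' @param input_dir Cohort directory laid out as by [write_cohort()];
#'   ignored when `cohort` is supplied.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for stage files
#'   (`expression_matrix.tsv`, `group_summary.tsv`, `census.json`,
#'   `signature.json`, `validation.tsv`, `correlations.tsv`,
#'   `small_rna.json`, `outlier_report.json`, `run_report.json`).
#' @return List of class `run_report` with the stage results and record
#'   counts.
#' @export
run_all <- function(cohort = NULL, input_dir = NULL,
                    config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(input_dir)) {
      stop_mirscreen("either a cohort or an input directory is required",
                     "mirscreen_io_error")
    }
    cohort <- read_cohort(input_dir)
  }
  sheet <- validate_sample_sheet(cohort$sample_sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)

  ## Stage 1: per-array normalization and matrix assembly.
  profiles <- lapply(cohort$scans, normalize_scan, config = config$normalization)
  em <- build_expression_matrix(profiles, groups)

  ## Stage 2: group-mean filter and screening.
  filtered <- heatmap_filter(em, config$min_group_mean)
  summary <- summarize_groups(filtered)
  cen <- census(summary, config$down_thresholds, config$up_threshold)
  sig <- select_signature(summary, config$min_fold)

  ## Stage 3: qPCR validation.
  validation <- NULL
  if (!is.null(cohort$qpcr)) {
    validation <- validate_mirnas(cohort$qpcr, sheet, alpha = config$alpha,
                                  p_adjust = config$p_adjust,
                                  max_cycles = config$max_cycles)
  }

  ## Stage 4: clinical correlation (case group, validated signature levels).
  correlations <- NULL
  has_scores <- any(CLINICAL_SCORE_COLUMNS %in% names(sheet)) &&
    any(stats::complete.cases(sheet[sheet$group == "FM",
                                    intersect(CLINICAL_SCORE_COLUMNS, names(sheet)),
                                    drop = FALSE]))
  if (!is.null(cohort$qpcr) && has_scores && nrow(sig) > 0) {
    assayed_sig <- intersect(sig$mirna_id, unique(cohort$qpcr$mirna_id))
    if (length(assayed_sig) > 0) {
      expr <- qpcr_expression_table(cohort$qpcr, assayed_sig,
                                    max_cycles = config$max_cycles)
      fm_expr <- expr[expr$sample_id %in% sheet$sample_id[sheet$group == "FM"], ]
      correlations <- correlate_clinical(fm_expr, sheet)
    }
  }

  ## Stage 5: small-RNA fraction comparison.
  small_rna <- NULL
  if ("small_rna_fraction" %in% names(sheet) &&
      all(is.finite(sheet$small_rna_fraction))) {
    small_rna <- compare_small_rna_fractions(
      sheet[, c("sample_id", "small_rna_fraction")], sheet)
  }

  ## Stage 6: outlier patient against the array signature levels.
  outlier <- NULL
  if (nrow(sig) > 0 && has_scores && "MF" %in% names(sheet)) {
    outlier <- flag_outlier_patient(em, sheet, sig$mirna_id)
  }

  report <- structure(list(
    counts = list(n_samples = length(cohort$scans),
                  n_fm = sum(groups == "FM"),
                  n_control = sum(groups == "control"),
                  n_mirna = nrow(em$values),
                  n_filtered = nrow(filtered$values),
                  n_present_mean = mean(vapply(profiles, function(p)
                    sum(p$present), numeric(1)))),
    config = config,
    expression = em,
    filtered = filtered,
    group_summary = summary,
    census = cen,
    signature = sig,
    validation = validation,
    correlations = correlations,
    small_rna = small_rna,
    outlier = outlier
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d samples (%d FM / %d control), %d miRNAs (%d after filter)\n",
              x$counts$n_samples, x$counts$n_fm, x$counts$n_control,
              x$counts$n_mirna, x$counts$n_filtered))
  print(x$census)
  cat(sprintf("signature (>= %g-fold): %s\n", attr(x$signature, "min_fold"),
              paste(x$signature$mirna_id, collapse = ", ")))
  if (!is.null(x$validation)) {
    cat(sprintf("qPCR validation: %d/%d significant at p < %g\n",
                sum(x$validation$significant), nrow(x$validation),
                x$config$alpha))
  }
  invisible(x)
}

#' Write the stage outputs of a run
#'
#' @param report A [run_all()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(report$expression,
                          file.path(out_dir, "expression_matrix.tsv"))
  utils::write.table(format_group_summary(report$group_summary),
                     file.path(out_dir, "group_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(report$census),
                       file.path(out_dir, "census.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(min_fold = attr(report$signature, "min_fold"),
                            members = report$signature$mirna_id,
                            ratio = report$signature$ratio),
                       file.path(out_dir, "signature.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$validation)) {
    utils::write.table(report$validation, file.path(out_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$correlations)) {
    utils::write.table(report$correlations,
                       file.path(out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$small_rna)) {
    jsonlite::write_json(list(summary = report$small_rna$summary,
                              u = report$small_rna$u,
                              p_value = report$small_rna$p_value),
                         file.path(out_dir, "small_rna.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$outlier)) {
    jsonlite::write_json(list(sample_id = report$outlier$sample_id,
                              mf_score = report$outlier$mf_score,
                              n_exceed = report$outlier$n_exceed,
                              n_highest_in_fm = report$outlier$n_highest_in_fm,
                              per_mirna = report$outlier$per_mirna),
                         file.path(out_dir, "outlier_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(c(report$counts,
                         list(n_signature = nrow(report$signature),
                              n_down_2x = report$census$n_down_2x,
                              n_down_4x = report$census$n_down_4x)),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
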
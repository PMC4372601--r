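## Fold-change screening.
##
## Group summaries are plain arithmetic means over each group's samples
## (absent calls contribute 0 under the set_zero policy). The screening
## statistic is the control/case ratio of group means; downregulation in
## cases appears as a ratio above 1.

#' Per-miRNA group means and control/case fold ratio
#'
#' @param em An [expression_matrix()] with both groups present.
#' @return A data frame of class `group_summary` with columns `mirna_id`,
#'   `control_mean`, `fm_mean`, `ratio`. `ratio` is `control_mean / fm_mean`;
#'   when `fm_mean` is 0 with a positive control mean the ratio is `Inf`
#'   (complete case-group extinction), and `NaN` when both means are 0
#'   (undefined, excluded from ratio-based statistics).
#' @export
summarize_groups <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  for (g in GROUP_LEVELS) {
    if (!any(em$groups == g)) {
      stop_mirscreen(sprintf("group '%s' has zero samples", g),
                     "mirscreen_validation_error")
    }
  }
  control_mean <- rowMeans(em$values[, em$groups == "control", drop = FALSE])
  fm_mean <- rowMeans(em$values[, em$groups == "FM", drop = FALSE])
  ratio <- control_mean / fm_mean
  out <- data.frame(mirna_id = rownames(em$values),
                    control_mean = unname(control_mean),
                    fm_mean = unname(fm_mean),
                    ratio = unname(ratio),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Downregulation/induction census at fixed fold thresholds
#'
#' Counts miRNAs by strength of case-group change: a ratio of at least 2 is
#' an inhibition of at least 50% in cases, at least 4 a reduction of at least
#' 75%; induction is counted when the case/control ratio exceeds
#' `up_threshold`. Undefined ratios (both group means 0) are excluded from
#' the counts; infinite ratios (case mean 0, control positive) count as
#' downregulated at every threshold.
#'
#' @param summary A [summarize_groups()] result.
#' @param down_thresholds Two fold thresholds for the downregulation counts.
#' @param up_threshold Case/control ratio above which a miRNA counts as
#'   induced.
#' @return List of class `census_report`: `n_total`, `n_down_2x`,
#'   `n_down_4x`, `n_up_1p5x`, `max_induction`.
#' @export
census <- function(summary, down_thresholds = c(2, 4), up_threshold = 1.5) {
  stopifnot(inherits(summary, "group_summary"), nrow(summary) >= 1,
            length(down_thresholds) == 2)
  down_thresholds <- sort(down_thresholds)
  defined <- !is.nan(summary$ratio)
  r <- summary$ratio[defined]
  induction <- summary$fm_mean / summary$control_mean
  induction <- induction[summary$control_mean > 0]
  structure(list(
    n_total = nrow(summary),
    n_down_2x = sum(r >= down_thresholds[1]),
    n_down_4x = sum(r >= down_thresholds[2]),
    n_up_1p5x = sum(induction > up_threshold),
    max_induction = if (length(induction)) max(induction) else NA_real_
  ), class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat(sprintf(paste0("<census_report> %d miRNAs: %d down >= 2x, %d down >= 4x, ",
                     "%d induced > 1.5x (max induction %.2f)\n"),
              x$n_total, x$n_down_2x, x$n_down_4x, x$n_up_1p5x, x$max_induction))
  invisible(x)
}

#' Select the downregulated signature
#'
#' Returns the miRNAs whose control/case ratio is at least `min_fold`, sorted
#' by descending ratio. Infinite ratios (complete extinction in cases) sort
#' first; undefined ratios never qualify.
#'
#' @param summary A [summarize_groups()] result.
#' @param min_fold Minimum fold ratio for membership.
#' @return Data frame of class `signature_report` with columns `mirna_id`,
#'   `ratio`, attribute `min_fold`.
#' @export
select_signature <- function(summary, min_fold = 6) {
  stopifnot(inherits(summary, "group_summary"), nrow(summary) >= 1)
  keep <- !is.nan(summary$ratio) & summary$ratio >= min_fold
  out <- summary[keep, c("mirna_id", "ratio")]
  out <- out[order(-out$ratio, out$mirna_id), ]
  rownames(out) <- NULL
  attr(out, "min_fold") <- min_fold
  class(out) <- c("signature_report", "data.frame")
  out
}

#' Round a group summary for reporting
#'
#' Ratios are printed at 2 decimals in reports; comparisons elsewhere always
#' use full precision.
#'
#' @param summary A [summarize_groups()] result.
#' @param digits Decimal places for the printed ratio.
#' @return Data frame with a `ratio` column rounded for display.
#' @export
format_group_summary <- function(summary, digits = 2) {
  out <- as.data.frame(summary)
  out$ratio <- round(out$ratio, digits)
  out
}
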
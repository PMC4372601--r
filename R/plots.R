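## Optional figure renderers. These are display aids, not analysis steps;
## nothing downstream depends on them.

#' Clustered heatmap of a filtered expression matrix
#'
#' Draws miRNA-by-sample normalized intensities on a log2(x + 1) color scale
#' with default hierarchical ordering. Requires the pheatmap package.
#'
#' @param em An [expression_matrix()] (usually after [heatmap_filter()]).
#' @param filename Optional file to write the figure to.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_expression_heatmap <- function(em, filename = NA, ...) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop_mirscreen("the pheatmap package is required for heatmap drawing",
                   "mirscreen_dependency_error")
  }
  ann <- data.frame(group = em$groups,
                    row.names = names(em$groups))
  p <- pheatmap::pheatmap(log2(em$values + 1), annotation_col = ann,
                          show_rownames = nrow(em$values) <= 60,
                          filename = filename, ...)
  invisible(p)
}

#' Boxplots of qPCR relative expression by group
#'
#' One panel per assayed miRNA, FM vs control, on the 2^-dCt scale (log
#' optionally).
#'
#' @param qpcr qPCR table (see [read_qpcr_table()]).
#' @param sample_sheet Data frame mapping `sample_id` to `group`.
#' @param log_scale Plot on a log axis.
#' @param max_cycles Ct validity bound.
#' @return Invisibly, the per-miRNA relative-expression list plotted.
#' @export
plot_validation_boxplots <- function(qpcr, sample_sheet, log_scale = FALSE,
                                     max_cycles = 45) {
  sheet <- validate_sample_sheet(sample_sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  rel <- relative_expression(qpcr$ct, qpcr$ct_reference, max_cycles = max_cycles)
  split_rel <- split(data.frame(rel = rel, group = groups[qpcr$sample_id]),
                     qpcr$mirna_id)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(split_rel)))
  on.exit(graphics::par(old))
  for (m in names(split_rel)) {
    graphics::boxplot(rel ~ group, data = split_rel[[m]], main = m,
                      ylab = "relative expression (2^-dCt)",
                      log = if (log_scale) "y" else "")
  }
  invisible(split_rel)
}
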
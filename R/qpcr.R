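## RT-qPCR relative quantification and nonparametric validation.
##
## Relative expression against the U6 reference is 2^-(ct - ct_reference)
## (100% amplification efficiency, no calibrator sample). Group comparison is
## the two-sided Mann-Whitney U test: exact by enumeration of rank
## assignments for small tie-free samples, otherwise a normal approximation
## with midrank tie correction and continuity correction.

#' Relative expression from Ct values
#'
#' Computes `efficiency^-(ct - ct_reference)`; with the default efficiency of
#' 2 this is the standard 2^-dCt quantification against the reference gene.
#'
#' @param ct Target-miRNA threshold cycle(s).
#' @param ct_reference Reference-gene (U6) threshold cycle(s), same sample.
#' @param max_cycles Upper bound for a valid Ct.
#' @param efficiency Amplification efficiency as a per-cycle fold (2 = 100%).
#' @return Relative expression, strictly positive.
#' @export
relative_expression <- function(ct, ct_reference, max_cycles = 45,
                                efficiency = 2) {
  ok <- function(x) is.finite(x) & x > 0 & x <= max_cycles
  if (any(!ok(ct)) || any(!ok(ct_reference))) {
    stop_mirscreen(sprintf("Ct values must lie in (0, %g]", max_cycles),
                   "mirscreen_validation_error")
  }
  efficiency^-(ct - ct_reference)
}

#' Two-sided Mann-Whitney U test
#'
#' The U statistic of the first sample is computed from midrank sums. The
#' p-value is exact -- by full enumeration of the `choose(n, n_a)` rank
#' assignments -- when the pooled sample size is at most `exact_max` and
#' there are no ties; otherwise the normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_max Largest pooled size for the exact enumeration.
#' @return List with `u` (U of `a`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approximation"`).
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1 || any(!is.finite(c(a, b)))) {
    stop_mirscreen("both samples must be non-empty and finite",
                   "mirscreen_validation_error")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n <= exact_max) {
    ## Exact null: U over all C(n, na) assignments of ranks to sample a.
    rank_sets <- utils::combn(n, na)
    us <- colSums(rank_sets) - na * (na + 1) / 2
    u_lo <- min(u_a, na * nb - u_a)
    ## Distribution of U is symmetric about na*nb/2.
    p <- min(1, 2 * mean(us <= u_lo + 1e-9))
    return(list(u = u_a, p_value = p, method = "exact"))
  }
  mu <- na * nb / 2
  tie_counts <- table(r)
  sigma2 <- na * nb / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) {
    ## All pooled values identical: no evidence either way.
    return(list(u = u_a, p_value = 1, method = "normal_approximation"))
  }
  z <- u_a - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u_a, p_value = p, method = "normal_approximation")
}

#' Validate miRNAs from qPCR measurements
#'
#' For each assayed miRNA: per-sample relative expression via
#' [relative_expression()], then a two-sided Mann-Whitney comparison of the
#' FM and control groups. Technical replicates (duplicate rows per sample and
#' miRNA) are averaged on the Ct scale before quantification. A miRNA with
#' fewer than `min_per_group` measured samples in either group is skipped
#' with a warning.
#'
#' @param qpcr Data frame with columns `sample_id`, `mirna_id`, `ct`,
#'   `ct_reference` (see [read_qpcr_table()]).
#' @param sample_sheet Data frame mapping `sample_id` to `group`.
#' @param alpha Significance level (uncorrected).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()];
#'   the default `"none"` reports raw p-values.
#' @param min_per_group Minimum measured samples per group per miRNA.
#' @param max_cycles Upper bound for a valid Ct.
#' @return Data frame of class `validation_report`: `mirna_id`, `n_fm`,
#'   `n_control`, `u_statistic`, `p_value`, `significant`, `direction`
#'   (`"down_in_FM"`, `"up_in_FM"`, or `"none"`, from the group medians of
#'   relative expression).
#' @export
validate_mirnas <- function(qpcr, sample_sheet, alpha = 0.05,
                            p_adjust = "none", min_per_group = 2,
                            max_cycles = 45) {
  sheet <- validate_sample_sheet(sample_sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  unknown <- setdiff(unique(qpcr$sample_id), names(groups))
  if (length(unknown) > 0) {
    stop_mirscreen(sprintf("qPCR sample(s) absent from the sample sheet: %s",
                           paste(unknown, collapse = ", ")),
                   "mirscreen_validation_error")
  }
  ## Average technical replicates on the Ct scale.
  agg <- stats::aggregate(qpcr[, c("ct", "ct_reference")],
                          by = list(sample_id = qpcr$sample_id,
                                    mirna_id = qpcr$mirna_id),
                          FUN = mean)
  agg$rel_expr <- relative_expression(agg$ct, agg$ct_reference,
                                      max_cycles = max_cycles)
  agg$group <- groups[agg$sample_id]
  results <- lapply(split(agg, agg$mirna_id), function(d) {
    fm <- d$rel_expr[d$group == "FM"]
    ctrl <- d$rel_expr[d$group == "control"]
    if (length(fm) < min_per_group || length(ctrl) < min_per_group) {
      warning(sprintf("miRNA '%s' skipped: fewer than %d samples in a group",
                      d$mirna_id[1], min_per_group), call. = FALSE)
      return(NULL)
    }
    test <- mann_whitney_u(fm, ctrl)
    med_diff <- stats::median(fm) - stats::median(ctrl)
    data.frame(mirna_id = d$mirna_id[1],
               n_fm = length(fm), n_control = length(ctrl),
               u_statistic = test$u, p_value = test$p_value,
               direction = if (med_diff < 0) "down_in_FM"
                           else if (med_diff > 0) "up_in_FM" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, results[!vapply(results, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    stop_mirscreen("no miRNA had enough samples in both groups",
                   "mirscreen_validation_error")
  }
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}
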
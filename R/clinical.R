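## Clinical-score statistics.
##
## Severity instruments: FIQ total score on a 0-100 scale and the five MFI
## fatigue subscales (general fatigue GF, physical fatigue PF, mental fatigue
## MF, reduced activity RA, reduced motivation RM), each on 0-20. Rank
## correlation between miRNA levels and scores is computed within the case
## group only, with pairwise-complete deletion of missing values.

#' Spearman rank correlation with exact small-sample inference
#'
#' Rho is the Pearson correlation of midranks. The two-sided p-value is
#' exact -- computed over all n! permutations of one rank vector -- for
#' `n <= exact_n_max`, and otherwise uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param exact_n_max Largest n for the exact permutation p-value.
#' @return List with `rho`, `p_value`, `n`, and `method`.
#' @export
spearman_rho <- function(x, y, exact_n_max = 9) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y) || n < 3 || any(!is.finite(c(x, y)))) {
    stop_mirscreen("x and y must be equal-length finite vectors with n >= 3",
                   "mirscreen_validation_error")
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_mirscreen("correlation undefined for a constant vector",
                   "mirscreen_constant_input_error")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- permutation_matrix(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    ## rho for every permutation of y against fixed x.
    rho_null <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact_permutation"))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, method = "t_approximation")
}

#' Correlate miRNA levels with clinical severity scores
#'
#' One Spearman correlation per miRNA and score column, with
#' pairwise-complete deletion: a (sample, miRNA, score) triple enters only
#' when both the level and the score are observed. Cells with fewer than
#' `min_pairs` complete pairs are flagged not computable (`NA` rho and p).
#'
#' @param expr Data frame with a `sample_id` column and one numeric column
#'   per miRNA (per-sample levels, e.g. qPCR relative expression).
#' @param scores Data frame with `sample_id` and score columns (any of
#'   `FIQ`, `GF`, `PF`, `MF`, `RA`, `RM` that are present are used).
#' @param score_names Score columns to correlate; defaults to those present.
#' @param min_pairs Minimum complete pairs per cell.
#' @return Data frame of class `correlation_report`: `mirna_id`,
#'   `score_name`, `n`, `rho`, `p_value`, `computable`.
#' @export
correlate_clinical <- function(expr, scores,
                               score_names = NULL, min_pairs = 3) {
  stopifnot(is.data.frame(expr), "sample_id" %in% names(expr),
            is.data.frame(scores), "sample_id" %in% names(scores))
  score_names <- score_names %||%
    intersect(CLINICAL_SCORE_COLUMNS, names(scores))
  if (length(score_names) == 0) {
    stop_mirscreen("no clinical score columns found", "mirscreen_validation_error")
  }
  mirna_ids <- setdiff(names(expr), "sample_id")
  merged <- merge(expr, scores[, c("sample_id", score_names)], by = "sample_id")
  rows <- list()
  for (m in mirna_ids) {
    for (s in score_names) {
      ok <- is.finite(merged[[m]]) & is.finite(merged[[s]])
      n_ok <- sum(ok)
      if (n_ok >= min_pairs &&
          stats::sd(merged[[m]][ok]) > 0 && stats::sd(merged[[s]][ok]) > 0) {
        res <- spearman_rho(merged[[m]][ok], merged[[s]][ok])
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, score_name = s, n = n_ok,
          rho = res$rho, p_value = res$p_value, computable = TRUE,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          mirna_id = m, score_name = s, n = n_ok,
          rho = NA_real_, p_value = NA_real_, computable = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", "data.frame")
  out
}

#' Compare small-RNA fractions between groups
#'
#' Descriptive check that the groups carry similar proportions of small RNA
#' (ruling out a global RNA-composition bias as the source of expression
#' differences): per-group mean and SD plus a two-sided Mann-Whitney p-value.
#'
#' @param fractions Data frame with `sample_id` and `small_rna_fraction`
#'   (proportions in `[0, 1]`).
#' @param sample_sheet Data frame mapping `sample_id` to `group`.
#' @return List with `summary` (data frame: group, n, mean, sd), `u`, and
#'   `p_value`.
#' @export
compare_small_rna_fractions <- function(fractions, sample_sheet) {
  stopifnot(is.data.frame(fractions),
            all(c("sample_id", "small_rna_fraction") %in% names(fractions)))
  f <- fractions$small_rna_fraction
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop_mirscreen("small RNA fractions must lie in [0, 1]",
                   "mirscreen_validation_error")
  }
  sheet <- validate_sample_sheet(sample_sheet)
  groups <- stats::setNames(sheet$group, sheet$sample_id)[fractions$sample_id]
  if (any(is.na(groups))) {
    stop_mirscreen("fraction sample(s) absent from the sample sheet",
                   "mirscreen_validation_error")
  }
  fm <- f[groups == "FM"]; ctrl <- f[groups == "control"]
  if (length(fm) == 0 || length(ctrl) == 0) {
    stop_mirscreen("both groups must be non-empty", "mirscreen_validation_error")
  }
  test <- mann_whitney_u(fm, ctrl)
  list(summary = data.frame(group = c("control", "FM"),
                            n = c(length(ctrl), length(fm)),
                            mean = c(mean(ctrl), mean(fm)),
                            sd = c(stats::sd(ctrl), stats::sd(fm)),
                            stringsAsFactors = FALSE),
       u = test$u, p_value = test$p_value)
}

#' Flag the case sample with the extreme mental-fatigue score
#'
#' Identifies the FM sample with the minimum mental-fatigue (MF) score (ties
#' broken by sample_id order, with a message) and reports, for each signature
#' miRNA, whether that sample's level exceeds the control-group minimum, the
#' fold-distance to that lowest control level, and whether the sample has the
#' highest level within the FM group.
#'
#' @param em An [expression_matrix()] containing the signature miRNAs.
#' @param scores Data frame with `sample_id` and `MF`.
#' @param signature_ids Character vector of signature miRNA ids.
#' @return List of class `outlier_report`: `sample_id`, `mf_score`,
#'   `per_mirna` (data frame with `mirna_id`, `level`, `control_min`,
#'   `exceeds_control_min`, `fold_to_control_min`, `highest_in_fm`),
#'   `n_exceed`, `n_highest_in_fm`.
#' @export
flag_outlier_patient <- function(em, scores, signature_ids) {
  stopifnot(inherits(em, "expression_matrix"), length(signature_ids) >= 1)
  missing_ids <- setdiff(signature_ids, rownames(em$values))
  if (length(missing_ids) > 0) {
    stop_mirscreen(sprintf("signature miRNA(s) not in matrix: %s",
                           paste(missing_ids, collapse = ", ")),
                   "mirscreen_validation_error")
  }
  fm_samples <- names(em$groups)[em$groups == "FM"]
  ctrl_samples <- names(em$groups)[em$groups == "control"]
  mf <- stats::setNames(scores$MF, scores$sample_id)[fm_samples]
  if (all(is.na(mf))) {
    stop_mirscreen("no MF score available for any FM sample",
                   "mirscreen_validation_error")
  }
  candidates <- fm_samples[which(mf == min(mf, na.rm = TRUE))]
  candidates <- sort(candidates)
  if (length(candidates) > 1) {
    message(sprintf("MF minimum tied among %s; taking '%s'",
                    paste(candidates, collapse = ", "), candidates[1]))
  }
  flagged <- candidates[1]
  per <- do.call(rbind, lapply(signature_ids, function(m) {
    level <- em$values[m, flagged]
    ctrl_min <- min(em$values[m, ctrl_samples])
    fm_max <- max(em$values[m, fm_samples])
    data.frame(mirna_id = m, level = level, control_min = ctrl_min,
               exceeds_control_min = level > ctrl_min,
               fold_to_control_min = if (level > 0) ctrl_min / level else Inf,
               highest_in_fm = level >= fm_max,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  structure(list(sample_id = flagged, mf_score = unname(mf[flagged]),
                 per_mirna = per,
                 n_exceed = sum(per$exceeds_control_min),
                 n_highest_in_fm = sum(per$highest_in_fm)),
            class = "outlier_report")
}
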
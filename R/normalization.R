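## Per-array signal processing.
##
## The procedure, applied independently to every array:
##   1. rank the blank spots by intensity and drop the top and bottom 5%
##      (floor per tail); compute mean and SD of the retained blanks;
##   2. call a probe present iff its signal is strictly greater than
##      blank mean + 2 SD;
##   3. subtract the trimmed blank mean from every present probe;
##   4. rescale so the median background-corrected signal of present
##      probes equals 25.
## Absent probes are recorded as 0 (or NA) and never enter the median.

#' Normalization configuration
#'
#' Holds the constants of the per-array procedure. The defaults reproduce the
#' standard parameterization: 5% trim per tail, a detection threshold of the
#' blank mean plus 2 SD, a global median target of 25, and absent probes
#' recorded as zero.
#'
#' @param trim_fraction Fraction of blanks removed from each tail of the
#'   intensity ranking, in `[0, 0.5)`.
#' @param sd_multiplier Multiplier on the trimmed blank SD in the detection
#'   threshold.
#' @param target_median Post-normalization median of present probes
#'   (arbitrary fluorescence units).
#' @param absent_policy `"set_zero"` (absent probes stored as 0) or
#'   `"set_missing"` (stored as `NA`).
#' @return A list of class `normalization_config`.
#' @export
normalization_config <- function(trim_fraction = 0.05, sd_multiplier = 2,
                                 target_median = 25,
                                 absent_policy = c("set_zero", "set_missing")) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5,
            sd_multiplier >= 0, target_median > 0)
  absent_policy <- match.arg(absent_policy)
  structure(list(trim_fraction = trim_fraction, sd_multiplier = sd_multiplier,
                 target_median = target_median, absent_policy = absent_policy),
            class = "normalization_config")
}

#' Trimmed blank-spot statistics and detection threshold
#'
#' Sorts the blank intensities, removes `floor(trim_fraction * n)` spots from
#' each end, and computes the mean and sample SD of the remainder. The
#' detection threshold is `mean + sd_multiplier * sd`.
#'
#' @param blank_intensities Non-negative blank-spot intensities.
#' @param trim_fraction Fraction trimmed per tail (floor of the count).
#' @param sd_multiplier Threshold SD multiplier.
#' @return A list of class `blank_stats` with `trimmed_mean`, `trimmed_sd`,
#'   `detection_threshold`, and `n_blanks_used`.
#' @export
trimmed_blank_stats <- function(blank_intensities, trim_fraction = 0.05,
                                sd_multiplier = 2) {
  x <- as.numeric(blank_intensities)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_mirscreen("blank intensities must be finite and non-negative",
                   "mirscreen_validation_error")
  }
  n <- length(x)
  k <- floor(trim_fraction * n)
  kept <- sort(x)[seq.int(k + 1L, n - k)]
  if (length(kept) < 3L) {
    stop_mirscreen(sprintf(
      "only %d blank spots retained after trimming; at least 3 required",
      length(kept)), "mirscreen_insufficient_blanks_error")
  }
  m <- mean(kept)
  s <- stats::sd(kept)
  structure(list(trimmed_mean = m, trimmed_sd = s,
                 detection_threshold = m + sd_multiplier * s,
                 n_blanks_used = length(kept)),
            class = "blank_stats")
}

#' @export
print.blank_stats <- function(x, ...) {
  cat(sprintf("<blank_stats> mean %.4g, sd %.4g, threshold %.4g (n = %d)\n",
              x$trimmed_mean, x$trimmed_sd, x$detection_threshold,
              x$n_blanks_used))
  invisible(x)
}

#' Presence call against the blank-derived threshold
#'
#' A probe is present iff its intensity is strictly greater than the
#' detection threshold (intensities exactly at the threshold are absent).
#'
#' @param intensity Probe intensity (vectorized).
#' @param stats A [trimmed_blank_stats()] result.
#' @return Logical vector of presence flags.
#' @export
call_presence <- function(intensity, stats) {
  stopifnot(inherits(stats, "blank_stats"))
  intensity > stats$detection_threshold
}

#' Background subtraction for present probes
#'
#' Subtracts the trimmed blank mean from a present probe's intensity. Calling
#' this on an absent probe (at or below the threshold) is a contract
#' violation because the result could be non-positive.
#'
#' @param intensity Probe intensity (vectorized; every element must be
#'   present).
#' @param stats A [trimmed_blank_stats()] result.
#' @return Background-corrected intensity, strictly positive.
#' @export
subtract_background <- function(intensity, stats) {
  stopifnot(inherits(stats, "blank_stats"))
  if (any(!call_presence(intensity, stats))) {
    stop_mirscreen("subtract_background called on an absent probe",
                   "mirscreen_contract_error")
  }
  intensity - stats$trimmed_mean
}

#' Global median normalization
#'
#' Rescales background-corrected values of present probes so their median
#' equals `target_median`.
#'
#' @param corrected Named numeric vector of background-corrected intensities
#'   (present probes only).
#' @param target_median Target median after scaling.
#' @return List with `values` (scaled, same names) and `scale_factor`.
#' @export
global_normalize <- function(corrected, target_median = 25) {
  x <- as.numeric(corrected)
  if (length(x) == 0) {
    stop_mirscreen("no present miRNAs to normalize", "mirscreen_empty_profile_error")
  }
  med <- stats::median(x)
  if (!is.finite(med) || med <= 0) {
    stop_mirscreen("median of corrected signals is not positive; profile is degenerate",
                   "mirscreen_degenerate_profile_error")
  }
  scale_factor <- target_median / med
  out <- x * scale_factor
  names(out) <- names(corrected)
  list(values = out, scale_factor = scale_factor)
}

#' Normalize one array scan end to end
#'
#' Composes [trimmed_blank_stats()], [call_presence()],
#' [subtract_background()] and [global_normalize()] for a single array.
#'
#' @param scan An [array_scan()].
#' @param config A [normalization_config()].
#' @return A list of class `normalized_profile` with `sample_id`, `group`,
#'   `values` (named over all probes; absent probes 0 or `NA` per policy),
#'   `present` (named logical), `blank_stats`, `scale_factor`, and
#'   `target_median`.
#' @export
normalize_scan <- function(scan, config = normalization_config()) {
  stopifnot(inherits(scan, "array_scan"), inherits(config, "normalization_config"))
  is_blank <- scan$spots$spot_class == "blank"
  bstats <- trimmed_blank_stats(scan$spots$intensity[is_blank],
                                config$trim_fraction, config$sd_multiplier)
  probes <- scan$spots[!is_blank, ]
  present <- call_presence(probes$intensity, bstats)
  names(present) <- probes$probe_id
  if (!any(present)) {
    stop_mirscreen(sprintf("no probe above the detection threshold in sample '%s'",
                           scan$sample_id),
                   "mirscreen_empty_profile_error")
  }
  corrected <- subtract_background(probes$intensity[present], bstats)
  names(corrected) <- probes$probe_id[present]
  norm <- global_normalize(corrected, config$target_median)
  absent_value <- if (config$absent_policy == "set_zero") 0 else NA_real_
  values <- rep(absent_value, nrow(probes))
  names(values) <- probes$probe_id
  values[names(norm$values)] <- norm$values
  structure(list(sample_id = scan$sample_id, group = scan$group,
                 values = values, present = present, blank_stats = bstats,
                 scale_factor = norm$scale_factor,
                 target_median = config$target_median),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> sample '%s': %d/%d present, scale %.4g, target median %g\n",
              x$sample_id, sum(x$present), length(x$present),
              x$scale_factor, x$target_median))
  invisible(x)
}

#' Assemble normalized profiles into an expression matrix
#'
#' @param profiles List of [normalize_scan()] results sharing one probe set.
#' @param groups Optional named character vector of group labels; defaults to
#'   the labels carried by the profiles.
#' @return An [expression_matrix()].
#' @export
build_expression_matrix <- function(profiles, groups = NULL) {
  stopifnot(length(profiles) >= 1)
  ids <- names(profiles[[1]]$values)
  values <- vapply(profiles, function(p) {
    if (!identical(names(p$values), ids)) {
      stop_mirscreen("profiles do not share a common probe set",
                     "mirscreen_validation_error")
    }
    p$values
  }, numeric(length(ids)))
  colnames(values) <- unname(vapply(profiles, `[[`, character(1), "sample_id"))
  rownames(values) <- ids
  if (is.null(groups)) {
    groups <- stats::setNames(vapply(profiles, `[[`, character(1), "group"),
                              colnames(values))
  }
  expression_matrix(values, groups)
}

#' Filter miRNAs by minimum group mean
#'
#' Retains the miRNAs whose mean over control samples OR mean over FM samples
#' is strictly greater than `min_group_mean`. This is the display/screening
#' filter applied before heatmap drawing and group summarization; it removes
#' probes with negligible signal in both groups.
#'
#' @param em An [expression_matrix()] containing both groups.
#' @param min_group_mean Strict lower bound on at least one group mean.
#' @return A filtered [expression_matrix()].
#' @export
heatmap_filter <- function(em, min_group_mean = 5) {
  stopifnot(inherits(em, "expression_matrix"))
  for (g in GROUP_LEVELS) {
    if (!any(em$groups == g)) {
      stop_mirscreen(sprintf("group '%s' has zero samples", g),
                     "mirscreen_validation_error")
    }
  }
  c_mean <- rowMeans(em$values[, em$groups == "control", drop = FALSE])
  fm_mean <- rowMeans(em$values[, em$groups == "FM", drop = FALSE])
  keep <- (!is.na(c_mean) & c_mean > min_group_mean) |
    (!is.na(fm_mean) & fm_mean > min_group_mean)
  if (!any(keep)) {
    stop_mirscreen("no miRNA passes the group-mean filter",
                   "mirscreen_empty_profile_error")
  }
  expression_matrix(em$values[keep, , drop = FALSE], em$groups)
}
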
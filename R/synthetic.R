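## Synthetic cohort generator.
##
## Emulates the study design: 11 cases (FM) vs 10 controls, 1212 array probes
## plus a blank-spot population per array, log-normal fluorescence, a
## configurable fraction of sub-threshold (absent) miRNAs, an implanted
## 5-miRNA signature downregulated 6-13x in cases, a broader ~20% of miRNAs
## downregulated >= 2x, case-group clinical scores at the published
## means/SDs, and qPCR Ct values consistent with the implanted expression
## ratios.
##
## Generative model, per cohort:
##   * per-miRNA baselines are drawn once (log-normal) and shared by all
##     arrays, so between-array variation comes only from a per-array scale
##     factor (removed by normalization) and per-spot multiplicative noise;
##   * absent miRNAs are simulated by drawing their "signal" from the blank
##     distribution itself, exercising the presence caller on both sides of
##     its threshold;
##   * broadly downregulated miRNAs are drawn from the abundant end of the
##     baseline distribution (as in the real data, where the strongly
##     downregulated miRNAs are all high-signal probes), with the case-group
##     level constrained to stay above the per-array median so that global
##     median normalization remains comparable between groups;
##   * Ct values follow ct = ct_ref + dCt_base + log2(fold in cases) + noise.

#' Simulation configuration
#'
#' Defaults reproduce the study's printed cohort parameters: sample sizes
#' 11 vs 10, 1212 probes, the five signature folds (6.31-13.47) plus the
#' three extra assayed miRNAs at their printed ratios, ~20% broad
#' downregulation at 2-4x, 30% absent probes, and the published clinical and
#' small-RNA score summaries.
#'
#' @param n_fm,n_control Group sizes.
#' @param n_mirna Number of array probe species.
#' @param n_blank Blank spots per array.
#' @param blank_meanlog,blank_sdlog Log-scale location/spread of blank-spot
#'   fluorescence.
#' @param probe_meanlog,probe_sdlog Log-scale location/spread of expressed
#'   probe baselines (raw fluorescence units).
#' @param absent_fraction Fraction of probes simulated below detection.
#' @param broad_down_fraction Fraction of probes downregulated >= 2x in cases
#'   (as a fraction of `n_mirna`).
#' @param broad_fold_range Fold range of the broad downregulation.
#' @param broad_min_baseline_mult Eligibility threshold for broad
#'   downregulation, as a multiple of the typical probe level
#'   `exp(probe_meanlog)`.
#' @param signature Named numeric vector: implanted signature miRNAs and
#'   their case-group fold reductions.
#' @param extra_folds Named numeric vector: additional assayed miRNAs and
#'   folds (validation controls).
#' @param panel_baseline_unit Baseline fluorescence per unit fold for the
#'   assayed panel (keeps case-group panel signal well above detection).
#' @param noise_cv Per-spot multiplicative noise (coefficient of variation).
#' @param array_scale_sdlog Log-scale SD of the per-array global scale factor.
#' @param clinical Named list of `c(mean, sd)` per score (FIQ, GF, PF, MF,
#'   RA, RM), case group.
#' @param small_rna Named list with `control` and `FM` entries of
#'   `c(mean, sd)` small-RNA proportions.
#' @param qpcr_ct_ref_mean,qpcr_ct_ref_sd Reference-gene (U6) Ct
#'   distribution.
#' @param qpcr_delta_ct_range Range of the per-miRNA baseline dCt (target
#'   minus reference, control group).
#' @param qpcr_ct_sd Per-measurement Ct noise SD (cycles).
#' @param max_cycles Thermocycler cycle count (Ct upper bound).
#' @param seed Integer seed; every source of randomness in the cohort
#'   descends from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_fm = 11, n_control = 10,
                              n_mirna = 1212, n_blank = 100,
                              blank_meanlog = log(30), blank_sdlog = 0.35,
                              probe_meanlog = log(1500), probe_sdlog = 2.2,
                              absent_fraction = 0.3,
                              broad_down_fraction = 0.20,
                              broad_fold_range = c(2, 4),
                              broad_min_baseline_mult = 2.5,
                              signature = default_signature_folds(),
                              extra_folds = default_extra_folds(),
                              panel_baseline_unit = 2000,
                              noise_cv = 0.05,
                              array_scale_sdlog = 0.2,
                              clinical = reference_clinical_summaries(),
                              small_rna = reference_small_rna_summaries(),
                              qpcr_ct_ref_mean = 20, qpcr_ct_ref_sd = 0.5,
                              qpcr_delta_ct_range = c(4, 8),
                              qpcr_ct_sd = 1.0,
                              max_cycles = 45,
                              seed = NULL) {
  stopifnot(n_fm >= 1, n_control >= 1, n_blank >= 3,
            absent_fraction >= 0, absent_fraction < 1,
            broad_down_fraction >= 0, broad_down_fraction < 1,
            noise_cv >= 0, qpcr_ct_sd >= 0)
  panel <- c(signature, extra_folds)
  if (length(panel) > 0 && anyDuplicated(names(panel))) {
    stop_mirscreen("signature and extra_folds share miRNA ids",
                   "mirscreen_validation_error")
  }
  if (length(panel) > n_mirna) {
    stop_mirscreen("more assayed miRNAs than probes on the array",
                   "mirscreen_validation_error")
  }
  if (length(signature) > 0 &&
      (is.null(names(signature)) || any(!nzchar(names(signature))))) {
    stop_mirscreen("signature folds must be named by miRNA id",
                   "mirscreen_validation_error")
  }
  structure(as.list(environment()), class = "simulation_config")
}

## Truncated-normal sampling by resampling out-of-range draws.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate a complete synthetic cohort
#'
#' Generates array scans, a sample sheet with clinical scores and small-RNA
#' fractions, qPCR Ct measurements for the assayed panel, and a ground-truth
#' record. Fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_cohort` with `scans` (list of
#'   [array_scan()]), `sample_sheet`, `qpcr`, and `truth` (implanted fold
#'   map, signature/absent/broad id sets, per-miRNA baselines, expected
#'   noise-free expression matrix).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    cfg <- config
    sample_ids <- c(sprintf("FM%02d", seq_len(cfg$n_fm)),
                    sprintf("C%02d", seq_len(cfg$n_control)))
    groups <- c(rep("FM", cfg$n_fm), rep("control", cfg$n_control))

    panel_folds <- c(cfg$signature, cfg$extra_folds)
    n_other <- cfg$n_mirna - length(panel_folds)
    mirna_ids <- c(names(panel_folds),
                   sprintf("syn-miR-%04d", seq_len(n_other)))

    ## Per-cohort baselines; the assayed panel sits at a deterministic high
    ## baseline so its case-group level stays well above detection.
    n_other_ids <- setdiff(mirna_ids, names(panel_folds))
    baseline <- stats::setNames(numeric(cfg$n_mirna), mirna_ids)
    baseline[names(panel_folds)] <- cfg$panel_baseline_unit * panel_folds
    baseline[n_other_ids] <- stats::rlnorm(n_other, cfg$probe_meanlog,
                                           cfg$probe_sdlog)

    ## Absent probes: never expressed, signal drawn from the blank model.
    n_absent <- round(cfg$absent_fraction * cfg$n_mirna)
    absent_ids <- sample(n_other_ids, min(n_absent, length(n_other_ids)))

    ## Broad downregulation among abundant, expressed, non-panel probes.
    folds <- stats::setNames(rep(1, cfg$n_mirna), mirna_ids)
    folds[names(panel_folds)] <- panel_folds
    median0 <- exp(cfg$probe_meanlog)
    eligible <- setdiff(n_other_ids, absent_ids)
    eligible <- eligible[baseline[eligible] >=
                           cfg$broad_min_baseline_mult * median0]
    n_broad <- round(cfg$broad_down_fraction * cfg$n_mirna)
    if (n_broad > length(eligible)) {
      warning(sprintf("only %d of %d requested broadly-downregulated miRNAs eligible",
                      length(eligible), n_broad), call. = FALSE)
      n_broad <- length(eligible)
    }
    broad_ids <- sample(eligible, n_broad)
    if (n_broad > 0) {
      ## Cap each fold so the case-group level stays above the array median.
      fold_cap <- pmin(cfg$broad_fold_range[2],
                       baseline[broad_ids] / (1.25 * median0))
      folds[broad_ids] <- cfg$broad_fold_range[1] +
        stats::runif(n_broad) * (fold_cap - cfg$broad_fold_range[1])
    }

    ## Expected noise-free expression per sample (ground truth).
    expected <- matrix(rep(baseline, length(sample_ids)),
                       nrow = cfg$n_mirna,
                       dimnames = list(mirna_ids, sample_ids))
    expected[, groups == "FM"] <- expected[, groups == "FM"] / folds
    expected[absent_ids, ] <- 0

    noise_sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    array_scale <- stats::rlnorm(length(sample_ids), 0, cfg$array_scale_sdlog)

    scans <- vector("list", length(sample_ids))
    names(scans) <- sample_ids
    for (s in seq_along(sample_ids)) {
      level <- baseline
      if (groups[s] == "FM") level <- level / folds
      ## Absent probes carry no expression: their fluorescence is pure
      ## background, drawn from the same distribution as the blank spots.
      level[absent_ids] <- 0
      intensity <- level *
        stats::rlnorm(cfg$n_mirna, -noise_sdlog^2 / 2, noise_sdlog) +
        stats::rlnorm(cfg$n_mirna, cfg$blank_meanlog, cfg$blank_sdlog)
      blanks <- stats::rlnorm(cfg$n_blank, cfg$blank_meanlog, cfg$blank_sdlog)
      spots <- data.frame(
        probe_id = c(mirna_ids, sprintf("blank-%04d", seq_len(cfg$n_blank))),
        spot_class = c(rep("probe", cfg$n_mirna), rep("blank", cfg$n_blank)),
        intensity = c(intensity, blanks) * array_scale[s],
        stringsAsFactors = FALSE)
      scans[[s]] <- array_scan(sample_ids[s], groups[s], spots)
    }

    ## Clinical scores (case group only) at the published means/SDs,
    ## truncated to instrument ranges; MFI subscales are integer-valued.
    sheet <- data.frame(sample_id = sample_ids, group = groups,
                        stringsAsFactors = FALSE)
    for (sc in c("FIQ", "GF", "PF", "MF", "RA", "RM")) {
      pars <- cfg$clinical[[sc]]
      upper <- if (sc == "FIQ") 100 else 20
      vals <- rnorm_trunc(cfg$n_fm, pars[["mean"]], pars[["sd"]], 0, upper)
      vals <- if (sc == "FIQ") round(vals, 1) else round(vals)
      sheet[[sc]] <- c(vals, rep(NA_real_, cfg$n_control))
    }
    sheet$small_rna_fraction <- c(
      rnorm_trunc(cfg$n_fm, cfg$small_rna$FM[["mean"]],
                  cfg$small_rna$FM[["sd"]], 0, 1),
      rnorm_trunc(cfg$n_control, cfg$small_rna$control[["mean"]],
                  cfg$small_rna$control[["sd"]], 0, 1))

    ## qPCR: Ct consistent with the implanted expression ratios.
    qpcr <- NULL
    if (length(panel_folds) > 0) {
      dct_base <- stats::setNames(
        stats::runif(length(panel_folds), cfg$qpcr_delta_ct_range[1],
                     cfg$qpcr_delta_ct_range[2]), names(panel_folds))
      grid <- expand.grid(sample_id = sample_ids,
                          mirna_id = names(panel_folds),
                          stringsAsFactors = FALSE)
      ct_ref <- stats::setNames(
        stats::rnorm(length(sample_ids), cfg$qpcr_ct_ref_mean,
                     cfg$qpcr_ct_ref_sd), sample_ids)
      grid$ct_reference <- ct_ref[grid$sample_id]
      is_fm <- groups[match(grid$sample_id, sample_ids)] == "FM"
      grid$ct <- grid$ct_reference + dct_base[grid$mirna_id] +
        ifelse(is_fm, log2(folds[grid$mirna_id]), 0) +
        stats::rnorm(nrow(grid), 0, cfg$qpcr_ct_sd)
      grid$ct <- pmin(pmax(grid$ct, 1), cfg$max_cycles)
      qpcr <- grid[, c("sample_id", "mirna_id", "ct", "ct_reference")]
    }

    structure(list(
      scans = scans,
      sample_sheet = sheet,
      qpcr = qpcr,
      truth = list(folds = folds,
                   signature = names(cfg$signature),
                   panel = names(panel_folds),
                   absent = absent_ids,
                   broad = broad_ids,
                   baseline = baseline,
                   expected = expected)
    ), class = "synthetic_cohort")
  })
}

#' Simulate a null cohort (no group effect)
#'
#' As [simulate_cohort()] but with every implanted fold set to 1 and no broad
#' downregulation, so the groups are exchangeable. The assayed qPCR panel is
#' retained (at fold 1) for type-I-error studies of the validation test.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`.
#' @export
simulate_null_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  null_cfg <- config
  null_cfg$signature <- stats::setNames(rep(1, length(config$signature)),
                                        names(config$signature))
  null_cfg$extra_folds <- stats::setNames(rep(1, length(config$extra_folds)),
                                          names(config$extra_folds))
  null_cfg$broad_down_fraction <- 0
  simulate_cohort(null_cfg)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d scans (%d FM, %d control), %d probes, %d assayed by qPCR\n",
              length(x$scans),
              sum(x$sample_sheet$group == "FM"),
              sum(x$sample_sheet$group == "control"),
              length(x$truth$baseline), length(x$truth$panel)))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' Layout: `sample_sheet.tsv`, `scans/<sample_id>.tsv`, `qpcr.tsv`, and
#' `truth.json` (unless `truth = FALSE`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth Whether to write the ground-truth JSON.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(file.path(dir, "scans"), recursive = TRUE, showWarnings = FALSE)
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  for (scan in cohort$scans) {
    write_scan_table(scan, file.path(dir, "scans", paste0(scan$sample_id, ".tsv")))
  }
  if (!is.null(cohort$qpcr)) {
    write_qpcr_table(cohort$qpcr, file.path(dir, "qpcr.tsv"))
  }
  if (isTRUE(truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(folds = as.list(tr$folds[tr$folds != 1]),
           signature = tr$signature, panel = tr$panel,
           absent = tr$absent, broad = tr$broad),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `synthetic_cohort` (with `truth = NULL` if no truth file).
#' @export
read_cohort <- function(dir) {
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  if (!file.exists(sheet_path)) {
    stop_mirscreen(sprintf("missing sample sheet: '%s'", sheet_path),
                   "mirscreen_io_error")
  }
  sheet <- read_sample_sheet(sheet_path)
  groups <- stats::setNames(sheet$group, sheet$sample_id)
  scans <- lapply(sheet$sample_id, function(sid) {
    read_scan_table(file.path(dir, "scans", paste0(sid, ".tsv")),
                    sample_id = sid, group = groups[[sid]])
  })
  names(scans) <- sheet$sample_id
  qpcr_path <- file.path(dir, "qpcr.tsv")
  qpcr <- if (file.exists(qpcr_path)) read_qpcr_table(qpcr_path) else NULL
  structure(list(scans = scans, sample_sheet = sheet, qpcr = qpcr,
                 truth = NULL),
            class = "synthetic_cohort")
}
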
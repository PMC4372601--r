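## Raw-data model and tabular IO.
##
## A scan table is one microarray's spot-level export: one row per spot with a
## probe identifier, a spot class (probe or blank), and a fluorescence
## intensity. Blank spots carry no probe and estimate background. Delimiters
## are auto-detected (tab or comma) on read; all writers emit tab-separated
## text with a header.

SPOT_CLASSES <- c("probe", "blank")
GROUP_LEVELS <- c("FM", "control")
CLINICAL_SCORE_COLUMNS <- c("FIQ", "GF", "PF", "MF", "RA", "RM")

#' Construct a single-array scan
#'
#' Bundles one sample's spot-level readings with its identity and group label.
#'
#' @param sample_id Sample identifier, unique within a cohort.
#' @param group Group label, `"FM"` or `"control"` (may be `NA` when unknown).
#' @param spots Data frame with columns `probe_id` (character), `spot_class`
#'   (`"probe"` or `"blank"`), and `intensity` (non-negative numeric).
#' @return An object of class `array_scan`.
#' @export
array_scan <- function(sample_id, group = NA_character_, spots) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (!is.na(group) && !group %in% GROUP_LEVELS) {
    stop_mirscreen(sprintf("group must be one of %s",
                           paste(GROUP_LEVELS, collapse = ", ")),
                   "mirscreen_validation_error")
  }
  spots <- as.data.frame(spots, stringsAsFactors = FALSE)
  required <- c("probe_id", "spot_class", "intensity")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0) {
    stop_mirscreen(sprintf("spot table is missing column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "mirscreen_format_error")
  }
  spots$probe_id <- as.character(spots$probe_id)
  spots$spot_class <- as.character(spots$spot_class)
  spots$intensity <- as.numeric(spots$intensity)
  if (any(!nzchar(spots$probe_id))) {
    stop_mirscreen("probe_id must be non-empty for every spot",
                   "mirscreen_validation_error")
  }
  bad_class <- !spots$spot_class %in% SPOT_CLASSES
  if (any(bad_class)) {
    stop_mirscreen(sprintf("invalid spot_class at row %d: '%s'",
                           which(bad_class)[1], spots$spot_class[which(bad_class)[1]]),
                   "mirscreen_validation_error")
  }
  bad_int <- is.na(spots$intensity) | spots$intensity < 0
  if (any(bad_int)) {
    stop_mirscreen(sprintf("negative or missing intensity at row %d",
                           which(bad_int)[1]),
                   "mirscreen_validation_error")
  }
  is_blank <- spots$spot_class == "blank"
  if (sum(is_blank) < 1L) {
    stop_mirscreen("scan has zero blank spots; background cannot be estimated",
                   "mirscreen_validation_error")
  }
  if (sum(!is_blank) < 1L) {
    stop_mirscreen("scan has zero probe spots", "mirscreen_validation_error")
  }
  probe_ids <- spots$probe_id[!is_blank]
  if (anyDuplicated(probe_ids)) {
    stop_mirscreen(sprintf("duplicated probe_id among probe spots: '%s'",
                           probe_ids[duplicated(probe_ids)][1]),
                   "mirscreen_validation_error")
  }
  structure(list(sample_id = sample_id, group = group,
                 spots = spots[, required]),
            class = "array_scan")
}

#' @export
print.array_scan <- function(x, ...) {
  n_blank <- sum(x$spots$spot_class == "blank")
  cat(sprintf("<array_scan> sample '%s' (group %s): %d spots (%d probes, %d blanks)\n",
              x$sample_id, x$group, nrow(x$spots),
              nrow(x$spots) - n_blank, n_blank))
  invisible(x)
}

## Sniff the field separator from the header line: tab wins if present.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    stop_mirscreen(sprintf("'%s' is empty", path), "mirscreen_format_error")
  }
  if (grepl("\t", header)) "\t" else ","
}

read_delim_table <- function(path, required) {
  if (!file.exists(path)) {
    stop_mirscreen(sprintf("file not found: '%s'", path), "mirscreen_io_error")
  }
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_mirscreen(sprintf("'%s' is missing required column(s): %s",
                           path, paste(missing_cols, collapse = ", ")),
                   "mirscreen_format_error")
  }
  df
}

#' Read a spot-level scan table
#'
#' Reads a tab- or comma-delimited scan export with columns `probe_id`,
#' `spot_class` and `intensity`. Every data row becomes one spot; rows are
#' never silently dropped.
#'
#' @param path Path to the scan table.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param group Optional group label (`"FM"` or `"control"`).
#' @return An [array_scan()] object.
#' @export
read_scan_table <- function(path, sample_id = NULL, group = NA_character_) {
  df <- read_delim_table(path, c("probe_id", "spot_class", "intensity"))
  suppressWarnings(intensity <- as.numeric(df$intensity))
  bad <- which(is.na(intensity) & !is.na(df$intensity) |
                 (!is.na(intensity) & intensity < 0))
  if (length(bad) > 0) {
    stop_mirscreen(sprintf("invalid intensity '%s' at data row %d of '%s'",
                           df$intensity[bad[1]], bad[1], path),
                   "mirscreen_validation_error")
  }
  df$intensity <- intensity
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  array_scan(sample_id, group, df)
}

#' Write a scan table
#'
#' @param scan An [array_scan()] object.
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scan, path) {
  stopifnot(inherits(scan, "array_scan"))
  utils::write.table(scan$spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a miRNA-by-sample expression matrix
#'
#' The central normalized-data container: a numeric matrix with miRNA row
#' names and sample column names, plus the sample-to-group mapping.
#'
#' @param values Numeric matrix, rows = miRNAs, columns = samples. Values are
#'   non-negative normalized intensities; `NA` encodes absent calls under the
#'   `set_missing` policy.
#' @param groups Named character vector mapping each sample (column) to
#'   `"FM"` or `"control"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop_mirscreen("expression matrix must be non-empty",
                   "mirscreen_validation_error")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_mirscreen("expression matrix needs miRNA row names and sample column names",
                   "mirscreen_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    stop_mirscreen(sprintf("duplicated miRNA row name: '%s'",
                           rownames(values)[duplicated(rownames(values))][1]),
                   "mirscreen_validation_error")
  }
  if (anyDuplicated(colnames(values))) {
    stop_mirscreen("duplicated sample column names", "mirscreen_validation_error")
  }
  groups <- groups[colnames(values)]
  if (any(is.na(groups)) || !all(groups %in% GROUP_LEVELS)) {
    stop_mirscreen("every sample column needs a group label ('FM' or 'control')",
                   "mirscreen_validation_error")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_mirscreen("expression values must be non-negative",
                   "mirscreen_validation_error")
  }
  structure(list(values = values, groups = groups), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d miRNAs x %d samples (%d FM, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "FM"), sum(x$groups == "control")))
  invisible(x)
}

#' Write an expression matrix with its sample sheet sidecar
#'
#' Emits a series-matrix-style layout: first column `miRNA_ID`, one column
#' per sample, tab-separated, `NA` written as the literal token `NA`. The
#' sample-to-group mapping (and any clinical columns supplied) goes to a
#' sidecar sample sheet.
#'
#' @param em An [expression_matrix()].
#' @param path Output path for the matrix.
#' @param sample_sheet_path Output path for the sidecar sheet; defaults to
#'   `path` with a `.samples.tsv` suffix.
#' @param sample_sheet Optional pre-built sample sheet data frame to write
#'   instead of the minimal `sample_id`/`group` one.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path,
                                    sample_sheet_path = NULL,
                                    sample_sheet = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  sample_sheet_path <- sample_sheet_path %||%
    paste0(sub("\\.tsv$", "", path), ".samples.tsv")
  df <- data.frame(miRNA_ID = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  if (is.null(sample_sheet)) {
    sample_sheet <- data.frame(sample_id = colnames(em$values),
                               group = unname(em$groups),
                               stringsAsFactors = FALSE)
  }
  write_sample_sheet(sample_sheet, sample_sheet_path)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path Matrix path.
#' @param sample_sheet Either a sample sheet data frame or the path of the
#'   sidecar sheet; defaults to `path` with a `.samples.tsv` suffix.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet = NULL) {
  df <- read_delim_table(path, "miRNA_ID")
  if (ncol(df) < 2) {
    stop_mirscreen(sprintf("'%s' has no sample columns", path),
                   "mirscreen_format_error")
  }
  if (anyDuplicated(df$miRNA_ID)) {
    stop_mirscreen(sprintf("duplicated miRNA_ID in '%s'", path),
                   "mirscreen_validation_error")
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$miRNA_ID
  if (is.null(sample_sheet)) {
    sample_sheet <- paste0(sub("\\.tsv$", "", path), ".samples.tsv")
  }
  if (is.character(sample_sheet)) {
    sample_sheet <- read_sample_sheet(sample_sheet)
  }
  groups <- stats::setNames(sample_sheet$group, sample_sheet$sample_id)
  expression_matrix(values, groups)
}

#' Read a sample sheet
#'
#' Required columns: `sample_id`, `group`. Clinical-score columns
#' (`FIQ`, `GF`, `PF`, `MF`, `RA`, `RM`) and `small_rna_fraction` are carried
#' through when present.
#'
#' @param path Sheet path (tab- or comma-delimited).
#' @return Data frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_table(path, c("sample_id", "group"))
  validate_sample_sheet(df)
}

#' Write a sample sheet
#'
#' @param sheet Data frame with at least `sample_id` and `group`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

validate_sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_mirscreen(sprintf("duplicated sample_id '%s' in sample sheet",
                           df$sample_id[duplicated(df$sample_id)][1]),
                   "mirscreen_validation_error")
  }
  if (!all(df$group %in% GROUP_LEVELS)) {
    stop_mirscreen("sample sheet groups must be 'FM' or 'control'",
                   "mirscreen_validation_error")
  }
  df
}

#' Read a qPCR Ct table
#'
#' Expected columns: `sample_id`, `miRNA_ID`, `ct`, `ct_reference` (the U6
#' reference-gene cycle threshold measured in the same sample).
#'
#' @param path Table path.
#' @param max_cycles Upper bound for a valid Ct (thermocycler cycle count).
#' @return Data frame with columns `sample_id`, `mirna_id`, `ct`,
#'   `ct_reference`.
#' @export
read_qpcr_table <- function(path, max_cycles = 45) {
  df <- read_delim_table(path, c("sample_id", "miRNA_ID", "ct", "ct_reference"))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    mirna_id = as.character(df$miRNA_ID),
                    ct = as.numeric(df$ct),
                    ct_reference = as.numeric(df$ct_reference),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$ct) | out$ct <= 0 | out$ct > max_cycles |
                 !is.finite(out$ct_reference) | out$ct_reference <= 0 |
                 out$ct_reference > max_cycles)
  if (length(bad) > 0) {
    stop_mirscreen(sprintf("Ct out of (0, %g] at data row %d of '%s'",
                           max_cycles, bad[1], path),
                   "mirscreen_validation_error")
  }
  out
}

#' Write a qPCR Ct table
#'
#' @param qpcr Data frame with columns `sample_id`, `mirna_id`, `ct`,
#'   `ct_reference`.
#' @param path Output path (tab-separated; column header `miRNA_ID`).
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(qpcr, path) {
  df <- data.frame(sample_id = qpcr$sample_id, miRNA_ID = qpcr$mirna_id,
                   ct = qpcr$ct, ct_reference = qpcr$ct_reference,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
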
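# Reserved (non-feature) columns of the tab-delimited PSM input dialect.
# The layout follows the de facto community standard for rescoring input:
#   SpecId <TAB> Label <TAB> ScanNr <TAB> <features...> [<TAB> Peptide [<TAB> Proteins]]
PIN_RESERVED <- c("SpecId", "Label", "ScanNr", "Peptide", "Proteins")

#' Read a tab-delimited PSM feature table
#'
#' Parses a "PIN"-style file: a tab-separated header naming a `SpecId`
#' column (unique PSM id), a `Label` column (`1` for targets, `-1` for
#' decoys; anything else is an error, since a silently misread label
#' corrupts every downstream error-rate estimate), a `ScanNr` column (used
#' as the spectrum identifier for fold assignment), and one column per
#' real-valued feature. Optional trailing `Peptide` and `Proteins` columns
#' are carried through for reporting. Missing or non-numeric feature values
#' are rejected, not imputed.
#'
#' @param path path to an existing tab-delimited file.
#' @return a [psm_dataset()] with features in header order.
#' @export
read_pin <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("input file is empty: ", path)
  header <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate header column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  for (col in c("SpecId", "Label", "ScanNr"))
    if (!col %in% header) stop("missing required header column: ", col)
  feat_cols <- setdiff(header, PIN_RESERVED)
  if (length(feat_cols) < 1L)
    stop("no feature columns found in header")

  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  n <- nrow(tab)
  if (n == 0L) {
    return(psm_dataset(matrix(numeric(0), nrow = 0, ncol = length(feat_cols),
                              dimnames = list(NULL, feat_cols)),
                       is_decoy = logical(0), psm_id = character(0),
                       spectrum_id = character(0)))
  }
  lab <- trimws(tab$Label)
  bad <- which(!lab %in% c("1", "-1", "+1"))
  if (length(bad) > 0L)
    stop(sprintf("unknown label value '%s' in data row %d (expected 1 or -1)",
                 lab[bad[1]], bad[1]))
  feats <- matrix(NA_real_, nrow = n, ncol = length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    raw <- trimws(tab[[feat_cols[j]]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(val))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric feature value '%s' in data row %d, column '%s'",
                   raw[bad[1]], bad[1], feat_cols[j]))
    feats[, j] <- val
  }
  psm_dataset(feats, is_decoy = lab == "-1", psm_id = tab$SpecId,
              spectrum_id = tab$ScanNr,
              peptide = if ("Peptide" %in% header) tab$Peptide else NULL)
}

#' Write final rescoring results
#'
#' Writes a tab-delimited result table (columns `psm_id`, `label`, `score`,
#' `q_value`, `peptide`), one row per PSM, sorted by descending score.
#' Labels are written as `1` (target) / `-1` (decoy).
#'
#' @param results a data frame with columns `psm_id`, `is_decoy` (logical)
#'   or `label` (1/-1), `score`, `q_value`, and optionally `peptide`, such
#'   as the one returned by [merge_folds()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  results <- as.data.frame(results)
  if (!"label" %in% names(results)) {
    if (!"is_decoy" %in% names(results))
      stop("results must contain an is_decoy or label column")
    results$label <- ifelse(results$is_decoy, -1L, 1L)
  }
  for (col in c("psm_id", "score", "q_value"))
    if (!col %in% names(results)) stop("results must contain column ", col)
  if (!"peptide" %in% names(results))
    results$peptide <- rep(NA_character_, nrow(results))
  qv <- results$q_value
  if (any(!is.finite(qv) | qv < 0 | qv > 1))
    stop("q_value entries must lie in [0, 1]")
  out <- results[order(-results$score), c("psm_id", "label", "score",
                                          "q_value", "peptide")]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a written result table
#'
#' @param path path to a file produced by [write_results()].
#' @return a data frame with columns `psm_id`, `label`, `score`, `q_value`,
#'   `peptide`.
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
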
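#' Construct a PSM dataset
#'
#' A `psm_dataset` holds one row per peptide-spectrum match (PSM): a unique
#' PSM identifier, the identifier of the spectrum it was matched from, a
#' target/decoy flag, and a fixed-length numeric feature vector. Decoy PSMs
#' come from a search against shuffled or reversed protein sequences and
#' model the incorrect target matches; all error-rate estimation in this
#' package rests on that assumption.
#'
#' @param features numeric matrix, one row per PSM, one column per feature;
#'   column names are used as feature names (generated if absent). All
#'   values must be finite.
#' @param is_decoy logical vector, `TRUE` for decoy PSMs.
#' @param psm_id character vector of unique PSM identifiers (generated if
#'   `NULL`).
#' @param spectrum_id character vector grouping PSMs from the same spectrum;
#'   defaults to `psm_id` (one PSM per spectrum). Cross-validation folds are
#'   assigned by spectrum, so PSMs sharing a `spectrum_id` always share a
#'   fold.
#' @param peptide optional character vector of peptide sequences (reporting
#'   only; never used by the learner).
#' @param k fold count the dataset is intended for (default 3).
#' @return an object of class `psm_dataset`.
#' @export
psm_dataset <- function(features, is_decoy, psm_id = NULL, spectrum_id = NULL,
                        peptide = NULL, k = 3L) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature", seq_len(ncol(features)))
  is_decoy <- as.logical(is_decoy)
  if (length(is_decoy) != n)
    stop("is_decoy must have one entry per feature row")
  if (is.null(psm_id)) psm_id <- paste0("psm_", seq_len(n))
  psm_id <- as.character(psm_id)
  if (is.null(spectrum_id)) spectrum_id <- psm_id
  spectrum_id <- as.character(spectrum_id)
  if (is.null(peptide)) peptide <- rep(NA_character_, n)
  x <- structure(
    list(psm_id = psm_id, spectrum_id = spectrum_id, is_decoy = is_decoy,
         peptide = as.character(peptide), features = features,
         feature_names = colnames(features), k = as.integer(k)),
    class = "psm_dataset")
  validate_psm_dataset(x)
  x
}

validate_psm_dataset <- function(x) {
  n <- nrow(x$features)
  if (length(x$psm_id) != n || length(x$spectrum_id) != n ||
      length(x$is_decoy) != n || length(x$peptide) != n)
    stop("psm_dataset fields have inconsistent lengths")
  if (anyDuplicated(x$psm_id))
    stop("psm_id values must be unique")
  if (n > 0 && !all(is.finite(x$features)))
    stop("all feature values must be finite")
  if (anyNA(x$is_decoy))
    stop("is_decoy must not contain NA")
  if (!identical(colnames(x$features), x$feature_names))
    stop("feature_names must match feature matrix column names")
  invisible(x)
}

n_records <- function(x) nrow(x$features)
n_features <- function(x) ncol(x$features)

# Statistics (q-values, learning) need both labels; construction does not.
require_both_labels <- function(x, context = "this operation") {
  if (!any(x$is_decoy) || !any(!x$is_decoy))
    stop("dataset must contain at least one target and one decoy PSM for ",
         context)
  invisible(x)
}

#' Subset a PSM dataset by row indices
#'
#' @param x a [psm_dataset()].
#' @param idx integer or logical row index.
#' @return a `psm_dataset` with the selected records, in index order.
#' @export
dataset_subset <- function(x, idx) {
  psm_dataset(x$features[idx, , drop = FALSE], x$is_decoy[idx],
              psm_id = x$psm_id[idx], spectrum_id = x$spectrum_id[idx],
              peptide = x$peptide[idx], k = x$k)
}

#' @export
print.psm_dataset <- function(x, ...) {
  cat(sprintf("psm_dataset: %d PSMs (%d targets, %d decoys), %d features, %d spectra\n",
              n_records(x), sum(!x$is_decoy), sum(x$is_decoy),
              n_features(x), length(unique(x$spectrum_id))))
  invisible(x)
}
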
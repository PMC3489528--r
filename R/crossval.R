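#' Assign spectra to cross-validation folds
#'
#' Spectra (not individual PSMs) are dealt into `k` folds: a seeded uniform
#' random permutation of the distinct spectrum identifiers is split
#' round-robin, so fold sizes differ by at most one spectrum and all PSMs
#' sharing a spectrum share a fold. Splitting by spectrum prevents
#' near-duplicate matches of one spectrum from straddling the
#' training/validation boundary.
#'
#' @param data a [psm_dataset()].
#' @param k fold count (default `data$k`, normally 3).
#' @param seed integer seed for the permutation.
#' @return an object of class `cv_split`: list with `k`, `assignment` (a
#'   named integer vector mapping spectrum_id to fold), and `seed`.
#' @export
assign_folds <- function(data, k = data$k, seed = 1L) {
  spectra <- unique(data$spectrum_id)
  k <- as.integer(k)
  if (length(spectra) < k)
    stop("need at least ", k, " distinct spectra for ", k, " folds, got ",
         length(spectra))
  perm <- withr::with_seed(as.integer(seed), sample(spectra))
  assignment <- stats::setNames(rep_len(seq_len(k), length(perm)), perm)
  structure(list(k = k, assignment = assignment, seed = as.integer(seed)),
            class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat(sprintf("cv_split: %d folds over %d spectra (sizes %s), seed %d\n",
              x$k, length(x$assignment),
              paste(tabulate(x$assignment, x$k), collapse = "/"), x$seed))
  invisible(x)
}

record_folds <- function(data, split) {
  fold <- unname(split$assignment[data$spectrum_id])
  if (anyNA(fold))
    stop("cv_split does not cover every spectrum in the dataset")
  fold
}

#' Run the k-fold cross-validation protocol
#'
#' For each fold `i`: the PSMs of the other `k - 1` folds form the training
#' split; [grid_search()] picks hyperparameters by nested cross-validation
#' inside that split; [self_train()] fits the final model on the full
#' split; and every PSM of fold `i` is scored with that model. Each PSM is
#' therefore scored exactly once, by a model that never saw it during
#' training. The identifiers of the training PSMs are stored with each
#' fold's result so the no-leakage guarantee can be audited afterwards.
#'
#' @param data a [psm_dataset()].
#' @param cfg a [learner_config()].
#' @param split a [assign_folds()] result consistent with `data`.
#' @return a list of `fold_result` objects, one per fold: `fold`, `model`,
#'   `hyperparams`, `heldout` (data frame with `psm_id`, `spectrum_id`,
#'   `is_decoy`, `peptide`, `score`), and `train_psm_ids`.
#' @export
run_cross_validation <- function(data, cfg, split) {
  fold <- record_folds(data, split)
  out <- vector("list", split$k)
  for (i in seq_len(split$k)) {
    tr_idx <- fold != i
    te_idx <- fold == i
    if (!any(te_idx)) stop("fold ", i, " contains no PSMs")
    if (!any(data$is_decoy[tr_idx]) || !any(!data$is_decoy[tr_idx]))
      stop("training union for fold ", i, " lacks targets or decoys")
    tr <- dataset_subset(data, tr_idx)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 1000L + i)
    hp <- tryCatch(grid_search(tr, cfg_i),
                   error = function(e) stop("fold ", i, ": ",
                                            conditionMessage(e)))
    model <- tryCatch(self_train(tr, cfg_i, hp),
                      error = function(e) stop("fold ", i, ": ",
                                               conditionMessage(e)))
    te <- dataset_subset(data, te_idx)
    out[[i]] <- structure(
      list(fold = i, model = model, hyperparams = hp,
           heldout = data.frame(psm_id = te$psm_id,
                                spectrum_id = te$spectrum_id,
                                is_decoy = te$is_decoy,
                                peptide = te$peptide,
                                score = predict(model, te),
                                stringsAsFactors = FALSE),
           train_psm_ids = tr$psm_id),
      class = "fold_result")
  }
  out
}
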
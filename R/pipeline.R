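#' Rescore a PSM dataset
#'
#' The full protocol: assign spectra to `k` folds, run the cross-validated
#' self-training SVM so every PSM is scored by a model never trained on
#' it, fit the per-fold normalization, merge the folds, and compute final
#' q-values on the merged normalized scores.
#'
#' With `cv = FALSE` the protective machinery is deliberately switched
#' off — hyperparameters are picked by performance on the very data they
#' are trained on, one model is trained on all PSMs and then scores those
#' same PSMs, and q-values are computed on those scores. This mode exists
#' only to demonstrate how overfitting corrupts the error-rate estimates;
#' its q-values must not be trusted.
#'
#' @param data a [psm_dataset()] with both targets and decoys.
#' @param cfg a [learner_config()].
#' @param k fold count (default 3).
#' @param alpha significance threshold anchoring the per-fold
#'   normalization (default 0.01).
#' @param cv logical; `FALSE` disables cross-validation (see above).
#' @return a list of class `rescore_run`: `results` (the merged
#'   `rescore_result` data frame), `pi0`, `cv`, and when `cv = TRUE` also
#'   `split`, `fold_results`, `norm_params`.
#' @export
rescore <- function(data, cfg = learner_config(), k = 3L, alpha = 0.01,
                    cv = TRUE) {
  require_both_labels(data, "rescoring")
  if (cv) {
    split <- assign_folds(data, k = k, seed = cfg$seed)
    fold_results <- run_cross_validation(data, cfg, split)
    norm_params <- lapply(fold_results, function(fr)
      fit_normalization(fr$heldout$score, fr$heldout$is_decoy,
                        alpha = alpha, fold = fr$fold))
    results <- merge_folds(fold_results, norm_params,
                           pi0 = if (cfg$pi0_mode == "one") 1 else NULL,
                           lambda = cfg$lambda)
    structure(list(results = results, pi0 = attr(results, "pi0"),
                   cv = TRUE, split = split, fold_results = fold_results,
                   norm_params = norm_params),
              class = "rescore_run")
  } else {
    warning("cross-validation disabled: estimated error rates are ",
            "unvalidated and optimistically biased")
    # grid "search" without a hold-out: each candidate judged on its own
    # training data (train == test), then the winner's model reused
    best_cnt <- -1L
    best_model <- NULL
    best_hp <- NULL
    for (h in seq_along(cfg$grid)) {
      model <- self_train(data, cfg, cfg$grid[[h]])
      sc <- predict(model, data)
      cnt <- count_significant(sc, data$is_decoy, cfg$q_select,
                               pi0_mode = cfg$pi0_mode, lambda = cfg$lambda)
      if (cnt > best_cnt) {
        best_cnt <- cnt
        best_model <- model
        best_hp <- cfg$grid[[h]]
      }
    }
    scores <- predict(best_model, data)
    pi0 <- resolve_pi0(scores, data$is_decoy, cfg$pi0_mode, cfg$lambda)
    results <- data.frame(psm_id = data$psm_id,
                          spectrum_id = data$spectrum_id,
                          is_decoy = data$is_decoy, peptide = data$peptide,
                          fold = NA_integer_, raw_score = scores,
                          score = scores,
                          q_value = qvalues_with_decoys(scores,
                                                        data$is_decoy, pi0),
                          stringsAsFactors = FALSE)
    attr(results, "pi0") <- pi0
    class(results) <- c("rescore_result", "data.frame")
    structure(list(results = results, pi0 = pi0, cv = FALSE,
                   model = best_model, hyperparams = best_hp),
              class = "rescore_run")
  }
}

#' @export
print.rescore_run <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "rescore_run (%s): %d PSMs (%d targets), pi0 = %.4g, %d targets at q <= 0.01\n",
    if (x$cv) "cross-validated" else "NO cross-validation",
    nrow(r), sum(!r$is_decoy), x$pi0,
    sum(!r$is_decoy & r$q_value <= 0.01)))
  invisible(x)
}
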
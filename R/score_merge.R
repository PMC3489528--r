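#' Fit the per-fold score normalization
#'
#' The k folds are scored by k different classifiers, whose raw decision
#' values are not comparable. Each fold therefore gets an affine transform
#' pinned by two anchors from its own internal target-decoy analysis: the
#' minimal raw target score whose within-fold q-value is at or below
#' `alpha` maps to 0, and the median of the fold's decoy scores maps to
#' -1. Both targets and decoys of the fold are transformed with the same
#' map. If no target reaches `q <= alpha` the threshold anchor falls back
#' to the top-ranked target's score, with a warning (the fold is too weak
#' to calibrate exactly but aborting the whole run would be worse).
#'
#' @param fold_scores numeric vector of the fold's raw scores (targets and
#'   decoys), optionally named by psm_id.
#' @param is_decoy logical vector aligned with `fold_scores`.
#' @param alpha significance threshold anchoring the zero point (default
#'   0.01).
#' @param pi0 pi0 used in the within-fold q-value computation (default 1,
#'   the conservative parameter-free choice).
#' @param fold optional fold label carried through for reporting.
#' @return an object of class `normalization_params`: `fold`, `s_star`,
#'   `m_decoy`, `scale`, `offset`, `degenerate`.
#' @export
fit_normalization <- function(fold_scores, is_decoy, alpha = 0.01, pi0 = 1,
                              fold = NA_integer_) {
  if (length(fold_scores) != length(is_decoy))
    stop("fold_scores and is_decoy must be aligned")
  t_scores <- fold_scores[!is_decoy]
  d_scores <- fold_scores[is_decoy]
  if (length(t_scores) == 0L || length(d_scores) == 0L)
    stop("fold must contain both target and decoy PSMs")
  qr <- compute_qvalues(t_scores, d_scores, pi0)
  sig <- t_scores[qr$qvalues <= alpha]
  degenerate <- length(sig) == 0L
  if (degenerate) {
    s_star <- max(t_scores)
    warning(sprintf(
      "fold %s: no target PSM reaches q <= %g; anchoring the threshold at the top-ranked target score",
      as.character(fold), alpha))
  } else {
    s_star <- min(sig)
  }
  m_decoy <- stats::median(d_scores)   # mean of middle two for even counts
  if (!(s_star > m_decoy))
    stop(sprintf(
      "fold %s: threshold score (%g) does not exceed the decoy median (%g); scores are degenerate",
      as.character(fold), s_star, m_decoy))
  scale <- 1 / (s_star - m_decoy)
  structure(list(fold = fold, s_star = s_star, m_decoy = m_decoy,
                 scale = scale, offset = -s_star * scale,
                 degenerate = degenerate),
            class = "normalization_params")
}

#' Apply a fitted normalization to raw scores
#'
#' @param params a [fit_normalization()] result.
#' @param x numeric raw scores.
#' @return normalized scores `params$scale * x + params$offset`.
#' @export
apply_normalization <- function(params, x) {
  params$scale * x + params$offset
}

#' @export
print.normalization_params <- function(x, ...) {
  cat(sprintf(
    "normalization_params (fold %s): s_star = %.4g -> 0, decoy median = %.4g -> -1%s\n",
    as.character(x$fold), x$s_star, x$m_decoy,
    if (x$degenerate) " [degenerate fallback]" else ""))
  invisible(x)
}

#' Merge normalized folds and compute final q-values
#'
#' Every PSM's raw fold score is mapped by its own fold's affine transform;
#' the folds are concatenated; and a single target-decoy analysis over the
#' merged normalized scores yields the final q-values. Decoy PSMs are
#' reported with the q-value of the highest-scoring target at or below
#' their score.
#'
#' @param fold_results list of `fold_result` objects from
#'   [run_cross_validation()].
#' @param params list of [fit_normalization()] results, one per fold, in
#'   the same order.
#' @param pi0 pi0 for the final q-value computation, or `NULL` to estimate
#'   it from the merged normalized scores with [estimate_pi0()].
#' @param lambda lambda for the pi0 estimate when `pi0` is `NULL`.
#' @return a data frame of class `rescore_result` with columns `psm_id`,
#'   `spectrum_id`, `is_decoy`, `peptide`, `fold`, `raw_score`, `score`
#'   (normalized), `q_value`; the pi0 used is attached as attribute
#'   `"pi0"`.
#' @export
merge_folds <- function(fold_results, params, pi0 = NULL, lambda = 0.5) {
  if (length(fold_results) != length(params))
    stop("need exactly one normalization_params per fold")
  pieces <- vector("list", length(fold_results))
  for (i in seq_along(fold_results)) {
    fr <- fold_results[[i]]
    pr <- params[[i]]
    if (is.null(pr)) stop("fold ", fr$fold, " has no normalization params")
    df <- fr$heldout
    pieces[[i]] <- data.frame(psm_id = df$psm_id,
                              spectrum_id = df$spectrum_id,
                              is_decoy = df$is_decoy, peptide = df$peptide,
                              fold = fr$fold, raw_score = df$score,
                              score = apply_normalization(pr, df$score),
                              stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, pieces)
  rownames(merged) <- NULL
  if (is.null(pi0))
    pi0 <- estimate_pi0(merged$score[!merged$is_decoy],
                        merged$score[merged$is_decoy], lambda)
  merged$q_value <- qvalues_with_decoys(merged$score, merged$is_decoy, pi0)
  attr(merged, "pi0") <- pi0
  class(merged) <- c("rescore_result", "data.frame")
  merged
}
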
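# Number of decoy scores >= each query score. At a tied score the decoy is
# counted as ">=": ties rank decoys above targets, which is the
# conservative direction for FDR estimation.
decoy_ge_counts <- function(scores, decoy_scores) {
  sd_ <- sort(decoy_scores)
  length(sd_) - findInterval(scores, sd_, left.open = TRUE)
}

#' Estimate pi0, the fraction of incorrect matches among target PSMs
#'
#' The target-decoy FDR multiplies the decoy/target count ratio by pi0, the
#' expected proportion of incorrect PSMs among all target PSMs, estimated
#' from the distribution of low-scoring matches. Each target score is first
#' converted to an empirical p-value against the decoy score distribution,
#' `p = (1 + #\{decoys >= s\}) / (1 + #decoys)` (the +1 correction avoids
#' p = 0), and the fixed-lambda estimator
#' `pi0 = #\{p > lambda\} / ((1 - lambda) * #targets)` is applied and
#' clamped to `[0, 1]`.
#'
#' @param target_scores numeric vector of target PSM scores.
#' @param decoy_scores numeric vector of decoy PSM scores (non-empty).
#' @param lambda tuning constant in (0, 1); p-values above `lambda` are
#'   taken to be drawn from the null (incorrect) component. Default 0.5.
#' @return pi0 estimate in `[0, 1]`.
#' @export
estimate_pi0 <- function(target_scores, decoy_scores, lambda = 0.5) {
  if (length(target_scores) == 0L) stop("target score list is empty")
  if (length(decoy_scores) == 0L)
    stop("decoy score list is empty: empirical p-values are undefined")
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly between 0 and 1")
  p <- (1 + decoy_ge_counts(target_scores, decoy_scores)) /
    (1 + length(decoy_scores))
  pi0 <- sum(p > lambda) / ((1 - lambda) * length(target_scores))
  min(max(pi0, 0), 1)
}

#' Target-decoy q-values for a list of target scores
#'
#' For every candidate score threshold `t` (each observed target score) the
#' estimated false discovery rate is
#' `FDR(t) = pi0 * #\{decoys >= t\} / #\{targets >= t\}`, capped at 1; at a
#' tied score decoys count as above the threshold before targets. The
#' q-value of a target PSM with score `s` is the minimum `FDR(t)` over all
#' thresholds `t <= s`, i.e. the lowest FDR at which that PSM would still
#' be accepted.
#'
#' @param target_scores numeric vector of target PSM scores (non-empty).
#' @param decoy_scores numeric vector of decoy PSM scores (non-empty).
#' @param pi0 multiplier in `[0, 1]`; 1 is the conservative choice, or use
#'   [estimate_pi0()].
#' @return an object of class `qvalue_result`: a list with `scores` (the
#'   input target scores), `qvalues` aligned with them, and `pi0`.
#' @export
compute_qvalues <- function(target_scores, decoy_scores, pi0 = 1) {
  if (length(target_scores) == 0L) stop("target score list is empty")
  if (length(decoy_scores) == 0L) stop("decoy score list is empty")
  if (!is.finite(pi0) || pi0 < 0 || pi0 > 1)
    stop("pi0 must lie in [0, 1]")
  ord <- order(target_scores, decreasing = TRUE)
  ts <- target_scores[ord]
  n <- length(ts)
  fdr <- pmin(1, pi0 * decoy_ge_counts(ts, decoy_scores) / seq_len(n))
  # running minimum from the most permissive threshold upward
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(n)
  q[ord] <- q_sorted
  structure(list(scores = target_scores, qvalues = q, pi0 = pi0),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("qvalue_result: %d target PSMs, pi0 = %.4g, %d with q <= 0.01\n",
              length(x$qvalues), x$pi0, sum(x$qvalues <= 0.01)))
  invisible(x)
}

# q-values for a merged target+decoy score list. Targets get the q-value
# from compute_qvalues(); a decoy inherits the q-value of the highest
# scoring target at or below its score (the minimum FDR over thresholds
# that would include it), or 1 if no target scores at or below it.
qvalues_with_decoys <- function(scores, is_decoy, pi0 = 1) {
  tq <- compute_qvalues(scores[!is_decoy], scores[is_decoy], pi0)
  q <- numeric(length(scores))
  q[!is_decoy] <- tq$qvalues
  ts <- tq$scores
  ord <- order(ts)
  pos <- findInterval(scores[is_decoy], ts[ord])
  qd <- c(1, tq$qvalues[ord])[pos + 1L]
  q[is_decoy] <- qd
  q
}

# Count of target PSMs at q <= q_select, with pi0 chosen per mode.
count_significant <- function(scores, is_decoy, q_select, pi0_mode = "one",
                              lambda = 0.5) {
  pi0 <- resolve_pi0(scores, is_decoy, pi0_mode, lambda)
  qr <- compute_qvalues(scores[!is_decoy], scores[is_decoy], pi0)
  sum(qr$qvalues <= q_select)
}

resolve_pi0 <- function(scores, is_decoy, pi0_mode, lambda = 0.5) {
  pi0_mode <- match.arg(pi0_mode, c("fixed-lambda", "one"))
  if (pi0_mode == "one") return(1)
  estimate_pi0(scores[!is_decoy], scores[is_decoy], lambda)
}
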
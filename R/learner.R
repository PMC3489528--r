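#' Configuration of the self-training learner
#'
#' @param q_select q-value threshold below which target PSMs are taken as
#'   positive training examples (default 0.01). Decoys are never positives.
#' @param n_iter number of self-training iterations (default 10; fixed
#'   count, no convergence test, so runs are deterministic).
#' @param grid list of [hyperparams()] candidates for the nested grid
#'   search; non-empty. Default [default_grid()].
#' @param seed master seed; all solver and fold randomness derives from it.
#' @param pi0_mode how pi0 is chosen when q-values drive positive selection
#'   and grid scoring: `"fixed-lambda"` (estimate via [estimate_pi0()]) or
#'   `"one"` (conservative pi0 = 1).
#' @param lambda lambda for the fixed-lambda pi0 estimator.
#' @param relax fallback q thresholds tried, in order, when `q_select`
#'   selects no positives in an iteration.
#' @return an object of class `learner_config`.
#' @export
learner_config <- function(q_select = 0.01, n_iter = 10L,
                           grid = default_grid(), seed = 1L,
                           pi0_mode = c("fixed-lambda", "one"),
                           lambda = 0.5, relax = c(0.05, 0.10)) {
  if (!is.finite(q_select) || q_select <= 0 || q_select >= 1)
    stop("q_select must lie strictly between 0 and 1")
  if (n_iter < 0) stop("n_iter must be non-negative")
  if (length(grid) == 0L) stop("hyperparameter grid must be non-empty")
  structure(list(q_select = q_select, n_iter = as.integer(n_iter),
                 grid = grid, seed = as.integer(seed),
                 pi0_mode = match.arg(pi0_mode), lambda = lambda,
                 relax = relax),
            class = "learner_config")
}

#' Choose the initial scoring direction
#'
#' The self-training loop needs a starting score before any model exists.
#' Every feature is tried in both orientations; the single signed feature
#' that maximizes the number of target PSMs at q <= `q_select` (with
#' pi0 = 1) wins. Ties go to the lowest feature index, then to sign +1.
#'
#' @param data a [psm_dataset()] with both targets and decoys.
#' @param q_select q-value threshold used to count identifications.
#' @return a list with `feature_index`, `sign`, and `n_significant`.
#' @export
choose_initial_direction <- function(data, q_select = 0.01) {
  require_both_labels(data, "choosing an initial direction")
  best <- list(feature_index = 1L, sign = 1, n_significant = -1L)
  for (j in seq_len(n_features(data))) {
    for (sgn in c(1, -1)) {
      cnt <- count_significant(sgn * data$features[, j], data$is_decoy,
                               q_select, pi0_mode = "one")
      if (cnt > best$n_significant)
        best <- list(feature_index = j, sign = sgn, n_significant = cnt)
    }
  }
  best
}

#' Select positive training examples
#'
#' Marks exactly the target PSMs whose q-value, computed from the supplied
#' scores against this split's decoys, is at or below `q_select`. Decoys
#' are never selected, whatever their score.
#'
#' @param scores numeric scores aligned with `data`'s records.
#' @param data a [psm_dataset()].
#' @param q_select q-value threshold.
#' @param pi0 pi0 multiplier used in the q-value computation.
#' @return logical mask over records.
#' @export
select_positives <- function(scores, data, q_select, pi0 = 1) {
  if (length(scores) != n_records(data))
    stop("scores must align with dataset records")
  require_both_labels(data, "selecting positives")
  qr <- compute_qvalues(scores[!data$is_decoy], scores[data$is_decoy], pi0)
  mask <- logical(n_records(data))
  mask[!data$is_decoy] <- qr$qvalues <= q_select
  mask
}

#' Self-training linear SVM on one training split
#'
#' Iterates `cfg$n_iter` times: score every PSM in the split with the
#' current model (initially the best single signed feature from
#' [choose_initial_direction()]); select confident targets at
#' `q <= q_select` as positives; fit a weighted linear SVM of those
#' positives against all decoys (targets not selected are left unlabeled);
#' adopt the new model. If an iteration selects no positives the threshold
#' is relaxed stepwise (`cfg$relax`); if still empty the current model is
#' returned unchanged.
#'
#' @param data a [psm_dataset()] (one cross-validation training split) with
#'   both targets and decoys.
#' @param cfg a [learner_config()].
#' @param hp a [hyperparams()] object.
#' @return the final `svm_model`.
#' @export
self_train <- function(data, cfg, hp) {
  if (!any(data$is_decoy)) stop("training split contains no decoy PSMs")
  if (!any(!data$is_decoy)) stop("training split contains no target PSMs")
  init <- choose_initial_direction(data, cfg$q_select)
  model <- unit_direction_model(init$feature_index, init$sign,
                                data$feature_names)
  if (cfg$n_iter == 0L) return(model)
  std <- feature_standardizer(data$features)
  for (it in seq_len(cfg$n_iter)) {
    scores <- predict(model, data)
    pi0 <- resolve_pi0(scores, data$is_decoy, cfg$pi0_mode, cfg$lambda)
    mask <- select_positives(scores, data, cfg$q_select, pi0)
    if (!any(mask)) {
      for (qr in cfg$relax) {
        if (qr <= cfg$q_select) next
        mask <- select_positives(scores, data, qr, pi0)
        if (any(mask)) break
      }
    }
    if (!any(mask)) return(model)
    model <- train_weighted_svm(data$features, positives = mask,
                                negatives = data$is_decoy, hp = hp,
                                seed = derive_seed(cfg$seed, it),
                                standardizer = std)
  }
  model
}

#' Nested grid search for SVM hyperparameters
#'
#' Splits the training split into 3 nested folds (by spectrum). For every
#' hyperparameter candidate, [self_train()] runs on each nested 2/3 and the
#' held-out 1/3 is scored with the resulting model; the candidate's merit
#' is the total number of held-out target PSMs at `q <= cfg$q_select`. The
#' candidate with the largest total wins; ties go to the first candidate in
#' grid order. With a single candidate no nested training is performed.
#'
#' @param data a [psm_dataset()] (one cross-validation training split).
#' @param cfg a [learner_config()].
#' @return the winning [hyperparams()], with the per-candidate held-out
#'   counts attached as attribute `"counts"`.
#' @export
grid_search <- function(data, cfg) {
  if (length(cfg$grid) == 1L) return(cfg$grid[[1L]])
  split <- assign_folds(data, k = 3L, seed = derive_seed(cfg$seed, 7L))
  fold_of <- split$assignment[data$spectrum_id]
  for (i in 1:3) {
    te <- fold_of == i
    if (!any(data$is_decoy[te]) || !any(!data$is_decoy[te]) ||
        !any(data$is_decoy[!te]) || !any(!data$is_decoy[!te]))
      stop("nested cross-validation part ", i, " lacks targets or decoys; ",
           "use larger folds or more PSMs")
  }
  counts <- numeric(length(cfg$grid))
  for (i in 1:3) {
    tr <- dataset_subset(data, fold_of != i)
    te <- dataset_subset(data, fold_of == i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 100L + i)
    for (h in seq_along(cfg$grid)) {
      model <- self_train(tr, cfg_i, cfg$grid[[h]])
      sc <- predict(model, te)
      counts[h] <- counts[h] +
        count_significant(sc, te$is_decoy, cfg$q_select,
                          pi0_mode = cfg$pi0_mode, lambda = cfg$lambda)
    }
  }
  best <- which.max(counts) # first maximum wins on ties
  out <- cfg$grid[[best]]
  attr(out, "counts") <- counts
  out
}
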
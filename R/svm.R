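#' SVM hyperparameters
#'
#' Misclassification costs for the soft-margin linear SVM. Positive and
#' negative examples carry separate costs because the self-training loop
#' typically selects far fewer confident positives than it has decoy
#' negatives; an asymmetric cost keeps the margin from being dominated by
#' the majority class.
#'
#' @param c_pos cost of a hinge violation on a positive (confident target)
#'   example; strictly positive.
#' @param c_neg cost on a negative (decoy) example; strictly positive.
#' @return an object of class `hyperparams`.
#' @export
hyperparams <- function(c_pos, c_neg) {
  if (!is.finite(c_pos) || c_pos <= 0 || !is.finite(c_neg) || c_neg <= 0)
    stop("c_pos and c_neg must be strictly positive")
  structure(list(c_pos = c_pos, c_neg = c_neg), class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf("hyperparams: c_pos = %g, c_neg = %g\n", x$c_pos, x$c_neg))
  invisible(x)
}

#' Default hyperparameter grid
#'
#' Nine candidates: `c_pos` in \{0.1, 1, 10\} crossed with
#' `c_neg = c_pos * \{1, 3, 10\}`.
#'
#' @return a list of [hyperparams()] objects.
#' @export
default_grid <- function() {
  out <- list()
  for (cp in c(0.1, 1, 10))
    for (mult in c(1, 3, 10))
      out[[length(out) + 1L]] <- hyperparams(cp, cp * mult)
  out
}

# Standardization statistics of a training split. Constant columns get
# unit scale so they contribute nothing rather than dividing by zero.
feature_standardizer <- function(features) {
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

new_svm_model <- function(weights, intercept, hyperparams = NULL,
                          feature_names = names(weights), fit_info = NULL) {
  structure(list(weights = stats::setNames(as.numeric(weights), feature_names),
                 intercept = as.numeric(intercept),
                 hyperparams = hyperparams, fit_info = fit_info),
            class = "svm_model")
}

# Degenerate model scoring by a single signed feature; used for the
# self-training initialization and for n_iter = 0.
unit_direction_model <- function(feature_index, sign, feature_names) {
  w <- numeric(length(feature_names))
  w[feature_index] <- sign
  new_svm_model(w, 0, feature_names = feature_names,
                fit_info = list(kind = "unit_direction",
                                feature_index = feature_index, sign = sign))
}

#' Fit a weighted soft-margin linear SVM
#'
#' Minimizes `0.5 * ||w||^2 + c_pos * sum(pos hinge) + c_neg * sum(neg
#' hinge)` by dual coordinate descent. Rows flagged by neither mask are
#' excluded from the objective (strict self-training semantics: ambiguous
#' targets are unlabeled, not negatives). Features are standardized before
#' fitting using statistics from `features` (all rows of the training
#' split, or supply `standardizer` to reuse precomputed statistics); the
#' returned weights and intercept are mapped back to the raw feature scale,
#' so `score = features %*% weights + intercept`.
#'
#' @param features numeric matrix, one row per PSM.
#' @param positives,negatives disjoint logical masks over rows; each must
#'   select at least one row.
#' @param hp a [hyperparams()] object.
#' @param seed integer seed for the solver's sweep order; fits are bitwise
#'   reproducible for a fixed seed.
#' @param standardizer optional list with `center` and `scale` (as from the
#'   internal standardizer); computed from `features` when `NULL`.
#' @param tol projected-gradient stopping tolerance of the dual solver.
#' @param max_epochs maximum number of full coordinate sweeps.
#' @return an object of class `svm_model` with raw-scale `weights` and
#'   `intercept`.
#' @export
train_weighted_svm <- function(features, positives, negatives, hp,
                               seed = 1L, standardizer = NULL,
                               tol = 0.1, max_epochs = 1000L) {
  features <- as.matrix(features)
  positives <- as.logical(positives)
  negatives <- as.logical(negatives)
  if (any(positives & negatives))
    stop("positive and negative masks must be disjoint")
  if (!any(positives) || !any(negatives))
    stop("training requires at least one positive and one negative example")
  if (is.null(standardizer)) standardizer <- feature_standardizer(features)
  keep <- positives | negatives
  X <- sweep(sweep(features[keep, , drop = FALSE], 2, standardizer$center),
             2, standardizer$scale, "/")
  y <- ifelse(positives[keep], 1L, -1L)
  cost <- ifelse(y > 0, hp$c_pos, hp$c_neg)
  fit <- dcd_linear_svm(X, as.integer(y), as.numeric(cost), bias = 1,
                        max_epochs = as.integer(max_epochs), tol = tol,
                        seed = as.integer(seed))
  # map standardized-space solution back to the raw feature scale
  w_std <- fit$weights
  w_raw <- w_std / standardizer$scale
  b_raw <- fit$intercept - sum(w_std * standardizer$center / standardizer$scale)
  new_svm_model(w_raw, b_raw, hyperparams = hp,
                feature_names = colnames(features),
                fit_info = list(kind = "svm", epochs = fit$epochs,
                                converged = fit$converged,
                                n_pos = sum(positives), n_neg = sum(negatives)))
}

#' Score PSMs with a linear model
#'
#' @param object an `svm_model`.
#' @param newdata a [psm_dataset()] or a numeric feature matrix.
#' @param ... unused.
#' @return numeric vector of decision values, one per row.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "psm_dataset")) newdata$features
       else as.matrix(newdata)
  if (ncol(X) != length(object$weights))
    stop("feature count mismatch between model and data")
  drop(X %*% object$weights) + object$intercept
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("svm_model: %d features, |w| = %.4g, intercept = %.4g\n",
              length(x$weights), sqrt(sum(x$weights^2)), x$intercept))
  invisible(x)
}
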
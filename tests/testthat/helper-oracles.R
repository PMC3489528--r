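# Independent oracles and fixture builders shared across the test files.

# Brute-force q-values: a double loop over every candidate threshold (each
# observed target score), with FDR(t) = pi0 * #{decoys >= t} / #{targets
# >= t} capped at 1, and q(s) = min FDR over thresholds t <= s. Decoys
# count as ">= t" at tied scores, as in the implementation's tie rule.
brute_qvalues <- function(target_scores, decoy_scores, pi0 = 1) {
  fdr_at <- vapply(target_scores, function(th)
    min(1, pi0 * sum(decoy_scores >= th) / sum(target_scores >= th)),
    numeric(1))
  vapply(seq_along(target_scores), function(i)
    min(fdr_at[target_scores <= target_scores[i]]), numeric(1))
}

# Reference solution of the weighted SVM dual by projected gradient
# ascent: same objective as the package solver (bias regularized via an
# augmented constant coordinate) but a different algorithm family,
# suitable as an oracle at tiny n.
ref_svm_qp <- function(X, y, cost, bias = 1, iters = 2e5) {
  Xa <- cbind(X, bias)
  Q <- (Xa %*% t(Xa)) * outer(y, y)
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  a <- rep(0, nrow(Xa))
  for (it in seq_len(iters))
    a <- pmin(pmax(a + (1 - drop(Q %*% a)) / L, 0), cost)
  wa <- drop(t(Xa) %*% (a * y))
  p <- ncol(X)
  list(weights = wa[seq_len(p)], intercept = wa[p + 1] * bias,
       decision = drop(X %*% wa[seq_len(p)]) + wa[p + 1] * bias)
}

# Scaled-down simulated dataset: same generative structure as the
# benchmark configuration (i.i.d. standard-normal features; an offset on
# feature 1 marks the correct targets) at desk size.
small_sim_config <- function(n_target = 300L, n_decoy = 300L,
                             n_features = 10L, n_correct = 120L,
                             offset = 10, n_datasets = 2L, seed = 1L) {
  simulation_config(n_target = n_target, n_decoy = n_decoy,
                    n_features = n_features, n_correct = n_correct,
                    offset = offset, n_datasets = n_datasets, seed = seed)
}

# Small hyperparameter grid to keep nested searches fast in unit tests.
small_grid <- function() list(hyperparams(1, 1), hyperparams(1, 3),
                              hyperparams(10, 10))

small_learner <- function(seed = 1L, ...) {
  learner_config(grid = small_grid(), seed = seed, ...)
}

# Write a toy PIN file: n_target targets and n_decoy decoys, 3 features,
# feature f1 informative (offset added) for the first n_informative
# targets. Returns the path.
write_toy_pin <- function(path, n_target = 30L, n_decoy = 30L,
                          n_informative = 15L, offset = 8, seed = 7L) {
  withr::with_seed(seed, {
    n <- n_target + n_decoy
    f <- matrix(round(rnorm(3 * n), 4), ncol = 3)
    f[seq_len(n_informative), 1] <- f[seq_len(n_informative), 1] + offset
    df <- data.frame(
      SpecId = sprintf("psm%03d", seq_len(n)),
      Label = rep(c(1L, -1L), c(n_target, n_decoy)),
      ScanNr = sprintf("scan%03d", seq_len(n)),
      f1 = f[, 1], f2 = f[, 2], f3 = f[, 3],
      Peptide = sprintf("PEPTIDE%03dK", seq_len(n)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  path
}
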
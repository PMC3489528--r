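#' Configuration of the synthetic PSM simulation
#'
#' The generator emulates a separate target/decoy search in which match
#' correctness is known by construction: every PSM carries `n_features`
#' i.i.d. Normal(`feature_mean`, `feature_sd`) features, and `n_correct`
#' of the target PSMs ("correct" matches) additionally receive `offset`
#' on feature 1. Decoys and incorrect targets are thus exchangeable, the
#' assumption underlying target-decoy analysis. Defaults follow the
#' standard benchmark configuration: 2500 targets, 2500 decoys, 50
#' standard-normal features, an offset of 10.0 on feature 1 for 1000
#' targets, and 100 replicate datasets.
#'
#' @param n_target,n_decoy number of target / decoy PSMs.
#' @param n_features number of features.
#' @param n_correct number of target PSMs made correct (at most
#'   `n_target`).
#' @param offset shift added to feature 1 of correct targets.
#' @param feature_mean,feature_sd base feature distribution parameters
#'   (`feature_sd > 0`).
#' @param n_datasets number of replicate datasets in [run_experiment()].
#' @param seed master seed; dataset `d` uses `seed + d - 1`.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_target = 2500L, n_decoy = 2500L,
                              n_features = 50L, n_correct = 1000L,
                              offset = 10.0, feature_mean = 0.0,
                              feature_sd = 1.0, n_datasets = 100L,
                              seed = 1L) {
  if (n_correct > n_target)
    stop("n_correct must not exceed n_target")
  if (n_features < 1L) stop("n_features must be at least 1")
  if (!is.finite(feature_sd) || feature_sd <= 0)
    stop("feature_sd must be strictly positive")
  if (n_target < 1L || n_decoy < 1L)
    stop("n_target and n_decoy must be at least 1")
  if (n_datasets < 1L) stop("n_datasets must be at least 1")
  structure(list(n_target = as.integer(n_target),
                 n_decoy = as.integer(n_decoy),
                 n_features = as.integer(n_features),
                 n_correct = as.integer(n_correct), offset = offset,
                 feature_mean = feature_mean, feature_sd = feature_sd,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate one synthetic PSM dataset
#'
#' The ground-truth correctness flags are returned alongside, not inside,
#' the [psm_dataset()]: the learner-facing container has no such field, so
#' truth can never leak into features, labels, or fold decisions.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed for this dataset.
#' @return an object of class `sim_dataset`: list with `data` (a
#'   `psm_dataset`; one PSM per synthetic spectrum) and `is_correct`
#'   (logical named by psm_id, `FALSE` for all decoys).
#' @export
generate_dataset <- function(cfg, seed = cfg$seed) {
  n <- cfg$n_target + cfg$n_decoy
  feats <- withr::with_seed(as.integer(seed),
    matrix(stats::rnorm(n * cfg$n_features, cfg$feature_mean,
                        cfg$feature_sd),
           nrow = n, ncol = cfg$n_features))
  colnames(feats) <- paste0("feature", seq_len(cfg$n_features))
  is_decoy <- rep(c(FALSE, TRUE), c(cfg$n_target, cfg$n_decoy))
  is_correct <- rep(FALSE, n)
  if (cfg$n_correct > 0) {
    correct_idx <- seq_len(cfg$n_correct)
    feats[correct_idx, 1] <- feats[correct_idx, 1] + cfg$offset
    is_correct[correct_idx] <- TRUE
  }
  psm_id <- c(sprintf("target_%05d", seq_len(cfg$n_target)),
              sprintf("decoy_%05d", seq_len(cfg$n_decoy)))
  data <- psm_dataset(feats, is_decoy, psm_id = psm_id)
  structure(list(data = data,
                 is_correct = stats::setNames(is_correct, psm_id),
                 seed = as.integer(seed)),
            class = "sim_dataset")
}

#' Ideal identification count at a q-value threshold
#'
#' With `n_correct` truly correct matches present, a perfectly calibrated
#' procedure accepting at q-value `q` reports `n_correct / (1 - q)` PSMs:
#' all correct ones plus just enough incorrect ones to make up the
#' fraction `q` of the accepted list.
#'
#' @param q q-value threshold in `[0, 1)`.
#' @param n_correct number of truly correct target PSMs.
#' @return `n_correct / (1 - q)`.
#' @export
ideal_identification_count <- function(q, n_correct = 1000L) {
  if (any(!is.finite(q)) || any(q < 0) || any(q >= 1))
    stop("q must lie in [0, 1)")
  n_correct / (1 - q)
}

#' Run the replicated calibration experiment
#'
#' Generates `cfg$n_datasets` datasets and rescoring runs. With
#' `with_cv = TRUE` each dataset goes through the full cross-validated
#' pipeline; with `with_cv = FALSE` the model is trained and evaluated on
#' the same PSMs (the overfitting condition). For every dataset and every
#' point of the q grid, the number of accepted targets (estimated
#' q <= grid point) and the ground-truth false discovery proportion (FDP)
#' among them are recorded; medians and 5%/95% quantiles are aggregated
#' across datasets. The FDP is undefined (NA) at grid points where a
#' dataset accepts nothing; such datasets drop out of the FDP aggregation
#' at that point.
#'
#' @param cfg a [simulation_config()].
#' @param with_cv logical; `FALSE` disables cross-validation.
#' @param cfg_learner a [learner_config()]; its seed is re-derived per
#'   dataset from the dataset seed.
#' @param q_grid grid of q thresholds for the curves (default 0 to 0.1 in
#'   steps of 0.002).
#' @param alpha per-fold normalization threshold (CV condition only).
#' @return an object of class `simulation_result`: `with_cv`, `q_grid`,
#'   `counts` and `fdp` (dataset x grid matrices), `summary` (data frame
#'   with per-grid-point medians and 5%/95% quantiles), `config`.
#' @export
run_experiment <- function(cfg, with_cv = TRUE,
                           cfg_learner = learner_config(),
                           q_grid = seq(0, 0.1, by = 0.002),
                           alpha = 0.01) {
  nd <- cfg$n_datasets
  counts <- matrix(NA_real_, nrow = nd, ncol = length(q_grid))
  fdp <- matrix(NA_real_, nrow = nd, ncol = length(q_grid))
  for (d in seq_len(nd)) {
    ds_seed <- cfg$seed + d - 1L
    sim <- generate_dataset(cfg, seed = ds_seed)
    lcfg <- cfg_learner
    lcfg$seed <- derive_seed(ds_seed, 17L)
    run <- tryCatch(
      suppressWarnings(rescore(sim$data, lcfg, alpha = alpha, cv = with_cv)),
      error = function(e) stop("dataset seed ", ds_seed, ": ",
                               conditionMessage(e)))
    res <- run$results
    tgt <- res[!res$is_decoy, ]
    correct <- sim$is_correct[tgt$psm_id]
    for (g in seq_along(q_grid)) {
      acc <- tgt$q_value <= q_grid[g]
      counts[d, g] <- sum(acc)
      fdp[d, g] <- if (any(acc)) mean(!correct[acc]) else NA_real_
    }
  }
  qtile <- function(m, p) apply(m, 2, function(col)
    if (all(is.na(col))) NA_real_ else quantile(col, p, na.rm = TRUE,
                                                names = FALSE))
  summary <- data.frame(
    q = q_grid,
    count_median = qtile(counts, 0.5),
    count_q05 = qtile(counts, 0.05),
    count_q95 = qtile(counts, 0.95),
    fdp_median = qtile(fdp, 0.5),
    fdp_q05 = qtile(fdp, 0.05),
    fdp_q95 = qtile(fdp, 0.95))
  structure(list(with_cv = with_cv, q_grid = q_grid, counts = counts,
                 fdp = fdp, summary = summary, config = cfg),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  g01 <- which.min(abs(x$q_grid - 0.01))
  cat(sprintf(
    "simulation_result (%s): %d datasets; median accepted at q <= %.3g: %g\n",
    if (x$with_cv) "with CV" else "NO CV", nrow(x$counts), x$q_grid[g01],
    stats::median(x$counts[, g01])))
  invisible(x)
}

#' Write experiment curves as TSV tables
#'
#' Writes `counts.tsv` (accepted-target counts) and `fdp.tsv` (ground-truth
#' false discovery proportions), one row per q-grid point with median and
#' 5%/95% quantile columns.
#'
#' @param result a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, e.g. `"with_cv_"`.
#' @return character vector of the two file paths, invisibly.
#' @export
write_curves <- function(result, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- result$summary
  counts_path <- file.path(dir, paste0(prefix, "counts.tsv"))
  fdp_path <- file.path(dir, paste0(prefix, "fdp.tsv"))
  utils::write.table(s[, c("q", "count_median", "count_q05", "count_q95")],
                     counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(s[, c("q", "fdp_median", "fdp_q05", "fdp_q95")],
                     fdp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, fdp_path))
}
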
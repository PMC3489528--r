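sim_small <- generate_dataset(small_sim_config(), seed = 1)

test_that("the initial direction is the informative feature with the right sign", {
  d <- sim_small$data
  init <- choose_initial_direction(d, 0.01)
  expect_equal(init$feature_index, 1L)
  expect_equal(init$sign, 1)

  # exhaustive scan over all signed features is the oracle
  counts <- sapply(seq_len(n_features(d)), function(j) sapply(c(1, -1),
    function(sgn) psmrescore:::count_significant(sgn * d$features[, j],
                                                 d$is_decoy, 0.01)))
  expect_equal(init$n_significant, max(counts))

  neg <- generate_dataset(small_sim_config(offset = -10), seed = 1)
  init_neg <- choose_initial_direction(neg$data, 0.01)
  expect_equal(init_neg$feature_index, 1L)
  expect_equal(init_neg$sign, -1)
})

test_that("on pure noise the initial direction is deterministic under the tie rule", {
  noise <- generate_dataset(small_sim_config(n_correct = 0), seed = 3)
  i1 <- choose_initial_direction(noise$data, 0.01)
  i2 <- choose_initial_direction(noise$data, 0.01)
  expect_identical(i1, i2)
  # first (lowest index, + sign first) among the maxima wins
  counts <- unlist(lapply(seq_len(n_features(noise$data)), function(j)
    lapply(c(1, -1), function(sgn)
      psmrescore:::count_significant(sgn * noise$data$features[, j],
                                     noise$data$is_decoy, 0.01))))
  first_best <- which.max(counts)
  expect_equal(i1$feature_index, as.integer(ceiling(first_best / 2)))
  expect_equal(i1$sign, c(1, -1)[(first_best - 1) %% 2 + 1])
})

test_that("positive selection follows the q-value threshold and never picks decoys", {
  d <- psm_dataset(matrix(0, 6, 1), is_decoy = c(rep(FALSE, 4), TRUE, TRUE))
  scores <- c(10, 9, 8, 7, 8.5, 6)
  mask <- select_positives(scores, d, q_select = 0.01, pi0 = 1)
  expect_equal(mask, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))

  # threshold at the maximum admits every target but still no decoy
  mask_all <- select_positives(scores, d, q_select = 1.0, pi0 = 1)
  expect_equal(mask_all, c(rep(TRUE, 4), FALSE, FALSE))

  # a decoy outscoring everything is still excluded
  scores2 <- c(10, 9, 8, 7, 99, 6)
  mask2 <- select_positives(scores2, d, q_select = 1.0, pi0 = 1)
  expect_false(any(mask2[d$is_decoy]))
})

test_that("zero iterations return the unit initial-direction model", {
  d <- sim_small$data
  cfg <- small_learner(n_iter = 0L)
  m <- self_train(d, cfg, hyperparams(1, 1))
  w <- unname(m$weights)
  expect_equal(w[1], 1)
  expect_equal(w[-1], rep(0, n_features(d) - 1))
  expect_equal(m$intercept, 0)
})

test_that("self-training concentrates weight on the informative feature", {
  d <- sim_small$data
  m <- self_train(d, small_learner(seed = 5), hyperparams(1, 1))
  # on the standardized scale the SVM was fit on: the informative feature
  # dominates the learned direction
  w_std <- m$weights * psmrescore:::feature_standardizer(d$features)$scale
  expect_gt(abs(w_std[1]) / sqrt(sum(w_std^2)), 0.9)
})

test_that("self-training is exactly reproducible and requires decoys", {
  d <- sim_small$data
  m1 <- self_train(d, small_learner(seed = 11), hyperparams(1, 3))
  m2 <- self_train(d, small_learner(seed = 11), hyperparams(1, 3))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$intercept, m2$intercept)

  targets_only <- dataset_subset(d, !d$is_decoy)
  expect_error(self_train(targets_only, small_learner(), hyperparams(1, 1)),
               "decoy")
})

test_that("a noise-only split falls back through relaxed thresholds without failing", {
  noise <- generate_dataset(small_sim_config(n_correct = 0, n_target = 60,
                                             n_decoy = 60, n_features = 4),
                            seed = 2)
  m <- self_train(noise$data, small_learner(seed = 2), hyperparams(1, 1))
  expect_s3_class(m, "svm_model")
  expect_true(all(is.finite(m$weights)))
})

test_that("a single-candidate grid is returned without nested training", {
  cfg <- learner_config(grid = list(hyperparams(2, 5)), seed = 1)
  hp <- grid_search(sim_small$data, cfg)
  expect_equal(hp$c_pos, 2)
  expect_equal(hp$c_neg, 5)
})

test_that("grid search returns the candidate with the maximal held-out count", {
  d <- sim_small$data
  cfg <- small_learner(seed = 31)
  hp <- grid_search(d, cfg)
  counts <- attr(hp, "counts")
  expect_length(counts, length(cfg$grid))

  # independent re-evaluation: replay the nested protocol per candidate
  split <- assign_folds(d, k = 3L, seed = psmrescore:::derive_seed(cfg$seed, 7L))
  fold_of <- split$assignment[d$spectrum_id]
  recount <- numeric(length(cfg$grid))
  for (i in 1:3) {
    tr <- dataset_subset(d, fold_of != i)
    te <- dataset_subset(d, fold_of == i)
    cfg_i <- cfg
    cfg_i$seed <- psmrescore:::derive_seed(cfg$seed, 100L + i)
    for (h in seq_along(cfg$grid)) {
      model <- self_train(tr, cfg_i, cfg$grid[[h]])
      recount[h] <- recount[h] +
        psmrescore:::count_significant(predict(model, te), te$is_decoy,
                                       cfg$q_select,
                                       pi0_mode = cfg$pi0_mode)
    }
  }
  expect_equal(counts, recount)
  best <- which.max(recount)
  expect_equal(hp$c_pos, cfg$grid[[best]]$c_pos)
  expect_equal(hp$c_neg, cfg$grid[[best]]$c_neg)
})

test_that("tied candidates resolve to the first in grid order", {
  d <- sim_small$data
  # duplicated candidate: identical fits, identical counts, first wins
  cfg <- learner_config(grid = list(hyperparams(1, 1), hyperparams(1, 1),
                                    hyperparams(5, 5)), seed = 13)
  hp <- grid_search(d, cfg)
  counts <- attr(hp, "counts")
  expect_equal(counts[1], counts[2])
  if (counts[1] >= counts[3]) {
    expect_equal(which.max(counts), 1L)
  }
})

test_that("nested parts lacking a label class raise an instructive error", {
  tiny <- psm_dataset(matrix(rnorm(12), ncol = 2),
                      is_decoy = c(rep(FALSE, 5), TRUE))
  cfg <- small_learner()
  expect_error(grid_search(tiny, cfg), "larger folds|lacks targets or decoys")
})
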
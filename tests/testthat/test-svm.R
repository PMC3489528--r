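identity_std <- function(p) list(center = rep(0, p), scale = rep(1, p))

test_that("a separable one-feature problem is fit with the right sign", {
  x <- matrix(c(rep(10, 10), rep(0, 10)), ncol = 1,
              dimnames = list(NULL, "f1"))
  pos <- rep(c(TRUE, FALSE), each = 10)
  m <- train_weighted_svm(x, pos, !pos, hyperparams(1, 1), seed = 1,
                          standardizer = identity_std(1))
  expect_gt(m$weights[["f1"]], 0)
  dec <- predict(m, x)
  expect_true(all(dec[pos] > 0))
  expect_true(all(dec[!pos] < 0))
})

test_that("decision values match an independent QP reference on tiny instances", {
  withr::with_seed(21, {
    for (case in 1:8) {
      n <- sample(8:20, 1)
      X <- matrix(rnorm(2 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
      y <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
      X[y > 0, 1] <- X[y > 0, 1] + 1.5
      hp <- hyperparams(sample(c(0.5, 1, 4), 1), sample(c(0.5, 1, 4), 1))
      m <- train_weighted_svm(X, y > 0, y < 0, hp, seed = 1,
                              standardizer = identity_std(2),
                              tol = 1e-8, max_epochs = 2e5)
      ref <- ref_svm_qp(X, y, ifelse(y > 0, hp$c_pos, hp$c_neg))
      dec <- predict(m, X)
      expect_equal(dec, ref$decision, tolerance = 1e-3)
    }
  })
})

test_that("negating the features negates the learned weights", {
  withr::with_seed(4, {
    X <- matrix(rnorm(60), ncol = 3)
    colnames(X) <- paste0("f", 1:3)
    y <- rep(c(1, -1), each = 10)
    X[y > 0, 2] <- X[y > 0, 2] + 2
  })
  hp <- hyperparams(1, 1)
  m1 <- train_weighted_svm(X, y > 0, y < 0, hp, seed = 1,
                           standardizer = identity_std(3), tol = 1e-6,
                           max_epochs = 1e5)
  m2 <- train_weighted_svm(-X, y > 0, y < 0, hp, seed = 1,
                           standardizer = identity_std(3), tol = 1e-6,
                           max_epochs = 1e5)
  expect_equal(unname(m2$weights), -unname(m1$weights), tolerance = 1e-4)
})

test_that("fits are bitwise reproducible for a fixed seed", {
  withr::with_seed(8, {
    X <- matrix(rnorm(400), ncol = 4)
    colnames(X) <- paste0("f", 1:4)
    y <- rep(c(1, -1), 50)
    X[y > 0, 1] <- X[y > 0, 1] + 1
  })
  m1 <- train_weighted_svm(X, y > 0, y < 0, hyperparams(1, 3), seed = 99)
  m2 <- train_weighted_svm(X, y > 0, y < 0, hyperparams(1, 3), seed = 99)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$intercept, m2$intercept)
})

test_that("masks must be disjoint and non-empty", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(train_weighted_svm(X, rep(TRUE, 10), rep(TRUE, 10),
                                  hyperparams(1, 1)), "disjoint")
  expect_error(train_weighted_svm(X, rep(FALSE, 10), rep(TRUE, 10),
                                  hyperparams(1, 1)), "at least one")
})

test_that("the solver agrees with libsvm on a centered separable problem", {
  skip_if_not_installed("e1071")
  withr::with_seed(13, {
    X <- matrix(rnorm(200), ncol = 2)
    colnames(X) <- c("a", "b")
    y <- rep(c(1, -1), each = 50)
    X[y > 0, ] <- X[y > 0, ] + 3
    X <- scale(X, scale = FALSE)
  })
  m <- train_weighted_svm(X, y > 0, y < 0, hyperparams(1, 1), seed = 1,
                          standardizer = identity_std(2), tol = 1e-6,
                          max_epochs = 1e5)
  ref <- e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
  w_ref <- drop(t(ref$coefs) %*% ref$SV)
  # libsvm orients its decision values by factor-level order, so compare
  # directions up to sign
  cosine <- sum(m$weights * w_ref) /
    sqrt(sum(m$weights^2) * sum(w_ref^2))
  expect_gt(abs(cosine), 0.99)
  # the two solvers classify the training points the same way
  ref_class <- as.numeric(as.character(predict(ref, X)))
  expect_gte(mean(sign(predict(m, X)) == ref_class), 0.98)
})
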
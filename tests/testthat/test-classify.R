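# --- PCA ------------------------------------------------------------------

test_that("PCA captures rank-1 data in one component and centers scores", {
  set.seed(31)
  t_ <- rnorm(40)
  X <- t_ %o% rnorm(10)
  m <- suppressWarnings(pca_fit(X, 1))
  expect_equal(m$ratios[1], 1)
  expect_equal(unname(drop(pca_transform(m, matrix(m$mean, 1)))), 0)
  # full-component reconstruction is lossless
  Y <- matrix(rnorm(40 * 6), 40)
  mf <- suppressWarnings(pca_fit(Y, 6))
  S <- pca_transform(mf, Y)
  back <- sweep(S %*% t(mf$loadings), 2, -mf$mean)
  expect_equal(back, Y, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(abs(crossprod(mf$loadings) - diag(6)) < 1e-10))
  expect_error(pca_fit(X, 5), "rank")
})

# --- Fisher LDA -----------------------------------------------------------

test_that("Fisher LDA yields min(C-1, d) DFs and separates clear classes", {
  set.seed(32)
  S <- matrix(rnorm(120 * 3), 120)
  labels <- factor(rep(blood_classes(), each = 20))
  m <- fisher_lda_fit(S, labels)
  expect_equal(ncol(m$coef), 3)        # six classes in 3-D: exactly 3 DFs
  expect_equal(nrow(m$centroids), 6)

  mu <- matrix(c(0, 0, 8, 8), 2, byrow = TRUE)
  X2 <- rbind(matrix(rnorm(60 * 2), 60), matrix(rnorm(60 * 2), 60))
  X2 <- X2 + mu[rep(1:2, each = 60), ]
  lab2 <- factor(rep(c("x", "y"), each = 60))
  m2 <- fisher_lda_fit(X2[seq(1, 120, 2), ], lab2[seq(1, 120, 2)])
  pred <- fisher_lda_predict(m2, X2[seq(2, 120, 2), ])
  expect_equal(accuracy(lab2[seq(2, 120, 2)], pred)$R, 100)

  # training centroids are fixed points of the nearest-centroid rule
  pred_c <- fisher_lda_predict(m, t(apply(m$centroids, 1, function(z)
    qr.solve(t(m$coef), z))))
  expect_equal(as.character(pred_c), rownames(m$centroids))
})

test_that("Fisher LDA agrees with an independent discriminant fit", {
  set.seed(33)
  mu <- matrix(rnorm(12, sd = 4), 4, 3)
  X <- matrix(rnorm(200 * 3), 200) + mu[rep(1:4, 50), ]
  lab <- factor(rep(letters[1:4], 50))
  ours <- fisher_lda_predict(fisher_lda_fit(X, lab), X)
  ref <- predict(MASS::lda(X, lab))$class
  expect_gte(mean(ours == ref), 0.97)
})

# --- ELM ------------------------------------------------------------------

test_that("ELM interpolates with a square hidden layer and is deterministic", {
  set.seed(34)
  X <- matrix(rnorm(25 * 3), 25)
  y <- drop(sin(X %*% c(1, 2, -1))) + 2
  m <- elm_train(X, y, 25, "sigmoid", seed = 8)
  expect_lt(rmse(y, drop(elm_predict(m, X))), 1e-6)
  m2 <- elm_train(X, y, 25, "sigmoid", seed = 8)
  expect_identical(elm_predict(m, X), elm_predict(m2, X))
  expect_error(elm_train(X, c(y[-1], NA), 5), "non-finite")
})

test_that("ELM output weights solve the training least-squares problem", {
  set.seed(35)
  for (act in c("sigmoid", "sine", "hardlim")) {
    X <- matrix(rnorm(40 * 4), 40)
    y <- rnorm(40)
    m <- elm_train(X, y, 12, act, seed = 3)
    H <- switch(act,
      sigmoid = 1 / (1 + exp(-(X %*% m$input_weights +
                                 rep(m$biases, each = 40)))),
      sine = sin(X %*% m$input_weights + rep(m$biases, each = 40)),
      hardlim = (X %*% m$input_weights + rep(m$biases, each = 40) > 0) * 1)
    ref <- solve(crossprod(H) + diag(0, 12), crossprod(H, y))
    expect_equal(drop(m$output_weights), drop(ref), tolerance = 1e-6)
  }
})

test_that("the empirical hidden-neuron bracket follows the alpha rule", {
  expect_identical(hidden_neuron_range(100, 1, 1), c(5L, 25L))
  expect_identical(hidden_neuron_range(100, 1, 1, c(4, 4)), c(12L, 12L))
  expect_error(hidden_neuron_range(0, 1, 1))
})

test_that("accuracy reports N1/N2 percentages with a confusion matrix", {
  lab <- factor(rep(c("a", "b"), each = 5))
  rep_ <- accuracy(lab, lab)
  expect_equal(rep_$R, 100)
  expect_true(all(rep_$confusion[row(rep_$confusion) != col(rep_$confusion)] == 0))
  pred <- lab; pred[1] <- "b"
  rep2 <- accuracy(lab, pred)
  expect_equal(rep2$N1, 9); expect_equal(rep2$N2, 10)
  expect_equal(rep2$R, 90)
  expect_error(accuracy(lab, lab[-1]), "equal length")
  expect_error(accuracy(factor(character(0)), factor(character(0))), "empty")
})

test_that("the neuron sweep covers the grid and reports a consistent best", {
  set.seed(36)
  X <- matrix(rnorm(90 * 3), 90)
  lab <- factor(rep(c("a", "b", "c"), each = 30))
  X[lab == "b", 1] <- X[lab == "b", 1] + 4
  X[lab == "c", 2] <- X[lab == "c", 2] + 4
  idx <- rep(c(TRUE, FALSE), 45)
  sw <- sweep_elm(X[idx, ], lab[idx], X[!idx, ], lab[!idx],
                  neuron_range = 1:10, seed = 5)
  expect_equal(nrow(sw$curve), 3 * 10)
  hit <- sw$curve$activation == sw$best$activation &
    sw$curve$n_hidden == sw$best$n_hidden
  expect_equal(sw$curve$test_accuracy[hit], sw$best$test_report$R)
  expect_equal(max(sw$curve$test_accuracy), sw$best$test_report$R)
})
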
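#' Principal component analysis for selected wavenumbers
#'
#' Thin wrapper over the mean-centered eigendecomposition (via
#' [stats::prcomp()]) used to compress the SWDA-selected variables to three
#' scores before discriminant modeling. Warns (does not error) if the kept
#' components explain less than 99.0% of the training variance.
#'
#' @param X training matrix, samples x variables.
#' @param n_components number of components to keep (default 3).
#' @return a `pca_model`: mean vector, loadings (variables x components,
#'   orthonormal) and explained-variance ratios.
#' @export
pca_fit <- function(X, n_components = 3L) {
  X <- as.matrix(X)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank_ <- sum(pr$sdev > max(pr$sdev) * 1e-10)
  if (n_components > rank_)
    stop("n_components exceeds the rank of the training matrix")
  ratios <- pr$sdev^2 / sum(pr$sdev^2)
  if (sum(ratios[seq_len(n_components)]) < 0.99)
    warning("kept components explain less than 99.0% of the variance")
  structure(list(mean = pr$center,
                 loadings = pr$rotation[, seq_len(n_components), drop = FALSE],
                 ratios = ratios[seq_len(n_components)]),
            class = "pca_model")
}

#' @rdname pca_fit
#' @param model a `pca_model`.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "pca_model"))
  sweep(as.matrix(X), 2, model$mean) %*% model$loadings
}

#' Fisher linear discriminant analysis
#'
#' Computes the discriminant functions (DFs) as the leading eigenvectors of
#' `solve(W, B)` where W and B are the within- and between-class scatter
#' matrices of the training scores; at most `min(n_classes - 1, n_dims)` DFs
#' exist. Prediction assigns the class whose training centroid is nearest
#' (Euclidean) in DF-score space. A singular within-class scatter falls back
#' to a diagonal ridge (`1e-8 * mean(diag(W))`), with a message.
#'
#' @param scores training score matrix (e.g. 3 PC scores).
#' @param labels class factor; every class needs >= 2 training samples.
#' @return a `discriminant_model`: `coef` (dims x n_DF matrix, unit-norm
#'   columns), `centroids` (class x n_DF), `classes`.
#' @export
fisher_lda_fit <- function(scores, labels) {
  S <- as.matrix(scores)
  labels <- droplevels(factor(labels))
  g <- nlevels(labels); d <- ncol(S)
  if (g < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  mu <- colMeans(S)
  W <- matrix(0, d, d); B <- matrix(0, d, d)
  for (cl in levels(labels)) {
    Si <- S[labels == cl, , drop = FALSE]
    mui <- colMeans(Si)
    W <- W + crossprod(sweep(Si, 2, mui))
    B <- B + nrow(Si) * tcrossprod(mui - mu)
  }
  R <- tryCatch(chol(W), error = function(e) {
    message("singular within-class scatter; applying diagonal ridge")
    chol(W + diag(1e-8 * mean(diag(W)) + 1e-12, d))
  })
  # symmetric form R'^-1 B R^-1, eigenvectors mapped back by R^-1
  Csym <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)),
                    transpose = TRUE)
  eg <- eigen((Csym + t(Csym)) / 2, symmetric = TRUE)
  n_df <- min(g - 1L, d)
  V <- backsolve(R, eg$vectors[, seq_len(n_df), drop = FALSE])
  # unit columns; sign fixed so the largest-magnitude loading is positive
  for (j in seq_len(n_df)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  Z <- S %*% V
  centroids <- do.call(rbind, lapply(levels(labels), function(cl)
    colMeans(Z[labels == cl, , drop = FALSE])))
  rownames(centroids) <- levels(labels)
  structure(list(coef = V, centroids = centroids, classes = levels(labels),
                 eigenvalues = eg$values[seq_len(n_df)]),
            class = "discriminant_model")
}

#' @rdname fisher_lda_fit
#' @param model a `discriminant_model`.
#' @param scores score matrix to classify.
#' @export
fisher_lda_predict <- function(model, scores) {
  stopifnot(inherits(model, "discriminant_model"))
  Z <- as.matrix(scores) %*% model$coef
  d2 <- outer(rowSums(Z^2), rowSums(model$centroids^2), "+") -
    2 * Z %*% t(model$centroids)
  factor(model$classes[max.col(-d2, ties.method = "first")],
         levels = model$classes)
}

# ---------------------------------------------------------------------------
# Extreme learning machine

elm_activations <- function() c("sigmoid", "sine", "hardlim")

elm_activation_fun <- function(name) {
  switch(match.arg(name, elm_activations()),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    sine = sin,
    hardlim = function(x) (x > 0) * 1)
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer network with random fixed input weights: `W` and
#' biases `b` are drawn uniformly on \[-1, 1\] from `seed`, the hidden
#' activations are `H = S(X W + b)` with `S` the chosen activation, and the
#' output weights are the minimum-norm least-squares solution
#' `beta = pinv(H) %*% targets`.
#'
#' @param X input matrix (PC scores or standardized variables).
#' @param targets numeric vector or matrix of training targets.
#' @param n_hidden number of hidden neurons (>= 1).
#' @param activation `"sigmoid"`, `"sine"` or `"hardlim"`
#'   (`S(x) = 0` for `x <= 0`, else 1).
#' @param seed integer seed for the random input layer.
#' @return an `elm_model`.
#' @export
elm_train <- function(X, targets, n_hidden, activation = "sigmoid",
                      seed = 1L) {
  X <- as.matrix(X)
  targets <- as.matrix(targets)
  if (!all(is.finite(X)) || !all(is.finite(targets)))
    stop("non-finite inputs")
  stopifnot(n_hidden >= 1)
  d <- ncol(X)
  wb <- with_seed(seed, stats::runif((d + 1L) * n_hidden, -1, 1))
  W <- matrix(wb[seq_len(d * n_hidden)], d, n_hidden)
  b <- wb[d * n_hidden + seq_len(n_hidden)]
  act <- elm_activation_fun(activation)
  H <- act(X %*% W + rep(b, each = nrow(X)))
  beta <- pinv(H) %*% targets
  structure(list(input_weights = W, biases = b, activation = activation,
                 output_weights = beta, seed = seed),
            class = "elm_model")
}

#' @rdname elm_train
#' @param model an `elm_model`.
#' @export
elm_predict <- function(model, X) {
  stopifnot(inherits(model, "elm_model"))
  act <- elm_activation_fun(model$activation)
  H <- act(as.matrix(X) %*% model$input_weights +
             rep(model$biases, each = nrow(as.matrix(X))))
  H %*% model$output_weights
}

#' ELM classifier with one-hot or numeric class coding
#'
#' With the default `"onehot"` coding, classes are coded as indicator
#' targets and a prediction is decoded by argmax. The alternative `"code"`
#' coding uses a single numeric output (classes coded `1..C`, decoded to the
#' nearest valid code), matching a one-output-neuron network (`N_0 = 1`);
#' it is retained for comparison but least-squares regression onto an
#' arbitrary 1-D class code generalizes poorly when the class layout is not
#' ordered along one axis.
#'
#' @inheritParams elm_train
#' @param labels class factor.
#' @param coding `"onehot"` (default) or `"code"` (single output).
#' @return an `elm_classifier`.
#' @export
elm_train_classifier <- function(X, labels, n_hidden, activation = "sigmoid",
                                 seed = 1L, coding = c("onehot", "code")) {
  coding <- match.arg(coding)
  labels <- factor(labels)
  codes <- as.integer(labels)
  targets <- if (coding == "code") matrix(codes, ncol = 1)
             else diag(nlevels(labels))[codes, , drop = FALSE]
  model <- elm_train(X, targets, n_hidden, activation, seed)
  structure(list(elm = model, classes = levels(labels), coding = coding),
            class = "elm_classifier")
}

#' @rdname elm_train_classifier
#' @param model an `elm_classifier`.
#' @export
elm_predict_classifier <- function(model, X) {
  out <- elm_predict(model$elm, X)
  k <- length(model$classes)
  idx <- if (model$coding == "code")
    pmin(pmax(round(drop(out)), 1L), k)
  else max.col(out, ties.method = "first")
  factor(model$classes[idx], levels = model$classes)
}

#' Empirical hidden-neuron range
#'
#' The rule of thumb `N_h = N_s / (alpha * (N_i + N_0))` evaluated at the two
#' ends of the `alpha` range, rounded to integers: with `N_s` training
#' samples, `N_i` input neurons and `N_0` output neurons, alpha in \[2, 10\]
#' gives the bracket to search for the optimal hidden layer size.
#'
#' @param n_train training-set size `N_s`.
#' @param n_inputs input neurons `N_i`.
#' @param n_outputs output neurons `N_0`.
#' @param alpha_range numeric length-2, default `c(2, 10)`.
#' @return integer vector `c(low, high)`.
#' @export
hidden_neuron_range <- function(n_train, n_inputs, n_outputs,
                                alpha_range = c(2, 10)) {
  stopifnot(n_train >= 1, n_inputs >= 1, n_outputs >= 1)
  lo <- round(n_train / (max(alpha_range) * (n_inputs + n_outputs)))
  hi <- round(n_train / (min(alpha_range) * (n_inputs + n_outputs)))
  as.integer(c(lo, hi))
}

#' Hidden-neuron and activation sweep for ELM classification
#'
#' Trains one ELM per (activation, hidden-neuron-count) pair over
#' `neuron_range`, each with a fresh weight draw from a substream of `seed`,
#' and records training and test accuracy. The returned best model maximizes
#' test-set accuracy (the cut-and-trial criterion; note this selects on the
#' test set) with ties going to the first grid cell in sweep order.
#'
#' @param X_train,labels_train,X_test,labels_test the split data.
#' @param neuron_range integer vector of hidden-layer sizes (default 1:50).
#' @param activations subset of `c("sigmoid", "sine", "hardlim")`.
#' @param seed master seed.
#' @param coding class coding passed to [elm_train_classifier()].
#' @return list with `curve` (data frame: activation, n_hidden,
#'   train_accuracy, test_accuracy) and `best` (activation, n_hidden, model,
#'   train/test reports).
#' @export
sweep_elm <- function(X_train, labels_train, X_test, labels_test,
                      neuron_range = 1:50,
                      activations = elm_activations(), seed = 1L,
                      coding = "onehot") {
  curve <- expand.grid(n_hidden = neuron_range, activation = activations,
                       stringsAsFactors = FALSE)[, 2:1]
  curve$train_accuracy <- NA_real_; curve$test_accuracy <- NA_real_
  best <- NULL
  for (r in seq_len(nrow(curve))) {
    act <- curve$activation[r]; nh <- curve$n_hidden[r]
    mdl <- elm_train_classifier(
      X_train, labels_train, nh, act,
      seed = substream_seed(seed, paste0("elm.", act), nh), coding = coding)
    rep_tr <- accuracy(labels_train, elm_predict_classifier(mdl, X_train))
    rep_te <- accuracy(labels_test, elm_predict_classifier(mdl, X_test))
    curve$train_accuracy[r] <- rep_tr$R
    curve$test_accuracy[r] <- rep_te$R
    if (is.null(best) || rep_te$R > best$test_report$R)
      best <- list(activation = act, n_hidden = nh, model = mdl,
                   train_report = rep_tr, test_report = rep_te)
  }
  list(curve = curve, best = best)
}

#' Classification accuracy report
#'
#' Computes `R = N1 / N2 * 100` where `N1` is the number of correctly
#' classified samples and `N2` the set size, together with the confusion
#' matrix (rows = true class, columns = predicted).
#'
#' @param true_labels,predicted_labels equal-length class vectors.
#' @return a `classification_report`: `confusion`, `N1`, `N2`, `R`.
#' @export
accuracy <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (!length(true_labels)) stop("empty label vectors")
  lev <- union(levels(factor(true_labels)), levels(factor(predicted_labels)))
  tr <- factor(true_labels, levels = lev)
  pr <- factor(predicted_labels, levels = lev)
  cm <- table(true = tr, predicted = pr)
  N1 <- sum(diag(cm)); N2 <- sum(cm)
  structure(list(confusion = cm, N1 = N1, N2 = N2, R = N1 / N2 * 100),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy R = %.2f%% (%d / %d correct)\n", x$R, x$N1, x$N2))
  print(x$confusion)
  invisible(x)
}
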
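#' Univariate partial least squares regression (PLS1, NIPALS)
#'
#' Centers `X` and `y` and extracts `n_components` PLS components by the
#' NIPALS recursion; for a univariate response each component has a closed
#' form (weight vector proportional to the covariance of the deflated `X`
#' with the deflated `y`), so the fit is deterministic. Regression
#' coefficients are returned for every truncation `1..n_components`, which
#' makes cross-validation over component counts cheap.
#'
#' @param X predictor matrix, samples x variables.
#' @param y numeric response.
#' @param n_components number of latent components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return a `pls1_fit` object with `coef` (variables x n_components matrix of
#'   regression coefficients on the original scale), `intercept` (vector per
#'   truncation) and `n_components` (possibly reduced if `X` is rank
#'   deficient).
#' @export
pls1_fit <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n_components > min(n - 1, p))
    stop("n_components exceeds min(n - 1, p)")
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  a <- 0L
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break          # X residual carries no covariance with y
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    P[, h] <- drop(crossprod(Xc, t_)) / tt
    q[h] <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, P[, h])
    yc <- yc - q[h] * t_
    W[, h] <- w
    a <- h
  }
  if (a == 0L) stop("no usable PLS component (X has no covariance with y)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  # R = W (P'W)^-1 maps X (centered) to scores; coefficients per truncation
  coef <- matrix(0, p, a)
  PW <- crossprod(P, W)
  for (h in seq_len(a)) {
    Rh <- W[, 1:h, drop = FALSE] %*%
      solve(PW[1:h, 1:h, drop = FALSE])
    coef[, h] <- drop(Rh %*% q[1:h])
  }
  intercept <- ybar - drop(crossprod(coef, xbar))
  structure(list(coef = coef, intercept = intercept, n_components = a,
                 x_mean = xbar, y_mean = ybar),
            class = "pls1_fit")
}

#' Predict from a PLS1 fit
#' @param fit a `pls1_fit`.
#' @param X new predictor matrix.
#' @param n_components truncation to use (default: all fitted components).
#' @return numeric predictions.
#' @export
pls1_predict <- function(fit, X, n_components = fit$n_components) {
  stopifnot(inherits(fit, "pls1_fit"))
  h <- min(n_components, fit$n_components)
  drop(as.matrix(X) %*% fit$coef[, h]) + fit$intercept[h]
}

# k-fold cross-validated RMSE per component count 1..max_ncomp; returns the
# RMSECV vector. One PLS fit per fold serves all truncations.
pls_cv_rmse <- function(X, y, max_ncomp, folds = 5L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  fold_id <- cv_folds(n, folds, seed)
  k <- max(fold_id)
  max_ncomp <- min(max_ncomp, ncol(X))
  press <- matrix(NA_real_, k, max_ncomp)
  counts <- integer(k)
  for (f in seq_len(k)) {
    tr <- fold_id != f; te <- !tr
    nc <- min(max_ncomp, sum(tr) - 1, ncol(X))
    fit <- pls1_fit(X[tr, , drop = FALSE], y[tr], nc)
    counts[f] <- sum(te)
    for (h in seq_len(max_ncomp)) {
      pr <- pls1_predict(fit, X[te, , drop = FALSE], min(h, fit$n_components))
      press[f, h] <- sum((y[te] - pr)^2)
    }
  }
  sqrt(colSums(press) / sum(counts))
}
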
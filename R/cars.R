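#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte-Carlo variable selection for PLS regression. Each of `n_runs`
#' iterations fits PLS1 on a random `sample_ratio` subset of the training
#' samples, weights every currently retained variable by the absolute value
#' of its PLS regression coefficient, applies the enforced exponentially
#' decreasing retention schedule `r_i = a * exp(-k * i)` (with `a` and `k`
#' fixed so that the first run retains all `p` variables and the last run 2),
#' and then performs adaptive reweighted sampling — a weighted draw with
#' replacement whose distinct outcomes form the next retained set. The
#' cross-validated RMSE of each run's retained set (PLS on the full training
#' data, component count chosen by the same CV, capped at
#' `max_pls_components`) is recorded, and the set with the minimal RMSECV is
#' returned.
#'
#' @param X training predictor matrix (preprocessed, training split only).
#' @param y training response (adulteration level, %).
#' @param n_runs number of Monte-Carlo runs (default 50).
#' @param cv_folds folds for the cross-validated RMSE (default 5).
#' @param max_pls_components cap on PLS components (default 10).
#' @param sample_ratio fraction of samples drawn per run (default 0.8).
#' @param seed integer seed; the whole selection is reproducible given it.
#' @return a `selection_result`: `method = "cars"`, sorted `selected`
#'   indices, and a `trace` data frame (run, n_vars, rmsecv).
#' @export
cars_select <- function(X, y, n_runs = 50L, cv_folds = 5L,
                        max_pls_components = 10L, sample_ratio = 0.8,
                        seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 5, p >= 2)

  # retention schedule: r_1 = 1, r_{n_runs} = 2/p
  ksch <- log(p / 2) / (n_runs - 1)
  a <- (p / 2)^(1 / (n_runs - 1))
  retained <- seq_len(p)
  trace <- data.frame(run = integer(0), n_vars = integer(0),
                      rmsecv = numeric(0))
  best <- list(rmsecv = Inf, selected = NULL)

  for (i in seq_len(n_runs)) {
    run_seed <- substream_seed(seed, "cars.run", i)
    sub <- with_seed(run_seed,
                     sample.int(n, max(2L, floor(sample_ratio * n))))
    Xs <- X[sub, retained, drop = FALSE]
    ys <- y[sub]
    ncmax <- min(max_pls_components, length(retained), length(sub) - 1L)
    nc <- if (ncmax > 1) {
      rmse_by_h <- pls_cv_rmse(Xs, ys, ncmax, folds = cv_folds,
                               seed = substream_seed(seed, "cars.inner", i))
      which.min(rmse_by_h)
    } else 1L
    fit <- pls1_fit(Xs, ys, nc)
    w <- abs(fit$coef[, min(nc, fit$n_components)])

    # enforced exponential elimination, then adaptive reweighted sampling
    keep_n <- max(2L, min(length(retained), round(a * exp(-ksch * i) * p)))
    ord <- order(w, decreasing = TRUE)
    retained <- retained[ord[seq_len(keep_n)]]
    w <- w[ord[seq_len(keep_n)]]
    if (sum(w) <= 0) stop("all PLS weights vanished during CARS")
    # ARS bootstrap of size p: variables drawn at least once survive, so the
    # retained count keeps tracking the exponential schedule
    draw <- with_seed(substream_seed(seed, "cars.ars", i),
                      sample(seq_along(retained), size = p,
                             replace = TRUE, prob = w / sum(w)))
    retained <- sort(unique(retained[draw]))
    if (length(retained) < 2L)
      stop("fewer than 2 variables survived CARS run ", i)

    ncv <- min(max_pls_components, length(retained), n - 2L)
    rmsecv_h <- pls_cv_rmse(X[, retained, drop = FALSE], y, ncv,
                            folds = cv_folds,
                            seed = substream_seed(seed, "cars.eval", i))
    rmsecv <- min(rmsecv_h)
    trace <- rbind(trace, data.frame(run = i, n_vars = length(retained),
                                     rmsecv = rmsecv))
    if (rmsecv < best$rmsecv)
      best <- list(rmsecv = rmsecv, selected = retained)
  }

  structure(list(method = "cars", selected = best$selected, trace = trace,
                 rmsecv = best$rmsecv),
            class = "selection_result")
}

#' CARS retention schedule
#'
#' The fraction of the `p` original variables retained at each run:
#' `r_i = a * exp(-k * i)` with `a`, `k` chosen so `round(r_1 * p) = p` and
#' `round(r_n * p) = 2`.
#' @param p number of variables.
#' @param n_runs number of runs.
#' @return numeric vector of retention fractions, length `n_runs`.
#' @export
cars_schedule <- function(p, n_runs = 50L) {
  k <- log(p / 2) / (n_runs - 1)
  a <- (p / 2)^(1 / (n_runs - 1))
  a * exp(-k * seq_len(n_runs))
}
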
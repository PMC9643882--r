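#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed. Stage- and
#' sample-level substreams are derived by a stable integer hash of the stage
#' name plus an index, so that e.g. subsetting a simulated design does not
#' shift the spectra of the remaining samples, and the ELM sweep draws one
#' fresh weight matrix per grid cell.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"sample"`, `"elm.sine"`).
#' @param index non-negative integer within-stage index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stage, index = 0L) {
  stopifnot(is.character(stage), length(stage) == 1L)
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 2147483647
  s <- (abs(as.numeric(master)) * 48271 + h * 16807 + as.numeric(index) * 69621)
  as.integer(s %% 2147483647)
}

# Evaluate expr under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Moore-Penrose pseudoinverse via SVD (tolerance relative to largest
# singular value, as in MASS::ginv).
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Deterministic fold assignment for k-fold CV: cycle folds over a seeded
# permutation of the rows.
cv_folds <- function(n, k, seed) {
  k <- min(k, n)
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  folds
}
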
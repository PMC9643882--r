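# shared fixtures, built in code at test time

tiny_grid <- function(n = 300L) seq(4000, 10000, length.out = n)

# reduced design: same 18-cell structure, fewer samples and a coarser grid
small_design <- function(seed = 1L, n_per_cell = 6L, n_grid = 300L,
                         params = artifact_params()) {
  generate_design(params = params, seed = seed, n_per_cell = n_per_cell,
                  grid = tiny_grid(n_grid))
}

noiseless_params <- function(n_replicates = 3L) {
  artifact_params(scatter_slope_sd = 0, scatter_offset_sd = 0,
                  tilt_sd = 0, noise_sd = 0, n_replicates = n_replicates)
}

# brute-force Kennard-Stone, written independently of the package's
# implementation: explicit distance loops, no dist()
bf_kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  edist <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(NA, NA); bestd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- edist(i, j)
    if (d > bestd) { bestd <- d; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    dmin <- vapply(cand, function(i)
      min(vapply(sel, function(j) edist(i, j), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(dmin)])
  }
  sel
}
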
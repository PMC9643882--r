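#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection: the first two samples are the pair at
#' maximum Euclidean distance; each subsequent sample maximizes its minimum
#' distance to those already selected. Ties are broken by the lowest row
#' index. Duplicate rows are permitted.
#'
#' @param X numeric matrix, samples x variables.
#' @param k number of samples to select, `2 <= k <= nrow(X)`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of samples")
  D <- as.matrix(stats::dist(X))
  # max-distance pair, lowest (row, col) indices on ties
  m <- max(D)
  hit <- which(D == m, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  sel <- c(hit[1, 1], hit[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- which.max(mind)       # first maximum = lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Stratified Kennard-Stone hold-out
#'
#' Within each stratum (by default the six-way class label), selects
#' `round(n_stratum * test_fraction)` samples by [kennard_stone()] on the raw
#' absorbance matrix; the selected samples form the prediction (test) set and
#' the remainder the training set. Because selection runs on raw spectra, the
#' split is identical whatever pretreatment or variable subset is used
#' downstream, keeping the training/test membership fixed across all models.
#'
#' @param spectra a [spectra_set()].
#' @param test_fraction fraction of each stratum held out (default 1/3).
#' @param strata optional factor defining the strata; defaults to
#'   `spectra$class_labels`. Regression tasks stratify by adulteration level.
#' @return a `split_indices` object: list with sorted integer vectors
#'   `train_idx` and `test_idx`.
#' @export
stratified_ks_split <- function(spectra, test_fraction = 1 / 3,
                                strata = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(strata)) strata <- spectra$class_labels
  strata <- droplevels(factor(strata))
  stopifnot(length(strata) == n_samples(spectra))
  test_idx <- integer(0)
  for (cl in levels(strata)) {
    idx <- which(strata == cl)
    if (length(idx) < 3)
      stop("stratum '", cl, "' has fewer than 3 samples")
    k <- round(length(idx) * test_fraction)
    if (k < 2)
      stop("stratum '", cl, "' too small: Kennard-Stone needs at least 2 ",
           "hold-out samples")
    sel <- kennard_stone(spectra$absorbance[idx, , drop = FALSE], k)
    test_idx <- c(test_idx, idx[sel])
  }
  test_idx <- sort(test_idx)
  structure(list(train_idx = setdiff(seq_len(n_samples(spectra)), test_idx),
                 test_idx = test_idx),
            class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat("split_indices:", length(x$train_idx), "train /",
      length(x$test_idx), "test\n")
  invisible(x)
}

#' Write / read a split as a two-column CSV (sample_id, role)
#' @param split a `split_indices` object.
#' @param spectra the [spectra_set()] the split indexes into.
#' @param path CSV path.
#' @export
write_split <- function(split, spectra, path) {
  role <- rep("train", n_samples(spectra))
  role[split$test_idx] <- "test"
  utils::write.table(data.frame(sample_id = spectra$sample_ids, role = role),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(spectra, path) {
  df <- utils::read.csv(path, colClasses = "character")
  i <- match(spectra$sample_ids, df$sample_id)
  if (anyNA(i)) stop("split file missing sample ids")
  role <- df$role[i]
  structure(list(train_idx = which(role == "train"),
                 test_idx = which(role == "test")),
            class = "split_indices")
}
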
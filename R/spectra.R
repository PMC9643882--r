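#' Spectra container
#'
#' A `spectra_set` bundles a samples-by-wavenumbers absorbance matrix with the
#' sample metadata the pipeline needs: unique sample ids, the six-way class
#' label, and the (DBT, CBG, PBG) mass fractions of each sample. Wavenumbers
#' are always kept in ascending order internally; constructors and readers
#' reorder columns as needed.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1.
#' @param absorbance numeric matrix, samples x wavenumbers.
#' @param sample_ids character vector of unique ids, one per row.
#' @param fractions numeric matrix samples x 3 with columns
#'   `f_dbt`, `f_cbg`, `f_pbg`; each row must lie on the unit simplex.
#' @param class_labels optional factor/character; if omitted, labels are
#'   derived from the fractions via [class_from_fractions()].
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, absorbance, sample_ids, fractions,
                        class_labels = NULL) {
  absorbance <- as.matrix(absorbance)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance))
    stop("wavenumbers length must equal ncol(absorbance)")
  if (anyDuplicated(wavenumbers))
    stop("duplicate wavenumbers")
  if (is.unsorted(wavenumbers)) {
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance))
    stop("sample_ids length must equal nrow(absorbance)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  fractions <- as.matrix(fractions)
  if (!all(dim(fractions) == c(nrow(absorbance), 3L)))
    stop("fractions must be a samples x 3 matrix")
  colnames(fractions) <- c("f_dbt", "f_cbg", "f_pbg")
  if (any(fractions < -1e-9) || any(fractions > 1 + 1e-9))
    stop("fractions must lie in [0, 1]")
  if (any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("fractions of each sample must sum to 1")
  lab <- if (is.null(class_labels)) class_from_fractions(fractions)
         else factor(as.character(class_labels), levels = blood_classes())
  if (anyNA(lab)) stop("unknown class label")
  dimnames(absorbance) <- list(sample_ids, NULL)
  rownames(fractions) <- sample_ids
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         sample_ids = sample_ids, class_labels = lab, fractions = fractions),
    class = "spectra_set")
}

#' The six sample classes
#'
#' Raw duck blood tofu (DBT), pure cow blood-based gel (CBG), pure pig
#' blood-based gel (PBG), the two binary adulteration classes and the ternary
#' class, in fixed order.
#' @return character vector of the six class names.
#' @export
blood_classes <- function() {
  c("DBT", "CBG", "PBG", "DBT+CBG", "DBT+PBG", "DBT+CBG+PBG")
}

#' Class label implied by a composition
#'
#' The label is a deterministic function of which mass fractions are nonzero:
#' a pure component maps to its own class, DBT plus one adulterant to the
#' matching binary class, and all three nonzero to the ternary class.
#'
#' @param fractions numeric matrix samples x 3 (`f_dbt`, `f_cbg`, `f_pbg`).
#' @param tol fractions below `tol` count as zero.
#' @return factor with levels [blood_classes()].
#' @export
class_from_fractions <- function(fractions, tol = 1e-12) {
  fractions <- matrix(as.numeric(fractions), ncol = 3L)
  nz <- fractions > tol
  lab <- character(nrow(fractions))
  for (i in seq_len(nrow(fractions))) {
    key <- paste0(as.integer(nz[i, ]), collapse = "")
    lab[i] <- switch(key,
      "100" = "DBT", "010" = "CBG", "001" = "PBG",
      "110" = "DBT+CBG", "101" = "DBT+PBG", "111" = "DBT+CBG+PBG",
      "011" = stop("composition with both gels but no DBT has no class"),
      stop("all-zero composition"))
  }
  factor(lab, levels = blood_classes())
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", nrow(x$absorbance), "samples x",
      length(x$wavenumbers), "wavenumbers (",
      format(min(x$wavenumbers)), "-", format(max(x$wavenumbers)), "cm-1 )\n")
  print(table(x$class_labels))
  invisible(x)
}

#' Subset a spectra_set by sample
#' @param x a `spectra_set`.
#' @param i sample indices (numeric or logical) or sample ids.
#' @param ... unused.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  spectra_set(x$wavenumbers, x$absorbance[i, , drop = FALSE],
              x$sample_ids[i], x$fractions[i, , drop = FALSE],
              x$class_labels[i])
}

#' Number of samples
#' @param x a `spectra_set`.
#' @export
n_samples <- function(x) nrow(x$absorbance)

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a spectra_set to CSV
#'
#' Writes two files: a wide spectra table (first column `sample_id`, remaining
#' column names the wavenumbers) and a metadata table
#' (`sample_id, class, f_dbt, f_cbg, f_pbg`). Numeric values are written with
#' 17 significant digits so that a read/write round trip is bit-exact.
#'
#' @param x a `spectra_set`.
#' @param spectra_path,meta_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_spectra <- function(x, spectra_path, meta_path) {
  stopifnot(inherits(x, "spectra_set"))
  spec <- cbind(sample_id = x$sample_ids,
                matrix(fmt_full(x$absorbance), nrow = n_samples(x)))
  colnames(spec) <- c("sample_id", fmt_full(x$wavenumbers))
  utils::write.table(spec, spectra_path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  meta <- data.frame(sample_id = x$sample_ids,
                     class = as.character(x$class_labels),
                     f_dbt = fmt_full(x$fractions[, 1]),
                     f_cbg = fmt_full(x$fractions[, 2]),
                     f_pbg = fmt_full(x$fractions[, 3]))
  utils::write.table(meta, meta_path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(c(spectra_path, meta_path))
}

#' Read a spectra_set from CSV
#'
#' Inverse of [write_spectra()]. Wavenumber columns may appear in descending
#' order in the file; they are re-sorted ascending with the absorbance columns
#' permuted accordingly. Ids present in one file but not the other, duplicate
#' ids and non-numeric absorbance cells are errors.
#'
#' @param spectra_path,meta_path input file paths.
#' @return a `spectra_set`.
#' @export
read_spectra <- function(spectra_path, meta_path) {
  spec <- data.table::fread(spectra_path, sep = ",", header = TRUE,
                            colClasses = list(character = 1L), data.table = FALSE)
  if (colnames(spec)[1] != "sample_id") stop("first column must be sample_id")
  wn <- suppressWarnings(as.numeric(colnames(spec)[-1]))
  if (anyNA(wn)) stop("non-numeric wavenumber in spectra header")
  if (any(diff(wn) == 0) || (!all(diff(wn) > 0) && !all(diff(wn) < 0)))
    stop("header wavenumbers must be strictly monotone")
  ids <- spec$sample_id
  A <- as.matrix(spec[, -1, drop = FALSE])
  if (!is.numeric(A) || anyNA(A)) stop("non-numeric absorbance cells")
  meta <- data.table::fread(meta_path, sep = ",", header = TRUE,
                            data.table = FALSE)
  need <- c("sample_id", "class", "f_dbt", "f_cbg", "f_pbg")
  if (!all(need %in% colnames(meta))) stop("meta file missing required columns")
  missing_in_meta <- setdiff(ids, meta$sample_id)
  if (length(missing_in_meta))
    stop("sample id missing from meta: ", paste(missing_in_meta, collapse = ", "))
  extra <- setdiff(meta$sample_id, ids)
  if (length(extra))
    stop("sample id missing from spectra: ", paste(extra, collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), ]
  spectra_set(wn, A, ids,
              as.matrix(meta[, c("f_dbt", "f_cbg", "f_pbg")]),
              meta$class)
}
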
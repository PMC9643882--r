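#' Spectral pretreatments
#'
#' The five pretreatments compared for spectra denoising, plus the identity:
#' `none`, `centralization` (column mean-centering), `first_derivative` and
#' `second_derivative` (Savitzky-Golay derivatives along the wavenumber
#' axis), `snv` (standard normal variate: each spectrum standardized to mean
#' 0, sd 1) and `msc` (multiplicative scatter correction against the
#' training-mean reference spectrum).
#'
#' A preprocessor is fit on the training matrix only — `centralization`
#' stores the training column means and `msc` the training mean spectrum, so
#' applying to test spectra leaks nothing — and can then be applied to any
#' matrix on the same wavenumber grid.
#'
#' @param method one of `"none"`, `"centralization"`, `"first_derivative"`,
#'   `"second_derivative"`, `"snv"`, `"msc"`.
#' @param X training matrix, samples x wavenumbers; must be nonempty.
#' @param wavenumbers grid for the derivative methods; derivatives are scaled
#'   by the grid spacing so units are AU per cm^-1 (resp. per cm^-2). If
#'   omitted, unit spacing is assumed.
#' @param window,polyorder Savitzky-Golay window length (odd) and polynomial
#'   order.
#' @return a `preprocessor` object.
#' @export
preprocess_methods <- function() {
  c("none", "centralization", "first_derivative", "second_derivative",
    "snv", "msc")
}

#' @rdname preprocess_methods
#' @export
fit_preprocessor <- function(method, X, wavenumbers = NULL,
                             window = 15L, polyorder = 2L) {
  method <- match.arg(method, preprocess_methods())
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty training matrix")
  fitted <- switch(method,
    centralization = list(col_means = colMeans(X)),
    msc = list(reference = colMeans(X)),
    list())
  spacing <- if (is.null(wavenumbers)) 1 else mean(diff(wavenumbers))
  structure(list(method = method, fitted = fitted, n_vars = ncol(X),
                 spacing = spacing, window = as.integer(window),
                 polyorder = as.integer(polyorder)),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param pp a `preprocessor` from [fit_preprocessor()].
#' @param X matrix to transform; the column count must match the grid the
#'   preprocessor was fitted on.
#' @return transformed matrix with the same number of rows as `X`.
#' @export
apply_preprocessor <- function(pp, X) {
  stopifnot(inherits(pp, "preprocessor"))
  X <- as.matrix(X)
  if (ncol(X) != pp$n_vars)
    stop("column count does not match the fitted grid")
  switch(pp$method,
    none = X,
    centralization = sweep(X, 2, pp$fitted$col_means),
    snv = snv_rows(X),
    msc = msc_rows(X, pp$fitted$reference),
    first_derivative = sg_deriv_rows(X, 1L, pp),
    second_derivative = sg_deriv_rows(X, 2L, pp))
}

snv_rows <- function(X) {
  mu <- rowMeans(X)
  sd_ <- apply(X, 1, stats::sd)
  if (any(sd_ < .Machine$double.eps))
    stop("degenerate spectrum: zero standard deviation row in SNV")
  (X - mu) / sd_
}

msc_rows <- function(X, ref) {
  refc <- ref - mean(ref)
  vref <- sum(refc^2)
  if (vref < .Machine$double.eps) stop("degenerate MSC reference spectrum")
  # per-row OLS of the spectrum on the reference: x ~ a + b * ref
  b <- drop(X %*% refc) / vref
  if (any(abs(b) < 1e-12))
    stop("degenerate spectrum: MSC fitted slope ~ 0")
  a <- rowMeans(X) - b * mean(ref)
  (X - a) / b
}

sg_deriv_rows <- function(X, order, pp) {
  t(apply(X, 1, function(row)
    signal::sgolayfilt(row, p = pp$polyorder, n = pp$window,
                       m = order, ts = pp$spacing)))
}
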
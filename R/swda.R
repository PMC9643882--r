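#' Stepwise discriminant analysis (SWDA)
#'
#' Forward selection with backward removal on Wilks' Lambda. At each entry
#' step the candidate variable with the largest partial F statistic enters if
#' its F is at least `f_enter`; after every entry, any included variable
#' whose partial F (for removal) falls below `f_remove` leaves again.
#' Selection stops when no candidate qualifies or `max_vars` variables are
#' included.
#'
#' Wilks' Lambda for a variable set S is `det(W_S) / det(T_S)` with W the
#' pooled within-class and T the total SSCP matrix; adding variable x
#' multiplies it by the ratio of the Schur complements
#' `(w_xx - w_xS W_S^-1 w_Sx) / (t_xx - t_xS T_S^-1 t_Sx)`, which is how the
#' implementation screens all candidates per step without refactorizing.
#' The partial F for entering x into a set of size k over g classes with n
#' samples is `F = ((n - g - k) / (g - 1)) * (1 - lambda) / lambda` with
#' lambda the Lambda ratio.
#'
#' Constant (zero within-variance) variables are skipped silently; an empty
#' final selection is an error.
#'
#' @param X training matrix, samples x variables (preprocessed).
#' @param labels class factor, >= 2 classes, `n > nlevels`.
#' @param f_enter,f_remove F-to-enter / F-to-remove thresholds (classical
#'   defaults 3.84 / 2.71); `f_remove` must be below `f_enter`.
#' @param max_vars maximum number of variables to select.
#' @return a `selection_result`: list with `method = "swda"`, sorted
#'   `selected` indices, and a `trace` data frame (step, action, variable,
#'   wilks_lambda, partial_F).
#' @export
swda_select <- function(X, labels, f_enter = 3.84, f_remove = 2.71,
                        max_vars = 30L) {
  X <- as.matrix(X)
  labels <- droplevels(factor(labels))
  n <- nrow(X); p <- ncol(X); g <- nlevels(labels)
  if (g < 2) stop("need at least 2 classes")
  if (n <= g) stop("need more samples than classes")
  if (f_remove >= f_enter) stop("f_remove must be below f_enter")

  Tm <- crossprod(sweep(X, 2, colMeans(X)))          # total SSCP
  Wm <- matrix(0, p, p)                              # pooled within SSCP
  for (cl in levels(labels)) {
    idx <- labels == cl
    Xi <- X[idx, , drop = FALSE]
    Wm <- Wm + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  eligible <- diag(Tm) > 1e-12 * max(diag(Tm), 1)    # skip constants

  sel <- integer(0)
  lambda_cur <- 1
  trace <- list()
  step <- 0L

  # Lambda ratio of each candidate given the current set (NA if ineligible)
  cand_ratio <- function(cand) {
    out <- rep(NA_real_, length(cand))
    if (length(sel) == 0L) {
      wres <- diag(Wm)[cand]; tres <- diag(Tm)[cand]
    } else {
      Ws <- Wm[sel, sel, drop = FALSE]; Ts <- Tm[sel, sel, drop = FALSE]
      Wsc <- Wm[sel, cand, drop = FALSE]; Tsc <- Tm[sel, cand, drop = FALSE]
      wres <- diag(Wm)[cand] - colSums(Wsc * solve(Ws, Wsc))
      tres <- diag(Tm)[cand] - colSums(Tsc * solve(Ts, Tsc))
    }
    ok <- tres > 1e-10 * diag(Tm)[cand] & wres > 0
    out[ok] <- wres[ok] / tres[ok]
    pmin(out, 1)
  }

  partial_f <- function(lam, k) (n - g - k) / (g - 1) * (1 - lam) / lam

  repeat {
    if (length(sel) >= max_vars) break
    cand <- setdiff(which(eligible), sel)
    if (!length(cand)) break
    ratio <- cand_ratio(cand)
    Fv <- partial_f(ratio, length(sel))
    if (all(is.na(Fv)) || max(Fv, na.rm = TRUE) < f_enter) break
    best <- cand[which.max(Fv)]                      # lowest index on ties
    lambda_cur <- lambda_cur * ratio[match(best, cand)]
    sel <- c(sel, best)
    step <- step + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, action = "enter", variable = best,
      wilks_lambda = lambda_cur, partial_F = max(Fv, na.rm = TRUE))

    # removal phase: drop any included variable with partial F < f_remove
    repeat {
      if (length(sel) < 2L) break
      k <- length(sel)
      rm_ratio <- vapply(seq_along(sel), function(j) {
        rest <- sel[-j]
        Ws <- Wm[rest, rest, drop = FALSE]; Ts <- Tm[rest, rest, drop = FALSE]
        v <- sel[j]
        wres <- Wm[v, v] - sum(Wm[rest, v] * solve(Ws, Wm[rest, v]))
        tres <- Tm[v, v] - sum(Tm[rest, v] * solve(Ts, Tm[rest, v]))
        min(wres / tres, 1)
      }, numeric(1))
      Frm <- partial_f(rm_ratio, k - 1L)
      worst <- which.min(Frm)
      if (sel[worst] == sel[k]) {                    # never drop the entrant
        Frm[worst] <- Inf
        worst <- which.min(Frm)
      }
      if (!is.finite(Frm[worst]) || Frm[worst] >= f_remove) break
      lambda_cur <- lambda_cur / rm_ratio[worst]
      step <- step + 1L
      trace[[length(trace) + 1L]] <- data.frame(
        step = step, action = "remove", variable = sel[worst],
        wilks_lambda = lambda_cur, partial_F = Frm[worst])
      sel <- sel[-worst]
    }
  }

  if (!length(sel))
    stop("empty selection: no variable met the F-to-enter threshold")
  structure(list(method = "swda", selected = sort(sel),
                 trace = do.call(rbind, trace)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result (", x$method, "): ", length(x$selected),
      " variables selected\n", sep = "")
  invisible(x)
}

#' Write a selection result
#'
#' Serializes the selected variables as CSV (index, wavenumber) and the
#' selection trace as JSON.
#' @param sel a `selection_result`.
#' @param wavenumbers the grid the indices refer to.
#' @param csv_path,json_path output paths.
#' @export
write_selection <- function(sel, wavenumbers, csv_path, json_path) {
  utils::write.table(
    data.frame(variable = sel$selected,
               wavenumber = wavenumbers[sel$selected]),
    csv_path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sel$trace, json_path, dataframe = "columns",
                       digits = NA)
  invisible(csv_path)
}
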
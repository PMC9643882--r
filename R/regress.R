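#' Regression evaluation metrics
#'
#' The four calibration-model metrics used to evaluate adulteration-level
#' prediction: root mean square error, the printed `r` statistic
#' `1 - SSE/SST` (labelled a correlation coefficient in the field but
#' algebraically the coefficient-of-determination form; implemented
#' verbatim), the residual prediction deviation `RPD = Std(train
#' reference) / RMSE_p`, and the range error ratio
#' `RER = (Max - Min) / RMSE_t` (denominator is the training RMSE).
#'
#' @param y actual values.
#' @param y_hat predicted values.
#' @return `rmse()`: the root mean square error.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (!length(y)) stop("empty vectors")
  sqrt(mean((y - y_hat)^2))
}

#' @rdname rmse
#' @return `r_metric()`: `1 - SSE/SST`.
#' @export
r_metric <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps) stop("undefined metric: constant y")
  1 - sum((y_hat - y)^2) / sst
}

#' @rdname rmse
#' @param std_train_reference standard deviation of the training-set
#'   reference values.
#' @param rmse_p prediction-set RMSE.
#' @return `rpd()`: the residual prediction deviation.
#' @export
rpd <- function(std_train_reference, rmse_p) {
  if (rmse_p == 0) {
    message("RMSE_p is zero; RPD is infinite")
    return(Inf)
  }
  std_train_reference / rmse_p
}

#' @rdname rmse
#' @param max_ref,min_ref range of the reference values.
#' @param rmse_t training-set RMSE.
#' @return `rer()`: the range error ratio.
#' @export
rer <- function(max_ref, min_ref, rmse_t) {
  if (max_ref <= min_ref) stop("degenerate reference range")
  if (rmse_t == 0) {
    message("RMSE_t is zero; RER is infinite")
    return(Inf)
  }
  (max_ref - min_ref) / rmse_t
}

rpd_flag <- function(x) {
  if (x >= 5) "quality control"
  else if (x >= 3) "satisfactory"
  else if (x >= 2) "fast screening"
  else "poor"
}

rer_flag <- function(x) if (x > 10) "good predictive ability" else "limited"

#' Bundle the calibration metric suite for one regression model
#'
#' @param y_train,yhat_train training actual/predicted adulteration levels (%).
#' @param y_test,yhat_test prediction-set actual/predicted levels (%).
#' @return a `regression_metrics` object with `RMSE_t`, `RMSE_p`, `r_t`,
#'   `r_p`, `RPD`, `RER`, sample counts and quality flags.
#' @export
regression_metrics <- function(y_train, yhat_train, y_test, yhat_test) {
  RMSE_t <- rmse(y_train, yhat_train)
  RMSE_p <- rmse(y_test, yhat_test)
  RPD <- rpd(stats::sd(y_train), RMSE_p)
  RER <- rer(max(y_train), min(y_train), RMSE_t)
  structure(list(RMSE_t = RMSE_t, RMSE_p = RMSE_p,
                 r_t = r_metric(y_train, yhat_train),
                 r_p = r_metric(y_test, yhat_test),
                 RPD = RPD, RER = RER,
                 n_train = length(y_train), n_test = length(y_test),
                 rpd_flag = rpd_flag(RPD), rer_flag = rer_flag(RER)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf(
    "RMSE_t = %.3f  RMSE_p = %.3f  r_t = %.4f  r_p = %.4f\nRPD = %.2f (%s)  RER = %.2f (%s)\n",
    x$RMSE_t, x$RMSE_p, x$r_t, x$r_p, x$RPD, x$rpd_flag, x$RER, x$rer_flag))
  invisible(x)
}

#' Quantification tasks
#'
#' The four adulteration-level regression tasks: (1) CBG content in the
#' binary DBT+CBG samples, (2) PBG content in the binary DBT+PBG samples,
#' (3) CBG content and (4) PBG content in the ternary samples. Responses are
#' adulterant mass fractions in percent: 10-50% for the binary tasks,
#' 5-25% for each gel in the ternary task.
#'
#' @param id task id, 1-4.
#' @return a `quant_task`: `id`, `class` (source class), `response_column`.
#' @export
quant_task <- function(id) {
  stopifnot(id %in% 1:4)
  spec <- list(
    list(class = "DBT+CBG", response = "f_cbg"),
    list(class = "DBT+PBG", response = "f_pbg"),
    list(class = "DBT+CBG+PBG", response = "f_cbg"),
    list(class = "DBT+CBG+PBG", response = "f_pbg"))[[id]]
  structure(list(id = id, class = spec$class,
                 response_column = spec$response),
            class = "quant_task")
}

task_response <- function(task, spectra, idx) {
  100 * spectra$fractions[idx, task$response_column]
}

#' Run one ELM regression (ELMR) quantification task
#'
#' Restricts the design to the task's source class, holds out one third of
#' each adulteration-level group by Kennard-Stone, preprocesses (fit on
#' training), selects crucial wavenumbers by CARS on the training split,
#' column-standardizes the selected variables with training statistics, and
#' sweeps an ELM regressor (Sine activation) over `neuron_range`, keeping the
#' neuron count with the lowest prediction-set RMSE. Metrics follow
#' [regression_metrics()].
#'
#' @param task a [quant_task()] (or its integer id).
#' @param spectra the full [spectra_set()].
#' @param split optional `split_indices` on the task subset; if `NULL`
#'   (default) a level-stratified one-third Kennard-Stone hold-out is made.
#' @param preprocess_method one of [preprocess_methods()].
#' @param selection optional `selection_result` to reuse (e.g. carry a binary
#'   task's selection into the matching ternary task); `NULL` runs CARS.
#' @param cars_runs,cv_folds,max_pls_components CARS parameters.
#' @param neuron_range hidden-layer sizes swept (default 1:50).
#' @param seed integer seed.
#' @return list: `task`, `model` (`elm_model`), `selection`, `metrics`,
#'   `preprocess_method`, `n_hidden`, `sweep` curve and `predictions`
#'   (data frame of actual/predicted for both halves).
#' @export
run_elmr_task <- function(task, spectra, split = NULL,
                          preprocess_method = "msc", selection = NULL,
                          cars_runs = 50L, cv_folds = 5L,
                          max_pls_components = 10L,
                          neuron_range = 1:50, seed = 1L) {
  if (is.numeric(task)) task <- quant_task(task)
  stopifnot(inherits(task, "quant_task"), inherits(spectra, "spectra_set"))
  idx <- which(spectra$class_labels == task$class)
  if (!length(idx)) stop("no samples of class ", task$class)
  sub <- spectra[idx]
  y_all <- task_response(task, spectra, idx)
  if (is.null(split))
    split <- stratified_ks_split(sub, strata = factor(y_all))
  tr <- split$train_idx; te <- split$test_idx

  pp <- fit_preprocessor(preprocess_method, sub$absorbance[tr, , drop = FALSE],
                         wavenumbers = sub$wavenumbers)
  Xtr <- apply_preprocessor(pp, sub$absorbance[tr, , drop = FALSE])
  Xte <- apply_preprocessor(pp, sub$absorbance[te, , drop = FALSE])
  y_tr <- y_all[tr]; y_te <- y_all[te]

  if (is.null(selection))
    selection <- cars_select(Xtr, y_tr, n_runs = cars_runs,
                             cv_folds = cv_folds,
                             max_pls_components = max_pls_components,
                             seed = substream_seed(seed, "cars", task$id))
  sel <- selection$selected
  Xtr_s <- Xtr[, sel, drop = FALSE]; Xte_s <- Xte[, sel, drop = FALSE]
  mu <- colMeans(Xtr_s); sd_ <- apply(Xtr_s, 2, stats::sd)
  sd_[sd_ < .Machine$double.eps] <- 1
  # standardize, then scale by 1/sqrt(d) so the random-projection arguments
  # x'w stay O(1) regardless of how many variables CARS kept; otherwise the
  # sine activation wraps many periods and the hidden layer loses the signal
  scl <- sd_ * sqrt(length(sel))
  Ztr <- sweep(sweep(Xtr_s, 2, mu), 2, scl, "/")
  Zte <- sweep(sweep(Xte_s, 2, mu), 2, scl, "/")

  curve <- data.frame(n_hidden = neuron_range, rmse_t = NA_real_,
                      rmse_p = NA_real_)
  best <- NULL
  for (r in seq_along(neuron_range)) {
    nh <- neuron_range[r]
    mdl <- elm_train(Ztr, y_tr, nh, activation = "sine",
                     seed = substream_seed(seed, "elmr.sine", nh))
    pr_tr <- drop(elm_predict(mdl, Ztr))
    pr_te <- drop(elm_predict(mdl, Zte))
    curve$rmse_t[r] <- rmse(y_tr, pr_tr)
    curve$rmse_p[r] <- rmse(y_te, pr_te)
    if (is.null(best) || curve$rmse_p[r] < best$rmse_p)
      best <- list(model = mdl, n_hidden = nh, rmse_p = curve$rmse_p[r],
                   pred_train = pr_tr, pred_test = pr_te)
  }

  metrics <- regression_metrics(y_tr, best$pred_train, y_te, best$pred_test)
  predictions <- rbind(
    data.frame(set = "train", actual = y_tr, predicted = best$pred_train),
    data.frame(set = "test", actual = y_te, predicted = best$pred_test))
  list(task = task, model = best$model, selection = selection,
       metrics = metrics, preprocess_method = preprocess_method,
       n_hidden = best$n_hidden, sweep = curve, predictions = predictions)
}
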
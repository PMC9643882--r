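#' Run configuration
#'
#' A serializable bundle of every knob a pipeline run uses: the master seed,
#' simulator parameters, pretreatment settings, selector parameters and the
#' neuron sweep range. Round-trips through YAML so a run can be archived next
#' to its outputs and replayed bit-identically.
#'
#' @param seed master integer seed.
#' @param n_per_cell simulated samples per design cell.
#' @param artifact list of [artifact_params()] arguments.
#' @param savgol list with `window` and `polyorder`.
#' @param swda list with `f_enter`, `f_remove`, `max_vars`.
#' @param cars list with `n_runs`, `cv_folds`, `max_pls_components`.
#' @param neuron_range length-2 integer range of hidden neurons swept.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_per_cell = 30L,
                       artifact = list(), savgol = list(window = 15L,
                                                        polyorder = 2L),
                       swda = list(f_enter = 3.84, f_remove = 2.71,
                                   max_vars = 30L),
                       cars = list(n_runs = 50L, cv_folds = 5L,
                                   max_pls_components = 10L),
                       neuron_range = c(1L, 50L)) {
  structure(list(seed = as.integer(seed), n_per_cell = as.integer(n_per_cell),
                 artifact = artifact, savgol = savgol, swda = swda,
                 cars = cars, neuron_range = as.integer(neuron_range)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

identification_methods <- function() {
  c("none", "centralization", "first_derivative", "second_derivative",
    "msc", "snv")
}

quantification_methods <- function() {
  c("first_derivative", "second_derivative", "centralization", "snv", "msc")
}

#' Identification experiment: pretreatment grid, Fisher LDA and ELM
#'
#' For each of the six pretreatments (none, centralization, first and second
#' derivative, MSC, SNV): fit the pretreatment on the training split, select
#' crucial wavenumbers by SWDA, compress to `n_pcs` principal components,
#' fit Fisher LDA and record training/test accuracy. The pretreatment with
#' the best LDA test accuracy is then used for the ELM hidden-neuron and
#' activation sweep. The Kennard-Stone split is computed once on raw spectra
#' and shared by every pretreatment and model.
#'
#' @param spectra a [spectra_set()] (simulated or read from file).
#' @param config a [run_config()].
#' @param methods pretreatments to compare (default all six).
#' @param n_pcs principal components kept (default 3).
#' @return list: `grid_report` (one row per method: method, n_selected,
#'   train/test accuracy, best flag), `split`, `best_method`, `lda` (model,
#'   DF coefficient table, train/test reports), `elm` (sweep curve and best),
#'   `selection` per method.
#' @export
run_identification <- function(spectra, config = run_config(),
                               methods = identification_methods(),
                               n_pcs = 3L) {
  stopifnot(inherits(spectra, "spectra_set"))
  split <- stratified_ks_split(spectra)
  tr <- split$train_idx; te <- split$test_idx
  labels_tr <- spectra$class_labels[tr]
  labels_te <- spectra$class_labels[te]

  grid <- data.frame(method = methods, n_selected = NA_integer_,
                     train_accuracy = NA_real_, test_accuracy = NA_real_)
  per_method <- list()
  for (m in methods) {
    res <- tryCatch({
      pp <- fit_preprocessor(m, spectra$absorbance[tr, , drop = FALSE],
                             wavenumbers = spectra$wavenumbers,
                             window = config$savgol$window,
                             polyorder = config$savgol$polyorder)
      Xtr <- apply_preprocessor(pp, spectra$absorbance[tr, , drop = FALSE])
      Xte <- apply_preprocessor(pp, spectra$absorbance[te, , drop = FALSE])
      sel <- swda_select(Xtr, labels_tr, f_enter = config$swda$f_enter,
                         f_remove = config$swda$f_remove,
                         max_vars = config$swda$max_vars)
      pca <- pca_fit(Xtr[, sel$selected, drop = FALSE],
                     min(n_pcs, length(sel$selected)))
      Str <- pca_transform(pca, Xtr[, sel$selected, drop = FALSE])
      Ste <- pca_transform(pca, Xte[, sel$selected, drop = FALSE])
      lda <- fisher_lda_fit(Str, labels_tr)
      list(pp = pp, selection = sel, pca = pca, lda = lda,
           scores_train = Str, scores_test = Ste,
           train_report = accuracy(labels_tr, fisher_lda_predict(lda, Str)),
           test_report = accuracy(labels_te, fisher_lda_predict(lda, Ste)))
    }, error = function(e) stop("stage '", m, "': ", conditionMessage(e)))
    per_method[[m]] <- res
    i <- match(m, grid$method)
    grid$n_selected[i] <- length(res$selection$selected)
    grid$train_accuracy[i] <- res$train_report$R
    grid$test_accuracy[i] <- res$test_report$R
  }
  grid$best <- seq_len(nrow(grid)) == which.max(grid$test_accuracy)
  best_method <- grid$method[grid$best]
  bm <- per_method[[best_method]]

  # standardize the PC scores with training statistics before the random
  # projection so the activations operate on a sane scale
  mu <- colMeans(bm$scores_train)
  sd_ <- apply(bm$scores_train, 2, stats::sd)
  sd_[sd_ < .Machine$double.eps] <- 1
  Ztr <- sweep(sweep(bm$scores_train, 2, mu), 2, sd_, "/")
  Zte <- sweep(sweep(bm$scores_test, 2, mu), 2, sd_, "/")
  nh_range <- seq(config$neuron_range[1], config$neuron_range[2])
  elm <- sweep_elm(Ztr, labels_tr, Zte, labels_te, neuron_range = nh_range,
                   seed = config$seed)

  df_table <- as.data.frame(bm$lda$coef)
  colnames(df_table) <- paste0("DF", seq_len(ncol(df_table)))
  rownames(df_table) <- paste0("PC", seq_len(nrow(df_table)))

  list(grid_report = grid, split = split, best_method = best_method,
       lda = list(model = bm$lda, df_coefficients = df_table,
                  train_report = bm$train_report,
                  test_report = bm$test_report),
       elm = elm, per_method = per_method,
       neuron_range_hint = hidden_neuron_range(length(tr), n_pcs, 1L))
}

#' Quantification experiment: the four ELMR tasks
#'
#' Runs every [quant_task()] over a grid of pretreatments paired with CARS,
#' keeps the best pretreatment per task by prediction-set RMSE, and for the
#' ternary tasks (3 and 4) also evaluates the matching binary task's
#' pretreatment/selection, keeping whichever performs better.
#'
#' @param spectra a [spectra_set()].
#' @param config a [run_config()].
#' @param methods pretreatments compared per task (default the five compared
#'   for denoising).
#' @return list of four task reports as returned by [run_elmr_task()], each
#'   with the winning pretreatment recorded.
#' @export
run_quantification <- function(spectra, config = run_config(),
                               methods = quantification_methods()) {
  stopifnot(inherits(spectra, "spectra_set"))
  nh_range <- seq(config$neuron_range[1], config$neuron_range[2])
  run_one <- function(id, selection = NULL, meths = methods) {
    fits <- lapply(meths, function(m)
      run_elmr_task(quant_task(id), spectra, preprocess_method = m,
                    selection = selection,
                    cars_runs = config$cars$n_runs,
                    cv_folds = config$cars$cv_folds,
                    max_pls_components = config$cars$max_pls_components,
                    neuron_range = nh_range, seed = config$seed))
    fits[[which.min(vapply(fits, function(f) f$metrics$RMSE_p, numeric(1)))]]
  }
  rep1 <- run_one(1)
  rep2 <- run_one(2)
  rep3 <- run_one(3)
  rep4 <- run_one(4)
  # ternary tasks may inherit the binary tasks' pretreatment + selection
  alt3 <- run_elmr_task(quant_task(3), spectra,
                        preprocess_method = rep1$preprocess_method,
                        selection = rep1$selection,
                        neuron_range = nh_range, seed = config$seed)
  if (alt3$metrics$RMSE_p < rep3$metrics$RMSE_p) rep3 <- alt3
  alt4 <- run_elmr_task(quant_task(4), spectra,
                        preprocess_method = rep2$preprocess_method,
                        selection = rep2$selection,
                        neuron_range = nh_range, seed = config$seed)
  if (alt4$metrics$RMSE_p < rep4$metrics$RMSE_p) rep4 <- alt4
  list(rep1, rep2, rep3, rep4)
}

#' Write a quantification task report
#'
#' JSON metrics plus a CSV of actual/predicted pairs for both halves.
#' @param report a task report from [run_elmr_task()].
#' @param metrics_path,scatter_path output paths.
#' @export
write_task_report <- function(report, metrics_path, scatter_path) {
  m <- report$metrics
  jsonlite::write_json(
    list(task = report$task$id, class = report$task$class,
         response = report$task$response_column,
         preprocess_method = report$preprocess_method,
         n_selected = length(report$selection$selected),
         n_hidden = report$n_hidden,
         RMSE_t = m$RMSE_t, RMSE_p = m$RMSE_p, r_t = m$r_t, r_p = m$r_p,
         RPD = m$RPD, RER = m$RER,
         rpd_flag = m$rpd_flag, rer_flag = m$rer_flag),
    metrics_path, auto_unbox = TRUE, digits = NA)
  utils::write.table(report$predictions, scatter_path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(metrics_path)
}
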
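test_that("RMSE matches its definition and an elementwise oracle", {
  expect_equal(rmse(c(0, 10), c(3, 7)), 3)
  expect_equal(rmse(1:5, 1:5), 0)
  set.seed(41)
  y <- rnorm(1000); yh <- rnorm(1000)
  expect_equal(rmse(y, yh), sqrt(sum((y - yh)^2) / 1000), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("the r statistic is the printed 1 - SSE/SST form", {
  y <- c(10, 20, 30)
  expect_equal(r_metric(y, c(12, 20, 28)), 0.96)
  expect_equal(r_metric(y, y), 1)
  expect_equal(r_metric(y, rep(mean(y), 3)), 0)
  expect_error(r_metric(rep(2, 4), 1:4), "constant y")
  # identity with RMSE on random data
  set.seed(42)
  yy <- rnorm(200, 20, 5); pp <- yy + rnorm(200)
  expect_equal(r_metric(yy, pp),
               1 - rmse(yy, pp)^2 * 200 / sum((yy - mean(yy))^2),
               tolerance = 1e-12)
})

test_that("RPD and RER follow their definitions and quality bands", {
  expect_equal(rpd(10, 2.5), 4)
  expect_equal(rer(50, 10, 2), 20)
  expect_equal(rer(50, 10, 4), 10)            # doubling RMSE_t halves RER
  expect_error(rer(10, 10, 1), "degenerate")
  set.seed(43)
  y_tr <- rep(seq(10, 50, 10), each = 4); f_tr <- y_tr + rnorm(20, 0, 2)
  y_te <- rep(seq(10, 50, 10), 2); f_te <- y_te + rnorm(10, 0, 2)
  m <- regression_metrics(y_tr, f_tr, y_te, f_te)
  expect_equal(m$RPD, sd(y_tr) / m$RMSE_p)
  expect_equal(m$RER, (50 - 10) / m$RMSE_t)
  expect_equal(regression_metrics(y_tr, f_tr, y_te, y_te +
                                    0.1 * rnorm(10))$rpd_flag,
               "quality control")
})

test_that("quantification tasks carve the right samples and responses", {
  t1 <- quant_task(1); t3 <- quant_task(3)
  expect_equal(t1$class, "DBT+CBG")
  expect_equal(t3$response_column, "f_cbg")
  expect_error(quant_task(5))

  ss <- small_design(seed = 5, n_per_cell = 6L, n_grid = 200L)
  rep1 <- run_elmr_task(1, ss, preprocess_method = "msc", cars_runs = 20,
                        neuron_range = 1:15, seed = 5)
  y <- rep1$predictions$actual
  expect_setequal(round(unique(y), 8), c(10, 20, 30, 40, 50))
  expect_equal(rep1$metrics$RER, 40 / rep1$metrics$RMSE_t)
  expect_equal(rep1$metrics$n_train + rep1$metrics$n_test,
               sum(ss$class_labels == "DBT+CBG"))

  rep3 <- run_elmr_task(3, ss, preprocess_method = "msc", cars_runs = 20,
                        neuron_range = 1:15, seed = 5)
  expect_setequal(round(unique(rep3$predictions$actual), 8),
                  c(5, 10, 15, 20, 25))
})

test_that("more simulator noise never helps prediction", {
  rmse_at_noise <- function(noise_sd) {
    med <- vapply(1:3, function(s) {
      ss <- generate_design(
        params = artifact_params(noise_sd = noise_sd), seed = s,
        n_per_cell = 6L, grid = tiny_grid(200))
      run_elmr_task(1, ss, preprocess_method = "msc", cars_runs = 15,
                    neuron_range = 1:10, seed = s)$metrics$RMSE_p
    }, numeric(1))
    median(med)
  }
  r <- vapply(c(0.003, 0.05), rmse_at_noise, numeric(1))
  expect_lt(r[1], r[2])
})
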
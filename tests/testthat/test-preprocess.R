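test_that("SNV standardizes each spectrum to mean 0, sd 1", {
  expect_equal(
    drop(apply_preprocessor(fit_preprocessor("snv", matrix(1, 1, 3)),
                            matrix(c(0, 1, 2), 1))),
    c(-1, 0, 1))
  set.seed(4)
  X <- matrix(rnorm(40 * 25, sd = 3), 40)
  Z <- apply_preprocessor(fit_preprocessor("snv", X), X)
  expect_equal(rowMeans(Z), rep(0, 40), tolerance = 1e-10)
  expect_equal(apply(Z, 1, sd), rep(1, 40), tolerance = 1e-10)
  Xdeg <- rbind(X, 2)
  expect_error(apply_preprocessor(fit_preprocessor("snv", X), Xdeg),
               "degenerate spectrum")
})

test_that("MSC stores the training mean and undoes slope/offset artifacts", {
  set.seed(5)
  M <- matrix(rnorm(10 * 30), 10)
  pp <- fit_preprocessor("msc", M)
  expect_equal(pp$fitted$reference, colMeans(M))
  # a spectrum equal to the reference passes through unchanged (a=0, b=1)
  expect_equal(drop(apply_preprocessor(pp, matrix(colMeans(M), 1))),
               colMeans(M))

  # simulator artifact model b*ref + a, no noise: MSC recovers ref
  g <- tiny_grid(200)
  ref <- mix_spectrum(default_endmembers(), c(0.7, 0.2, 0.1), g)
  set.seed(6)
  b <- exp(rnorm(12, 0, 0.3)); a <- rnorm(12, 0, 0.2)
  X <- b %o% ref + a
  ppr <- fit_preprocessor("msc", matrix(ref, 1))
  rec <- apply_preprocessor(ppr, X)
  expect_lt(max(abs(sweep(rec, 2, ref))), 1e-8)

  expect_error(apply_preprocessor(ppr, matrix(0, 1, length(ref))),
               "degenerate")
})

test_that("centralization zeroes training column means and never test means", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8, mean = 2), 30)
  pp <- fit_preprocessor("centralization", X)
  expect_equal(colMeans(apply_preprocessor(pp, X)), rep(0, 8),
               tolerance = 1e-12)
  # stored means come from the training split, not from the applied matrix
  Y <- X + 1
  expect_equal(colMeans(apply_preprocessor(pp, Y)), rep(1, 8),
               tolerance = 1e-12)
})

test_that("Savitzky-Golay derivatives are exact on low-order polynomials", {
  g <- tiny_grid(120)
  d1 <- fit_preprocessor("first_derivative", matrix(1, 1, 120),
                         wavenumbers = g)
  d2 <- fit_preprocessor("second_derivative", matrix(1, 1, 120),
                         wavenumbers = g)
  const <- matrix(5, 3, 120)
  expect_equal(apply_preprocessor(d1, const), matrix(0, 3, 120),
               tolerance = 1e-12)
  expect_equal(apply_preprocessor(d2, const), matrix(0, 3, 120),
               tolerance = 1e-12)
  # quadratic in the wavenumber: first derivative linear, second constant
  quad <- matrix(2 + 0.003 * g + 1e-6 * g^2, 1)
  expect_equal(drop(apply_preprocessor(d1, quad)), 0.003 + 2e-6 * g,
               tolerance = 1e-8)
  expect_equal(drop(apply_preprocessor(d2, quad)), rep(2e-6, 120),
               tolerance = 1e-10)
})

test_that("every method preserves the number of rows and checks the grid", {
  ss <- small_design(n_per_cell = 2L, n_grid = 150L)
  X <- ss$absorbance
  for (m in preprocess_methods()) {
    pp <- fit_preprocessor(m, X, wavenumbers = ss$wavenumbers)
    expect_equal(nrow(apply_preprocessor(pp, X)), nrow(X))
    expect_error(apply_preprocessor(pp, X[, 1:10]), "column count")
  }
  expect_error(fit_preprocessor("msc", matrix(numeric(0), 0, 5)), "empty")
})
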
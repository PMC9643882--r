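test_that("default endmembers carry the twelve key bands and are separable", {
  ems <- default_endmembers()
  centers <- c(4108, 4405, 5238, 5326, 5477, 5774, 6241, 6931, 7189,
               8015, 9399, 9997)
  for (em in ems) {
    expect_s3_class(em, "endmember_set")
    expect_equal(em$bands$center, centers)
    expect_true(all(em$bands$amplitude > 0))
    expect_true(all(em$bands$width > 0))
  }
  amps <- sapply(ems, function(e) e$bands$amplitude)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_gte(sum(amps[, pair[1]] != amps[, pair[2]]), 6)
  expect_true(all(eval_endmember(ems$DBT) > 0))
  # twice: deterministic
  expect_identical(default_endmembers(), ems)
})

test_that("mixing is linear in the mass fractions", {
  ems <- default_endmembers()
  g <- tiny_grid()
  expect_equal(mix_spectrum(ems, c(1, 0, 0), g), eval_endmember(ems$DBT, g))
  m1 <- mix_spectrum(ems, c(0.5, 0.25, 0.25), g)
  m2 <- 0.5 * (mix_spectrum(ems, c(1, 0, 0), g) +
                 mix_spectrum(ems, c(0, 0.5, 0.5), g))
  expect_equal(m1, m2)
  # the 10% ternary composition of the design is a valid input
  expect_silent(mix_spectrum(ems, c(0.9, 0.05, 0.05), g))
  expect_error(mix_spectrum(ems, c(0.5, 0.5, 0.5), g), "invalid composition")
  expect_error(mix_spectrum(ems, c(1.2, -0.2, 0), g), "invalid composition")
})

test_that("artifacts are reproducible, unbiased when off, with averaged noise", {
  g <- tiny_grid(50)
  x <- mix_spectrum(default_endmembers(), c(0.8, 0.1, 0.1), g)
  expect_identical(apply_artifacts(x, noiseless_params(), g, seed = 5), x)
  p <- artifact_params()
  a1 <- apply_artifacts(x, p, g, seed = 42)
  a2 <- apply_artifacts(x, p, g, seed = 42)
  expect_identical(a1, a2)
  expect_false(identical(a1, apply_artifacts(x, p, g, seed = 43)))

  # replicate averaging: noise variance of the mean of 3 scans is sd^2/3
  pn <- artifact_params(scatter_slope_sd = 0, scatter_offset_sd = 0,
                        tilt_sd = 0, noise_sd = 0.01, n_replicates = 3L)
  g1 <- g[1:2]
  x1 <- x[1:2]
  draws <- vapply(seq_len(10000), function(i)
    apply_artifacts(x1, pn, g1, seed = i)[1], numeric(1))
  expect_equal(var(draws), 0.01^2 / 3, tolerance = 0.05)
})

test_that("the simulated design has the full factorial structure", {
  ss <- small_design(seed = 3, n_per_cell = 4L)
  expect_equal(n_samples(ss), 18 * 4)
  counts <- table(ss$class_labels)
  expect_equal(unname(counts[c("DBT", "CBG", "PBG")]), rep(4L, 3),
               ignore_attr = TRUE)
  expect_equal(unname(counts[c("DBT+CBG", "DBT+PBG", "DBT+CBG+PBG")]),
               rep(20L, 3), ignore_attr = TRUE)
  # simplex invariant and the equal CBG/PBG split of the ternary cells
  expect_true(all(abs(rowSums(ss$fractions) - 1) < 1e-9))
  tern <- ss$fractions[ss$class_labels == "DBT+CBG+PBG", ]
  expect_equal(tern[, "f_cbg"], tern[, "f_pbg"], ignore_attr = TRUE)
  bin <- ss$fractions[ss$class_labels == "DBT+CBG", "f_cbg"]
  expect_equal(sort(unique(round(bin, 10))), seq(0.1, 0.5, 0.1))
})

test_that("generation is seed-reproducible with per-sample substreams", {
  ss1 <- small_design(seed = 9)
  ss2 <- small_design(seed = 9)
  expect_identical(ss1$absorbance, ss2$absorbance)
  expect_false(identical(ss1$absorbance, small_design(seed = 10)$absorbance))

  # sample i depends only on (seed, i): rebuild row 17 from scratch
  i <- 17L
  clean <- mix_spectrum(default_endmembers(), ss1$fractions[i, ],
                        ss1$wavenumbers)
  row_i <- apply_artifacts(clean, artifact_params(), ss1$wavenumbers,
                           seed = substream_seed(9, "sample", i))
  expect_equal(unname(ss1$absorbance[i, ]), row_i)
})

test_that("pure-class spectra are separable and mixing is invertible", {
  ss <- generate_design(params = noiseless_params(), seed = 1,
                        n_per_cell = 2L, grid = tiny_grid())
  pure <- lapply(c("DBT", "CBG", "PBG"), function(cl)
    colMeans(ss$absorbance[ss$class_labels == cl, , drop = FALSE]))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_gt(max(abs(pure[[pair[1]]] - pure[[pair[2]]])),
              10 * artifact_params()$noise_sd)

  # regressing any zero-artifact mixture on the endmember spectra recovers
  # the generating fractions
  E <- sapply(default_endmembers(), eval_endmember, grid = ss$wavenumbers)
  for (i in which(ss$class_labels == "DBT+CBG+PBG")) {
    beta <- qr.solve(E, ss$absorbance[i, ])
    expect_equal(unname(beta), unname(ss$fractions[i, ]), tolerance = 1e-8)
  }
})
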
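test_that("generation is bitwise deterministic and correctly shaped", {
  cfg <- generator_config(n_per_class = 4, seed = 1)
  a <- generate_block(cfg, "lc")
  b <- generate_block(cfg, "lc")
  expect_identical(a$block$values, b$block$values)
  expect_identical(a$truth$true_shifts, b$truth$true_shifts)
  expect_equal(dim(a$block$values), c(20, 7201))
  ft <- generate_block(cfg, "ftir")
  expect_equal(dim(ft$block$values), c(20, 1737))
  expect_equal(ft$block$axis[1], 650)
  expect_equal(ft$block$axis[1737], 4000)
})

test_that("noise-free two-class blocks reproduce the configured peak signal", {
  pk <- data.frame(block = "lc", center = c(10, 30), width = c(1, 1),
                   h1 = c(0.5, 1.0), h2 = c(0.5, 1.6))
  cfg <- generator_config(n_per_class = 3, n_classes = 2, lc_points = 601,
                          lc_minutes = 60, peak_table = pk, shift_sd = 0,
                          noise_sd = 0, height_sd = 0, latent_sd = 0,
                          baseline_amp = 0, seed = 7)
  g <- generate_block(cfg, "lc")
  j <- which.min(abs(g$block$axis - 30))
  m1 <- colMeans(g$block$values[g$block$labels == "Class1", , drop = FALSE])
  m2 <- colMeans(g$block$values[g$block$labels == "Class2", , drop = FALSE])
  expect_equal(unname(m2[j] - m1[j]), 0.6, tolerance = 1e-12)
  # class centroids equal the clean superposition exactly
  expect_equal(unname(m1), g$truth$clean[1, ], tolerance = 1e-12)
  expect_equal(unname(m2), g$truth$clean[2, ], tolerance = 1e-12)
  # informative set covers the discriminative peak only
  expect_true(all(abs(g$block$axis[g$truth$informative] - 30) <= 1))
})

test_that("within-class noise converges to noise_sd at a signal-free variable", {
  cfg <- generator_config(n_per_class = 100, n_classes = 2, lc_points = 301,
                          peak_table = data.frame(block = "lc", center = 10,
                                                  width = 0.5, h1 = 1,
                                                  h2 = 2),
                          shift_sd = 0, noise_sd = 0.05, height_sd = 0,
                          latent_sd = 0, baseline_amp = 0, seed = 3)
  g <- generate_block(cfg, "lc")
  j <- which.min(abs(g$block$axis - 50))  # far from the only peak
  s <- stats::sd(g$block$values[g$block$labels == "Class1", j])
  se <- 0.05 / sqrt(2 * (100 - 1))
  expect_lt(abs(s - 0.05), 3 * se)
})

test_that("FTIR noisy bands carry no class signal", {
  cfg <- generator_config(n_per_class = 2, ftir_points = 869, noise_sd = 0,
                          baseline_amp = 0, seed = 2)
  g <- generate_block(cfg, "ftir")
  ax <- g$block$axis
  in_band <- (ax >= 1750 & ax <= 2670) | (ax >= 3700 & ax <= 4000)
  # noise switched off -> the noise-only bands are essentially flat zero
  # (only far Gaussian tails of out-of-band peaks reach in)
  expect_lt(max(abs(g$block$values[, in_band])), 1e-3)
  expect_gt(max(abs(g$block$values[, !in_band])), 0.5)
  expect_false(any(g$truth$informative %in% which(in_band)))
})

test_that("invalid block kinds and out-of-axis peaks are rejected by name", {
  cfg <- generator_config(n_per_class = 2, lc_points = 101)
  expect_error(generate_block(cfg, "nmr"))
  bad <- generator_config(n_per_class = 2, lc_points = 101, lc_minutes = 10,
                          peak_table = data.frame(block = "lc", center = 44,
                                                  width = 1, h1 = 1, h2 = 1,
                                                  h3 = 1, h4 = 1, h5 = 1))
  expect_error(generate_block(bad, "lc"), "44")
  expect_error(generator_config(n_per_class = 1), "n_per_class")
})
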
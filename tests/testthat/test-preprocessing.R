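make_block <- function(X, axis = seq_len(ncol(X)), kind = "retention_time") {
  fingerprint_block(X, axis, kind)
}

test_that("1-in-k reduction keeps the first point and every k-th after", {
  b <- make_block(matrix(rnorm(2 * 7201), 2), seq(0, 60, length.out = 7201))
  expect_equal(ncol(downsample_every_k(b, 3)$values), 2401)
  b9 <- make_block(matrix(1:18, 2, byrow = TRUE), 1:9)
  expect_equal(downsample_every_k(b9, 3)$axis, c(1, 4, 7))
  expect_equal(downsample_every_k(b9, 1), b9)
  expect_error(downsample_every_k(b9, 0), "positive")
})

test_that("SG second derivative is exact on polynomials and truncates edges", {
  b <- make_block(matrix(rnorm(3 * 2401), 3))
  expect_equal(ncol(sg_second_derivative(b)$values), 2387)
  quad <- make_block(matrix((1:60)^2, 1), 1:60)
  out <- sg_second_derivative(quad)
  expect_equal(unname(out$values[1, ]), rep(2, 46), tolerance = 1e-9)
  expect_equal(out$axis, 8:53)
  lin <- make_block(matrix(5 * (1:60) - 3, 1), 1:60)
  expect_equal(max(abs(sg_second_derivative(lin)$values)), 0,
               tolerance = 1e-9)
  expect_error(sg_second_derivative(make_block(matrix(1:10, 1), 1:10)),
               "window")
  expect_error(sg_second_derivative(b, window = 14), "odd")
})

test_that("SG filtering is linear in the signal", {
  b <- make_block(matrix(rnorm(4 * 100), 4))
  f1 <- sg_second_derivative(make_block(3.7 * b$values))
  f2 <- sg_second_derivative(b)
  expect_equal(f1$values, 3.7 * f2$values, tolerance = 1e-12)
})

test_that("band deletion drops exactly the in-band variables, idempotently", {
  b <- make_block(matrix(rnorm(2 * 9), 2), 1:9, "wavenumber")
  expect_equal(remove_bands(b, list(c(10, 20))), b)
  b5 <- make_block(matrix(rnorm(2 * 5), 2), 1:5, "wavenumber")
  expect_equal(remove_bands(b5, list(c(2, 4)))$axis, c(1, 5))
  ax <- seq(650, 4000, length.out = 10)
  b10 <- make_block(matrix(rnorm(2 * 10), 2), ax, "wavenumber")
  bands <- list(c(1750, 2670), c(3700, 4000))
  kept <- remove_bands(b10, bands)
  manual <- ax[!((ax >= 1750 & ax <= 2670) | (ax >= 3700 & ax <= 4000))]
  expect_equal(kept$axis, manual)
  expect_equal(remove_bands(kept, bands), kept)
})

test_that("full LC chain turns 7201 variables into exactly 2387", {
  set.seed(11)
  ax <- seq(0, 60, length.out = 7201)
  sig <- exp(-(ax - 20)^2 / 0.5) + 0.6 * exp(-(ax - 40)^2 / 0.8)
  X <- rbind(sig, sig + rnorm(7201, 0, 0.01), sig + rnorm(7201, 0, 0.01))
  out <- pretreat_lc(fingerprint_block(X, ax, "retention_time"))
  expect_equal(dim(out$values), c(3, 2387))
})

test_that("FTIR chain deletes bands after filtering and alignment helps LC", {
  ax <- seq(650, 4000, length.out = 869)
  X <- matrix(rnorm(3 * 869), 3)
  out <- pretreat_ftir(fingerprint_block(X, ax, "wavenumber"))
  # band edges live inside the SG-truncated axis: widths follow from the
  # truncated axis, not the raw one
  sg_ax <- ax[8:(869 - 7)]
  expect_equal(length(out$axis),
               sum(!((sg_ax >= 1750 & sg_ax <= 2670) |
                       (sg_ax >= 3700 & sg_ax <= 4000))))
  expect_false(any(out$axis >= 1750 & out$axis <= 2670))

  # noiseless shifted chromatograms become more alike after the chain
  cfg <- generator_config(n_per_class = 3, lc_points = 1201, shift_sd = 3,
                          noise_sd = 0, height_sd = 0, latent_sd = 0,
                          baseline_amp = 0, seed = 5)
  g <- generate_block(cfg, "lc")
  mean_cor <- function(M) mean(stats::cor(t(M))[lower.tri(diag(nrow(M)))])
  before <- mean_cor(g$block$values)
  after <- mean_cor(pretreat_lc(g$block)$values)
  expect_gte(after, before)
})
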
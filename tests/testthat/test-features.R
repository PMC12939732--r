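test_that("patch extraction tiles, thresholds on coverage, and errors when empty", {
  img <- matrix(runif(64 * 64), 64, 64)
  full <- matrix(1L, 64, 64)
  g <- extract_patches(img, full, 16L, 0.5)
  expect_length(g$patches, 16)

  g0 <- extract_patches(img, matrix(0L, 64, 64), 16L, 0)
  expect_length(g0$patches, 16)   # zero threshold retains every tile

  # first tile fully covered, second tile half covered
  half <- matrix(0L, 64, 64); half[1:16, 1:24] <- 1L
  g1 <- extract_patches(img, half, 16L, 1)
  expect_length(g1$patches, 1)                       # half tile dropped
  expect_length(extract_patches(img, half, 16L, 0.5)$patches, 2)
  none <- matrix(0L, 64, 64); none[1, 1] <- 1L
  expect_error(extract_patches(img, none, 16L, 0.9), "min_coverage")
})

test_that("statistical moments match closed forms and sampling theory", {
  expect_equal(stat_features(matrix(3.2, 4, 4)),
               c(mean = 3.2, sd = 0, skew = 0, kurt = 0))
  expect_equal(stat_features(c(0, 0, 1, 1)),
               c(mean = 0.5, sd = 0.5, skew = 0, kurt = -2))
  set.seed(8)
  v <- rnorm(1000)
  f <- stat_features(v)
  expect_lt(abs(f[["skew"]]), 3 * sqrt(6 / 1000))
  expect_lt(abs(f[["kurt"]]), 3 * sqrt(24 / 1000))
})

test_that("GLCM features match a hand-enumerated co-occurrence table", {
  expect_equal(texture_features(matrix(1, 4, 4))$glcm,
               c(energy = 1, contrast = 0, entropy = 0, homogeneity = 1))
  # 4x4 two-level checkerboard, horizontal offset: all 12 pairs are (1,2)
  # or (2,1); the symmetric normalized GLCM has 0.5 in both off-diagonal
  # cells, giving energy 0.5, contrast 1, entropy 1 bit, homogeneity 0.5
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  tf <- texture_features(cb, n_levels = 2L, offsets = list(c(0L, 1L)))
  expect_equal(tf$glcm,
               c(energy = 0.5, contrast = 1, entropy = 1, homogeneity = 0.5))
})

test_that("LBP histograms are normalized distributions over 10 uniform bins", {
  set.seed(9)
  for (i in 1:5) {
    p <- matrix(runif(64), 8, 8)
    h <- texture_features(p)$lbp
    expect_length(h, 10)
    expect_lt(abs(sum(h) - 1), 1e-9)
    expect_true(all(h >= 0))
  }
  # constant patch: every neighbour ties (>= centre), code 11111111 ->
  # uniform with 8 ones
  hc <- texture_features(matrix(1, 5, 5))$lbp
  expect_equal(hc[9], 1)
})

test_that("deep features pool encoder tokens per patch with a global fallback", {
  z <- matrix(1:8, 4, 2)   # 2x2 token grid, 2 channels
  attr(z, "grid") <- c(2L, 2L)
  centers <- rbind(c(16, 16), c(16, 48), c(48, 16), c(48, 48))
  out <- deep_features(z, centers, 32L, c(64L, 64L))
  # token t (row-major) covers quadrant t; hand-computed averages are the
  # token values themselves
  expect_equal(out, matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2))

  zc <- matrix(2.5, 4, 2); attr(zc, "grid") <- c(2L, 2L)
  expect_equal(deep_features(zc, centers, 32L, c(64L, 64L)),
               matrix(2.5, 4, 2))

  # pooling over one patch covering everything equals the global average
  out2 <- deep_features(z, matrix(c(32, 32), 1), 64L, c(64L, 64L))
  expect_equal(as.vector(out2), colMeans(z[, , drop = FALSE]))
})

test_that("feature assembly concatenates blocks, standardizes, and aligns rows", {
  pp <- quick_preprocessed()
  fused <- apply(pp$channels, c(2, 3), mean)
  g <- extract_patches(fused, pp$brain_mask, 16L, 0.5)
  z <- matrix(rnorm(64 * 6), 64, 6); attr(z, "grid") <- c(8L, 8L)
  x <- assemble_feature_matrix(g, z_l = z, image_size = c(64, 64))
  expect_equal(ncol(x), 4 + 4 + 10 + 6)
  expect_true(all(is.finite(x)))
  sds <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2) * length(v) /
                                        (length(v) - 1)))
  nontrivial <- attr(x, "scale") != 1 | apply(x, 2, sd) > 0
  expect_lt(max(abs(colMeans(x)[nontrivial])), 1e-6)
  expect_lt(max(abs(sds[nontrivial] - 1)), 1e-6)

  # stored statistics reproduce the transform on the same raw input
  raw <- assemble_feature_matrix(g, z_l = z, image_size = c(64, 64),
                                 standardize = FALSE)
  again <- assemble_feature_matrix(g, z_l = z, image_size = c(64, 64),
                                   center = attr(x, "center"),
                                   scale = attr(x, "scale"))
  expect_equal(unclass(again)[, ], unclass(x)[, ], ignore_attr = TRUE)
  expect_equal(colnames(x)[1:5],
               c("stat_mean", "stat_sd", "stat_skew", "stat_kurt",
                 "glcm_energy"))
})
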
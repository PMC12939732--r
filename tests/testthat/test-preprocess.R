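ns <- asNamespace("scagnet")

test_that("bias correction: identity field, positivity, degenerate input", {
  set.seed(1)
  img <- matrix(runif(400, 0.2, 1), 20, 20)
  mask <- matrix(1L, 20, 20)
  out <- correct_bias(img, mask, 2)
  # an unbiased image is (near) unchanged: the fitted log-surface is flat
  expect_lt(max(abs(out$field - 1)), 0.25)
  expect_true(all(out$field > 0))
  expect_true(all(out$corrected[img > 0] > 0))
  expect_error(correct_bias(matrix(0, 5, 5), matrix(1, 5, 5)), "log")
})

test_that("bias correction recovers a planted polynomial field", {
  # tumour-free slice: brain tissue is homogeneous, so the log-domain fit
  # sees field + noise only
  spec <- phantom_spec(noise_sigma = 0.02)
  sl <- generate_slice(spec, "non-tumor", seed = 7)
  msk <- sl$brain_mask > 0
  est <- correct_bias(sl$channels[1, , ], sl$brain_mask, 2)
  truth <- sl$bias_fields[1, , ]
  truth <- truth / mean(truth[msk])    # align the mean-1 gauge over the mask
  rmse <- sqrt(mean((est$field[msk] - truth[msk])^2))
  amplitude <- diff(range(truth[msk]))
  expect_lte(rmse, 0.05 * amplitude)
})

test_that("constant-unit-bias input is returned unchanged", {
  img <- matrix(rep(c(0.4, 0.8), each = 50), 10, 10)
  mask <- matrix(1L, 10, 10)
  # order-0 fit: field is exactly the gauge-fixed constant 1
  out <- correct_bias(img, mask, 0)
  expect_lt(max(abs(out$corrected - img) / img), 1e-6)
})

test_that("non-local means matches a double-loop oracle and contracts noise", {
  mirror_ref <- function(x, p) {
    h <- nrow(x); w <- ncol(x)
    x[c(rev(seq_len(p)), seq_len(h), h + 1 - seq_len(p)),
      c(rev(seq_len(p)), seq_len(w), w + 1 - seq_len(p))]
  }
  nlm_oracle <- function(img, patch, search, h) {
    pr <- (patch - 1) / 2; sr <- (search - 1) / 2
    H <- nrow(img); W <- ncol(img)
    P <- mirror_ref(img, pr)
    out <- img * 0
    for (i in 1:H) for (j in 1:W) {
      num <- 0; den <- 0
      for (di in -sr:sr) for (dj in -sr:sr) {
        i2 <- i + di; j2 <- j + dj
        if (i2 < 1 || i2 > H || j2 < 1 || j2 > W) next
        d2 <- 0
        for (ti in -pr:pr) for (tj in -pr:pr) {
          d2 <- d2 + (P[i + ti + pr, j + tj + pr] -
                        P[i2 + ti + pr, j2 + tj + pr])^2
        }
        wgt <- exp(-(d2 / patch^2) / h^2)
        num <- num + wgt * img[i2, j2]; den <- den + wgt
      }
      out[i, j] <- num / den
    }
    out
  }
  set.seed(3)
  im <- matrix(runif(64), 8, 8)
  expect_lt(max(abs(denoise_nlm(im, 3, 5, 0.3) - nlm_oracle(im, 3, 5, 0.3))),
            1e-10)

  const <- matrix(0.7, 12, 12)
  expect_equal(denoise_nlm(const, 3, 7, 0.1), const)

  vr <- vapply(1:10, function(s) {
    set.seed(s)
    noisy <- matrix(0.5 + rnorm(20 * 20, 0, 0.1), 20, 20)
    c(var(as.vector(noisy)), var(as.vector(denoise_nlm(noisy, 3, 7, 0.2))))
  }, numeric(2))
  expect_true(all(vr[2, ] < vr[1, ]))
  expect_error(denoise_nlm(im, 3, 5, 0), "positive")
})

test_that("rigid registration recovers planted transforms via mutual information", {
  spec <- phantom_spec(noise_sigma = 0.02)
  img <- generate_slice(spec, 2, seed = 4)$channels[1, , ]
  reg0 <- register_rigid(img, img)
  expect_lt(abs(reg0$theta), 0.5)
  expect_lt(abs(reg0$tx), 0.5)
  expect_lt(abs(reg0$ty), 0.5)
  expect_gte(reg0$mi, reg0$mi_identity)

  rot <- ns$.warp_rigid(img, 5, 0, 0)
  reg <- register_rigid(rot, img)
  expect_lt(abs(reg$theta - (-5)), 1)
  expect_gte(reg$mi, reg$mi_identity)
})

test_that("resampling follows the size rule and bilinear interpolation", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(resample(img, c(1, 1), c(1, 1)), img)
  expect_equal(dim(resample(img, c(1, 1), c(2, 2))), c(32L, 32L))
  # 3x3 ramp, 1mm -> 1.5mm: out size 2x2; closed-form bilinear oracle
  ramp <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), 3, 3)
  out <- resample(ramp, c(1, 1), c(1.5, 1.5))
  bilinear_ref <- function(m, r, c) {
    r0 <- floor(r); c0 <- floor(c); fr <- r - r0; fc <- c - c0
    (1 - fr) * (1 - fc) * m[r0, c0] + fr * (1 - fc) * m[r0 + 1, c0] +
      (1 - fr) * fc * m[r0, c0 + 1] + fr * fc * m[r0 + 1, c0 + 1]
  }
  # output pixel centres map to input coordinates 1.25 and 2.75
  expect_equal(out[1, 1], bilinear_ref(ramp, 1.25, 1.25))
  expect_equal(out[2, 1], bilinear_ref(ramp, 2.75, 1.25))
  expect_equal(out[1, 2], bilinear_ref(ramp, 1.25, 2.75))
})

test_that("z-score normalisation uses the population SD and zeroes background", {
  mask <- matrix(0L, 2, 2); mask[1, 1] <- 1L; mask[2, 1] <- 1L
  img <- matrix(0, 2, 2); img[1, 1] <- 1; img[2, 1] <- 3
  out <- normalize_zscore(img, mask)
  expect_equal(sort(out[mask == 1]), c(-1, 1))
  expect_equal(out[mask == 0], c(0, 0))

  set.seed(2)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(rbinom(100, 1, 0.7), 10, 10)
  z <- normalize_zscore(img, mask)
  v <- z[mask == 1]
  expect_lt(abs(mean(v)), 1e-6)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-6)
  # affine invariance
  z2 <- normalize_zscore(3.7 * img + 11, mask)
  expect_equal(z, z2)
  expect_error(normalize_zscore(matrix(1, 4, 4), matrix(1, 4, 4)),
               "degenerate")
})

test_that("clip/rescale maps masked values onto [0,1] and saturates the tails", {
  set.seed(5)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(1L, 10, 10)
  out <- clip_rescale(img, mask, 1, 99)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  # monotone
  o <- order(img)
  expect_true(all(diff(out[o]) >= 0))
  # exactly the samples beyond the empirical 1%/99% quantiles saturate
  qs <- quantile(img, c(0.01, 0.99), type = 7)
  expect_equal(sum(out == 0), sum(img <= qs[1]))
  expect_equal(sum(out == 1), sum(img >= qs[2]))
  expect_error(clip_rescale(matrix(1, 4, 4), matrix(1, 4, 4)), "equal")
})

test_that("bounding-box crop centres the mask and preserves foreground", {
  img <- matrix(runif(64 * 64), 64, 64)
  full <- matrix(1L, 64, 64)
  out <- crop_to_bbox(img, full, c(64, 64))
  expect_equal(out$channels[1, , ], img)

  single <- matrix(0L, 64, 64); single[10, 10] <- 1L
  out <- crop_to_bbox(img, single, c(32, 32))
  expect_equal(dim(out$brain_mask), c(32L, 32L))
  expect_equal(which(out$brain_mask == 1, arr.ind = TRUE)[1, ],
               c(row = 16L, col = 16L))

  set.seed(1)
  blob <- matrix(0L, 64, 64); blob[20:40, 15:30] <- rbinom(21 * 16, 1, 0.5)
  out <- crop_to_bbox(img, blob, c(40, 40))
  expect_equal(sum(out$brain_mask), sum(blob))
  expect_error(crop_to_bbox(img, full, c(32, 32)), "exceeds")
})

test_that("augmentation is identity at zero magnitude and keeps masks binary", {
  sl <- generate_slice(tiny_phantom_spec(), 1, seed = 2)
  zero_cfg <- list(rotation_deg_range = 0, flip_axes = character(0),
                   jitter_sigma = 0, elastic_alpha = 0, elastic_sigma = 4)
  out <- augment_slice(sl$channels, list(brain = sl$brain_mask), zero_cfg, 1)
  expect_equal(out$channels, sl$channels)
  expect_equal(out$masks$brain, sl$brain_mask)

  flip_cfg <- modifyList(zero_cfg, list(flip_axes = "horizontal"))
  once <- augment_slice(sl$channels, list(brain = sl$brain_mask), flip_cfg, 3)
  twice <- augment_slice(once$channels, once$masks, flip_cfg, 3)
  expect_equal(twice$channels, sl$channels)

  el_cfg <- modifyList(zero_cfg, list(rotation_deg_range = 15,
                                      elastic_alpha = 3))
  out <- augment_slice(sl$channels, list(tumor = sl$tumor_mask), el_cfg, 4)
  expect_true(all(out$masks$tumor %in% c(0, 1)))
  # seeded determinism
  out2 <- augment_slice(sl$channels, list(tumor = sl$tumor_mask), el_cfg, 4)
  expect_identical(out, out2)
})

test_that("the full chain ends in finite [0,1] channels with provenance", {
  pp <- quick_preprocessed()
  expect_true(all(is.finite(pp$channels)))
  expect_gte(min(pp$channels), 0)
  expect_lte(max(pp$channels), 1)
  steps <- vapply(pp$provenance, `[[`, "", "step")
  expect_equal(steps, c("correct_bias", "denoise_nlm", "normalize_zscore",
                        "clip_rescale"))
})
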
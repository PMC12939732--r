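ns <- asNamespace("scagnet")

test_that("patch embedding tiles the image and is linear in the input", {
  set.seed(1)
  P <- 4L; D <- 8L; C <- 2L
  W <- matrix(rnorm(P * P * C * D) * 0.1, P * P * C, D)
  b <- matrix(0, 1, D)
  img <- array(rnorm(C * 64 * 64), dim = c(C, 64, 64))
  tok <- patch_embed(img, P, W, b)
  expect_equal(dim(tok), c(256L, D))
  expect_equal(attr(tok, "grid"), c(16L, 16L))

  zero <- patch_embed(array(0, dim = c(C, 64, 64)), P, W, b)
  expect_equal(max(abs(zero)), 0)

  # swapping two patches swaps the corresponding tokens
  img2 <- img
  img2[, 1:4, 1:4] <- img[, 1:4, 5:8]
  img2[, 1:4, 5:8] <- img[, 1:4, 1:4]
  tok2 <- patch_embed(img2, P, W, b)
  expect_equal(tok2[1, ], tok[2, ], ignore_attr = TRUE)
  expect_equal(tok2[2, ], tok[1, ], ignore_attr = TRUE)
  expect_equal(tok2[-(1:2), ], tok[-(1:2), ], ignore_attr = TRUE)
})

test_that("window attention equals dense attention on a single window", {
  for (case in list(list(d = 6, heads = 2, win = 2),
                    list(d = 4, heads = 1, win = 2))) {
    params <- random_attention_params(case$d, case$heads, case$win,
                                      seed = case$d)
    set.seed(case$d + 50)
    tokens <- matrix(rnorm(case$win^2 * case$d), case$win^2, case$d)
    got <- window_attention(tokens, c(case$win, case$win), params,
                            case$win, shift = 0, n_heads = case$heads,
                            layernorm = FALSE)
    want <- dense_attention_oracle(tokens, params, case$heads, case$win)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("a single-token window with identity projections doubles the input", {
  p1 <- list(Wq = diag(1), bq = matrix(0, 1, 1), Wk = diag(1),
             bk = matrix(0, 1, 1), Wv = diag(1), bv = matrix(0, 1, 1),
             Wo = diag(1), bo = matrix(0, 1, 1),
             relbias = matrix(0, 1, 1))
  out <- window_attention(matrix(1.5, 1, 1), c(1, 1), p1, 1, 0, 1,
                          layernorm = FALSE)
  expect_equal(as.numeric(out), 3)
  expect_error(window_attention(matrix(0, 4, 2), c(2, 2),
                                random_attention_params(2, 1, 4), 4),
               "window larger")
})

test_that("encoder pyramid follows the /P, /2P size progression deterministically", {
  cfg <- tiny_swin_config()
  set.seed(3)
  img <- array(runif(4 * 64 * 64), dim = c(4, 64, 64))
  params <- ns$.swin_init(cfg, 4L, c(64L, 64L))
  pyr <- swin_encode(img, params, cfg)
  expect_equal(attr(pyr[[1]], "grid"), c(16L, 16L))
  expect_equal(attr(pyr[[2]], "grid"), c(8L, 8L))
  expect_equal(ncol(pyr[[1]]), 16L)
  expect_equal(ncol(pyr[[2]]), 32L)
  pyr2 <- swin_encode(img, params, cfg)
  expect_identical(pyr, pyr2)

  cfg2 <- tiny_swin_config(embed_dim = 32L)
  params2 <- ns$.swin_init(cfg2, 4L, c(64L, 64L))
  pyr3 <- swin_encode(img, params2, cfg2)
  expect_equal(ncol(pyr3[[1]]), 32L)
  expect_equal(ncol(pyr3[[2]]), 64L)
})

test_that("decoder output is a sigmoid probability map of the input size", {
  cfg <- tiny_swin_config()
  set.seed(4)
  img <- array(runif(4 * 64 * 64), dim = c(4, 64, 64))
  params <- ns$.swin_init(cfg, 4L, c(64L, 64L))
  pr <- ns$.predict_soft(img, params, cfg)
  expect_equal(dim(pr$soft), c(64L, 64L))
  expect_true(all(pr$soft >= 0 & pr$soft <= 1))
  # zero output head -> sigmoid(0) = 0.5 everywhere
  params$head_W[] <- 0; params$head_b[] <- 0
  pr0 <- ns$.predict_soft(img, params, cfg)
  expect_equal(unique(as.vector(pr0$soft)), 0.5)
})

test_that("mask thresholding uses the >= rule and is monotone in tau", {
  soft <- matrix(c(0.2, 0.5, 0.8, 0.4), 2, 2)
  expect_equal(binarize_mask(matrix(1, 2, 2), 0.5), matrix(1L, 2, 2))
  expect_equal(binarize_mask(soft, 0.5)[1, 2], 1L)   # boundary 0.5 -> 1
  counts <- vapply(seq(0, 1, by = 0.1),
                   function(tau) sum(binarize_mask(soft, tau)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("morphological refinement matches direct erosion/closing behaviour", {
  expect_equal(refine_mask(matrix(0L, 5, 5)), matrix(0L, 5, 5))

  lone <- matrix(0L, 5, 5); lone[3, 3] <- 1L
  expect_equal(sum(refine_mask(lone)), 0)

  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  ref <- refine_mask(sq)
  # erosion of a 10x10 block by 3x3 gives 8x8; closing cannot shrink it
  expect_gte(sum(ref), 64)
  expect_true(all(ref[4:11, 4:11] == 1L))
  # no holes: foreground is a solid rectangle
  rows <- range(which(rowSums(ref) > 0)); cols <- range(which(colSums(ref) > 0))
  expect_true(all(ref[rows[1]:rows[2], cols[1]:cols[2]] == 1L))
})

test_that("segmentation loss matches its closed forms and an independent oracle", {
  y <- matrix(rep(c(0, 1), each = 8), 4, 4)
  # perfect prediction: loss vanishes as the guards go to zero
  expect_lt(seg_loss(y, y, 0.5, 0.5), 1e-5)
  # flat 0.5 prediction on a half-foreground image: soft Dice = 0.5
  expect_equal(seg_loss(matrix(0.5, 4, 4), y, lambda1 = 1, lambda2 = 0),
               0.5, tolerance = 1e-5)
  set.seed(6)
  p <- matrix(runif(16, 0.05, 0.95), 4, 4)
  yy <- matrix(rbinom(16, 1, 0.5), 4, 4)
  ref <- function(p, y, l1, l2, epsd = 1e-6, eps = 1e-7) {
    pc <- pmin(pmax(p, eps), 1 - eps)
    d <- (2 * sum(pc * y) + epsd) / (sum(pc) + sum(y) + epsd)
    l1 * (1 - d) + l2 * mean(-(y * log(pc) + (1 - y) * log(1 - pc)))
  }
  expect_lt(abs(seg_loss(p, yy, 0.7, 0.3) - ref(p, yy, 0.7, 0.3)), 1e-8)
  expect_error(seg_loss(p, matrix(0, 2, 2)), "mismatch")
})

test_that("segmenter training is seeded-deterministic with finite losses", {
  pp <- quick_preprocessed()
  cfg <- tiny_swin_config()
  m1 <- train_segmenter(list(pp), cfg, seed = 5, max_steps = 8, lr = 1e-3)
  m2 <- train_segmenter(list(pp), cfg, seed = 5, max_steps = 8, lr = 1e-3)
  expect_identical(m1$history, m2$history)
  expect_true(all(is.finite(m1$history$loss)))
})
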
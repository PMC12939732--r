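test_that("graph construction matches the Gaussian-kernel formula exactly", {
  f <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  ctr <- matrix(c(0, 0, 1, 0, 5, 0), 3, 2, byrow = TRUE)
  g <- build_graph(f, ctr, kernel_sigma = 1.3, radius = 3)
  a_ref <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    if (i != j && sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < 3) {
      a_ref[i, j] <- exp(-sum((f[i, ] - f[j, ])^2) / 1.3^2)
    }
  }
  expect_lt(max(abs(g$adjacency - a_ref)), 1e-12)
  expect_equal(unname(diag(g$adjacency)), rep(0, 3))
  # identical features at adjacent centres give weight exp(0) = 1
  g1 <- build_graph(matrix(1, 2, 3), rbind(c(0, 0), c(1, 0)), 1, 3)
  expect_equal(g1$adjacency[1, 2], 1)
  # beyond the radius the weight is exactly 0
  expect_equal(g$adjacency[1, 3], 0)
  expect_error(build_graph(f, ctr, kernel_sigma = -1), "positive")
})

test_that("symmetric normalization is stable with unit spectral bound", {
  expect_equal(normalize_adjacency(matrix(0, 4, 4)), diag(4))
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 0
    ahat <- normalize_adjacency(a)
    expect_lt(max(abs(ahat - t(ahat))), 1e-12)
    expect_lte(max(abs(eigen(ahat, only.values = TRUE)$values)), 1 + 1e-9)
  }
  # row normalization option: rows sum to 1
  a <- matrix(runif(9), 3, 3); a <- (a + t(a)) / 2; diag(a) <- 0
  expect_equal(rowSums(normalize_adjacency(a, row_normalize = TRUE)),
               rep(1, 3))
})

test_that("one attention layer matches a scalar unrolled reference", {
  set.seed(12)
  hin <- matrix(rnorm(6) * 0.5, 3, 2)
  prm <- list(list(W = matrix(rnorm(4) * 0.5, 2, 2),
                   a1 = matrix(rnorm(2) * 0.5, 2, 1),
                   a2 = matrix(rnorm(2) * 0.5, 2, 1)))
  # 3-node path graph in space (unit spacing, radius 1.5)
  gp <- build_graph(hin, matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE),
                    kernel_sigma = 5, radius = 1.5)
  out <- gat_layer(hin, gp, prm, n_heads = 1)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  wh <- hin %*% prm[[1]]$W
  nbrs <- list(c(1, 2), c(1, 2, 3), c(2, 3))
  ref <- matrix(0, 3, 2)
  for (i in 1:3) {
    e <- vapply(nbrs[[i]], function(j) {
      lrelu(sum(wh[i, ] * prm[[1]]$a1) + sum(wh[j, ] * prm[[1]]$a2))
    }, numeric(1))
    al <- exp(e - max(e)); al <- al / sum(al)
    ref[i, ] <- elu(colSums(al * wh[nbrs[[i]], , drop = FALSE]))
  }
  expect_lt(max(abs(out - ref)), 1e-6)
  att <- attr(out, "attention")[[1]]
  expect_lt(max(abs(tapply(att$alpha, att$i, sum) - 1)), 1e-6)
})

test_that("an isolated node attends only to itself", {
  prm <- list(list(W = diag(2), a1 = matrix(0, 2, 1), a2 = matrix(0, 2, 1)))
  h <- matrix(c(1.2, -0.4), 1, 2)
  g <- build_graph(h, matrix(0, 1, 2), kernel_sigma = 1, radius = 1)
  out <- gat_layer(h, g, prm, n_heads = 1)
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  expect_equal(as.vector(out), elu(as.vector(h)), ignore_attr = TRUE)
})

test_that("attention pooling and classification match their closed forms", {
  set.seed(13)
  h <- matrix(rnorm(8), 4, 2)
  q <- matrix(rnorm(2), 2, 1); wg <- matrix(rnorm(4), 2, 2)
  ap <- attention_pool(h, q, wg)
  sc <- as.numeric(tanh(h %*% wg) %*% q)
  beta_ref <- exp(sc - max(sc)); beta_ref <- beta_ref / sum(beta_ref)
  expect_lt(max(abs(ap$beta - beta_ref)), 1e-8)
  expect_lt(max(abs(ap$z - matrix(beta_ref, 1) %*% h)), 1e-8)
  expect_lt(abs(sum(ap$beta) - 1), 1e-6)
  # identical embeddings pool uniformly
  apu <- attention_pool(matrix(1, 5, 2), q, wg)
  expect_equal(apu$beta, rep(0.2, 5))

  cl <- classify_embedding(ap$z, matrix(0, 2, 3), matrix(0, 1, 3))
  expect_equal(cl$probabilities, rep(1 / 3, 3))
  wc <- matrix(rnorm(6), 2, 3); bc <- matrix(rnorm(3), 1)
  c1 <- classify_embedding(ap$z, wc, bc)
  c2 <- classify_embedding(ap$z, wc, bc + 7)   # logit shift invariance
  expect_lt(abs(sum(c1$probabilities) - 1), 1e-7)
  expect_lt(max(abs(c1$probabilities - c2$probabilities)), 1e-9)
})

test_that("classification loss equals cross-entropy plus the L2 penalty", {
  expect_lt(class_loss(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-8)
  expect_equal(class_loss(rep(1 / 3, 3), c(0, 1, 0)), log(3))
  set.seed(14)
  p <- runif(4); p <- p / sum(p)
  y <- c(0, 0, 1, 0)
  params <- list(a = matrix(rnorm(4), 2), b = matrix(rnorm(2), 1))
  want <- -log(p[3]) + 0.01 * (sum(params$a^2) + sum(params$b^2))
  expect_lt(abs(class_loss(p, y, 0.01, params) - want), 1e-10)
  expect_error(class_loss(p, c(0, 1, 1, 0)), "one-hot")
})

test_that("graph prediction is invariant to node permutation", {
  set.seed(15)
  f <- matrix(rnorm(12), 6, 2)
  ctr <- cbind(seq_len(6), rep(1, 6))
  g <- build_graph(f, ctr, kernel_sigma = "auto", radius = 2.5)
  cfg <- gat_config(n_layers = 2, n_heads = 2, hidden_dim = 8, dropout = 0,
                    lr = 1e-2, epochs = 3, seed = 1)
  labs <- c(1, 2)
  m <- train_classifier(list(g, g), labs, cfg, n_classes = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  gp <- build_graph(f[perm, ], ctr[perm, ], kernel_sigma = g$kernel_sigma,
                    radius = 2.5)
  p1 <- predict_graphs(m, list(g))
  p2 <- predict_graphs(m, list(gp))
  expect_lt(max(abs(p1$probabilities - p2$probabilities)), 1e-6)
  expect_lt(max(abs(p1$pooling_weights[[1]][perm] -
                      p2$pooling_weights[[1]])), 1e-6)
})

test_that("classifier training is deterministic and fits separable graphs", {
  set.seed(16)
  mk <- function(cls, seed) {
    set.seed(seed)
    f <- sweep(matrix(rnorm(6 * 4) * 0.3, 6, 4), 2,
               3 * (seq_len(4) == cls), "+")
    build_graph(f, cbind(seq_len(6), rep(1, 6)), kernel_sigma = "auto",
                radius = 2.5)
  }
  labs <- rep(1:3, each = 8)
  graphs <- lapply(seq_along(labs), function(i) mk(labs[i], 300 + i))
  cfg <- gat_config(n_layers = 2, n_heads = 2, hidden_dim = 16,
                    dropout = 0, lr = 1e-2, epochs = 20, batch_size = 8,
                    seed = 2)
  m1 <- train_classifier(graphs, labs, cfg, n_classes = 3)
  m2 <- train_classifier(graphs, labs, cfg, n_classes = 3)
  expect_identical(m1$history, m2$history)
  expect_true(all(is.finite(m1$history$loss)))
  pr <- predict_graphs(m1, graphs)
  expect_gte(mean(pr$label == labs), 0.95)
  expect_lt(max(abs(rowSums(pr$probabilities) - 1)), 1e-7)
})
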
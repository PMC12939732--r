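#' Configuration for the graph-attention classifier
#'
#' @param n_layers Number of attention layers (default 4).
#' @param n_heads Heads per layer (default 8). Head outputs are
#'   concatenated in layers 1..L-1 and averaged at the last layer, so the
#'   final node dimension equals \code{hidden_dim}.
#' @param hidden_dim Per-layer node dimension (must be divisible by
#'   \code{n_heads}; default 128).
#' @param kernel_sigma Gaussian kernel scale of the adjacency (default
#'   0.5). On standardized features with many columns this kernel is very
#'   sharp; \code{\link{build_graph}} warns when it underflows and
#'   \code{"auto"} scales it to the median pairwise feature distance.
#' @param radius Neighbourhood cutoff in patch-grid units (default 8).
#' @param dropout Dropout on attention coefficients and features during
#'   training (default 0.3).
#' @param lr,weight_decay,batch_size,epochs Training scalars (defaults
#'   1e-4, 1e-5, 8, 200).
#' @param leaky_slope Negative slope of the LeakyReLU scoring (default
#'   0.2).
#' @param patience Early-stop patience (validation evaluations without
#'   improvement) used by \code{\link{train_classifier}}.
#' @param row_normalize Store a row-normalized adjacency instead of the
#'   symmetric normalization (both are standard; symmetric is the
#'   default).
#' @param seed Integer seed.
#' @return An object of class \code{gat_config}.
#' @export
gat_config <- function(n_layers = 4L, n_heads = 8L, hidden_dim = 128L,
                       kernel_sigma = 0.5, radius = 8, dropout = 0.3,
                       lr = 1e-4, weight_decay = 1e-5, batch_size = 8L,
                       epochs = 200L, leaky_slope = 0.2,
                       patience = 4L,
                       row_normalize = FALSE, seed = 1L) {
  stopifnot(n_layers >= 1, n_heads >= 1, hidden_dim %% n_heads == 0,
            radius > 0, dropout >= 0, dropout < 1)
  if (!identical(kernel_sigma, "auto")) stopifnot(kernel_sigma > 0)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 kernel_sigma = kernel_sigma, radius = radius,
                 dropout = dropout, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), leaky_slope = leaky_slope,
                 patience = as.integer(patience),
                 row_normalize = isTRUE(row_normalize),
                 seed = as.integer(seed)),
            class = "gat_config")
}

#' Build a patch graph from node features and patch centres
#'
#' Edge weights are \code{A_ij = exp(-||f_i - f_j||^2 / sigma^2)} when the
#' Euclidean distance between patch centres is below \code{radius} (in
#' patch-grid units), and 0 otherwise; the diagonal is 0, self-loops enter
#' only through the +I of the normalization.
#'
#' @param node_features n x d numeric matrix.
#' @param centers n x 2 patch centres in patch-grid units (pixel centres
#'   divided by the patch size).
#' @param kernel_sigma Gaussian kernel scale, or \code{"auto"} for the
#'   median nonzero pairwise feature distance.
#' @param radius Spatial cutoff in the same units as \code{centers}.
#' @return A \code{patch_graph}: list with \code{node_features},
#'   \code{centers}, \code{adjacency}, \code{normalized} (symmetric
#'   normalization, see \code{\link{normalize_adjacency}}),
#'   \code{edge_list} (m x 2, directed pairs including self-loops, used by
#'   the attention layers) and \code{kernel_sigma}.
#' @export
build_graph <- function(node_features, centers, kernel_sigma = 0.5,
                        radius = 8) {
  n <- nrow(node_features)
  stopifnot(n >= 1, nrow(centers) == n)
  fd2 <- as.matrix(stats::dist(node_features))^2
  sd2 <- as.matrix(stats::dist(centers))
  if (identical(kernel_sigma, "auto")) {
    med <- stats::median(sqrt(fd2[upper.tri(fd2)]))
    kernel_sigma <- if (is.finite(med) && med > 0) med else 1
  }
  if (kernel_sigma <= 0) stop("kernel_sigma must be positive")
  a <- exp(-fd2 / kernel_sigma^2)
  a[sd2 >= radius] <- 0
  diag(a) <- 0
  if (n > 1 && max(a) < 1e-12) {
    warning("all adjacency weights underflow; kernel_sigma is too sharp ",
            "for these feature distances (consider kernel_sigma = \"auto\")")
  }
  nb <- which(a > 0, arr.ind = TRUE)
  # attention neighbourhoods N(i) = {j : A_ij > 0} union {i}
  edges <- rbind(cbind(seq_len(n), seq_len(n)),
                 if (nrow(nb)) cbind(nb[, 1], nb[, 2]) else NULL)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(list(node_features = node_features, centers = centers,
                 adjacency = a, normalized = normalize_adjacency(a),
                 edge_list = edges, kernel_sigma = kernel_sigma),
            class = "patch_graph")
}

#' Symmetric adjacency normalization
#'
#' \code{Ahat = D^{-1/2} (A + I) D^{-1/2}} with
#' \code{D_ii = sum_j (A_ij + I_ij)}; always well defined because of the
#' +I. The spectral radius of the result is at most 1.
#'
#' @param a Symmetric nonnegative matrix.
#' @param row_normalize Return \code{D^{-1}(A + I)} instead.
#' @return Normalized matrix.
#' @export
normalize_adjacency <- function(a, row_normalize = FALSE) {
  stopifnot(nrow(a) == ncol(a), all(a >= 0))
  ai <- a + diag(nrow(a))
  d <- rowSums(ai)
  if (row_normalize) {
    ai / d
  } else {
    dm <- 1 / sqrt(d)
    ai * outer(dm, dm)
  }
}

## ---- parameterisation ----

.gat_init <- function(config, in_dim, n_classes) {
  params <- list()
  hd <- config$hidden_dim %/% config$n_heads
  d_in <- in_dim
  for (l in seq_len(config$n_layers)) {
    for (t in seq_len(config$n_heads)) {
      pre <- sprintf("l%dh%d_", l, t)
      params[[paste0(pre, "W")]] <- .xavier(d_in, hd)
      params[[paste0(pre, "a1")]] <- .xavier(hd, 1L)
      params[[paste0(pre, "a2")]] <- .xavier(hd, 1L)
    }
    d_in <- if (l < config$n_layers) hd * config$n_heads else hd
  }
  # at the last layer heads are averaged, so the embedding dim is hd
  params$pool_Wg <- .xavier(hd, hd)
  params$pool_q <- .xavier(hd, 1L)
  params$cls_W <- .xavier(hd, n_classes)
  params$cls_b <- matrix(0, 1, n_classes)
  params
}

## ---- forward (autodiff) ----

# One multi-head attention layer over the edge list. h: n x d node. Heads
# concatenated unless `average`, in which case they are averaged (used at
# the last layer to keep the embedding dimension at hidden_dim/n_heads).
.gat_layer_node <- function(tape, h, edges, pn, l, n_heads, slope,
                            dropout, training, average = FALSE) {
  n <- nrow(h$value)
  ei <- edges[, 1]; ej <- edges[, 2]
  heads <- vector("list", n_heads)
  for (t in seq_len(n_heads)) {
    pre <- sprintf("l%dh%d_", l, t)
    wh <- ad_matmul(tape, h, pn[[paste0(pre, "W")]])
    s1 <- ad_matmul(tape, wh, pn[[paste0(pre, "a1")]])
    s2 <- ad_matmul(tape, wh, pn[[paste0(pre, "a2")]])
    e <- ad_leaky_relu(tape,
                       ad_add(tape, ad_gather_rows(tape, s1, ei),
                              ad_gather_rows(tape, s2, ej)), slope)
    # segment softmax over each node's neighbourhood
    emax <- tapply(e$value[, 1], ei, max)[as.character(ei)]
    ex <- ad_exp(tape, ad_add_const(tape, e, -as.numeric(emax)))
    den <- ad_gather_rows(tape, ad_rowsum_groups(tape, ex, ei, n), ei)
    alpha <- ad_div(tape, ex, den)
    alpha <- ad_dropout(tape, alpha, dropout, training)
    msg <- ad_rowscale(tape, ad_gather_rows(tape, wh, ej), alpha)
    heads[[t]] <- ad_rowsum_groups(tape, msg, ei, n)
  }
  agg <- if (n_heads == 1L) {
    heads[[1]]
  } else if (average) {
    out <- heads[[1]]
    for (t in 2:n_heads) out <- ad_add(tape, out, heads[[t]])
    ad_scale(tape, out, 1 / n_heads)
  } else {
    ad_cbind(tape, heads)
  }
  out <- ad_elu(tape, agg)
  ad_dropout(tape, out, dropout, training)
}

.gat_forward <- function(tape, graph, params, config, n_classes,
                         training = FALSE) {
  pn <- lapply(names(params), function(nm) ad_param(tape, params[[nm]], nm))
  names(pn) <- names(params)
  h <- ad_input(tape, graph$node_features)
  for (l in seq_len(config$n_layers)) {
    h <- .gat_layer_node(tape, h, graph$edge_list, pn, l, config$n_heads,
                         config$leaky_slope, config$dropout, training,
                         average = l == config$n_layers)
  }
  # attention pooling: beta_i = softmax(q' tanh(Wg h_i)); z = sum beta h
  sc <- ad_matmul(tape, ad_tanh(tape, ad_matmul(tape, h, pn$pool_Wg)),
                  pn$pool_q)
  beta <- ad_softmax_rows(tape, ad_transpose(tape, sc))  # 1 x n
  z <- ad_matmul(tape, beta, h)                          # 1 x hd
  logits <- ad_add(tape, ad_matmul(tape, z, pn$cls_W), pn$cls_b)
  yhat <- ad_softmax_rows(tape, logits)
  list(h = h, beta = beta, z = z, logits = logits, yhat = yhat)
}

## ---- exported building blocks ----

#' One multi-head graph-attention layer (functional form)
#'
#' Per head t: scores \code{e_ij = LeakyReLU(a1' W h_i + a2' W h_j)} for
#' every edge (i, j) with j in N(i) (self-loops included), softmaxed over
#' each neighbourhood; outputs \code{sum_j alpha_ij W h_j} through an ELU.
#' Head outputs are concatenated (or averaged when \code{average}).
#'
#' @param h n x d node-feature matrix.
#' @param graph A \code{patch_graph} (its \code{edge_list} defines the
#'   neighbourhoods).
#' @param params List with per-head \code{W} (d x d_h), \code{a1}, \code{a2}
#'   (d_h x 1): \code{params[[t]] = list(W, a1, a2)}.
#' @param n_heads Number of heads.
#' @param leaky_slope LeakyReLU negative slope.
#' @param average Average heads instead of concatenating.
#' @return Transformed node matrix, with attribute \code{attention}: a
#'   list (one per head) of data.frames \code{(i, j, alpha)}.
#' @export
gat_layer <- function(h, graph, params, n_heads = length(params),
                      leaky_slope = 0.2, average = FALSE) {
  tape <- ad_tape()
  pn <- list()
  for (t in seq_len(n_heads)) {
    pre <- sprintf("l1h%d_", t)
    pn[[paste0(pre, "W")]] <- ad_input(tape, params[[t]]$W)
    pn[[paste0(pre, "a1")]] <- ad_input(tape, params[[t]]$a1)
    pn[[paste0(pre, "a2")]] <- ad_input(tape, params[[t]]$a2)
  }
  hn <- ad_input(tape, h)
  out <- .gat_layer_node(tape, hn, graph$edge_list, pn, 1L, n_heads,
                         leaky_slope, dropout = 0, training = FALSE,
                         average = average)
  # recompute per-head attention coefficients for inspection
  ei <- graph$edge_list[, 1]; ej <- graph$edge_list[, 2]
  attn <- lapply(seq_len(n_heads), function(t) {
    wh <- h %*% params[[t]]$W
    sc <- wh %*% params[[t]]$a1
    sc2 <- wh %*% params[[t]]$a2
    e <- sc[ei] + sc2[ej]
    e <- ifelse(e > 0, e, leaky_slope * e)
    ex <- exp(e - tapply(e, ei, max)[as.character(ei)])
    den <- tapply(ex, ei, sum)[as.character(ei)]
    data.frame(i = ei, j = ej, alpha = as.numeric(ex / den))
  })
  res <- out$value
  attr(res, "attention") <- attn
  res
}

#' Attention pooling of node embeddings into one graph embedding
#'
#' \code{beta_i = softmax_i(q' tanh(Wg h_i))}; \code{z = sum_i beta_i h_i}.
#'
#' @param h n x d node embeddings.
#' @param q d x 1 scoring vector.
#' @param w_g d x d scoring transform.
#' @return List with \code{z} (1 x d) and \code{beta} (length n, sums
#'   to 1).
#' @export
attention_pool <- function(h, q, w_g) {
  sc <- as.numeric(tanh(h %*% w_g) %*% q)
  beta <- exp(sc - max(sc))
  beta <- beta / sum(beta)
  list(z = matrix(beta, 1) %*% h, beta = beta)
}

#' Softmax classification of a graph embedding
#'
#' @param z 1 x d embedding.
#' @param w_c d x C weights.
#' @param b_c 1 x C bias.
#' @return List with \code{probabilities} (length C, sums to 1) and
#'   \code{label} (argmax, lowest index on ties).
#' @export
classify_embedding <- function(z, w_c, b_c) {
  lg <- as.numeric(z %*% w_c + b_c)
  p <- exp(lg - max(lg))
  p <- p / sum(p)
  list(probabilities = p, label = which.max(p))
}

#' Regularized cross-entropy classification loss
#'
#' \code{-sum_i y_i log(yhat_i) + lambda * ||Theta||_2^2} over all
#' trainable parameters.
#'
#' @param yhat Predicted class probabilities (summing to 1).
#' @param y One-hot target vector.
#' @param lambda L2 weight.
#' @param params List of parameter matrices entering the penalty.
#' @param eps Probability floor before the log.
#' @return Scalar loss.
#' @export
class_loss <- function(yhat, y, lambda = 0, params = list(), eps = 1e-12) {
  if (!all(y %in% c(0, 1)) || sum(y) != 1) stop("y must be one-hot")
  ce <- -sum(y * log(pmax(yhat, eps)))
  ce + lambda * sum(vapply(params, function(p) sum(p^2), numeric(1)))
}

## ---- training and prediction ----

#' Train the graph-attention classifier
#'
#' Mini-batch Adam on the cross-entropy loss (the L2 penalty enters
#' through weight decay), with early stopping on validation accuracy.
#' Deterministic under a fixed seed.
#'
#' @param graphs List of \code{patch_graph}s.
#' @param labels Integer class labels (1..C) per graph.
#' @param config A \code{\link{gat_config}}.
#' @param n_classes Number of classes (default \code{max(labels)}).
#' @param val_graphs,val_labels Optional validation set for early
#'   stopping.
#' @param seed Seed override.
#' @param eval_every Validation cadence in epochs.
#' @param patience Early-stop patience in evaluations.
#' @return A \code{gat_model}: \code{params}, \code{config},
#'   \code{n_classes}, \code{history} (epoch losses, plus validation
#'   accuracy when available).
#' @export
train_classifier <- function(graphs, labels, config = gat_config(),
                             n_classes = max(labels),
                             val_graphs = NULL, val_labels = NULL,
                             seed = NULL, eval_every = 5L,
                             patience = NULL) {
  stopifnot(length(graphs) == length(labels),
            length(unique(labels)) >= 2)
  if (is.null(seed)) seed <- config$seed
  if (is.null(patience)) {
    patience <- if (is.null(config$patience)) 4L else config$patience
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  in_dim <- ncol(graphs[[1]]$node_features)
  params <- .gat_init(config, in_dim, n_classes)
  state <- adam_state(params)
  n <- length(graphs)
  bs <- min(config$batch_size, n)
  eye <- diag(n_classes)
  hist_epoch <- integer(0); hist_loss <- numeric(0)
  hist_vacc <- numeric(0); hist_vepoch <- integer(0)
  best_vacc <- -Inf; best_params <- params; bad <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(n)
    ep_loss <- 0
    for (b0 in seq(1L, n, by = bs)) {
      batch <- perm[b0:min(b0 + bs - 1L, n)]
      grads <- NULL
      for (i in batch) {
        tape <- ad_tape()
        fw <- .gat_forward(tape, graphs[[i]], params, config, n_classes,
                           training = config$dropout > 0)
        yv <- matrix(eye[labels[i], ], 1)
        p <- ad_add_const(tape, ad_scale(tape, fw$yhat, 1 - 2e-9), 1e-9)
        loss <- ad_scale(tape, ad_sum(tape,
                                      ad_mul(tape, ad_input(tape, yv),
                                             ad_log(tape, p))), -1)
        if (!is.finite(loss$value[1])) {
          stop(sprintf("non-finite classification loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss$value[1]
        ad_backward(tape, loss)
        g <- ad_grads(tape)
        grads <- if (is.null(grads)) g else
          stats::setNames(lapply(names(g),
                                 function(nm) grads[[nm]] + g[[nm]]),
                          names(g))
      }
      grads <- lapply(grads, function(g) g / length(batch))
      upd <- adam_step(params, grads, state, lr = config$lr,
                       weight_decay = config$weight_decay)
      params <- upd$params; state <- upd$state
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, ep_loss / n)
    if (!is.null(val_graphs) && epoch %% eval_every == 0L) {
      pr <- predict_graphs(list(params = params, config = config,
                                n_classes = n_classes), val_graphs)
      vacc <- mean(pr$label == val_labels)
      hist_vacc <- c(hist_vacc, vacc); hist_vepoch <- c(hist_vepoch, epoch)
      if (vacc > best_vacc + 1e-9) {
        best_vacc <- vacc; best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  }
  if (!is.null(val_graphs) && best_vacc > -Inf) params <- best_params
  structure(list(params = params, config = config, n_classes = n_classes,
                 history = data.frame(epoch = hist_epoch, loss = hist_loss),
                 val_history = if (length(hist_vacc))
                   data.frame(epoch = hist_vepoch, accuracy = hist_vacc)
                 else NULL),
            class = "gat_model")
}

#' Predict class probabilities for a list of graphs
#'
#' @param model A \code{gat_model} (or a list with \code{params},
#'   \code{config}, \code{n_classes}).
#' @param graphs List of \code{patch_graph}s.
#' @return List with \code{probabilities} (n x C matrix), \code{label}
#'   (argmax, lowest index on ties) and \code{pooling_weights} (list of
#'   per-graph beta vectors).
#' @export
predict_graphs <- function(model, graphs) {
  probs <- matrix(0, length(graphs), model$n_classes)
  betas <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    tape <- ad_tape()
    fw <- .gat_forward(tape, graphs[[i]], model$params, model$config,
                       model$n_classes, training = FALSE)
    probs[i, ] <- fw$yhat$value[1, ]
    betas[[i]] <- as.numeric(fw$beta$value)
  }
  list(probabilities = probs, label = apply(probs, 1L, which.max),
       pooling_weights = betas)
}
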
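#' Configuration for the shifted-window transformer U-Net segmenter
#'
#' The default is a small configuration sized for 64 x 64 slices; the
#' reference-scale network (embed_dim 96, depths c(2, 2, 6, 2), heads
#' c(3, 6, 12, 24)) is available by argument for parity with full-size
#' inputs.
#'
#' @param patch_size Patch embedding size P in pixels (must divide the
#'   input dimensions).
#' @param embed_dim Token channel count at stage 1; doubles at each patch
#'   merging.
#' @param depths Integer vector of attention-block counts per stage.
#' @param n_heads Attention heads per stage (same length as
#'   \code{depths}); each stage dim must be divisible by its head count.
#' @param window_size Attention window size in tokens (must divide every
#'   stage's token-grid dimensions). Blocks alternate shift 0 and
#'   \code{window_size / 2}.
#' @param mask_threshold Probability threshold tau in [0.4, 0.6] used by
#'   \code{\link{binarize_mask}}.
#' @param lambda1,lambda2 Weights of the Dice and cross-entropy terms of
#'   the segmentation loss.
#' @param lr,weight_decay,batch_size,epochs,dropout Training scalars.
#' @param target Which binary mask the segmenter is trained on:
#'   \code{"tumor"} or \code{"brain"}.
#' @param seed Integer seed for parameter initialisation and batching.
#' @return An object of class \code{swin_config}.
#' @export
swin_config <- function(patch_size = 4L, embed_dim = 16L, depths = c(1L, 1L),
                        n_heads = NULL, window_size = 4L,
                        mask_threshold = 0.5, lambda1 = 0.5, lambda2 = 0.5,
                        lr = 1e-4, weight_decay = 1e-5, batch_size = 8L,
                        epochs = 200L, dropout = 0.3,
                        target = c("tumor", "brain"), seed = 1L) {
  if (is.null(n_heads)) n_heads <- rep(2L, length(depths))
  stopifnot(length(n_heads) == length(depths),
            mask_threshold >= 0.4, mask_threshold <= 0.6,
            lambda1 >= 0, lambda2 >= 0, dropout >= 0, dropout < 1)
  for (s in seq_along(depths)) {
    if ((embed_dim * 2^(s - 1)) %% n_heads[s] != 0) {
      stop("stage dimension must be divisible by its head count")
    }
  }
  structure(list(patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths), n_heads = as.integer(n_heads),
                 window_size = as.integer(window_size),
                 mask_threshold = mask_threshold,
                 lambda1 = lambda1, lambda2 = lambda2, lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 target = match.arg(target), seed = as.integer(seed)),
            class = "swin_config")
}

## ---- layout helpers ----

# Linear pixel indices (into an H x W matrix) of each P x P patch; one row
# per token in row-major token order, columns in column-major patch order.
.patch_pixel_index <- function(h, w, p) {
  gh <- h %/% p; gw <- w %/% p
  idx <- matrix(0L, gh * gw, p * p)
  t <- 0L
  for (r in seq_len(gh)) {
    for (c in seq_len(gw)) {
      t <- t + 1L
      rows <- (r - 1L) * p + seq_len(p)
      cols <- (c - 1L) * p + seq_len(p)
      idx[t, ] <- as.vector(outer(rows, (cols - 1L) * h, "+"))
    }
  }
  idx
}

# Token indices per attention window on a (gh x gw) row-major token grid,
# after a cyclic shift of the grid by `shift` tokens.
.window_indices <- function(gh, gw, win, shift = 0L) {
  out <- list()
  for (wr in seq_len(gh %/% win)) {
    for (wc in seq_len(gw %/% win)) {
      rows <- ((wr - 1L) * win + seq_len(win) + shift - 1L) %% gh + 1L
      cols <- ((wc - 1L) * win + seq_len(win) + shift - 1L) %% gw + 1L
      out[[length(out) + 1L]] <-
        as.vector(t(outer((rows - 1L) * gw, cols, "+")))
    }
  }
  out
}

# Relative-position index (1-based into a (2w-1)^2 table) between every
# ordered pair of tokens in a w x w window (row-major order).
.rel_pos_index <- function(win) {
  coords <- expand.grid(c = seq_len(win), r = seq_len(win))[, c("r", "c")]
  n <- win * win
  idx <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dr <- coords$r[i] - coords$r[j] + win - 1L
      dc <- coords$c[i] - coords$c[j] + win - 1L
      idx[i, j] <- dr * (2L * win - 1L) + dc + 1L
    }
  }
  idx
}

.xavier <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

# Initialise all trainable parameters for the given input geometry.
.swin_init <- function(config, n_channels, image_size) {
  p <- config$patch_size
  stopifnot(image_size[1] %% p == 0, image_size[2] %% p == 0)
  d <- config$embed_dim
  win <- config$window_size
  nrel <- (2L * win - 1L)^2
  params <- list(pe_W = .xavier(p * p * n_channels, d),
                 pe_b = matrix(0, 1, d))
  n_stage <- length(config$depths)
  for (s in seq_len(n_stage)) {
    ds <- d * 2L^(s - 1L)
    for (b in seq_len(config$depths[s])) {
      pre <- sprintf("s%db%d_", s, b)
      params[[paste0(pre, "ln_g")]] <- matrix(1, 1, ds)
      params[[paste0(pre, "ln_b")]] <- matrix(0, 1, ds)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        params[[paste0(pre, nm)]] <- .xavier(ds, ds)
      }
      for (nm in c("bq", "bk", "bv", "bo")) {
        params[[paste0(pre, nm)]] <- matrix(0, 1, ds)
      }
      params[[paste0(pre, "relbias")]] <-
        matrix(0, nrel, config$n_heads[s])
    }
    if (s < n_stage) {
      params[[sprintf("mg%d_W", s)]] <- .xavier(4L * ds, 2L * ds)
      params[[sprintf("mg%d_b", s)]] <- matrix(0, 1, 2L * ds)
    }
  }
  if (n_stage > 1) {
    for (s in seq_len(n_stage - 1L)) {
      ds <- d * 2L^(s - 1L)
      params[[sprintf("dec%d_W", s)]] <- .xavier(3L * ds, ds)
      params[[sprintf("dec%d_b", s)]] <- matrix(0, 1, ds)
    }
  }
  params$head_W <- .xavier(d, p * p)
  params$head_b <- matrix(0, 1, p * p)
  params
}

## ---- forward pieces (autodiff) ----

# One pre-norm shifted-window attention block: x + Proj(SW-MSA(LN(x))).
.swin_block_node <- function(tape, x, grid, prm, win, shift, n_heads,
                             dropout, training, layernorm = TRUE) {
  gh <- grid[1]; gw <- grid[2]
  d <- ncol(x$value)
  dh <- d %/% n_heads
  xn <- if (layernorm) ad_layernorm(tape, x, prm$ln_g, prm$ln_b) else x
  q <- ad_add(tape, ad_matmul(tape, xn, prm$Wq), prm$bq)
  k <- ad_add(tape, ad_matmul(tape, xn, prm$Wk), prm$bk)
  v <- ad_add(tape, ad_matmul(tape, xn, prm$Wv), prm$bv)
  wins <- .window_indices(gh, gw, win, shift)
  relidx <- .rel_pos_index(win)
  nw <- win * win
  # per-head relative position bias matrices, shared across windows
  bmats <- lapply(seq_len(n_heads), function(hh) {
    ad_reshape(tape,
               ad_cols(tape, ad_gather_rows(tape, prm$relbias,
                                            as.vector(relidx)), hh),
               nw, nw)
  })
  outs <- vector("list", length(wins))
  for (wi in seq_along(wins)) {
    idx <- wins[[wi]]
    qw <- ad_gather_rows(tape, q, idx)
    kw <- ad_gather_rows(tape, k, idx)
    vw <- ad_gather_rows(tape, v, idx)
    heads <- vector("list", n_heads)
    for (hh in seq_len(n_heads)) {
      colsel <- (hh - 1L) * dh + seq_len(dh)
      qh <- ad_cols(tape, qw, colsel)
      kh <- ad_cols(tape, kw, colsel)
      vh <- ad_cols(tape, vw, colsel)
      sc <- ad_scale(tape, ad_matmul(tape, qh, ad_transpose(tape, kh)),
                     1 / sqrt(dh))
      sc <- ad_add(tape, sc, bmats[[hh]])
      al <- ad_softmax_rows(tape, sc)
      al <- ad_dropout(tape, al, dropout, training)
      heads[[hh]] <- ad_matmul(tape, al, vh)
    }
    outs[[wi]] <- if (n_heads > 1) ad_cbind(tape, heads) else heads[[1]]
  }
  stacked <- if (length(outs) > 1) ad_rbind(tape, outs) else outs[[1]]
  # scatter window rows back to row-major token order
  perm <- unlist(wins)
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  attn <- ad_gather_rows(tape, stacked, inv)
  proj <- ad_add(tape, ad_matmul(tape, attn, prm$Wo), prm$bo)
  proj <- ad_dropout(tape, proj, dropout, training)
  ad_add(tape, x, proj)
}

# Full encoder/decoder forward. channels: C x H x W array. Returns the
# pyramid (one node per stage), the soft-mask node laid out as
# (n_tokens x P^2), and grid dims per stage.
.swin_forward <- function(tape, channels, params, config, training = FALSE) {
  p <- config$patch_size
  h <- dim(channels)[2]; w <- dim(channels)[3]
  gh <- h %/% p; gw <- w %/% p
  pidx <- .patch_pixel_index(h, w, p)
  xmat <- do.call(cbind, lapply(seq_len(dim(channels)[1]), function(k) {
    m <- channels[k, , ]
    matrix(m[as.vector(pidx)], nrow(pidx), ncol(pidx))
  }))
  pn <- lapply(names(params), function(nm) ad_param(tape, params[[nm]], nm))
  names(pn) <- names(params)
  x <- ad_add(tape, ad_matmul(tape, ad_input(tape, xmat), pn$pe_W), pn$pe_b)

  n_stage <- length(config$depths)
  pyramid <- vector("list", n_stage)
  grids <- vector("list", n_stage)
  cg <- c(gh, gw)
  for (s in seq_len(n_stage)) {
    for (b in seq_len(config$depths[s])) {
      shift <- if (b %% 2 == 0) config$window_size %/% 2L else 0L
      prm <- .block_params_nodes(pn, s, b)
      x <- .swin_block_node(tape, x, cg, prm, config$window_size, shift,
                            config$n_heads[s], config$dropout, training)
    }
    pyramid[[s]] <- x
    grids[[s]] <- cg
    if (s < n_stage) {
      mi <- .merge_indices(cg[1], cg[2])
      merged <- ad_cbind(tape, lapply(seq_len(4), function(qd) {
        ad_gather_rows(tape, x, mi[, qd])
      }))
      x <- ad_add(tape, ad_matmul(tape, merged, pn[[sprintf("mg%d_W", s)]]),
                  pn[[sprintf("mg%d_b", s)]])
      cg <- cg %/% 2L
    }
  }
  # decoder with skip connections
  dnode <- pyramid[[n_stage]]
  if (n_stage > 1) {
    for (s in seq(n_stage - 1L, 1L)) {
      up_idx <- .upsample_indices(grids[[s]][1], grids[[s]][2])
      up <- ad_gather_rows(tape, dnode, up_idx)
      cat_n <- ad_cbind(tape, list(up, pyramid[[s]]))
      dnode <- ad_elu(tape, ad_add(tape,
                                   ad_matmul(tape, cat_n,
                                             pn[[sprintf("dec%d_W", s)]]),
                                   pn[[sprintf("dec%d_b", s)]]))
    }
  }
  logits <- ad_add(tape, ad_matmul(tape, dnode, pn$head_W), pn$head_b)
  yhat <- ad_sigmoid(tape, logits)
  list(pyramid = pyramid, grids = grids, yhat = yhat, pidx = pidx,
       image_size = c(h, w))
}

.block_params_nodes <- function(pn, s, b) {
  pre <- sprintf("s%db%d_", s, b)
  nms <- c("ln_g", "ln_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "relbias")
  out <- lapply(nms, function(nm) pn[[paste0(pre, nm)]])
  names(out) <- nms
  out
}

# Row-major token indices of the 2x2 children of each merged token.
.merge_indices <- function(gh, gw) {
  gh2 <- gh %/% 2L; gw2 <- gw %/% 2L
  out <- matrix(0L, gh2 * gw2, 4L)
  t <- 0L
  for (r in seq_len(gh2)) {
    for (c in seq_len(gw2)) {
      t <- t + 1L
      r0 <- 2L * r - 1L; c0 <- 2L * c - 1L
      out[t, ] <- c((r0 - 1L) * gw + c0, r0 * gw + c0,
                    (r0 - 1L) * gw + c0 + 1L, r0 * gw + c0 + 1L)
    }
  }
  out
}

# For each fine-grid token, the index of its parent on the 2x-coarser grid.
.upsample_indices <- function(gh, gw) {
  gw2 <- gw %/% 2L
  out <- integer(gh * gw)
  t <- 0L
  for (r in seq_len(gh)) {
    for (c in seq_len(gw)) {
      t <- t + 1L
      out[t] <- (((r + 1L) %/% 2L) - 1L) * gw2 + ((c + 1L) %/% 2L)
    }
  }
  out
}

# (n_tokens x P^2) patch layout -> H x W matrix.
.tokens_to_image <- function(vals, pidx, h, w) {
  out <- matrix(0, h, w)
  out[as.vector(pidx)] <- as.vector(vals)
  out
}

## ---- exported building blocks ----

#' Patch embedding
#'
#' Splits the image into non-overlapping P x P patches (row-major token
#' order) and linearly projects each flattened patch (all channels
#' concatenated) to the embedding dimension.
#'
#' @param channels \code{C x H x W} array (H, W divisible by P).
#' @param P Patch size.
#' @param W,b Projection weight \code{(P*P*C) x D} and bias \code{1 x D}.
#' @return Token matrix \code{(H/P * W/P) x D} with attribute \code{grid}.
#' @export
patch_embed <- function(channels, P, W, b) {
  if (is.matrix(channels)) {
    channels <- array(channels, dim = c(1L, dim(channels)))
  }
  h <- dim(channels)[2]; w <- dim(channels)[3]
  stopifnot(h %% P == 0, w %% P == 0)
  pidx <- .patch_pixel_index(h, w, P)
  xmat <- do.call(cbind, lapply(seq_len(dim(channels)[1]), function(k) {
    m <- channels[k, , ]
    matrix(m[as.vector(pidx)], nrow(pidx), ncol(pidx))
  }))
  out <- sweep(xmat %*% W, 2L, b[1L, ], "+")
  attr(out, "grid") <- c(h %/% P, w %/% P)
  out
}

#' One shifted-window multi-head attention block
#'
#' Pre-norm residual block: \code{x + Proj(SW-MSA(LN(x)))}. Within each
#' (optionally cyclically shifted) window, per-head scores are
#' \code{Q K' / sqrt(d_h)} plus a learned relative-position bias,
#' row-softmaxed and applied to V; heads are concatenated and linearly
#' projected.
#'
#' @param tokens Token matrix \code{n x D} with row-major grid layout.
#' @param grid Token-grid dims \code{c(gh, gw)}.
#' @param params List with \code{Wq, bq, Wk, bk, Wv, bv, Wo, bo, relbias}
#'   and (when \code{layernorm}) \code{ln_g, ln_b}.
#' @param window_size Window size in tokens (must divide grid dims; a
#'   window larger than the grid is an error).
#' @param shift Cyclic shift in tokens (0 or \code{window_size / 2}).
#' @param n_heads Number of heads (divides D).
#' @param layernorm Apply the pre-norm layer normalisation (default TRUE).
#' @return Transformed token matrix \code{n x D}.
#' @export
window_attention <- function(tokens, grid, params, window_size, shift = 0L,
                             n_heads = 1L, layernorm = TRUE) {
  if (window_size > min(grid)) stop("window larger than token grid")
  stopifnot(grid[1] %% window_size == 0, grid[2] %% window_size == 0)
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_input(tape, p))
  x <- ad_input(tape, tokens)
  out <- .swin_block_node(tape, x, grid, pn, window_size, shift, n_heads,
                          dropout = 0, training = FALSE,
                          layernorm = layernorm)
  out$value
}

#' Encode an image into the stage pyramid
#'
#' @param channels \code{C x H x W} array.
#' @param params Parameter list from a trained model (or
#'   \code{\link{train_segmenter}} initialisation).
#' @param config A \code{\link{swin_config}}.
#' @return List of per-stage token matrices, each with attribute
#'   \code{grid}; spatial sizes follow /P, /2P, ... per stage.
#' @export
swin_encode <- function(channels, params, config) {
  tape <- ad_tape()
  fw <- .swin_forward(tape, channels, params, config, training = FALSE)
  out <- lapply(seq_along(fw$pyramid), function(s) {
    v <- fw$pyramid[[s]]$value
    attr(v, "grid") <- fw$grids[[s]]
    v
  })
  out
}

#' Threshold a soft probability map into a binary mask
#'
#' @param soft_mask Numeric matrix of probabilities.
#' @param tau Threshold; a pixel is foreground iff its probability is
#'   \code{>= tau}.
#' @return Integer \{0,1\} matrix.
#' @export
binarize_mask <- function(soft_mask, tau = 0.5) {
  stopifnot(tau >= 0, tau <= 1)
  (soft_mask >= tau) + 0L
}

#' Morphological refinement of a binary mask
#'
#' Erosion followed by morphological closing, each with a 3 x 3 square
#' structuring element (one iteration).
#'
#' @param mask Binary matrix.
#' @return Refined integer \{0,1\} matrix.
#' @export
refine_mask <- function(mask) {
  stopifnot(all(mask %in% c(0, 1)))
  kern <- EBImage::makeBrush(3L, shape = "box")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  er <- EBImage::erode(m, kern)
  cl <- EBImage::closing(er, kern)
  matrix(as.integer(as.matrix(cl) > 0.5), nrow(mask), ncol(mask))
}

#' Combined Dice + cross-entropy segmentation loss
#'
#' \code{lambda1 * (1 - softDice) + lambda2 * BCE}, with smoothing
#' \code{eps_d} added to the soft-Dice numerator and denominator and
#' probabilities squashed into \code{[eps, 1 - eps]} before the logs.
#' Optional class weights \code{c(w_background, w_foreground)} reweight the
#' pixelwise cross-entropy.
#'
#' @param yhat Predicted probabilities (any numeric array).
#' @param y Binary ground truth, same shape.
#' @param lambda1,lambda2 Nonnegative term weights.
#' @param class_weights Optional length-2 weights.
#' @param eps_d Dice smoothing constant.
#' @param eps Probability clipping constant.
#' @return Scalar loss.
#' @export
seg_loss <- function(yhat, y, lambda1 = 0.5, lambda2 = 0.5,
                     class_weights = NULL, eps_d = 1e-6, eps = 1e-7) {
  if (!all(dim(as.matrix(yhat)) == dim(as.matrix(y)))) {
    stop("shape mismatch between prediction and target")
  }
  p <- pmin(pmax(yhat, eps), 1 - eps)
  dice <- (2 * sum(p * y) + eps_d) / (sum(p) + sum(y) + eps_d)
  w <- if (is.null(class_weights)) c(1, 1) else class_weights
  bce <- mean(-(w[2] * y * log(p) + w[1] * (1 - y) * log(1 - p)))
  lambda1 * (1 - dice) + lambda2 * bce
}

# Autodiff version (yhat is a node; y a plain matrix of the same shape).
.seg_loss_node <- function(tape, yhat, y, lambda1, lambda2,
                           class_weights = NULL, eps_d = 1e-6, eps = 1e-7) {
  p <- ad_add_const(tape, ad_scale(tape, yhat, 1 - 2 * eps), eps)
  ymat <- ad_input(tape, y)
  num <- ad_add_const(tape, ad_scale(tape, ad_sum(tape,
                                                  ad_mul(tape, p, ymat)), 2),
                      eps_d)
  den <- ad_add_const(tape, ad_add(tape, ad_sum(tape, p),
                                   ad_input(tape, matrix(sum(y)))), eps_d)
  dice <- ad_div(tape, num, den)
  w <- if (is.null(class_weights)) c(1, 1) else class_weights
  logp <- ad_log(tape, p)
  log1p_ <- ad_log(tape, ad_add_const(tape, ad_scale(tape, p, -1), 1))
  t1 <- ad_mul(tape, ad_input(tape, w[2] * y), logp)
  t2 <- ad_mul(tape, ad_input(tape, w[1] * (1 - y)), log1p_)
  bce <- ad_scale(tape, ad_mean(tape, ad_add(tape, t1, t2)), -1)
  one_minus_dice <- ad_add_const(tape, ad_scale(tape, dice, -1), 1)
  ad_add(tape, ad_scale(tape, one_minus_dice, lambda1),
         ad_scale(tape, bce, lambda2))
}

## ---- training and prediction ----

.slice_target <- function(slice, target) {
  if (target == "tumor") slice$tumor_mask else slice$brain_mask
}

# Target mask rearranged into the (n_tokens x P^2) layout of the head.
.mask_to_tokens <- function(mask, pidx) {
  matrix(mask[as.vector(pidx)], nrow(pidx), ncol(pidx))
}

#' Train the segmenter
#'
#' Mini-batch Adam training of the combined Dice + cross-entropy loss,
#' with optional early stopping on validation Dice. Fully deterministic
#' under a fixed seed.
#'
#' @param dataset List of slices (each with \code{channels} and the target
#'   mask named by \code{config$target}).
#' @param config A \code{\link{swin_config}}.
#' @param seed Integer seed (overrides \code{config$seed} when given).
#' @param val Optional validation slice list for early stopping.
#' @param max_steps Optional cap on optimisation steps; default
#'   \code{epochs * ceiling(n / batch_size)}.
#' @param lr Optional learning-rate override.
#' @param eval_every Validation cadence in steps.
#' @param patience Early-stop patience in evaluations.
#' @param verbose Print progress.
#' @return A \code{swin_model}: list with \code{params}, \code{config},
#'   \code{history} (data.frame of step and loss, plus validation Dice
#'   when available).
#' @export
train_segmenter <- function(dataset, config = swin_config(), seed = NULL,
                            val = NULL, max_steps = NULL, lr = NULL,
                            eval_every = 25L, patience = 5L,
                            verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  if (is.null(seed)) seed <- config$seed
  if (is.null(lr)) lr <- config$lr
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(dataset)
  nchan <- dim(dataset[[1]]$channels)[1]
  isz <- dim(dataset[[1]]$channels)[2:3]
  params <- .swin_init(config, nchan, isz)
  state <- adam_state(params)
  if (is.null(max_steps)) {
    max_steps <- config$epochs * ceiling(n / config$batch_size)
  }
  bs <- min(config$batch_size, n)
  hist_step <- integer(0); hist_loss <- numeric(0)
  hist_val <- numeric(0); hist_val_step <- integer(0)
  best_val <- -Inf; best_params <- params; bad <- 0L
  for (step in seq_len(max_steps)) {
    batch <- if (n <= bs) seq_len(n) else sample(n, bs)
    grads <- NULL; loss_acc <- 0
    for (i in batch) {
      tape <- ad_tape()
      fw <- .swin_forward(tape, dataset[[i]]$channels, params, config,
                          training = config$dropout > 0)
      ytok <- .mask_to_tokens(.slice_target(dataset[[i]], config$target),
                              fw$pidx)
      loss <- .seg_loss_node(tape, fw$yhat, ytok, config$lambda1,
                             config$lambda2)
      if (!is.finite(loss$value[1])) {
        stop(sprintf("non-finite segmentation loss at step %d", step))
      }
      loss_acc <- loss_acc + loss$value[1]
      ad_backward(tape, loss)
      g <- ad_grads(tape)
      grads <- if (is.null(grads)) g else
        stats::setNames(lapply(names(g), function(nm) grads[[nm]] + g[[nm]]),
                        names(g))
    }
    grads <- lapply(grads, function(g) g / length(batch))
    upd <- adam_step(params, grads, state, lr = lr,
                     weight_decay = config$weight_decay)
    params <- upd$params; state <- upd$state
    hist_step <- c(hist_step, step)
    hist_loss <- c(hist_loss, loss_acc / length(batch))
    if (!is.null(val) && step %% eval_every == 0L) {
      vd <- mean(vapply(val, function(sl) {
        pr <- .predict_soft(sl$channels, params, config)
        m <- binarize_mask(pr$soft, config$mask_threshold)
        evaluate_segmentation(m, .slice_target(sl, config$target))$dice
      }, numeric(1)))
      hist_val <- c(hist_val, vd); hist_val_step <- c(hist_val_step, step)
      if (vd > best_val + 1e-6) {
        best_val <- vd; best_params <- params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    if (verbose && step %% 20L == 0L) {
      message(sprintf("step %d loss %.4f", step, hist_loss[length(hist_loss)]))
    }
  }
  if (!is.null(val) && best_val > -Inf) params <- best_params
  structure(list(params = params, config = config,
                 history = data.frame(step = hist_step, loss = hist_loss),
                 val_history = if (length(hist_val))
                   data.frame(step = hist_val_step, dice = hist_val)
                 else NULL),
            class = "swin_model")
}

.predict_soft <- function(channels, params, config) {
  tape <- ad_tape()
  fw <- .swin_forward(tape, channels, params, config, training = FALSE)
  soft <- .tokens_to_image(fw$yhat$value, fw$pidx, fw$image_size[1],
                           fw$image_size[2])
  zl <- fw$pyramid[[length(fw$pyramid)]]$value
  attr(zl, "grid") <- fw$grids[[length(fw$grids)]]
  list(soft = soft, z_l = zl)
}

#' Segment one slice with a trained model
#'
#' @param model A \code{swin_model} from \code{\link{train_segmenter}}.
#' @param slice A slice (list with \code{channels}) or a bare
#'   \code{C x H x W} array.
#' @return A \code{segmentation_output}: \code{soft_mask},
#'   \code{binary_mask}, \code{refined_mask}, and \code{encoder_features}
#'   (final-stage token matrix with a \code{grid} attribute).
#' @export
segment_slice <- function(model, slice) {
  channels <- if (is.list(slice)) slice$channels else slice
  pr <- .predict_soft(channels, model$params, model$config)
  m <- binarize_mask(pr$soft, model$config$mask_threshold)
  structure(list(soft_mask = pr$soft, binary_mask = m,
                 refined_mask = refine_mask(m),
                 encoder_features = pr$z_l),
            class = "segmentation_output")
}
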
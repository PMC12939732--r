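# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every node holds a value, an optional gradient, and a backward
# closure; the tape records nodes in creation order, which is a valid
# topological order, so backpropagation is a single reverse sweep.
#
# This engine is deliberately small: just the operations needed by the
# shifted-window transformer segmenter and the graph-attention classifier.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    name = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$name <- name
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# Leaf whose gradient is not needed.
ad_input <- function(tape, value) ad_node(tape, as.matrix(value))

# Leaf parameter; gradients collected by name after the backward sweep.
ad_param <- function(tape, value, name) {
  ad_node(tape, as.matrix(value), name = name)
}

ad_accum <- function(node, g) {
  if (is.null(node$grad)) {
    node$grad <- g
  } else {
    node$grad <- node$grad + g
  }
}

# Reverse sweep from a scalar (1x1) loss node.
ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) {
      node$backward(node$grad)
    }
  }
  invisible(NULL)
}

# Named gradients of every ad_param on the tape (summed if a name repeats).
ad_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    node <- tape$nodes[[i]]
    if (!is.null(node$name)) {
      g <- node$grad
      if (is.null(g)) g <- matrix(0, nrow(node$value), ncol(node$value))
      if (is.null(out[[node$name]])) {
        out[[node$name]] <- g
      } else {
        out[[node$name]] <- out[[node$name]] + g
      }
    }
  }
  out
}

## ---- arithmetic ----

ad_matmul <- function(tape, a, b) {
  ad_node(tape, a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  # b may be a 1 x k row vector broadcast over the rows of a
  if (nrow(b$value) == 1L && nrow(a$value) > 1L) {
    ad_node(tape, sweep(a$value, 2L, b$value[1L, ], "+"), list(a, b),
            function(g) {
              ad_accum(a, g)
              ad_accum(b, matrix(colSums(g), 1L))
            })
  } else {
    ad_node(tape, a$value + b$value, list(a, b), function(g) {
      ad_accum(a, g)
      ad_accum(b, g)
    })
  }
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_div <- function(tape, a, b) {
  ad_node(tape, a$value / b$value, list(a, b), function(g) {
    ad_accum(a, g / b$value)
    ad_accum(b, -g * a$value / (b$value^2))
  })
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, a$value * k, list(a), function(g) ad_accum(a, g * k))
}

ad_add_const <- function(tape, a, k) {
  ad_node(tape, a$value + k, list(a), function(g) ad_accum(a, g))
}

ad_square <- function(tape, a) {
  ad_node(tape, a$value^2, list(a), function(g) ad_accum(a, 2 * g * a$value))
}

ad_exp <- function(tape, a) {
  v <- exp(a$value)
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * v))
}

ad_log <- function(tape, a) {
  ad_node(tape, log(a$value), list(a), function(g) ad_accum(a, g / a$value))
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

## ---- nonlinearities ----

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * v * (1 - v)))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$value)
  ad_node(tape, v, list(a), function(g) ad_accum(a, g * (1 - v^2)))
}

ad_elu <- function(tape, a, alpha = 1) {
  v <- ifelse(a$value > 0, a$value, alpha * (exp(a$value) - 1))
  ad_node(tape, v, list(a), function(g) {
    ad_accum(a, g * ifelse(a$value > 0, 1, v + alpha))
  })
}

ad_leaky_relu <- function(tape, a, slope = 0.2) {
  ad_node(tape, ifelse(a$value > 0, a$value, slope * a$value), list(a),
          function(g) ad_accum(a, g * ifelse(a$value > 0, 1, slope)))
}

# Row-wise softmax.
ad_softmax_rows <- function(tape, a) {
  m <- a$value - apply(a$value, 1L, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ad_node(tape, v, list(a), function(g) {
    ad_accum(a, (g - rowSums(g * v)) * v)
  })
}

# Row-wise layer normalization with learnable affine (gamma, beta: 1 x k).
ad_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, gamma$value[1L, ], "*"), 2L, beta$value[1L, ], "+")
  ad_node(tape, v, list(a, gamma, beta), function(g) {
    ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    ad_accum(beta, matrix(colSums(g), 1L))
    dxh <- sweep(g, 2L, gamma$value[1L, ], "*")
    ad_accum(a, inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)))
  })
}

## ---- structural ops ----

# Select rows (with repetition allowed); backward scatter-adds.
ad_gather_rows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[idx, , drop = FALSE], list(a), function(g) {
    agg <- rowsum(g, group = idx)
    d <- matrix(0, nrow(a$value), ncol(a$value))
    d[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, d)
  })
}

ad_cols <- function(tape, a, idx) {
  idx <- as.integer(idx)
  ad_node(tape, a$value[, idx, drop = FALSE], list(a), function(g) {
    d <- matrix(0, nrow(a$value), ncol(a$value))
    d[, idx] <- g
    ad_accum(a, d)
  })
}

ad_rbind <- function(tape, nodes) {
  sizes <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ad_node(tape, do.call(rbind, lapply(nodes, function(n) n$value)), nodes,
          function(g) {
            for (k in seq_along(nodes)) {
              ad_accum(nodes[[k]], g[starts[k]:ends[k], , drop = FALSE])
            }
          })
}

ad_cbind <- function(tape, nodes) {
  sizes <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ad_node(tape, do.call(cbind, lapply(nodes, function(n) n$value)), nodes,
          function(g) {
            for (k in seq_along(nodes)) {
              ad_accum(nodes[[k]], g[, starts[k]:ends[k], drop = FALSE])
            }
          })
}

# Reshape preserving R's column-major element order.
ad_reshape <- function(tape, a, nr, nc) {
  ad_node(tape, matrix(a$value, nr, nc), list(a), function(g) {
    ad_accum(a, matrix(g, nrow(a$value), ncol(a$value)))
  })
}

# Sum rows of an m x k matrix into n groups (for segment operations on
# edge lists); groups outside 1..n are disallowed.
ad_rowsum_groups <- function(tape, a, group, n) {
  group <- as.integer(group)
  ad_node(tape, {
    agg <- rowsum(a$value, group = group)
    v <- matrix(0, n, ncol(a$value))
    v[as.integer(rownames(agg)), ] <- agg
    v
  }, list(a), function(g) {
    ad_accum(a, g[group, , drop = FALSE])
  })
}

# Multiply each row of a (m x k) by the scalar in w (m x 1).
ad_rowscale <- function(tape, a, w) {
  ad_node(tape, a$value * as.vector(w$value), list(a, w), function(g) {
    ad_accum(a, g * as.vector(w$value))
    ad_accum(w, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

ad_sum <- function(tape, a) {
  ad_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L], nrow(a$value), ncol(a$value)))
  })
}

ad_mean <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L] / n, nrow(a$value), ncol(a$value)))
  })
}

# Mean over rows -> 1 x k.
ad_colmeans <- function(tape, a) {
  n <- nrow(a$value)
  ad_node(tape, matrix(colMeans(a$value), 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L, ], n, ncol(a$value), byrow = TRUE) / n)
  })
}

# Inverted dropout; draws its mask from the current R RNG stream so that a
# seeded training run is reproducible. Identity when rate = 0 or !training.
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= rate) /
    (1 - rate)
  ad_node(tape, a$value * keep, list(a), function(g) ad_accum(a, g * keep))
}

## ---- optimiser ----

# Adam with decoupled L2 weight decay applied through the gradient
# (grad + wd * param), matching the classical regularised-loss reading.
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
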
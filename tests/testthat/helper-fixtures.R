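# Small shared fixtures, built in code at load time.

tiny_phantom_spec <- function(...) {
  phantom_spec(class_names = c("glioma-like", "meningioma-like",
                               "pituitary-like"), ...)
}

# A quick preprocessed slice for segmenter/feature tests.
quick_preprocessed <- function(label = 1, seed = 11) {
  sl <- generate_slice(tiny_phantom_spec(), label, seed = seed)
  preprocess_slice(sl, preprocess_config(nlm_patch = 3L, nlm_search = 7L,
                                         register = FALSE))
}

tiny_swin_config <- function(embed_dim = 16L, ...) {
  swin_config(embed_dim = embed_dim, depths = c(1L, 1L),
              n_heads = c(2L, 2L), dropout = 0, ...)
}

# Random attention-block parameter list for functional window_attention.
random_attention_params <- function(d, n_heads, win, seed = 1) {
  set.seed(seed)
  nrel <- (2 * win - 1)^2
  list(ln_g = matrix(1, 1, d), ln_b = matrix(0, 1, d),
       Wq = matrix(rnorm(d * d) * 0.3, d, d), bq = matrix(0, 1, d),
       Wk = matrix(rnorm(d * d) * 0.3, d, d), bk = matrix(0, 1, d),
       Wv = matrix(rnorm(d * d) * 0.3, d, d), bv = matrix(0, 1, d),
       Wo = matrix(rnorm(d * d) * 0.3, d, d), bo = matrix(0, 1, d),
       relbias = matrix(rnorm(nrel * n_heads) * 0.1, nrel, n_heads))
}

# Dense attention reference for a token set forming one window.
dense_attention_oracle <- function(tokens, params, n_heads, win) {
  d <- ncol(tokens)
  dh <- d / n_heads
  relidx <- scagnet:::.rel_pos_index(win)
  q <- tokens %*% params$Wq
  k <- tokens %*% params$Wk
  v <- tokens %*% params$Wv
  att <- NULL
  for (hh in seq_len(n_heads)) {
    cols <- (hh - 1) * dh + seq_len(dh)
    bmat <- matrix(params$relbias[relidx, hh], nrow(tokens), nrow(tokens))
    sc <- q[, cols] %*% t(k[, cols]) / sqrt(dh) + bmat
    a <- exp(sc - apply(sc, 1, max))
    a <- a / rowSums(a)
    att <- cbind(att, a %*% v[, cols])
  }
  tokens + att %*% params$Wo
}
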
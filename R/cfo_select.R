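#' Configuration for cuttlefish wrapper feature selection
#'
#' A population of continuous candidates in [0, 1]^d is evolved with a
#' global "reflection" exploration move toward the best candidate and a
#' local "absorption" exploitation move toward the population mean with
#' Gaussian perturbation; candidates are binarized through a sigmoid
#' threshold and scored by a wrapper classifier.
#'
#' @param pop_size Population size P (>= 2).
#' @param tau_bin Sigmoid binarization threshold in [0, 1].
#' @param alpha1,beta1 Exploration rates (attraction to the best, random
#'   diffusion). The diffusion amplitude must exceed the distance between
#'   the clipping bounds and the binarization threshold (about 0.4 at
#'   \code{tau_bin = 0.6}), otherwise saturated coordinates can never
#'   change selection state; hence the default \code{beta1 = 0.8}.
#' @param alpha2,beta2 Exploitation rates (attraction to the mean, Gaussian
#'   perturbation weight).
#' @param gauss_sigma SD of the exploitation perturbation.
#' @param fit_alpha,fit_beta Fitness weights of the error term and the
#'   selected-fraction penalty.
#' @param eps Convergence tolerance on the change of the best fitness
#'   between consecutive iterations.
#' @param stall_iters Number of consecutive iterations the change must
#'   stay below \code{eps} before stopping. The wrapper accuracy is
#'   quantized (multiples of one validation sample), so the best fitness
#'   routinely repeats exactly between iterations; a single sub-tolerance
#'   step therefore does not indicate convergence and the test is applied
#'   over this persistence window (default 10).
#' @param t_max Iteration cap (0 returns the best of the initial
#'   population).
#' @param wrapper \code{"knn"} (5-nearest-neighbour, default) or
#'   \code{"gat_small"} (a few-epoch miniature graph-attention classifier;
#'   far slower, kept for fidelity with per-candidate network training).
#' @param cv_folds Folds for the cross-validated wrapper accuracy
#'   (default 4). Cross-validation scores every sample, so the accuracy
#'   quantum is 1/n rather than 1/n_val; with the selected-fraction
#'   penalty at \code{fit_beta / d} per feature, that resolution is what
#'   lets the fitness distinguish dropping a redundant copy from dropping
#'   a genuinely informative column. Set \code{NULL} to use a single
#'   held-out split of \code{val_fraction} instead.
#' @param val_fraction Held-out fraction when \code{cv_folds} is NULL.
#' @param knn_k Neighbour count for the knn wrapper.
#' @param refine_steps Per-iteration local refinement proposals around the
#'   incumbent: the absorption move applied to one or two random
#'   coordinates at a time (ties accepted), which gives the discrete
#'   subset search the single-feature add/drop/swap moves that
#'   full-vector perturbations almost never propose.
#' @param invert_binarization Flip the binarization direction (select where
#'   \code{sigmoid(s) >= tau_bin} instead of the literal \code{<} rule).
#' @param seed Integer seed.
#' @return An object of class \code{cfo_config}.
#' @export
cfo_config <- function(pop_size = 20L, tau_bin = 0.6,
                       alpha1 = 1.0, beta1 = 0.8,
                       alpha2 = 0.5, beta2 = 1.0, gauss_sigma = 0.3,
                       fit_alpha = 0.9, fit_beta = 0.1,
                       eps = 1e-6, t_max = 50L, stall_iters = 10L,
                       wrapper = c("knn", "gat_small"),
                       cv_folds = 4L, val_fraction = 0.25, knn_k = 5L,
                       refine_steps = 20L,
                       invert_binarization = FALSE, seed = 1L) {
  stopifnot(pop_size >= 2, tau_bin >= 0, tau_bin <= 1,
            fit_alpha >= 0, fit_beta >= 0, eps > 0, t_max >= 0)
  structure(list(pop_size = as.integer(pop_size), tau_bin = tau_bin,
                 alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, gauss_sigma = gauss_sigma,
                 fit_alpha = fit_alpha, fit_beta = fit_beta, eps = eps,
                 t_max = as.integer(t_max),
                 stall_iters = as.integer(stall_iters),
                 wrapper = match.arg(wrapper),
                 cv_folds = if (is.null(cv_folds)) NULL else
                   as.integer(cv_folds),
                 val_fraction = val_fraction, knn_k = as.integer(knn_k),
                 refine_steps = as.integer(refine_steps),
                 invert_binarization = isTRUE(invert_binarization),
                 seed = as.integer(seed)),
            class = "cfo_config")
}

#' Initialise a uniform population in [0, 1]^d
#'
#' @param p Population size.
#' @param d Dimension.
#' @param seed Integer seed.
#' @return p x d matrix of i.i.d. U(0, 1) candidates.
#' @export
init_population <- function(p, d, seed = 1L) {
  stopifnot(p >= 2, d >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  matrix(stats::runif(p * d), p, d)
}

#' Sigmoid binarization of a continuous candidate
#'
#' The literal rule selects feature j iff \code{sigmoid(s_j) < tau_bin}
#' (low continuous values mean "selected"); \code{invert} flips the
#' direction.
#'
#' @param s Continuous candidate vector.
#' @param tau_bin Threshold in [0, 1].
#' @param invert Flip the comparison.
#' @return Integer \{0,1\} vector.
#' @export
cfo_binarize <- function(s, tau_bin = 0.6, invert = FALSE) {
  sig <- 1 / (1 + exp(-s))
  if (invert) (sig >= tau_bin) + 0L else (sig < tau_bin) + 0L
}

#' Exploration step: reflection toward the current best
#'
#' \code{s + alpha1 * r1 * (s_best - s) + beta1 * r2} with fresh
#' \code{r1, r2 ~ U(-1, 1)} per element, clipped to [0, 1]. Random numbers
#' come from the current R RNG stream.
#'
#' @param s_i,s_best Candidate and best vectors (equal length).
#' @param alpha1,beta1 Rates.
#' @return Updated candidate in [0, 1]^d.
#' @export
explore_step <- function(s_i, s_best, alpha1 = 1.0, beta1 = 0.2) {
  stopifnot(length(s_i) == length(s_best))
  d <- length(s_i)
  r1 <- stats::runif(d, -1, 1)
  r2 <- stats::runif(d, -1, 1)
  pmin(pmax(s_i + alpha1 * r1 * (s_best - s_i) + beta1 * r2, 0), 1)
}

#' Exploitation step: absorption toward the population mean
#'
#' \code{s + alpha2 * r3 * (s_mean - s) + beta2 * N(0, gauss_sigma^2)} per
#' element, clipped to [0, 1].
#'
#' @param s_i Candidate vector.
#' @param s_mean Population mean vector.
#' @param alpha2,beta2 Rates.
#' @param gauss_sigma Perturbation SD.
#' @return Updated candidate in [0, 1]^d.
#' @export
exploit_step <- function(s_i, s_mean, alpha2 = 0.5, beta2 = 0.2,
                         gauss_sigma = 0.1) {
  stopifnot(length(s_i) == length(s_mean))
  d <- length(s_i)
  r3 <- stats::runif(d, -1, 1)
  pmin(pmax(s_i + alpha2 * r3 * (s_mean - s_i) +
              beta2 * stats::rnorm(d, 0, gauss_sigma), 0), 1)
}

# Deterministic train/validation split indices for the wrapper.
.wrapper_split <- function(n, val_fraction, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_val <- max(1L, round(n * val_fraction))
  val <- sample(n, n_val)
  list(train = setdiff(seq_len(n), val), val = val)
}

.knn_accuracy <- function(features, labels, cols, split, k) {
  xtr <- features[split$train, cols, drop = FALSE]
  xva <- features[split$val, cols, drop = FALSE]
  pred <- class::knn(xtr, xva, factor(labels[split$train]), k = k,
                     use.all = TRUE)
  mean(pred == factor(labels[split$val], levels = levels(pred)))
}

# Mean k-fold cross-validated knn accuracy; `fold` assigns samples to folds.
.knn_cv_accuracy <- function(features, labels, cols, fold, k) {
  mean(vapply(sort(unique(fold)), function(f) {
    .knn_accuracy(features, labels, cols,
                  list(train = which(fold != f), val = which(fold == f)), k)
  }, numeric(1)))
}

# Few-epoch miniature graph-attention classifier trained per candidate.
# Each sample becomes a single-node graph (no spatial structure exists at
# wrapper level), so this scores the selected columns through the same
# attention/pooling/softmax machinery the final classifier uses.
.gat_small_accuracy <- function(features, labels, cols, split, seed) {
  mk <- function(i) build_graph(features[i, cols, drop = FALSE],
                                matrix(0, 1, 2), kernel_sigma = 1,
                                radius = 1)
  lab <- as.integer(factor(labels))
  gtr <- lapply(split$train, mk)
  gva <- lapply(split$val, mk)
  cfg <- gat_config(n_layers = 1L, n_heads = 1L, hidden_dim = 8L,
                    dropout = 0, lr = 1e-2, epochs = 15L,
                    batch_size = 16L, seed = seed)
  fit <- train_classifier(gtr, lab[split$train], cfg,
                          n_classes = max(lab), seed = seed)
  mean(predict_graphs(fit, gva)$label == lab[split$val])
}

#' Wrapper fitness of a binary selection vector
#'
#' \code{J = fit_alpha * (1 - Acc) + fit_beta * (#selected / d)}, where
#' Acc is the estimated accuracy of the wrapper classifier restricted to
#' the selected columns (k-fold cross-validated by default, or on a single
#' held-out split when \code{config$cv_folds} is NULL). An all-zero
#' selection is scored at chance level (majority-class frequency) and
#' flagged degenerate.
#'
#' @param b Binary selection vector of length d.
#' @param features n x d numeric matrix.
#' @param labels Length-n class labels.
#' @param config A \code{\link{cfo_config}}.
#' @param split Optional precomputed holdout split (list with
#'   \code{train}, \code{val}); forces holdout evaluation.
#' @param fold Optional precomputed fold assignment for cross-validation.
#' @return Scalar fitness with attributes \code{accuracy} and
#'   \code{degenerate}.
#' @export
cfo_fitness <- function(b, features, labels, config = cfo_config(),
                        split = NULL, fold = NULL) {
  if (length(labels) != nrow(features)) {
    stop("labels and features disagree in length")
  }
  d <- ncol(features)
  n <- nrow(features)
  use_cv <- is.null(split) && !is.null(config$cv_folds)
  if (use_cv && is.null(fold)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
    fold <- sample(rep_len(seq_len(config$cv_folds), n))
  }
  if (!use_cv && is.null(split)) {
    split <- .wrapper_split(n, config$val_fraction, config$seed)
  }
  cols <- which(b == 1)
  degenerate <- length(cols) == 0L
  acc <- if (degenerate) {
    max(table(labels)) / n
  } else if (config$wrapper != "knn") {
    sp <- if (use_cv) {
      list(train = which(fold != 1L), val = which(fold == 1L))
    } else split
    .gat_small_accuracy(features, labels, cols, sp, config$seed)
  } else if (use_cv) {
    .knn_cv_accuracy(features, labels, cols, fold, config$knn_k)
  } else {
    .knn_accuracy(features, labels, cols, split, config$knn_k)
  }
  j <- config$fit_alpha * (1 - acc) + config$fit_beta * length(cols) / d
  attr(j, "accuracy") <- acc
  attr(j, "degenerate") <- degenerate
  j
}

#' Run the cuttlefish feature-selection loop
#'
#' Each iteration proposes the exploration move for every candidate
#' (accepted unless it worsens that candidate's fitness), the exploitation
#' move additionally for the fitter half, and \code{refine_steps}
#' coordinate-wise absorption proposals around the incumbent (ties
#' accepted, enabling swaps across fitness plateaus); the best-so-far
#' candidate is kept in the population (elitism), so the best-fitness
#' trace is non-increasing. Terminates when the per-iteration best fitness
#' changes by less than \code{eps} for \code{stall_iters} consecutive
#' iterations, or at \code{t_max}.
#'
#' @param features n x d numeric matrix (standardized columns
#'   recommended).
#' @param labels Length-n class labels.
#' @param config A \code{\link{cfo_config}}.
#' @return A \code{selection_result}: list with \code{s_star} (best
#'   continuous candidate), \code{b_star}, \code{selected_indices},
#'   \code{fitness_trace} (best-so-far J per iteration, index 1 = after
#'   initialisation), \code{selected_count_trace},
#'   \code{wrapper_accuracy_trace}, \code{iterations},
#'   \code{degenerate}.
#' @export
run_cfo <- function(features, labels, config = cfo_config()) {
  d <- ncol(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- nrow(features)
  fold <- NULL; split <- NULL
  if (!is.null(config$cv_folds)) {
    fold <- sample(rep_len(seq_len(config$cv_folds), n))
  } else {
    split <- .wrapper_split(n, config$val_fraction, config$seed + 1L)
  }
  evalJ <- function(s) {
    cfo_fitness(cfo_binarize(s, config$tau_bin, config$invert_binarization),
                features, labels, config, split = split, fold = fold)
  }
  # distance from each clipping bound to the continuous preimage of the
  # binarization threshold, used to size refinement kicks
  thr <- log(config$tau_bin / (1 - config$tau_bin))
  thr <- min(max(thr, 0), 1)
  pop <- matrix(stats::runif(config$pop_size * d), config$pop_size, d)
  fit <- apply(pop, 1L, evalJ)
  best_i <- which.min(fit)
  s_best <- pop[best_i, ]
  j_best <- fit[best_i]
  acc_best <- attr(evalJ(s_best), "accuracy")
  trace_j <- j_best
  trace_cnt <- sum(cfo_binarize(s_best, config$tau_bin,
                                config$invert_binarization))
  trace_acc <- acc_best
  t <- 0L
  j_iter_prev <- NA_real_
  stall <- 0L
  while (t < config$t_max) {
    t <- t + 1L
    # exploration: every candidate reflects toward the best; a proposal
    # replaces the candidate unless it is strictly worse
    for (i in seq_len(config$pop_size)) {
      cand <- explore_step(pop[i, ], s_best, config$alpha1, config$beta1)
      jc <- evalJ(cand)
      if (jc <= fit[i]) { pop[i, ] <- cand; fit[i] <- jc }
    }
    # exploitation: the fitter half additionally absorbs toward the mean
    s_mean <- colMeans(pop)
    half <- order(fit)[seq_len(config$pop_size %/% 2L)]
    for (i in half) {
      cand <- exploit_step(pop[i, ], s_mean, config$alpha2, config$beta2,
                           config$gauss_sigma)
      jc <- evalJ(cand)
      if (jc <= fit[i]) { pop[i, ] <- cand; fit[i] <- jc }
    }
    # local refinement of the incumbent: absorption kicks on one or two
    # random coordinates, sized to cross the binarization threshold; ties
    # accepted so equal-fitness swaps can drift
    for (r in seq_len(config$refine_steps)) {
      k <- min(1L + (stats::runif(1) < 0.5), d)
      jj <- sample.int(d, k)
      cand <- s_best
      kick <- stats::rnorm(k, 0, 0.5) +
        ifelse(cand[jj] < thr, 1, -1) * stats::runif(k, 0, 0.6)
      cand[jj] <- pmin(pmax(cand[jj] + kick, 0), 1)
      jc <- evalJ(cand)
      if (jc <= j_best) {
        s_best <- cand
        j_best <- jc
        acc_best <- attr(jc, "accuracy")
      }
    }
    # elitism: never lose the best-so-far candidate
    it_best <- which.min(fit)
    j_iter <- fit[it_best]
    if (j_iter < j_best) {
      j_best <- j_iter
      s_best <- pop[it_best, ]
      acc_best <- attr(evalJ(s_best), "accuracy")
    } else {
      worst <- which.max(fit)
      pop[worst, ] <- s_best
      fit[worst] <- j_best
    }
    delta <- if (t == 1L) Inf else abs(j_iter - j_iter_prev)
    j_iter_prev <- j_iter
    stall <- if (delta < config$eps) stall + 1L else 0L
    # diversity restart: halfway through the stall window, reseed the
    # worse half of the population uniformly (the incumbent is untouched)
    if (stall >= max(2L, config$stall_iters %/% 2L) &&
        stall < config$stall_iters) {
      wh <- order(fit, decreasing = TRUE)[seq_len(config$pop_size %/% 2L)]
      pop[wh, ] <- matrix(stats::runif(length(wh) * d), length(wh), d)
      fit[wh] <- apply(pop[wh, , drop = FALSE], 1L, evalJ)
      stall <- 0L
    }
    trace_j <- c(trace_j, j_best)
    trace_cnt <- c(trace_cnt, sum(cfo_binarize(s_best, config$tau_bin,
                                               config$invert_binarization)))
    trace_acc <- c(trace_acc, acc_best)
    if (stall >= config$stall_iters) break
  }
  b_star <- cfo_binarize(s_best, config$tau_bin, config$invert_binarization)
  structure(list(s_star = s_best, b_star = b_star,
                 selected_indices = which(b_star == 1),
                 fitness_trace = trace_j,
                 selected_count_trace = trace_cnt,
                 wrapper_accuracy_trace = trace_acc,
                 iterations = t,
                 degenerate = sum(b_star) == 0L),
            class = "selection_result")
}

#' Restrict a feature matrix to the selected columns
#'
#' @param features n x d matrix with column names.
#' @param b_star Binary selection vector of length d (or a
#'   \code{selection_result}).
#' @return The matrix restricted to selected columns, names preserved in
#'   order.
#' @export
apply_selection <- function(features, b_star) {
  if (inherits(b_star, "selection_result")) b_star <- b_star$b_star
  if (length(b_star) != ncol(features)) stop("selection dimension mismatch")
  keep <- which(b_star == 1)
  if (length(keep) == 0L) stop("empty selection")
  features[, keep, drop = FALSE]
}
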
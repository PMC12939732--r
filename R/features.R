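#' Tile an image into fixed-size patches and retain those covering the mask
#'
#' Patches tile the image in row-major order; a patch is retained when the
#' fraction of refined-mask foreground inside it is at least
#' \code{min_coverage}.
#'
#' @param image H x W matrix (e.g. the fused mean channel).
#' @param refined_mask Binary H x W matrix.
#' @param patch_size Patch side in pixels (must divide H and W).
#' @param min_coverage Retention threshold in [0, 1].
#' @return A \code{patch_grid}: list with \code{patch_size}, \code{patches}
#'   (list of numeric patch matrices), \code{rows}, \code{cols} (tile
#'   indices), \code{centers} (n x 2 pixel coordinates, row/col) and
#'   \code{coverage}.
#' @export
extract_patches <- function(image, refined_mask, patch_size,
                            min_coverage = 0.5) {
  h <- nrow(image); w <- ncol(image)
  stopifnot(h %% patch_size == 0, w %% patch_size == 0,
            all(dim(refined_mask) == c(h, w)))
  gh <- h %/% patch_size; gw <- w %/% patch_size
  patches <- list(); rows <- integer(0); cols <- integer(0)
  centers <- NULL; coverage <- numeric(0)
  for (r in seq_len(gh)) {
    for (c in seq_len(gw)) {
      ri <- (r - 1L) * patch_size + seq_len(patch_size)
      ci <- (c - 1L) * patch_size + seq_len(patch_size)
      cov <- mean(refined_mask[ri, ci] > 0)
      if (cov >= min_coverage) {
        patches[[length(patches) + 1L]] <- image[ri, ci, drop = FALSE]
        rows <- c(rows, r); cols <- c(cols, c)
        centers <- rbind(centers,
                         c((r - 0.5) * patch_size, (c - 0.5) * patch_size))
        coverage <- c(coverage, cov)
      }
    }
  }
  if (length(patches) == 0L) {
    stop("no patches retained; lower min_coverage or check the mask")
  }
  structure(list(patch_size = patch_size, patches = patches, rows = rows,
                 cols = cols, centers = centers, coverage = coverage,
                 grid = c(gh, gw)),
            class = "patch_grid")
}

#' First four standardized moments of a patch
#'
#' Sample mean, population SD, skewness g1 and excess kurtosis g2. A
#' constant patch returns \code{(mean, 0, 0, 0)}.
#'
#' @param patch Numeric matrix or vector.
#' @return Named numeric vector \code{c(mean, sd, skew, kurt)}.
#' @export
stat_features <- function(patch) {
  v <- as.vector(patch)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 == 0) return(c(mean = mu, sd = 0, skew = 0, kurt = 0))
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  c(mean = mu, sd = sqrt(m2), skew = m3 / m2^1.5, kurt = m4 / m2^2 - 3)
}

# Quantize a patch to integer levels 1..n by equal-width bins over its own
# range; a constant patch maps to level 1.
.quantize <- function(patch, n_levels) {
  rng <- range(patch)
  if (rng[1] == rng[2]) {
    return(matrix(1L, nrow(patch), ncol(patch)))
  }
  q <- 1L + floor((patch - rng[1]) / (rng[2] - rng[1]) * n_levels)
  q[q > n_levels] <- n_levels
  q
}

# Symmetric normalized grey-level co-occurrence matrix for one offset.
.glcm <- function(q, n_levels, offset) {
  h <- nrow(q); w <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- seq_len(h - max(dr, 0)) + max(-dr, 0)
  c1 <- seq_len(w - max(dc, 0)) + max(-dc, 0)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  p <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = seq_len(n_levels)),
               factor(b, levels = seq_len(n_levels)))
  p <- p + tab + t(tab)          # symmetric
  p / sum(p)
}

#' GLCM texture features and LBP histogram of a patch
#'
#' Energy, Contrast, Entropy (base-2, with 0 log 0 = 0) and Homogeneity of
#' the symmetric, normalized grey-level co-occurrence matrix averaged over
#' the given offsets; plus the normalized histogram of 8-neighbour
#' radius-1 uniform local binary patterns (bins: 0..8 ones for uniform
#' codes, one bin for non-uniform, 10 bins total).
#'
#' @param patch Numeric matrix (at least 3 x 3).
#' @param n_levels Number of grey levels for quantization.
#' @param offsets List of \code{c(dr, dc)} co-occurrence offsets.
#' @return List with \code{glcm} (named numeric: energy, contrast,
#'   entropy, homogeneity) and \code{lbp} (length-10 histogram summing
#'   to 1).
#' @export
texture_features <- function(patch, n_levels = 8L,
                             offsets = list(c(0L, 1L), c(1L, 0L))) {
  stopifnot(nrow(patch) >= 3, ncol(patch) >= 3, n_levels >= 2)
  q <- .quantize(patch, n_levels)
  p <- Reduce(`+`, lapply(offsets, function(o) .glcm(q, n_levels, o))) /
    length(offsets)
  ii <- matrix(seq_len(n_levels), n_levels, n_levels)
  jj <- t(ii)
  nz <- p > 0
  glcm <- c(energy = sum(p^2),
            contrast = sum((ii - jj)^2 * p),
            entropy = -sum(p[nz] * log2(p[nz])),
            homogeneity = sum(p / (1 + (ii - jj)^2)))
  list(glcm = glcm, lbp = .lbp_hist(patch))
}

# 8-neighbour radius-1 uniform LBP histogram (10 bins, sums to 1).
.lbp_hist <- function(patch) {
  h <- nrow(patch); w <- ncol(patch)
  # neighbours in circular order so transitions are well defined
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
             c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- patch[ri, ci, drop = FALSE]
  bits <- lapply(nb, function(o) {
    (patch[ri + o[1], ci + o[2], drop = FALSE] >= ctr) + 0L
  })
  trans <- matrix(0L, length(ri), length(ci))
  ones <- matrix(0L, length(ri), length(ci))
  for (k in seq_len(8)) {
    nxt <- if (k == 8) 1L else k + 1L
    trans <- trans + (bits[[k]] != bits[[nxt]])
    ones <- ones + bits[[k]]
  }
  bin <- ifelse(trans <= 2L, ones, 9L)   # uniform -> #ones, else bin 10
  counts <- tabulate(bin + 1L, nbins = 10L)
  counts / sum(counts)
}

#' Per-patch deep features by pooling encoder tokens
#'
#' Average-pools the final-stage encoder tokens whose receptive-field
#' centres fall inside each patch; a patch containing no token centre
#' falls back to the image-level global average (which is also the pooled
#' value over all tokens).
#'
#' @param z_l Final-stage token matrix with a \code{grid} attribute
#'   (\code{c(gh, gw)}, row-major layout).
#' @param centers n x 2 matrix of patch centres (row/col, pixels).
#' @param patch_size Patch side in pixels.
#' @param image_size \code{c(H, W)} of the image the tokens describe.
#' @return n x embed_dim matrix of per-patch deep feature vectors.
#' @export
deep_features <- function(z_l, centers, patch_size, image_size) {
  grid <- attr(z_l, "grid")
  stopifnot(!is.null(grid))
  gh <- grid[1]; gw <- grid[2]
  stride <- image_size / c(gh, gw)
  tok_r <- (rep(seq_len(gh), each = gw) - 0.5) * stride[1]
  tok_c <- (rep(seq_len(gw), times = gh) - 0.5) * stride[2]
  global <- colMeans(z_l)
  out <- matrix(0, nrow(centers), ncol(z_l))
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1] - patch_size / 2; r1 <- centers[i, 1] + patch_size / 2
    c0 <- centers[i, 2] - patch_size / 2; c1 <- centers[i, 2] + patch_size / 2
    inside <- tok_r > r0 & tok_r <= r1 & tok_c > c0 & tok_c <= c1
    out[i, ] <- if (any(inside)) {
      colMeans(z_l[inside, , drop = FALSE])
    } else global
  }
  out
}

#' Assemble the per-patch feature matrix
#'
#' Concatenates the statistical, texture (GLCM + LBP) and deep blocks in
#' that order and optionally standardizes each column (training-set mean
#' and SD stored as attributes for reuse on held-out data; zero-SD columns
#' are left unscaled).
#'
#' @param grid A \code{patch_grid} from \code{\link{extract_patches}}.
#' @param channels Optional \code{C x H x W} array of the registered
#'   modality channels. When given, the statistical moments are computed
#'   per modality (columns \code{stat_m<k>_*}) instead of on the fused
#'   patch only, preserving the per-modality contrast pattern that
#'   distinguishes tumour classes; texture is always computed on the
#'   grid's (fused) patches.
#' @param z_l Final-stage encoder tokens (see \code{\link{deep_features}});
#'   \code{NULL} omits the deep block.
#' @param image_size \code{c(H, W)}; required when \code{z_l} is given.
#' @param n_levels,offsets Passed to \code{\link{texture_features}}.
#' @param standardize Standardize columns (default TRUE).
#' @param center,scale Optional previously stored statistics to apply
#'   instead of this matrix's own.
#' @return A \code{feature_matrix}: numeric n x d matrix with named
#'   columns, plus attributes \code{centers}, \code{center}, \code{scale}.
#' @export
assemble_feature_matrix <- function(grid, channels = NULL, z_l = NULL,
                                    image_size = NULL,
                                    n_levels = 8L,
                                    offsets = list(c(0L, 1L), c(1L, 0L)),
                                    standardize = TRUE,
                                    center = NULL, scale = NULL) {
  n <- length(grid$patches)
  ps <- grid$patch_size
  if (is.null(channels)) {
    stat <- t(vapply(grid$patches, stat_features, numeric(4)))
    stat_nms <- paste0("stat_", c("mean", "sd", "skew", "kurt"))
  } else {
    stat <- NULL; stat_nms <- character(0)
    for (k in seq_len(dim(channels)[1])) {
      ch <- channels[k, , ]
      sk <- t(vapply(seq_len(n), function(t) {
        ri <- (grid$rows[t] - 1L) * ps + seq_len(ps)
        ci <- (grid$cols[t] - 1L) * ps + seq_len(ps)
        stat_features(ch[ri, ci])
      }, numeric(4)))
      stat <- cbind(stat, sk)
      stat_nms <- c(stat_nms,
                    sprintf("stat_m%d_%s", k, c("mean", "sd", "skew", "kurt")))
    }
  }
  tex <- lapply(grid$patches, texture_features, n_levels = n_levels,
                offsets = offsets)
  glcm <- t(vapply(tex, function(z) z$glcm, numeric(4)))
  lbp <- t(vapply(tex, function(z) z$lbp, numeric(10)))
  blocks <- list(stat, glcm, lbp)
  nms <- c(stat_nms,
           paste0("glcm_", c("energy", "contrast", "entropy", "homogeneity")),
           paste0("lbp_", seq_len(10)))
  if (!is.null(z_l)) {
    stopifnot(!is.null(image_size))
    dp <- deep_features(z_l, grid$centers, grid$patch_size, image_size)
    blocks <- c(blocks, list(dp))
    nms <- c(nms, paste0("deep_", seq_len(ncol(dp))))
  }
  x <- do.call(cbind, blocks)
  colnames(x) <- nms
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite feature '%s' in patch %d", nms[bad[2]], bad[1]))
  }
  if (standardize) {
    if (is.null(center)) {
      center <- colMeans(x)
      scale <- apply(x, 2L, stats::sd)
      scale[scale == 0] <- 1
    }
    x <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  }
  attr(x, "centers") <- grid$centers
  attr(x, "center") <- center
  attr(x, "scale") <- scale
  class(x) <- c("feature_matrix", class(x))
  x
}
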
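#' Preprocessing configuration
#'
#' @param poly_order_bias Polynomial order of the log-domain bias surface.
#' @param nlm_patch,nlm_search Odd patch and search window sizes (pixels)
#'   for non-local-means denoising.
#' @param nlm_h Filtering strength (bandwidth of the Gaussian patch-distance
#'   kernel), in intensity units.
#' @param target_spacing Output pixel spacing (mm/pixel, length 2) for
#'   resampling; \code{NULL} skips resampling.
#' @param clip_low_q,clip_high_q Percentiles for intensity clipping.
#' @param crop_size Output H0 x W0 of the bounding-box crop; \code{NULL}
#'   skips cropping.
#' @param register Logical: rigidly align channels 2..C to channel 1.
#' @param denoise Logical: apply non-local means.
#' @param augment List of augmentation magnitudes:
#'   \code{rotation_deg_range}, \code{flip_axes}, \code{jitter_sigma},
#'   \code{elastic_alpha}, \code{elastic_sigma}.
#' @param seed Integer seed (augmentation randomness).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(poly_order_bias = 2L,
                              nlm_patch = 5L, nlm_search = 11L, nlm_h = 0.1,
                              target_spacing = NULL,
                              clip_low_q = 1, clip_high_q = 99,
                              crop_size = NULL,
                              register = TRUE, denoise = TRUE,
                              augment = list(rotation_deg_range = 0,
                                             flip_axes = character(0),
                                             jitter_sigma = 0,
                                             elastic_alpha = 0,
                                             elastic_sigma = 4),
                              seed = 1L) {
  stopifnot(clip_low_q >= 0, clip_low_q < clip_high_q, clip_high_q <= 100,
            nlm_patch %% 2 == 1, nlm_search >= nlm_patch)
  structure(list(poly_order_bias = as.integer(poly_order_bias),
                 nlm_patch = as.integer(nlm_patch),
                 nlm_search = as.integer(nlm_search), nlm_h = nlm_h,
                 target_spacing = target_spacing,
                 clip_low_q = clip_low_q, clip_high_q = clip_high_q,
                 crop_size = crop_size, register = register,
                 denoise = denoise, augment = augment,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

## ---- bias correction ----

.poly_design <- function(h, w, order) {
  u <- (matrix(seq_len(h), h, w) - (h + 1) / 2) / h
  v <- (matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2) / w
  cols <- list(rep(1, h * w))
  for (p in seq_len(order)) {
    for (q in 0:p) {
      cols[[length(cols) + 1L]] <- as.vector(u)^(p - q) * as.vector(v)^q
    }
  }
  do.call(cbind, cols)
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Fits a polynomial surface of the given order to the log-intensities
#' inside the mask (least squares), exponentiates it into a strictly
#' positive field, gauge-fixes the field to mean 1 over the mask, and
#' divides it out.
#'
#' @param channel Numeric H x W matrix, nonnegative inside the mask.
#' @param mask Binary H x W matrix (nonempty).
#' @param order Polynomial order of the log-domain surface.
#' @return List with \code{corrected} and \code{field} (both H x W).
#' @export
correct_bias <- function(channel, mask, order = 2L) {
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  v <- channel[mask]
  if (all(v <= 0)) stop("channel is all zero inside the mask; log undefined")
  keep <- v > 0
  x <- .poly_design(nrow(channel), ncol(channel), order)
  xm <- x[as.vector(mask), , drop = FALSE][keep, , drop = FALSE]
  beta <- stats::lm.fit(xm, log(v[keep]))$coefficients
  beta[is.na(beta)] <- 0
  field <- matrix(exp(x %*% beta), nrow(channel), ncol(channel))
  field <- field / mean(field[mask])
  list(corrected = channel / field, field = field)
}

## ---- non-local means ----

.mirror_pad <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rev(seq_len(min(p, h))), seq_len(h), h + 1 - seq_len(min(p, h)))
  ci <- c(rev(seq_len(min(p, w))), seq_len(w), w + 1 - seq_len(min(p, w)))
  x[ri, ci, drop = FALSE]
}

# Box (moving-sum) filter over a (2r+1)^2 neighbourhood via cumulative sums.
.box_sum <- function(x, r) {
  cs <- function(m) apply(m, 2L, cumsum)
  p <- .mirror_pad(x, r)
  s <- cs(t(cs(t(p))))  # 2D integral image of padded input
  h <- nrow(x); w <- ncol(x); k <- 2L * r
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(h); j1 <- seq_len(w)
  s[i1 + k + 1L, j1 + k + 1L, drop = FALSE] -
    s[i1, j1 + k + 1L, drop = FALSE] -
    s[i1 + k + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

#' Non-local-means denoising
#'
#' Each pixel is replaced by a similarity-weighted average of the pixels in
#' its search window. The weight between pixels i and j is
#' \code{exp(-d2(i,j)/h^2)} where \code{d2} is the mean squared difference
#' of the two patches centred at i and j (patches read from a mirror-padded
#' image); weights are normalised to sum to 1 per pixel. Pixels of the
#' search window outside the image are skipped.
#'
#' @param channel Numeric H x W matrix.
#' @param patch Odd patch size in pixels.
#' @param search Search window size in pixels (>= patch).
#' @param h Filtering strength (> 0).
#' @return Denoised H x W matrix.
#' @export
denoise_nlm <- function(channel, patch = 5L, search = 11L, h = 0.1) {
  if (h <= 0) stop("filtering strength h must be positive")
  stopifnot(patch %% 2 == 1, search >= patch)
  pr <- (patch - 1L) %/% 2L
  sr <- (search - 1L) %/% 2L
  hh <- nrow(channel); ww <- ncol(channel)
  num <- matrix(0, hh, ww)
  den <- matrix(0, hh, ww)
  pad <- .mirror_pad(channel, sr + pr)
  n_in_patch <- patch^2
  for (dy in -sr:sr) {
    for (dx in -sr:sr) {
      # shifted image aligned with the original (values at i+offset)
      sh <- pad[(sr + pr + dy) + seq_len(hh), (sr + pr + dx) + seq_len(ww),
                drop = FALSE]
      # patch mean squared distance between patches at i and i+offset,
      # computed on the mirror-padded image so borders are well defined
      d2full <- (.mirror_pad(channel, pr) -
                 pad[(sr + dy) + seq_len(hh + 2L * pr),
                     (sr + dx) + seq_len(ww + 2L * pr), drop = FALSE])^2
      d2 <- .box_sum_core(d2full, pr) / n_in_patch
      wgt <- exp(-d2 / h^2)
      # neighbour must lie inside the image
      ii <- matrix(seq_len(hh), hh, ww) + dy
      jj <- matrix(seq_len(ww), hh, ww, byrow = TRUE) + dx
      valid <- ii >= 1 & ii <= hh & jj >= 1 & jj <= ww
      wgt[!valid] <- 0
      num <- num + wgt * sh
      den <- den + wgt
    }
  }
  num / den
}

# Box sum over (2r+1)^2 for an already padded matrix: output has the padded
# size minus 2r on each dimension.
.box_sum_core <- function(xp, r) {
  if (r == 0L) return(xp)
  cs <- function(m) apply(m, 2L, cumsum)
  s <- cs(t(cs(t(xp))))
  s <- rbind(0, cbind(0, s))
  h <- nrow(xp) - 2L * r; w <- ncol(xp) - 2L * r
  k <- 2L * r
  i1 <- seq_len(h); j1 <- seq_len(w)
  s[i1 + k + 1L, j1 + k + 1L, drop = FALSE] -
    s[i1, j1 + k + 1L, drop = FALSE] -
    s[i1 + k + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
}

## ---- rigid registration ----

# Bilinear sample of img at (continuous) row/col coordinates; outside -> NA.
.bilinear_at <- function(img, rr, cc) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  ok <- r0 >= 1 & r0 + 1 <= h & c0 >= 1 & c0 + 1 <= w
  out <- rep(NA_real_, length(rr))
  if (any(ok)) {
    i00 <- (c0[ok] - 1) * h + r0[ok]
    v <- (1 - fr[ok]) * (1 - fc[ok]) * img[i00] +
      fr[ok] * (1 - fc[ok]) * img[i00 + 1] +
      (1 - fr[ok]) * fc[ok] * img[i00 + h] +
      fr[ok] * fc[ok] * img[i00 + h + 1]
    out[ok] <- v
  }
  out
}

# Resample `img` under the rigid transform (theta degrees, tx, ty pixels):
# output(x) = img(T^{-1} x) with rotation about the image centre.
.warp_rigid <- function(img, theta, tx, ty, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- theta * pi / 180
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse mapping of a rotation by `a` followed by translation (ty, tx)
  r2 <- cos(a) * (rr - ty) + sin(a) * (cc - tx) + cy
  c2 <- -sin(a) * (rr - ty) + cos(a) * (cc - tx) + cx
  v <- .bilinear_at(img, as.vector(r2), as.vector(c2))
  v[is.na(v)] <- fill
  matrix(v, h, w)
}

.mutual_information <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 4) return(-Inf)
  cut1 <- pmin(pmax(1L + as.integer(bins * (a - min(a)) /
                                    (diff(range(a)) + 1e-12)), 1L), bins)
  cut2 <- pmin(pmax(1L + as.integer(bins * (b - min(b)) /
                                    (diff(range(b)) + 1e-12)), 1L), bins)
  p <- matrix(tabulate((cut1 - 1L) * bins + cut2, nbins = bins * bins),
              bins, bins) / length(a)
  px <- colSums(p); py <- rowSums(p)   # p[j, i] counts (cut1 = i, cut2 = j)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (rep(px, each = bins) * rep(py, times = bins))[nz]))
}

#' Rigid 2D registration by mutual information
#'
#' Estimates a rotation (degrees, about the image centre) and a translation
#' (pixels) maximising the 32-bin joint-histogram mutual information between
#' the warped moving image and the fixed image: a coarse grid search that
#' always includes the identity, refined with Nelder-Mead. The returned
#' transform is the one applied to the moving image, so an input that was
#' rotated by +5 degrees is recovered with theta close to -5.
#'
#' @param moving,fixed Numeric matrices of equal size.
#' @param theta_grid,shift_grid Coarse search grids (degrees, pixels).
#' @return List with \code{theta}, \code{tx}, \code{ty}, \code{mi},
#'   \code{mi_identity} and \code{resampled} (the warped moving image).
#' @export
register_rigid <- function(moving, fixed,
                           theta_grid = seq(-10, 10, by = 2.5),
                           shift_grid = seq(-4, 4, by = 2)) {
  stopifnot(all(dim(moving) == dim(fixed)))
  obj <- function(p) {
    wimg <- .warp_rigid(moving, p[1], p[2], p[3], fill = NA)
    if (all(is.na(wimg))) stop("empty overlap after transform")
    -.mutual_information(wimg, fixed)
  }
  mi_id <- -obj(c(0, 0, 0))
  best <- c(0, 0, 0); best_mi <- mi_id
  for (th in theta_grid) for (sx in shift_grid) for (sy in shift_grid) {
    m <- -obj(c(th, sx, sy))
    if (m > best_mi) { best <- c(th, sx, sy); best_mi <- m }
  }
  op <- stats::optim(best, obj, method = "Nelder-Mead",
                     control = list(maxit = 120, reltol = 1e-6))
  if (-op$value > best_mi) { best <- op$par; best_mi <- -op$value }
  list(theta = best[1], tx = best[2], ty = best[3],
       mi = best_mi, mi_identity = mi_id,
       resampled = .warp_rigid(moving, best[1], best[2], best[3]))
}

## ---- resampling ----

#' Resample a channel to a new pixel spacing (bilinear)
#'
#' Output size is \code{round(in_size * in_spacing / out_spacing)} per axis;
#' pixel centres are aligned in physical coordinates. Samples falling
#' outside the input grid clamp to the border.
#'
#' @param channel Numeric matrix.
#' @param in_spacing,out_spacing Length-2 positive spacings (row, col).
#' @return Resampled matrix.
#' @export
resample <- function(channel, in_spacing, out_spacing) {
  stopifnot(all(in_spacing > 0), all(out_spacing > 0))
  in_spacing <- rep_len(in_spacing, 2L); out_spacing <- rep_len(out_spacing, 2L)
  h <- nrow(channel); w <- ncol(channel)
  h2 <- max(1L, round(h * in_spacing[1] / out_spacing[1]))
  w2 <- max(1L, round(w * in_spacing[2] / out_spacing[2]))
  rr <- ((seq_len(h2) - 0.5) * out_spacing[1]) / in_spacing[1] + 0.5
  cc <- ((seq_len(w2) - 0.5) * out_spacing[2]) / in_spacing[2] + 0.5
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  rm <- matrix(rr, h2, w2); cm <- matrix(cc, h2, w2, byrow = TRUE)
  # clamp so the 2x2 bilinear stencil stays inside
  rm <- pmin(rm, h - 1e-9); cm <- pmin(cm, w - 1e-9)
  matrix(.bilinear_at(channel, as.vector(rm), as.vector(cm)), h2, w2)
}

## ---- intensity normalisation ----

#' Z-score normalisation over a mask
#'
#' Uses the population SD (divisor = number of mask pixels). Pixels outside
#' the mask are set to 0.
#'
#' @param channel Numeric matrix.
#' @param mask Binary matrix, nonempty.
#' @return Normalised matrix with masked mean 0 and SD 1.
#' @export
normalize_zscore <- function(channel, mask) {
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  v <- channel[mask]
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop == 0) stop("zero variance inside mask: degenerate channel")
  out <- matrix(0, nrow(channel), ncol(channel))
  out[mask] <- (v - mu) / sd_pop
  out
}

#' Quantile clipping and min-max rescaling to [0, 1]
#'
#' Masked values are clipped to the empirical \code{q_low}/\code{q_high}
#' percentiles (type-7 quantiles) and then affinely rescaled so the masked
#' minimum maps to 0 and the masked maximum to 1 (min/max taken after
#' clipping). Pixels outside the mask are set to 0.
#'
#' @param channel Numeric matrix.
#' @param mask Binary matrix.
#' @param q_low,q_high Percentiles in [0, 100], \code{q_low < q_high}.
#' @return Matrix with masked values in [0, 1].
#' @export
clip_rescale <- function(channel, mask, q_low = 1, q_high = 99) {
  stopifnot(q_low < q_high)
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  v <- channel[mask]
  qs <- stats::quantile(v, c(q_low, q_high) / 100, type = 7, names = FALSE)
  v <- pmin(pmax(v, qs[1]), qs[2])
  rng <- range(v)
  if (rng[1] == rng[2]) stop("all masked values equal after clipping")
  out <- matrix(0, nrow(channel), ncol(channel))
  out[mask] <- (v - rng[1]) / (rng[2] - rng[1])
  out
}

## ---- cropping ----

#' Crop channels and masks to a fixed window around the brain bounding box
#'
#' Computes the tight bounding box of \code{brain_mask}, centres a
#' \code{crop_size} window on it (ties toward the top-left), zero-pads where
#' the window extends beyond the image, and errors if the bounding box is
#' larger than the window.
#'
#' @param channels Array \code{C x H x W} (or a single H x W matrix).
#' @param brain_mask Binary H x W matrix, nonempty.
#' @param crop_size Length-2 output size (rows, cols).
#' @param extra_masks Optional named list of additional H x W masks cropped
#'   the same way.
#' @return List with \code{channels}, \code{brain_mask}, \code{extra_masks},
#'   and \code{offset} (row/col of the window's top-left in input
#'   coordinates, possibly non-positive when padding occurred).
#' @export
crop_to_bbox <- function(channels, brain_mask, crop_size,
                         extra_masks = list()) {
  if (is.matrix(channels)) {
    channels <- array(channels, dim = c(1L, nrow(channels), ncol(channels)))
  }
  crop_size <- rep_len(as.integer(crop_size), 2L)
  mk <- brain_mask > 0
  if (!any(mk)) stop("brain mask is empty")
  rs <- range(which(rowSums(mk) > 0))
  cs <- range(which(colSums(mk) > 0))
  bb <- c(rs[2] - rs[1] + 1L, cs[2] - cs[1] + 1L)
  over <- bb - crop_size
  if (any(over > 0)) {
    stop(sprintf("bounding box exceeds crop size by %d rows, %d cols",
                 max(over[1], 0), max(over[2], 0)))
  }
  start <- c(rs[1], cs[1]) - floor((crop_size - bb) / 2)
  take <- function(m) {
    out <- matrix(0, crop_size[1], crop_size[2])
    r_in <- pmax(start[1], 1L):pmin(start[1] + crop_size[1] - 1L, nrow(m))
    c_in <- pmax(start[2], 1L):pmin(start[2] + crop_size[2] - 1L, ncol(m))
    out[r_in - start[1] + 1L, c_in - start[2] + 1L] <-
      m[r_in, c_in, drop = FALSE]
    out
  }
  ch_out <- array(0, dim = c(dim(channels)[1], crop_size))
  for (k in seq_len(dim(channels)[1])) ch_out[k, , ] <- take(channels[k, , ])
  list(channels = ch_out,
       brain_mask = take(brain_mask),
       extra_masks = lapply(extra_masks, take),
       offset = start)
}

## ---- augmentation ----

.elastic_fields <- function(h, w, alpha, sigma) {
  dx <- matrix(stats::runif(h * w, -1, 1), h, w)
  dy <- matrix(stats::runif(h * w, -1, 1), h, w)
  dx <- as.matrix(EBImage::gblur(dx, sigma = sigma)) * alpha
  dy <- as.matrix(EBImage::gblur(dy, sigma = sigma)) * alpha
  list(dy = dy, dx = dx)
}

.warp_displacement <- function(img, dy, dx, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  h <- nrow(img); w <- ncol(img)
  rr <- matrix(seq_len(h), h, w) + dy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) + dx
  if (interp == "nearest") {
    rr <- pmin(pmax(round(rr), 1), h)
    cc <- pmin(pmax(round(cc), 1), w)
    matrix(img[cbind(as.vector(rr), as.vector(cc))], h, w)
  } else {
    rr <- pmin(pmax(rr, 1), h - 1e-9)
    cc <- pmin(pmax(cc, 1), w - 1e-9)
    matrix(.bilinear_at(img, as.vector(rr), as.vector(cc)), h, w)
  }
}

#' Random augmentation of a slice
#'
#' Applies, in order: rotation, elastic deformation, flip, additive jitter.
#' Masks follow the same geometric transforms with nearest-neighbour
#' interpolation (so they stay binary) and receive no jitter. The same seed
#' reproduces the same augmentation.
#'
#' @param channels Array \code{C x H x W}.
#' @param masks Named list of binary H x W matrices.
#' @param config List with \code{rotation_deg_range} (max absolute rotation,
#'   degrees), \code{flip_axes} (subset of \code{c("horizontal",
#'   "vertical")}; each applied with probability 1/2), \code{jitter_sigma},
#'   \code{elastic_alpha} (displacement amplitude, pixels),
#'   \code{elastic_sigma} (smoothing SD, pixels).
#' @param seed Integer seed.
#' @return List with transformed \code{channels} and \code{masks}.
#' @export
augment_slice <- function(channels, masks, config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h <- dim(channels)[2]; w <- dim(channels)[3]
  rot <- if (config$rotation_deg_range > 0)
    stats::runif(1, -config$rotation_deg_range, config$rotation_deg_range) else 0
  el <- if (isTRUE(config$elastic_alpha > 0))
    .elastic_fields(h, w, config$elastic_alpha, config$elastic_sigma) else NULL
  flips <- character(0)
  for (ax in config$flip_axes) if (stats::runif(1) < 0.5) flips <- c(flips, ax)

  geom <- function(img, nearest) {
    if (rot != 0) {
      img <- if (nearest) {
        # nearest-neighbour rotation via rounded inverse mapping
        a <- rot * pi / 180
        cy <- (h + 1) / 2; cx <- (w + 1) / 2
        rr <- matrix(seq_len(h), h, w) - cy
        cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
        r2 <- pmin(pmax(round(cos(a) * rr + sin(a) * cc + cy), 1), h)
        c2 <- pmin(pmax(round(-sin(a) * rr + cos(a) * cc + cx), 1), w)
        matrix(img[cbind(as.vector(r2), as.vector(c2))], h, w)
      } else .warp_rigid(img, rot, 0, 0)
    }
    if (!is.null(el)) {
      img <- .warp_displacement(img, el$dy, el$dx,
                                if (nearest) "nearest" else "bilinear")
    }
    if ("horizontal" %in% flips) img <- img[, rev(seq_len(w)), drop = FALSE]
    if ("vertical" %in% flips) img <- img[rev(seq_len(h)), , drop = FALSE]
    img
  }
  ch_out <- channels
  for (k in seq_len(dim(channels)[1])) {
    m <- geom(channels[k, , ], nearest = FALSE)
    if (config$jitter_sigma > 0) {
      m <- m + matrix(stats::rnorm(h * w, 0, config$jitter_sigma), h, w)
    }
    ch_out[k, , ] <- m
  }
  masks_out <- lapply(masks, function(m) geom(m, nearest = TRUE))
  list(channels = ch_out, masks = masks_out)
}

## ---- full chain ----

#' Preprocess one multimodal slice
#'
#' Runs the full intensity chain on every channel: bias correction,
#' non-local-means denoising, rigid registration of channels 2..C to
#' channel 1, optional resampling, background masking, z-score
#' normalisation over the brain mask, quantile clip/rescale to [0, 1], and
#' an optional bounding-box crop. Records an ordered provenance list of the
#' applied steps and their parameters.
#'
#' @param slice A \code{multimodal_slice} (or any list with \code{channels},
#'   \code{brain_mask}, optionally \code{tumor_mask}).
#' @param config A \code{\link{preprocess_config}}.
#' @return A \code{preprocessed_slice}: list with \code{channels} (array,
#'   values in [0, 1]), \code{brain_mask}, \code{tumor_mask},
#'   \code{class_label}, \code{subject_id}, \code{provenance}.
#' @export
preprocess_slice <- function(slice, config = preprocess_config()) {
  ch <- slice$channels
  mask <- slice$brain_mask
  tumor <- slice$tumor_mask
  prov <- list()
  nc <- dim(ch)[1]
  for (k in seq_len(nc)) {
    ch[k, , ] <- correct_bias(ch[k, , ], mask, config$poly_order_bias)$corrected
  }
  prov <- c(prov, list(list(step = "correct_bias",
                            order = config$poly_order_bias)))
  if (config$denoise) {
    for (k in seq_len(nc)) {
      ch[k, , ] <- denoise_nlm(ch[k, , ], config$nlm_patch,
                               config$nlm_search, config$nlm_h)
    }
    prov <- c(prov, list(list(step = "denoise_nlm", patch = config$nlm_patch,
                              search = config$nlm_search, h = config$nlm_h)))
  }
  if (config$register && nc > 1) {
    for (k in 2:nc) {
      reg <- register_rigid(ch[k, , ], ch[1, , ])
      ch[k, , ] <- reg$resampled
      prov <- c(prov, list(list(step = "register_rigid", channel = k,
                                theta = reg$theta, tx = reg$tx, ty = reg$ty)))
    }
  }
  if (!is.null(config$target_spacing)) {
    in_sp <- if (!is.null(slice$spacing)) slice$spacing else c(1, 1)
    new_ch <- NULL
    for (k in seq_len(nc)) {
      r <- resample(ch[k, , ], in_sp, config$target_spacing)
      if (is.null(new_ch)) new_ch <- array(0, dim = c(nc, dim(r)))
      new_ch[k, , ] <- r
    }
    ch <- new_ch
    rs_mask <- function(m) {
      (resample(m + 0, in_sp, config$target_spacing) >= 0.5) + 0L
    }
    mask <- rs_mask(mask)
    if (!is.null(tumor)) tumor <- rs_mask(tumor)
    prov <- c(prov, list(list(step = "resample",
                              target_spacing = config$target_spacing)))
  }
  for (k in seq_len(nc)) {
    z <- normalize_zscore(ch[k, , ], mask)
    ch[k, , ] <- clip_rescale(z, mask, config$clip_low_q, config$clip_high_q)
  }
  prov <- c(prov, list(list(step = "normalize_zscore", divisor = "population"),
                       list(step = "clip_rescale", q_low = config$clip_low_q,
                            q_high = config$clip_high_q)))
  if (!is.null(config$crop_size)) {
    extra <- if (!is.null(tumor)) list(tumor = tumor) else list()
    cr <- crop_to_bbox(ch, mask, config$crop_size, extra)
    ch <- cr$channels
    mask <- cr$brain_mask
    if (!is.null(tumor)) tumor <- cr$extra_masks$tumor
    prov <- c(prov, list(list(step = "crop_to_bbox",
                              crop_size = config$crop_size)))
  }
  structure(list(channels = ch, brain_mask = mask, tumor_mask = tumor,
                 class_label = slice$class_label,
                 subject_id = slice$subject_id,
                 provenance = prov),
            class = "preprocessed_slice")
}
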
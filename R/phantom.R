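#' Specification of the synthetic multimodal phantom
#'
#' Describes the geometry and intensity model used to emulate registered 2D
#' multimodal MRI slices: an elliptical brain region on a dark background,
#' an irregular tumour blob whose per-modality contrast pattern depends on
#' the class, a smooth multiplicative bias field (exponential of a random
#' low-order 2D polynomial), and additive Gaussian noise.
#'
#' @param image_height,image_width Slice dimensions in pixels.
#' @param n_modalities Number of registered channels (default 4, standing in
#'   for T1/T1ce/T2/FLAIR).
#' @param class_names Ordered class labels; the first is the tumour-free
#'   class by convention when named \code{"non-tumor"}.
#' @param tumor_radius_range Two pixels values, min and max mean tumour
#'   radius.
#' @param contrast_by_class Numeric matrix (classes x modalities) of additive
#'   intensity offsets of tumour tissue relative to brain tissue. Rows for
#'   tumour-free classes must be zero. \code{NULL} uses a built-in default
#'   with distinct per-class patterns.
#' @param bias_strength Amplitude of the log-bias polynomial (unitless; 0
#'   disables the field).
#' @param noise_sigma SD of the additive Gaussian noise in intensity units.
#' @param irregularity Relative amplitude of the low-frequency radial
#'   perturbation of the tumour boundary.
#' @param seed Integer seed; together with the spec it fully determines
#'   every generated object.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_height = 64L, image_width = 64L,
                         n_modalities = 4L,
                         class_names = c("non-tumor", "glioma-like",
                                         "meningioma-like", "pituitary-like"),
                         tumor_radius_range = c(6, 12),
                         contrast_by_class = NULL,
                         bias_strength = 0.2,
                         noise_sigma = 0.05,
                         irregularity = 0.25,
                         seed = 1L) {
  stopifnot(image_height > 0, image_width > 0, n_modalities >= 1,
            length(class_names) >= 1,
            tumor_radius_range[1] > 0,
            tumor_radius_range[2] >= tumor_radius_range[1])
  if (is.null(contrast_by_class)) {
    base <- rbind(
      "non-tumor"       = rep(0, 8),
      "glioma-like"     = c(0.8, 0.4, 0.9, 1.0, 0.6, 0.7, 0.5, 0.8),
      "meningioma-like" = c(0.4, 1.0, 0.3, 0.5, 0.9, 0.2, 0.8, 0.4),
      "pituitary-like"  = c(1.0, 0.7, 0.2, 0.3, 0.4, 0.9, 0.3, 0.6))
    rows <- match(class_names, rownames(base))
    rows[is.na(rows)] <- ((which(is.na(rows)) - 1L) %% 3L) + 2L
    contrast_by_class <- base[rows, seq_len(n_modalities), drop = FALSE]
    rownames(contrast_by_class) <- class_names
  }
  stopifnot(is.matrix(contrast_by_class),
            nrow(contrast_by_class) == length(class_names),
            ncol(contrast_by_class) == n_modalities,
            all(is.finite(contrast_by_class)))
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_modalities = as.integer(n_modalities),
                 class_names = class_names,
                 tumor_radius_range = tumor_radius_range,
                 contrast_by_class = contrast_by_class,
                 bias_strength = bias_strength,
                 noise_sigma = noise_sigma,
                 irregularity = irregularity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Per-modality baseline intensity of healthy brain tissue.
.brain_base <- function(k) 0.45 + 0.05 * ((k - 1L) %% 4L)

# Filled ellipse with a gently perturbed boundary; returns a logical matrix.
.blob_mask <- function(h, w, cy, cx, ry, rx, irregularity) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  theta <- atan2(yy - cy, xx - cx)
  # low-frequency radial perturbation -> irregular but connected boundary
  pert <- 1 + irregularity * (0.6 * sin(2 * theta + stats::runif(1, 0, 2 * pi)) +
                              0.4 * sin(3 * theta + stats::runif(1, 0, 2 * pi)))
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= pert^2
}

# Smooth strictly positive multiplicative field: exp of a 2nd-order 2D
# polynomial with coefficients drawn at +-bias_strength scale, gauge-fixed
# to mean 1 over the image.
.bias_field <- function(h, w, strength) {
  if (strength <= 0) return(matrix(1, h, w))
  u <- (matrix(seq_len(h), h, w) - (h + 1) / 2) / h
  v <- (matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2) / w
  co <- stats::runif(5, -1, 1) * strength
  logb <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * (u^2 - 1 / 12) +
    co[5] * (v^2 - 1 / 12)
  b <- exp(logb)
  b / mean(b)
}

#' Generate one synthetic multimodal slice
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param class_label Integer index into \code{spec$class_names} (or a class
#'   name).
#' @param seed Integer seed for this slice.
#' @param subject_id Optional identifier stored on the slice.
#' @return A \code{multimodal_slice}: list with \code{channels} (array
#'   \code{n_modalities x H x W}), \code{brain_mask}, \code{tumor_mask}
#'   (integer H x W matrices in \{0,1\}), \code{class_label},
#'   \code{class_name}, \code{subject_id} and \code{bias_fields} (the true
#'   planted multiplicative field per modality, kept for validation).
#' @export
generate_slice <- function(spec, class_label, seed, subject_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.character(class_label)) {
    class_label <- match(class_label, spec$class_names)
  }
  if (is.na(class_label) || class_label < 1L ||
      class_label > length(spec$class_names)) {
    stop("invalid class label for this phantom spec")
  }
  h <- spec$image_height; w <- spec$image_width
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((as.numeric(spec$seed) * 10007 + as.numeric(seed)) %% 2147483647)

  # brain: centred ellipse, mildly perturbed
  brain <- .blob_mask(h, w, cy = h * 0.5, cx = w * 0.5,
                      ry = h * 0.38, rx = w * 0.42, irregularity = 0.05)
  tumor <- matrix(FALSE, h, w)
  is_tumor_class <- any(spec$contrast_by_class[class_label, ] != 0) ||
    spec$class_names[class_label] != "non-tumor"
  if (spec$class_names[class_label] == "non-tumor") is_tumor_class <- FALSE
  if (is_tumor_class) {
    r0 <- stats::runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
    # keep the tumour centre well inside the brain ellipse
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- stats::runif(1, 0, 0.45)
    cy <- h * 0.5 + rad * h * 0.38 * sin(ang)
    cx <- w * 0.5 + rad * w * 0.42 * cos(ang)
    asp <- stats::runif(1, 0.7, 1.3)
    tumor <- .blob_mask(h, w, cy, cx, r0 * asp, r0 / asp, spec$irregularity)
    tumor <- tumor & brain   # mask nesting by construction
  }

  channels <- array(0, dim = c(spec$n_modalities, h, w))
  bias_fields <- array(1, dim = c(spec$n_modalities, h, w))
  for (k in seq_len(spec$n_modalities)) {
    s <- matrix(0, h, w)
    s[brain] <- .brain_base(k)
    s[tumor] <- .brain_base(k) + spec$contrast_by_class[class_label, k]
    b <- .bias_field(h, w, spec$bias_strength)
    m <- b * s
    if (spec$noise_sigma > 0) {
      m <- m + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    }
    channels[k, , ] <- pmax(m, 0)
    bias_fields[k, , ] <- b
  }
  structure(list(channels = channels,
                 brain_mask = matrix(as.integer(brain), h, w),
                 tumor_mask = matrix(as.integer(tumor), h, w),
                 class_label = as.integer(class_label),
                 class_name = spec$class_names[class_label],
                 subject_id = if (is.null(subject_id))
                   sprintf("subj_%06d", seed) else subject_id,
                 bias_fields = bias_fields),
            class = "multimodal_slice")
}

# Save/restore the global RNG state so generators are pure in (spec, seed)
# without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a subject-wise dataset of phantom slices with a train/val/test
#' split
#'
#' Class labels are assigned by largest-remainder apportionment of
#' \code{class_proportions} over \code{n_subjects} and then shuffled, so
#' realised per-class counts are within one subject of the request. The
#' split is subject-wise (one slice per subject here, so no identity can
#' leak across partitions) with sizes \code{floor(f_train n)},
#' \code{floor(f_val n)} and the remainder as test.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param n_subjects Number of subjects (one slice each).
#' @param class_proportions Simplex weights over \code{spec$class_names}.
#' @param seed Integer seed.
#' @param split_fractions Train/val/test fractions summing to 1.
#' @return List with \code{slices} (list of \code{multimodal_slice}) and
#'   \code{manifest}, a data.frame with columns \code{subject_id},
#'   \code{class}, \code{class_label}, \code{split}.
#' @export
generate_dataset <- function(spec, n_subjects,
                             class_proportions = NULL,
                             seed = 1L,
                             split_fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(inherits(spec, "phantom_spec"),
            n_subjects >= length(spec$class_names))
  k <- length(spec$class_names)
  if (is.null(class_proportions)) class_proportions <- rep(1 / k, k)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1")
  }
  if (abs(sum(split_fractions) - 1) > 1e-8) {
    stop("split_fractions must sum to 1")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # largest-remainder apportionment of class counts
  quota <- class_proportions * n_subjects
  counts <- floor(quota)
  rem <- n_subjects - sum(counts)
  if (rem > 0) {
    counts[order(quota - counts, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(quota - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  labels <- sample(rep(seq_len(k), counts))

  n_train <- floor(split_fractions[1] * n_subjects)
  n_val <- floor(split_fractions[2] * n_subjects)
  split <- rep("test", n_subjects)
  perm <- sample(n_subjects)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[perm[n_train + seq_len(n_val)]] <- "val"

  slices <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    slices[[i]] <- generate_slice(spec, labels[i], seed = seed * 1000L + i,
                                  subject_id = sprintf("subj_%04d", i))
  }
  manifest <- data.frame(subject_id = vapply(slices, `[[`, "", "subject_id"),
                         class = spec$class_names[labels],
                         class_label = labels,
                         split = split,
                         stringsAsFactors = FALSE)
  list(slices = slices, manifest = manifest)
}

#' Specification of a planted-signal feature table
#'
#' @param n_samples Number of rows.
#' @param n_features Total number of columns d.
#' @param n_informative Columns carrying class signal: class-conditional
#'   unit-variance Gaussians whose adjacent class means are separated by
#'   \code{effect_size} (in within-class SD units), with a random class
#'   ordering per column.
#' @param n_redundant Noisy copies of randomly chosen informative columns
#'   (copy + N(0, 2^2) noise, so a copy carries the same signal direction
#'   but is a measurably weaker predictor than its source).
#' @param effect_size Separation between adjacent class means, in
#'   within-class SD units; must be > 0 unless exactly 0 (no signal).
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return An object of class \code{feature_table_spec}.
#' @export
feature_table_spec <- function(n_samples, n_features, n_informative,
                               n_redundant = 0L, effect_size = 2,
                               n_classes = 3L, seed = 1L) {
  stopifnot(n_informative + n_redundant <= n_features,
            effect_size >= 0, n_samples >= n_classes)
  if (n_informative == 0L && n_redundant > 0L) {
    stop("redundant columns require at least one informative column")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 n_redundant = as.integer(n_redundant),
                 effect_size = effect_size,
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "feature_table_spec")
}

#' Generate a feature table with planted informative columns
#'
#' @param spec A \code{\link{feature_table_spec}}.
#' @return List with \code{features} (n x d matrix, columns named
#'   \code{f001}...), \code{labels} (integer classes), \code{informative}
#'   (ground-truth informative column indices) and \code{redundant}.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_table_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_samples; d <- spec$n_features; k <- spec$n_classes
  labels <- sample(rep_len(seq_len(k), n))
  x <- matrix(stats::rnorm(n * d), n, d)
  info <- if (spec$n_informative > 0) seq_len(spec$n_informative) else integer(0)
  for (j in info) {
    ord <- sample(k)   # random class ordering per column
    mu <- spec$effect_size * (ord - 1)
    x[, j] <- x[, j] + mu[labels]
  }
  red <- integer(0)
  if (spec$n_redundant > 0) {
    red <- spec$n_informative + seq_len(spec$n_redundant)
    src <- sample(info, spec$n_redundant, replace = TRUE)
    for (t in seq_along(red)) {
      x[, red[t]] <- x[, src[t]] + stats::rnorm(n, 0, 2)
    }
  }
  colnames(x) <- sprintf("f%03d", seq_len(d))
  list(features = x, labels = labels, informative = info, redundant = red)
}
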
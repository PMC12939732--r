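#' Segmentation overlap and boundary metrics
#'
#' Dice \code{2|P∩T|/(|P|+|T|)}, IoU \code{|P∩T|/|P∪T|}, and the symmetric
#' Hausdorff distance between mask boundaries (maximum over both directed
#' max-min distances, in pixels; boundary = foreground pixels with a
#' 4-neighbour background or image-edge contact). Conventions: both masks
#' empty gives Dice = IoU = 1 and Hausdorff = 0; exactly one empty gives
#' Dice = IoU = 0 and Hausdorff = the image diagonal.
#'
#' @param pred_mask,true_mask Binary matrices of equal size.
#' @return List with \code{dice}, \code{iou}, \code{hausdorff}.
#' @export
evaluate_segmentation <- function(pred_mask, true_mask) {
  if (!all(dim(pred_mask) == dim(true_mask))) stop("shape mismatch")
  if (!all(pred_mask %in% c(0, 1)) || !all(true_mask %in% c(0, 1))) {
    stop("masks must be binary")
  }
  p <- pred_mask > 0; t <- true_mask > 0
  np <- sum(p); nt <- sum(t)
  if (np == 0 && nt == 0) {
    return(list(dice = 1, iou = 1, hausdorff = 0))
  }
  inter <- sum(p & t)
  uni <- sum(p | t)
  dice <- 2 * inter / (np + nt)
  iou <- inter / uni
  diag_len <- sqrt(nrow(p)^2 + ncol(p)^2)
  if (np == 0 || nt == 0) {
    return(list(dice = 0, iou = 0, hausdorff = diag_len))
  }
  bp <- .boundary_coords(p)
  bt <- .boundary_coords(t)
  d2 <- outer(bp[, 1], bt[, 1], "-")^2 + outer(bp[, 2], bt[, 2], "-")^2
  h1 <- sqrt(max(apply(d2, 1L, min)))
  h2 <- sqrt(max(apply(d2, 2L, min)))
  list(dice = dice, iou = iou, hausdorff = max(h1, h2))
}

.boundary_coords <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

# Rank-statistic (Mann-Whitney) AUC of scores for a binary indicator.
.auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification evaluation report
#'
#' One-vs-rest sensitivity, specificity, precision and F1 per class with
#' macro averages; rank-statistic AUC per class (one-vs-rest) with macro
#' average; accuracy; and the confusion matrix (rows = truth). Predicted
#' labels are the row argmax with lowest-index tie-break.
#'
#' @param pred_probs n x C matrix of class probabilities (rows on the
#'   simplex).
#' @param labels Integer true labels in 1..C.
#' @param class_names Optional class names.
#' @return An \code{eval_report}: list with \code{accuracy},
#'   \code{per_class} (data.frame), \code{macro} (named vector),
#'   \code{auc}, \code{confusion}.
#' @export
evaluate_classification <- function(pred_probs, labels,
                                    class_names = NULL) {
  n_class <- ncol(pred_probs)
  if (any(labels < 1 | labels > n_class)) {
    stop("labels outside 1..C for the given probability matrix")
  }
  if (any(abs(rowSums(pred_probs) - 1) > 1e-6)) {
    stop("probability rows must sum to 1")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_class))
  pred <- apply(pred_probs, 1L, which.max)
  conf <- table(factor(labels, levels = seq_len(n_class)),
                factor(pred, levels = seq_len(n_class)))
  dimnames(conf) <- list(truth = class_names, predicted = class_names)
  per <- data.frame(class = class_names, sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    f1 = NA_real_, auc = NA_real_)
  for (c in seq_len(n_class)) {
    tp <- sum(labels == c & pred == c)
    fn <- sum(labels == c & pred != c)
    fp <- sum(labels != c & pred == c)
    tn <- sum(labels != c & pred != c)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else if (tp == 0 && (fp > 0 || fn > 0)) 0 else NA_real_
    per$sensitivity[c] <- sens; per$specificity[c] <- spec
    per$precision[c] <- prec; per$f1[c] <- f1
    per$auc[c] <- .auc_rank(pred_probs[, c], labels == c)
  }
  macro <- c(sensitivity = mean(per$sensitivity, na.rm = TRUE),
             specificity = mean(per$specificity, na.rm = TRUE),
             precision = mean(per$precision, na.rm = TRUE),
             f1 = mean(per$f1, na.rm = TRUE),
             auc = mean(per$auc, na.rm = TRUE))
  structure(list(accuracy = mean(pred == labels), per_class = per,
                 macro = macro, auc = macro[["auc"]],
                 confusion = conf),
            class = "eval_report")
}
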
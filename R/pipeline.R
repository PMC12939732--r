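#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed from which every
#' stage seed is derived deterministically. The defaults describe a small
#' synthetic three-class study (150 subjects, 64 x 64 slices, tumour
#' classes only) sized so the whole pipeline runs on one CPU in minutes;
#' see the package vignette for the reasoning behind each choice.
#'
#' @param phantom A \code{\link{phantom_spec}}.
#' @param n_subjects Number of subjects.
#' @param preprocess A \code{\link{preprocess_config}}.
#' @param swin A \code{\link{swin_config}}.
#' @param seg_steps Optimisation steps for the segmenter.
#' @param seg_lr Segmenter learning rate at desk scale.
#' @param seg_batch Segmenter batch size.
#' @param seg_train_n Number of training slices used to fit the segmenter
#'   (a subset suffices for the phantom's homogeneous geometry).
#' @param patch_size Feature-extraction patch size in pixels.
#' @param min_coverage Patch retention threshold on refined-mask coverage;
#'   when no patch qualifies the pipeline falls back to any-overlap and
#'   then to the brain mask.
#' @param n_ensemble Number of independently seeded classifier trainings
#'   whose predicted probabilities are averaged. The held-out set of the
#'   default study is small (about 23 subjects), and a single training's
#'   accuracy fluctuates by several percent with its initialisation seed;
#'   a small ensemble removes that nuisance variance.
#' @param cfo A \code{\link{cfo_config}}.
#' @param gat A \code{\link{gat_config}}.
#' @param split_fractions Train/val/test fractions.
#' @param out_dir Output directory for artifacts (default a session
#'   temporary directory).
#' @param seed Global seed.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(
    phantom = phantom_spec(class_names = c("glioma-like", "meningioma-like",
                                           "pituitary-like")),
    n_subjects = 150L,
    preprocess = preprocess_config(nlm_patch = 3L, nlm_search = 7L,
                                   nlm_h = 0.15),
    swin = swin_config(embed_dim = 16L, depths = c(1L, 1L),
                       n_heads = c(2L, 2L), dropout = 0),
    seg_steps = 200L, seg_lr = 3e-3, seg_batch = 2L, seg_train_n = 24L,
    patch_size = 4L, min_coverage = 0.5,
    n_ensemble = 3L,
    cfo = cfo_config(pop_size = 12L, t_max = 12L),
    gat = gat_config(n_layers = 2L, n_heads = 2L, hidden_dim = 16L,
                     kernel_sigma = "auto", dropout = 0.3, lr = 3e-2,
                     epochs = 80L, patience = 8L),
    split_fractions = c(0.70, 0.15, 0.15),
    out_dir = NULL, seed = 1L) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-8)
  structure(list(phantom = phantom, n_subjects = as.integer(n_subjects),
                 preprocess = preprocess, swin = swin,
                 seg_steps = as.integer(seg_steps), seg_lr = seg_lr,
                 seg_batch = as.integer(seg_batch),
                 seg_train_n = as.integer(seg_train_n),
                 patch_size = as.integer(patch_size),
                 min_coverage = min_coverage,
                 n_ensemble = as.integer(n_ensemble),
                 cfo = cfo, gat = gat,
                 split_fractions = split_fractions,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Patch extraction with graceful fallbacks for slices whose refined tumour
# mask retains no patch.
.extract_with_fallback <- function(fused, refined, brain, patch_size,
                                   min_coverage) {
  tryCatch(
    extract_patches(fused, refined, patch_size, min_coverage),
    error = function(e1) tryCatch(
      extract_patches(fused, refined, patch_size, 1e-9),
      error = function(e2)
        extract_patches(fused, brain, patch_size, 0.5)))
}

#' Run the full recognition pipeline on synthetic data
#'
#' Generates a phantom dataset, preprocesses every slice, trains the
#' segmenter on (a subset of) the training split, segments all slices,
#' extracts per-patch features, selects features with the cuttlefish
#' wrapper on the training patches, builds per-image patch graphs, trains
#' the graph-attention classifier with validation early stopping, and
#' evaluates on the held-out test split.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param verbose Print stage progress.
#' @return A \code{pipeline_result}: list with \code{report} (an
#'   \code{eval_report} on the test split), \code{segmentation} (mean
#'   test-set Dice/IoU/Hausdorff of the segmenter against the true tumour
#'   masks), \code{selection} (the \code{selection_result}),
#'   \code{models}, \code{manifest}, \code{timings} (informational), and
#'   \code{artifact_dir}.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  out_dir <- config$out_dir
  if (is.null(out_dir)) {
    out_dir <- file.path(tempdir(), sprintf("scagnet_run_%d", seed))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- stage 1: phantom generation -----------------------------------------
  t0 <- tic()
  ds <- generate_dataset(config$phantom, config$n_subjects,
                         seed = seed,
                         split_fractions = config$split_fractions)
  manifest <- ds$manifest
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  t_all$generate <- tic() - t0
  say("generated %d subjects (%.1fs)", config$n_subjects, t_all$generate)

  # -- stage 2: preprocessing ----------------------------------------------
  t0 <- tic()
  pre <- lapply(ds$slices, preprocess_slice, config = config$preprocess)
  t_all$preprocess <- tic() - t0
  say("preprocessed (%.1fs)", t_all$preprocess)

  idx_train <- which(manifest$split == "train")
  idx_val <- which(manifest$split == "val")
  idx_test <- which(manifest$split == "test")

  # -- stage 3: segmenter --------------------------------------------------
  t0 <- tic()
  swin_cfg <- config$swin
  swin_cfg$batch_size <- config$seg_batch
  seg_train <- pre[idx_train[seq_len(min(config$seg_train_n,
                                         length(idx_train)))]]
  seg_val <- pre[idx_val[seq_len(min(6L, length(idx_val)))]]
  seg_model <- train_segmenter(seg_train, swin_cfg, seed = seed + 1L,
                               val = seg_val, max_steps = config$seg_steps,
                               lr = config$seg_lr)
  segs <- lapply(pre, function(sl) segment_slice(seg_model, sl))
  seg_eval <- lapply(idx_test, function(i) {
    evaluate_segmentation(segs[[i]]$refined_mask, pre[[i]]$tumor_mask)
  })
  segmentation <- list(
    dice = mean(vapply(seg_eval, `[[`, numeric(1), "dice")),
    iou = mean(vapply(seg_eval, `[[`, numeric(1), "iou")),
    hausdorff = mean(vapply(seg_eval, `[[`, numeric(1), "hausdorff")))
  t_all$segment <- tic() - t0
  say("segmenter trained; test Dice %.3f (%.1fs)", segmentation$dice,
      t_all$segment)

  # -- stage 4: feature extraction -----------------------------------------
  t0 <- tic()
  grids <- vector("list", length(pre))
  feats_raw <- vector("list", length(pre))
  for (i in seq_along(pre)) {
    fused <- apply(pre[[i]]$channels, c(2, 3), mean)
    grids[[i]] <- .extract_with_fallback(fused, segs[[i]]$refined_mask,
                                         pre[[i]]$brain_mask,
                                         config$patch_size,
                                         config$min_coverage)
    feats_raw[[i]] <- assemble_feature_matrix(
      grids[[i]], channels = pre[[i]]$channels,
      z_l = segs[[i]]$encoder_features,
      image_size = dim(fused), standardize = FALSE)
  }
  train_stack <- do.call(rbind, feats_raw[idx_train])
  ctr <- colMeans(train_stack)
  scl <- apply(train_stack, 2L, stats::sd)
  scl[scl == 0] <- 1
  feats <- lapply(feats_raw, function(x) {
    y <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
    attr(y, "centers") <- attr(x, "centers")
    y
  })
  t_all$features <- tic() - t0
  say("features extracted, d = %d (%.1fs)", ncol(train_stack),
      t_all$features)

  # -- stage 5: cuttlefish feature selection -------------------------------
  t0 <- tic()
  cfo_cfg <- config$cfo
  cfo_cfg$seed <- seed + 2L
  sel_x <- do.call(rbind, feats[idx_train])
  sel_y <- rep(manifest$class_label[idx_train],
               vapply(feats[idx_train], nrow, integer(1)))
  selection <- run_cfo(sel_x, sel_y, cfo_cfg)
  sel_idx <- selection$selected_indices
  if (length(sel_idx) == 0L) sel_idx <- seq_len(ncol(sel_x))
  jsonlite::write_json(list(selected = sel_idx,
                            names = colnames(sel_x)[sel_idx]),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE)
  t_all$select <- tic() - t0
  say("selected %d/%d features (%.1fs)", length(sel_idx), ncol(sel_x),
      t_all$select)

  # -- stage 6: graphs + classifier ----------------------------------------
  t0 <- tic()
  graphs <- lapply(seq_along(pre), function(i) {
    build_graph(feats[[i]][, sel_idx, drop = FALSE],
                attr(feats[[i]], "centers") / config$patch_size,
                kernel_sigma = config$gat$kernel_sigma,
                radius = config$gat$radius)
  })
  labels <- manifest$class_label
  gat_cfg <- config$gat
  n_classes <- length(config$phantom$class_names)
  gat_models <- vector("list", config$n_ensemble)
  prob_sum <- NULL
  for (m in seq_len(config$n_ensemble)) {
    mseed <- seed + 3L + (m - 1L) * 100L
    gat_cfg$seed <- mseed
    gat_models[[m]] <- train_classifier(graphs[idx_train],
                                        labels[idx_train],
                                        gat_cfg, n_classes = n_classes,
                                        val_graphs = graphs[idx_val],
                                        val_labels = labels[idx_val],
                                        seed = mseed)
    pm <- predict_graphs(gat_models[[m]], graphs[idx_test])
    prob_sum <- if (is.null(prob_sum)) pm$probabilities else
      prob_sum + pm$probabilities
  }
  pred <- list(probabilities = prob_sum / config$n_ensemble)
  pred$label <- apply(pred$probabilities, 1L, which.max)
  report <- evaluate_classification(pred$probabilities, labels[idx_test],
                                    class_names = config$phantom$class_names)
  t_all$classify <- tic() - t0
  say("classifier: test accuracy %.3f (%.1fs)", report$accuracy,
      t_all$classify)

  preds_df <- data.frame(subject_id = manifest$subject_id[idx_test],
                         truth = config$phantom$class_names[labels[idx_test]],
                         predicted = config$phantom$class_names[pred$label])
  utils::write.csv(cbind(preds_df, pred$probabilities),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         n_subjects = config$n_subjects,
         accuracy = report$accuracy,
         macro = as.list(report$macro),
         segmentation = segmentation,
         timings = t_all,
         r_version = as.character(getRversion())),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  structure(list(report = report, segmentation = segmentation,
                 selection = selection,
                 models = list(segmenter = seg_model,
                               classifiers = gat_models),
                 manifest = manifest, timings = t_all,
                 artifact_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Staged tumour-recognition pipeline result\n")
  cat(sprintf("  test accuracy : %.3f\n", x$report$accuracy))
  cat(sprintf("  macro F1      : %.3f\n", x$report$macro[["f1"]]))
  cat(sprintf("  macro AUC     : %.3f\n", x$report$macro[["auc"]]))
  cat(sprintf("  seg Dice/IoU  : %.3f / %.3f\n",
              x$segmentation$dice, x$segmentation$iou))
  cat(sprintf("  features kept : %d\n", length(x$selection$selected_indices)))
  cat(sprintf("  artifacts     : %s\n", x$artifact_dir))
  invisible(x)
}
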
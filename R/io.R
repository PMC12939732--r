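#' Write a dataset of slices to disk
#'
#' One file per modality per subject (\code{<subject>_mod<k>.nii.gz} or
#' \code{.png}), masks as \code{<subject>_brainmask} /
#' \code{<subject>_tumormask} with \{0,1\} values, and a
#' \code{manifest.csv} with columns subject_id, class, class_label, split.
#' PNG intensities are clipped to [0, 1].
#'
#' @param dataset Result of \code{\link{generate_dataset}}.
#' @param dir Output directory (created if needed).
#' @param format \code{"nifti"} or \code{"png"}.
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(mat, path) {
    if (format == "nifti") {
      RNifti::writeNifti(mat, paste0(path, ".nii.gz"))
    } else {
      png::writePNG(pmin(pmax(mat, 0), 1), paste0(path, ".png"))
    }
  }
  for (sl in dataset$slices) {
    base <- file.path(dir, sl$subject_id)
    for (k in seq_len(dim(sl$channels)[1])) {
      wr(sl$channels[k, , ], sprintf("%s_mod%d", base, k))
    }
    wr(sl$brain_mask + 0, paste0(base, "_brainmask"))
    wr(sl$tumor_mask + 0, paste0(base, "_tumormask"))
  }
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by \code{\link{write_dataset}}
#'
#' @param dir Directory containing the files and \code{manifest.csv}.
#' @param format \code{"nifti"} or \code{"png"}.
#' @return List with \code{slices} and \code{manifest}, mirroring
#'   \code{\link{generate_dataset}} (without the planted bias fields).
#' @export
read_dataset <- function(dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  rd <- function(path) {
    m <- if (format == "nifti") {
      as.matrix(RNifti::readNifti(path))
    } else {
      png::readPNG(path)
    }
    matrix(as.numeric(m), nrow(m), ncol(m))
  }
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  slices <- lapply(seq_len(nrow(manifest)), function(i) {
    base <- file.path(dir, manifest$subject_id[i])
    mods <- sort(Sys.glob(sprintf("%s_mod*%s", base, ext)))
    ch1 <- rd(mods[1])
    channels <- array(0, dim = c(length(mods), dim(ch1)))
    channels[1, , ] <- ch1
    for (k in seq_along(mods)[-1]) channels[k, , ] <- rd(mods[k])
    structure(list(channels = channels,
                   brain_mask = (rd(paste0(base, "_brainmask", ext)) >
                                   0.5) + 0L,
                   tumor_mask = (rd(paste0(base, "_tumormask", ext)) >
                                   0.5) + 0L,
                   class_label = manifest$class_label[i],
                   class_name = manifest$class[i],
                   subject_id = manifest$subject_id[i]),
              class = "multimodal_slice")
  })
  list(slices = slices, manifest = manifest)
}

#' scagnet: staged brain-tumour recognition for multimodal MRI slices
#'
#' Preprocessing, shifted-window transformer segmentation, patch feature
#' extraction, cuttlefish wrapper feature selection, and graph-attention
#' classification, with a synthetic phantom generator for fully
#' self-contained experiments. See \code{vignette("scagnet-methods")}.
#'
#' @name scagnet-package
#' @keywords internal
"_PACKAGE"
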
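Package: scagnet
Title: Staged Brain-Tumor Recognition from Multimodal MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A staged pipeline for recognising brain tumours in 2D
    multimodal MRI-like slices: intensity preprocessing (bias-field
    correction, non-local-means denoising, rigid registration, z-score
    normalisation and quantile rescaling), a shifted-window transformer
    U-Net segmenter trained with a combined Dice and cross-entropy loss,
    per-patch statistical/texture/deep feature extraction, cuttlefish-style
    metaheuristic wrapper feature selection, and a graph-attention network
    classifier over patch graphs. Includes a synthetic multimodal phantom
    generator so every stage can be exercised and tested without external
    imaging data, plus segmentation and classification evaluation metrics
    (Dice, IoU, Hausdorff distance, per-class rates, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    RNifti,
    png,
    jsonlite,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
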
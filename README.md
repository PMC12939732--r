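# scagnet

Staged brain-tumour recognition for 2D multimodal MRI-like slices, built
as a fully self-contained R package: every stage runs and is tested on a
synthetic multimodal phantom, so no external imaging data is required.

The pipeline implements five stages:

1. **Preprocessing** — log-domain polynomial bias-field correction,
   non-local-means denoising, rigid registration by mutual information,
   bilinear resampling, z-score normalisation over the brain mask
   (population SD), 1%/99% quantile clipping with min–max rescaling to
   [0, 1], bounding-box cropping, and seeded augmentation
   (rotation → elastic → flip → jitter).
2. **Segmentation** — a shifted-window transformer U-Net: P×P patch
   embedding, pre-norm window-attention blocks
   `Z_l = SW-MSA(LN(Z_{l−1})) + Z_{l−1}` with learned relative-position
   bias and alternating half-window shifts, patch merging between stages,
   a skip-connected decoder with a sigmoid 1×1 head, thresholding at
   τ ∈ [0.4, 0.6], and morphological refinement (erode, then close, 3×3).
   Training minimises `λ₁(1 − Dice) + λ₂ BCE` with Adam.
3. **Patch features** — per-patch statistical moments (μ, σ, skewness,
   kurtosis), GLCM texture (Energy, Contrast, Entropy, Homogeneity) with
   a uniform-LBP histogram, and deep features pooled from the final
   encoder stage: `f_u = [f_stat ‖ f_tex ‖ f_deep]`.
4. **Feature selection** — a cuttlefish-style metaheuristic over
   continuous candidates `s ∈ [0,1]^d`, binarized by
   `b_j = 1 ⇔ sigmoid(s_j) < τ`, with reflection/absorption updates
   `s ← s + α₁ r₁ ⊙ (s_best − s) + β₁ r₂` and
   `s ← s + α₂ r₃ ⊙ (s̄ − s) + β₂ N(0, σ²)`, a 5-NN wrapper fitness
   `J = α(1 − Acc) + β·|s|/d`, elitism, and a stall-window convergence
   rule.
5. **Classification** — per-image patch graphs with Gaussian-kernel
   adjacency `A_ij = exp(−‖f_i − f_j‖²/σ²)` under a spatial radius
   cutoff, symmetric normalization `D^{−1/2}(A + I)D^{−1/2}`, multi-head
   graph-attention layers, attention pooling
   `z = Σ β_i h_i, β = softmax(qᵀ tanh(W_g h))`, and a softmax head with
   L2-regularised cross-entropy.

Evaluation covers Dice, IoU and boundary Hausdorff distance for masks,
and per-class/macro sensitivity, specificity, precision, F1 and
rank-statistic AUC for classification.

Both networks run on a small tape-based reverse-mode autodiff engine
included in the package (`R/autodiff.R`), so there is no deep-learning
framework dependency; gradients are validated against numerical
differentiation in the test-suite.

## A worked example

```r
library(scagnet)

res <- run_pipeline(pipeline_config(seed = 1), verbose = TRUE)
print(res)
```

This generates 150 synthetic subjects (three tumour classes, 64×64
four-modality slices), preprocesses them, trains the segmenter, extracts
and selects features, trains the graph classifier, and evaluates on the
held-out subject-wise test split. On one CPU it takes a few minutes and
prints:

```
Staged tumour-recognition pipeline result
  test accuracy : 0.913
  macro F1      : 0.911
  macro AUC     : 0.988
  seg Dice/IoU  : 0.822 / 0.700
  features kept : 15
  artifacts     : /tmp/.../scagnet_run_1
```

`test accuracy` is the held-out classification accuracy over the 23 test
subjects (chance ≈ 0.33); `seg Dice/IoU` compare the refined predicted
tumour masks with the phantom's ground truth; `features kept` is the
size of the selected feature subset out of 62 extracted columns. The
artifact directory holds the subject manifest, selection indices,
per-subject predictions and a JSON report.

A thin command-line front end is installed with the package:

```sh
scagnet generate --out phantoms/ --n 20 --seed 1 --format nifti
scagnet run-all  --seed 1
scagnet evaluate --pred pred_mask.png --truth true_mask.png
```

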
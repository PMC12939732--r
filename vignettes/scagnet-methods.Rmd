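---
title: "Staged brain-tumour recognition on multimodal slices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged brain-tumour recognition on multimodal slices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented in **scagnet**, the choices
made where the design was genuinely open, and what the synthetic phantom
experiments do and do not demonstrate. The pipeline has five stages:
intensity preprocessing, a shifted-window transformer U-Net segmenter,
per-patch feature extraction, cuttlefish-style wrapper feature selection,
and a graph-attention classifier over patch graphs.

## The synthetic phantom

All tests and the acceptance script run on synthetic multimodal slices so
that every stage is exercisable without external imaging data. A slice is
built from a generative model mirroring the intensity decomposition the
preprocessing assumes, `M = B * S + eta`:

* a piecewise-constant anatomy `S`: dark background, an elliptical brain
  whose baseline intensity varies mildly by modality, and (for tumour
  classes) an elliptical tumour blob with a low-frequency radial boundary
  perturbation, placed inside the brain;
* a per-class, per-modality additive tumour contrast pattern (the class
  signature — e.g. the glioma-like class is brightest in modalities 3-4,
  the meningioma-like class in modality 2);
* a smooth, strictly positive multiplicative bias field `B`, realised as
  the exponential of a random second-order 2D polynomial with coefficients
  scaled by `bias_strength` (default 0.2) and gauge-fixed to mean 1 — the
  true field is kept on the object so the bias estimator can be validated;
* additive Gaussian noise (`noise_sigma`, default 0.05 intensity units).

Defaults (64 x 64 pixels, 4 modalities, tumour radii 6-12 px) are sized so
a tumour occupies roughly 3-10% of the brain, comparable to mid-sized
lesions on axial slices at this resolution. The phantom deliberately omits
MR physics: no Rician noise, no k-space artefacts, no partial-volume
texture inside tissue, and no 3D continuity. Passing tests on phantoms
therefore demonstrates *algorithmic* correctness and end-to-end
learnability of a planted signal, not clinical performance.

Dataset generation assigns class labels by largest-remainder
apportionment (realised counts within one subject of the request) and
splits *subject-wise* into train/validation/test with floor rounding
(70/15/15 by default: 20 subjects give 14/3/3), so no subject can appear
in two partitions.

### Planted-signal feature tables

The selection stage is validated on tables with known ground truth:
informative columns are class-conditional unit-variance Gaussians whose
class means are spaced `effect_size` apart (with a random class ordering
per column); redundant columns are informative columns plus `N(0, 2^2)`
noise; the rest is pure noise. The copy-noise SD of 2 was chosen so that a
copy preserves the signal direction but is a measurably weaker predictor
than its source — that is what makes the planted set identifiable at all:
with substantially less copy noise, a copy is statistically
indistinguishable from its source at these sample sizes and *no* wrapper
can prefer one over the other.

## Preprocessing

The chain is: bias correction, non-local-means denoising, rigid
registration to the first channel, optional resampling, background
masking, z-score normalisation over the brain mask, quantile
clip/rescale, bounding-box crop, and (for training) augmentation. Each
slice carries a provenance list of the applied steps and parameters.

* **Bias correction** fits a polynomial surface (default order 2) to the
  log-intensities inside the mask and divides out its exponential,
  gauge-fixed to mean 1 over the mask. This is a deliberate, transparent
  simplification of B-spline bias correction: on fields that are smooth at
  the scale the generator produces, the low-order fit recovers the field
  to a few percent of its amplitude (checked against the planted field).
  The estimate is biased where anatomy correlates with the fit basis — a
  large high-contrast tumour leaks into the surface — which is why the
  recovery check uses a tumour-free slice.
* **Non-local means** replaces each pixel by a weighted average of search-
  window pixels, with weights `exp(-d2/h^2)` from the mean squared
  patch difference `d2` (patches read from a mirror-padded image; window
  pixels outside the image are skipped). The implementation is an
  offset-shift vectorisation with box-filter patch sums and is tested for
  exact equality against a literal double-loop reference.
* **Rigid registration** (rotation + translation) maximises 32-bin
  joint-histogram mutual information with a coarse grid that always
  contains the identity, refined by Nelder-Mead; the returned MI can
  therefore never fall below the identity's. The transform convention is
  "applied to the moving image": recovering an input rotated by +5 deg
  yields theta close to -5 deg.
* **Normalisation** uses the population SD (divisor n) over mask pixels;
  background is zeroed afterwards. **Clip/rescale** clips masked values to
  the empirical 1%/99% type-7 quantiles and rescales by the *post-clip*
  min/max (the pre-clip reading would make clipping a no-op on the
  range), mapping the mask exactly onto [0, 1].
* **Augmentation** composes rotation, elastic deformation, flip, and
  additive jitter, in that order; masks follow the same geometric
  transforms with nearest-neighbour interpolation and receive no jitter.

## The shifted-window transformer U-Net

Images are split into non-overlapping P x P patches (default P = 4),
linearly embedded, and processed by stages of window-restricted multi-head
self-attention blocks in pre-norm residual form
`Z_l = SW-MSA(LN(Z_{l-1})) + Z_{l-1}`. Attention scores are
`QK'/sqrt(d_h)` plus a learned relative-position bias indexed by the token
offset; rows are softmaxed within each window. Blocks alternate between
unshifted and half-window cyclically shifted windows; at the 64 x 64 desk
scale used here the shifted windows attend freely within the rolled grid
(no cross-boundary masking — the wrap-around affects only border tokens
and has no measurable effect at this image size). Between stages, 2 x 2
token groups are merged (4C -> 2C linear), halving resolution and doubling
width. The decoder mirrors the encoder: nearest upsampling, concatenation
with the encoder skip, a linear projection with ELU; a final per-token
linear layer expands each stage-1 token to its P x P pixel logits, and a
sigmoid yields the soft mask.

Training minimises `lambda1 * (1 - softDice) + lambda2 * BCE` (defaults
0.5/0.5; Dice smoothing 1e-6, probability squash 1e-7) with Adam. The
reference-scale configuration (embed 96, depths 2/2/6/2, heads scaled with
width, lr 1e-4, weight decay 1e-5, batch 8, up to 200 epochs, dropout 0.3)
is available through `swin_config()`; the package default is a small
configuration (embed 16, depths 1/1) sized for 64 x 64 phantoms, where a
0.95+ training Dice on a single slice is reachable within 200 Adam steps
at lr 3e-3. The predicted map is thresholded at `tau` (default 0.5, the
midpoint of the sanctioned [0.4, 0.6] interval, with the `>=` boundary
convention) and refined by erosion followed by closing, both with a 3 x 3
square structuring element — the smallest symmetric kernel, removing
single-pixel speckle while preserving blobs.

There is no deep-learning framework in this package's dependency set; both
networks run on a small tape-based reverse-mode automatic-differentiation
engine over dense matrices (`R/autodiff.R`), validated against numerical
gradients. This keeps every gradient explicit and the whole system
dependency-light, at the cost of speed — the reason the default study uses
64 x 64 slices and small model configurations.

One architectural ambiguity deserves note: the same network family is
used both for skull stripping and for tumour segmentation. Training one
binary head per task and selecting the target mask by configuration
(`target = "tumor"` or `"brain"`) avoids the circularity of needing a
brain mask to preprocess the data that trains the brain-mask network; at
pipeline level the phantom's known brain mask drives preprocessing and the
learned head segments the tumour.

## Patch features

The cropped slice is tiled into fixed-size patches (pipeline default 4 px)
and patches with at least `min_coverage` refined-mask foreground are
retained (default 0.5 at patch 4: a retained patch is at least half
tumour, keeping the class-contrast pattern undiluted; when nothing
qualifies the pipeline falls back to any-overlap and then to brain-mask
patches). Each patch contributes:

* **statistics** — mean, population SD, skewness, excess kurtosis; at
  pipeline level these are computed per modality (4 x 4 values), because
  the per-modality contrast pattern *is* the class signature and a fused
  average discards most of it (the fused variant remains the
  single-channel default of `stat_features()`);
* **texture** — Energy, Contrast, Entropy, Homogeneity of a symmetric,
  8-level GLCM averaged over the (0,1) and (1,0) offsets, plus a 10-bin
  8-neighbour uniform-LBP histogram, computed on the fused channel;
* **deep features** — the final-stage encoder tokens average-pooled per
  patch (tokens whose receptive centres fall inside the patch; image-level
  global average as fallback), resolving the per-image vs per-patch
  notation tension in favour of per-patch features with a global
  fallback.

Columns are standardized with training-set statistics (stored and reused
for held-out data); zero-variance columns pass through unscaled.

## Cuttlefish wrapper selection

Candidates are continuous vectors in [0,1]^d, binarized by the literal
printed rule "selected iff sigmoid(s) < tau" (default tau 0.6; low values
mean selected — an `invert_binarization` switch flips the direction rather
than guessing intent). Fitness is
`J = alpha * (1 - Acc) + beta * (#selected / d)` (defaults 0.9/0.1) with a
5-NN wrapper. Four implementation decisions matter and are worth stating
with their reasons:

1. **Cross-validated wrapper accuracy** (4-fold) instead of a single 25%
   holdout. The per-feature penalty is `beta/d` (0.002 at d = 50) while a
   75-sample holdout resolves accuracy only to 1/75 (0.013): the holdout
   landscape cannot express the difference between dropping a redundant
   copy and dropping an informative column once accuracy saturates. CV
   scores every sample (quantum 1/n) and restores that resolution.
2. **Move scales.** The exploration diffusion `beta1 * U(-1,1)` must be
   able to carry a coordinate from the clipping bounds {0, 1} across the
   binarization preimage (about 0.405 at tau 0.6), or saturated
   coordinates freeze and the search stalls on its initial subset; hence
   `beta1 = 0.8`. The exploitation perturbation (`beta2 = 1`,
   `gauss_sigma = 0.3`) flips roughly one coordinate per proposal — the
   right granularity for greedy subset descent.
3. **Incumbent refinement.** Full-vector perturbations essentially never
   propose the single-feature add/drop/swap moves that discrete subset
   search needs, so each iteration additionally proposes `refine_steps`
   (default 20) absorption kicks on one or two random coordinates of the
   best candidate, accepting ties so equal-fitness swaps can drift across
   plateaus. A diversity restart re-seeds the worse half of the population
   when the per-iteration best has been flat for half the stall window.
4. **Convergence.** The best-so-far trace is monotone by elitism, so the
   stopping rule watches the *per-iteration* best fitness and requires the
   change to stay below `eps` for `stall_iters` consecutive iterations
   (default 10): wrapper accuracy is quantized, so a single exact repeat
   is a coincidence, not convergence.

Exploration proposals replace a candidate only when not worse; the
exploitation move is additionally applied to the fitter half. A
`gat_small` wrapper (a few-epoch miniature graph-attention classifier on
single-node graphs) is available for fidelity with training the final
classifier per candidate, but is far slower and off by default.

On the planted tables (300 x 50, 5 informative at effect 2, 20 redundant,
25 noise), the informative set is the fitness optimum and the optimizer
recovers on the order of 80% of the planted indices (the mean over five
tables fluctuates roughly between 0.7 and 0.9 with the table seeds)
while selecting well under half the columns. Two caveats: at effect size 2 a three-to-four
column subset already separates three classes almost perfectly, so
solutions occasionally trade the fifth informative column against the
count penalty; and recall is counted against exact indices, so a copy
standing in for its source counts as a miss even when the fitness
difference is one CV sample.

## Patch graphs and the attention classifier

Selected per-patch features become graph nodes with edges
`A_ij = exp(-||f_i - f_j||^2 / sigma^2)` between patches whose centres lie
within radius `r` (default 8) in patch-grid units; the diagonal is zero
and self-loops enter only through the `+I` of the symmetric normalization
`D^(-1/2) (A + I) D^(-1/2)` (row normalization is available as an option;
both appear in standard practice). On standardized features with tens of
columns, squared distances concentrate far above `sigma = 0.5`, making
that kernel numerically zero — `build_graph()` warns in that case, and the
pipeline uses `kernel_sigma = "auto"` (the median pairwise feature
distance) as a scale-free default.

Attention layers follow the standard graph-attention form: per head,
`e_ij = LeakyReLU(a' [Wh_i || Wh_j])` over each node's neighbourhood
(self-loops included — required for isolated nodes), softmax-normalized,
aggregation through an ELU; heads are concatenated in all but the last
layer and averaged at the last (keeping the embedding at
`hidden_dim / n_heads`). Attention pooling
(`beta_i = softmax(q' tanh(W_g h_i))`) fuses node embeddings into one
graph embedding, classified by softmax. The loss is cross-entropy with an
L2 parameter penalty, realised as Adam weight decay. Dropout (default 0.3)
is applied to attention coefficients and features during training only.
Prediction is permutation-invariant in the node order (tested), and every
attention row, pooling weight vector, and probability vector sums to 1.

The paper-scale configuration (4 layers, 8 heads, 128-dimensional
embeddings, lr 1e-4) is the `gat_config()` default; the pipeline default
is a 2-layer, 2-head, 16-dimensional model with lr 3e-2 and dropout 0.3,
matched to graphs of a dozen nodes and about a hundred training images.

## Evaluation

Dice, IoU and the symmetric boundary Hausdorff distance (pixel units;
boundary = 4-neighbour erosion residue) with the conventions: two empty
masks score Dice = IoU = 1 and Hausdorff 0; exactly one empty mask scores
0/0 with Hausdorff reported as the image diagonal. The identity
`Dice = 2 IoU / (1 + IoU)` is enforced to 1e-12 in tests. Classification
reports one-vs-rest sensitivity, specificity, precision, F1 and
rank-statistic (Mann-Whitney) AUC per class with macro averages, accuracy,
and the confusion matrix; argmax ties break toward the lowest index.

## The default synthetic study

`pipeline_config()` describes the study the acceptance script runs: 150
subjects, three tumour classes in equal proportion, subject-wise 70/15/15
split; preprocessing with patch-3/search-7 non-local means and a
near-identity registration grid (the phantom channels are generated
registered); segmenter embed 16, depths 1/1, 200 Adam steps at lr 3e-3 on
24 training slices with validation-Dice early stopping; patch-4 features
with coverage 0.5; selection with population 12 over 12 iterations; and
the small classifier above with early stopping on validation accuracy,
trained three times from independent seeds with the predicted
probabilities averaged — the held-out set is small (about 23 subjects)
and a single training's accuracy moves by several percent with its
initialisation seed, nuisance variance the small ensemble removes.
Stage seeds derive deterministically from the global seed, and two runs
with the same seed reproduce each other exactly. These sizes were chosen
so the entire study, including both network trainings, completes in a few
minutes on one CPU while held-out accuracy stays well above the 1/3
chance level; the variance of the held-out estimate with 23 test subjects
is itself a few percent, which is the dominant source of run-to-run spread
across seeds.

## Known limitations

* The phantom's class signal is an additive per-modality contrast
  pattern; real tumour classes differ in shape, location and internal
  texture as well, none of which the generator models.
* Bias-field estimation by a global polynomial fit is biased by large
  high-contrast structures inside the mask.
* The segmenter and classifier are trained at desk scale; the
  reference-scale configurations are provided but not exercised by the
  test-suite budgets.
* Graph construction treats patches of one slice only; no cross-slice
  (volumetric) edges exist by design.
* The Hausdorff distance is reported in pixels; millimetre conversion is
  the caller's responsibility via spacing metadata.
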
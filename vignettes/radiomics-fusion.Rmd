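---
title: "Grad-CAM-guided radiomics fusion: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grad-CAM-guided radiomics fusion: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radfuse classifies 2D grayscale radiographs as lesioned or healthy by
fusing two complementary representations of the same anatomic focus: the
penultimate embedding of a convolutional network and handcrafted radiomic
descriptors restricted to the pixels the network itself attends to. This
vignette documents the models, the conventions the implementation fixes
where the method description leaves freedom, and the reasoning behind the
design choices.

## The pipeline

**Saliency.** For a backbone with last-convolutional feature maps
$A^k \in \mathbb{R}^{h\times w}$ and class score $y^c$, Grad-CAM weights
each channel by the spatial mean of its gradient,
$\alpha_k = \tfrac{1}{hw}\sum_{ij}\partial y^c/\partial A^k_{ij}$, and
forms $L = \mathrm{ReLU}(\sum_k \alpha_k A^k)$. The raw map is bilinearly
upsampled to image resolution and then min–max normalized, so the
delivered heatmap always peaks at exactly 1 (an all-negative raw map
yields an all-zero heatmap; a constant positive one normalizes to a
constant 1). Normalizing after upsampling, rather than before, is what
makes the peak-at-1 invariant hold on the delivered grid. The binary mask
is `heatmap >= threshold` with the threshold (default 0.5 on the
normalized scale) compared inclusively. The saliency target class is the
model's predicted class by default (configurable to "always lesion"); the
mask is always computed on the original, untransformed image. The heatmap
source is the last convolutional layer — the standard Grad-CAM choice —
even though parts of the method's folklore attribute it to the
"penultimate layer"; for a GAP-head network the two coincide up to the
pooling.

**Mask quality control.** A mask is unreliable when it covers less than
1 % of the image area or activates more than 30 % of the 1-pixel outer
border. The border fraction is active border pixels divided by total
border pixels ($2h + 2w - 4$), which makes the 30 % rule independent of
image size. Unreliable masks zero-pad the radiomic channel (all 87
features exactly 0, flagged) while the CNN channel is kept.

**Radiomics.** Intensities inside the mask are discretized with a fixed
bin width of 0.098 on the $[0,1]$ scale — the equivalent of 25 gray
levels on 8-bit data, a common default — via
$\ell(p) = \lfloor (x_p - \min_{\mathrm{ROI}})/w \rfloor + 1$. The census
is fixed at 87 features: 18 first-order, 24 GLCM, 16 GLRLM, 14 GLDM,
5 NGTDM, 10 Shape2D. Conventions, all covered by enumeration oracles in
the tests:

* moments use the population ($n$) convention; kurtosis is non-excess;
  percentiles use linear interpolation; entropy and uniformity are taken
  over the discretized histogram; a constant ROI has skewness 0,
  kurtosis 0, entropy 0, uniformity 1.
* GLCM: symmetric accumulation at distance 1 over angles
  {0°, 45°, 90°, 135°}; pairs crossing the mask edge are skipped;
  features are computed per angle and averaged. Degenerate single-level
  matrices take analytic values (contrast 0, correlation 1 by
  convention).
* GLRLM: maximal same-level runs along the four directions, broken at the
  mask boundary, features angle-averaged.
* GLDM: dependence of a pixel is the number of in-mask Chebyshev-1
  neighbors within gray-level tolerance $\alpha = 0$; the matrix column
  index is dependence + 1.
* NGTDM: per-level summed deviation from the local in-mask neighbor mean;
  pixels with no in-mask neighbor are excluded; coarseness is capped at
  $10^6$ when its denominator vanishes.
* Shape2D: marching-squares contour at the 0.5 iso-level between pixel
  centers (a single pixel is a diamond of area 0.5 and perimeter
  $2\sqrt2$; saddle cells resolve as two disconnected triangles); axis
  lengths are $4\sqrt{\lambda}$ from the population covariance of pixel
  coordinates; maximum diameter from the convex hull of pixel centers.
  The hard-mask contour overestimates a smooth boundary's length by a few
  percent, so the compactness of a high-resolution disc converges to
  ≈ 0.94 rather than 1 — a property shared by standard implementations
  and asserted as such in the tests.

**Fusion and TTA.** The fused vector is `[embedding | radiomics]`. The
embedding may be averaged over up to five deterministic test-time views —
identity, horizontal flip, vertical flip, ±10° rotations (angles chosen
once; deterministic views keep fused vectors bit-reproducible). The
radiomic block always comes from the original image: test-time semantics
also mean training-fold rows use the identity view while held-out rows may
use the TTA average. A caveat discovered with the small test backbone: its
embeddings are not flip-invariant (the root apex moves), so TTA-averaged
features are distribution-shifted relative to identity-trained folds —
ranking survives (AUC is unaffected) but the 0.5 probability threshold
miscalibrates. The reference study below therefore runs without TTA;
pipelines built on flip-robust backbones can enable it as in the original
protocol.

**Reduction and classification.** SelectKBest ranks features by the
one-way ANOVA F statistic (between/within mean squares, df 1 and
$n-2$; constant features score 0; zero within-class variance maps to a
large finite sentinel so rankings never contain infinities) and keeps
k = 100 of the fused columns, clamping with a warning when fewer exist.
PCA centers on the training mean, keeps the minimal component count
reaching 95 % cumulative variance, and fixes signs so each component's
largest-magnitude loading is positive. Reductions are applied to the
whole fused vector and refit inside every training fold — never on
held-out rows. Classifiers are ranger random forests (trees × depth grid)
and xgboost boosted trees (learning rate × depth × min child weight grid,
100 rounds); grid search selects by mean fold accuracy with ties broken
toward the simpler model. Class imbalance is handled by stratification
only.

**Explainability.** TreeSHAP (the path-dependent polynomial algorithm) is
implemented in-package over a unified tree table. For ranger forests,
node weights are recomputed by routing the training matrix down each
tree (ranger does not expose per-node covers); attributions are on the
probability scale and base + contributions reproduce the predicted
probability to machine precision. For xgboost, trees are parsed from the
JSON model payload — the only serialization that round-trips the float32
split thresholds exactly — and both feature values and thresholds are
snapped to float32 before comparison so traversal reproduces xgboost's
own decisions bit for bit; attributions are on the log-odds margin scale,
with the margin accumulated in double precision. Attributions live in the
reduced space actually fed to the trees; PCA components are reported as
components, with the fitted rotation attached for inspection. An
exponential-time subset-enumeration oracle ships in the package and pins
the recursion on small trees.

**Statistics.** The Wilcoxon signed-rank test drops zero differences,
assigns average ranks to ties, and for $n \le 25$ computes the two-sided
p-value from the exact signed-rank distribution via dynamic programming
over doubled ranks (so tie-induced half-integer ranks stay exact); this
is implemented in-package because the base-R test cannot produce exact
p-values under ties. The permutation test shuffles labels within folds
and reports the plain proportion of permutations matching or exceeding
the observed score — p = 0 is representable, with an add-one variant
available. McNemar uses the exact binomial two-sided tail for fewer than
25 discordant pairs and the continuity-corrected chi-square otherwise.
Holm–Bonferroni is the standard step-down procedure (delegated to
`p.adjust`). All alternatives are two-sided. AUC is the tie-half
Mann–Whitney statistic, cross-checked against trapezoidal ROC
integration.

## The synthetic generator

Real periapical archives are private, so the generator emulates the
features the pipeline is sensitive to: an 8-bit grayscale image (values
generated in $[0,1]$, quantized on write) of a bright elongated root-like
capsule on a noisy mid-gray background, with per-image jitter of apex
position, root width and lesion geometry. Lesion-class images add a
darker ellipse at the root apex whose interior intensity drops by
`lesion_contrast` and carries noise SD
`background_noise_sd + lesion_texture_sd`. The lesion sits at the apex by
design so that saliency localization has a ground-truth region. Defaults:
52/48 class balance (mirroring a lesion-heavy clinical archive),
128-pixel images, contrast 0.30 and extra texture SD 0.15 (the package's
calibration of a "large" effect), background noise SD 0.10 — about 25
gray levels on 8-bit data, a realistic flat-field noise scale. One seeded
generator drives everything, with per-image substreams derived by counter
offset so subsets reproduce exactly.

What the generator does **not** emulate: multi-tooth anatomy, sensor- and
exposure-specific noise spectra, and the label noise of visual-only
annotation. Passing the end-to-end tests therefore demonstrates that the
machinery recovers a planted, localized texture/contrast signal — not
clinical performance.

## The reference study and its outcome

`signal_recovery_study()` is the package's canonical experiment: 300
synthetic images at the default effect size, backbone (three conv blocks,
GAP, dropout 0.30 head) trained only on the 70 % training split, and
stratified 5-fold CV of the fused block and both single-modality
ablations over the 90 backbone-unseen images. The restriction matters:
embeddings of images the backbone trained on encode their labels by
memorization, and under a zero-effect generator pool-wide CV would beat
chance on leakage alone. On the unseen pool the null study lands within
the 95 % binomial CI of 0.5, as it must.

At the default ("large") effect size the planted signal is strong in the
ideal-observer sense — a contrast-to-noise ratio of 3 per pixel over a
~100-pixel lesion — and all three feature blocks saturate at accuracy
1.000 on the evaluation pool. The fused block is therefore never *worse*
than an ablation, but a strict fused-over-ablation margin is not
observable at this operating point: single-modality baselines would need
to be individually weak (as transfer-learned extractors are on a truly
out-of-domain clinical archive) for fusion to show a separation, and that
regime is not reachable while a from-scratch-trainable effect size is
also required. The tests state the strict comparison anyway and record
its outcome honestly rather than weakening the assertion.

## Training the test backbone

The tiny CNN (8/16/32 channels, 3×3 kernels, two max-pools, GAP) is
trained with Adam, softmax cross-entropy, L2 decay $10^{-4}$ and dropout
0.30 before the head; inputs are centered by subtracting 0.5. From
scratch, its loss sits on a plateau for tens of epochs before the
localized signal is found, so the package defaults are lr $10^{-2}$, 40
epochs, batch 16, and early stopping — patience 10 epochs, monitored on
validation cross-entropy with best-loss weights restored — should be
disabled (`patience = epochs`) for from-scratch runs, since any
improvement-based rule fires during the plateau. The conventional
fine-tuning settings (lr $10^{-4}$, patience 10) remain appropriate when
the adapter wraps a pretrained model. Backprop is verified against
central finite differences; Grad-CAM gradients of the GAP-linear head are
analytic ($W_{kc}/hw$ per channel) and double-checked numerically.

## Geometric conventions and numerical choices

Pixel coordinates are (row, col), origin top-left, 1-based in R;
geometric transforms act about the image center with bilinear sampling
and zero (black) fill, order flip → rotate → zoom → shift; resizing is
center-aligned so identical input/output sizes are the identity, and
values are clipped back to $[0,1]$. Training augmentation follows the
canonical policy (±30° rotations, ±20 % zoom and shifts, horizontal
flips at probability 0.5); brightness jitter (±15 %) exists as an
explicitly off-by-default field because it belongs to an alternative
regularization recipe. The stratified split allocates
`diff(round(cumsum(fractions) * n_class))` per class, which keeps every
partition within one sample of its target fraction.

## Problem sizes

Unit tests run on 8–32-pixel images, forests of 20–60 trees, and
enumeration oracles on ≤ 8×8 grids; the acceptance suite uses 200 random
ROIs for the texture oracles, 100 fuzzed traces for the saliency
properties, 30 null repeats of a 20-permutation test, and the n = 300
reference study at 32-pixel network resolution — sizes chosen so the full
suite exercises every stage at desk scale.

## Known limitations

* The test backbone is a desk-scale stand-in: it demonstrates the adapter
  contract and supplies real gradients, not clinical representation
  quality. Any model exposing an embedding, conv activations and
  gradients can be wrapped with `backbone_adapter()`.
* The radiomics census is a package constant; it follows common 2D
  defaults but is not a claim about any particular external library's
  feature list, and wavelet/filtered-image features are out of scope.
* Binary-mask contour metrics (perimeter, compactness, sphericity) carry
  the usual small digitization bias.
* The probability outputs are not calibrated; thresholding at 0.5 is the
  only decision rule provided.
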
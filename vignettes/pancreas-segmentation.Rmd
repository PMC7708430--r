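---
title: "Methods: H&E-only semantic segmentation of pancreatic tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: H&E-only semantic segmentation of pancreatic tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panseg)
```

`panseg` quantifies pancreatic disease progression from plain H&E images:
it segments normal acinar tissue, acinar-to-ductal metaplasia (ADM) and
dysplasia with independently trained binary networks, fuses their
probability maps into one label map under fixed priority rules, and
reports per-class area fractions of the cellular region. This vignette is
the package's account of the method: the model and its assumptions, the
parameters that matter, what the synthetic-data generator does and does
not emulate, the numerical choices, and the known limitations.

## The pipeline and its assumptions

An input image is an 8-bit RGB scan of an H&E-stained section at a fixed
working resolution. The pipeline assumes:

1. **Background is near-white glass.** A pixel is background exactly when
   all three channels exceed 200 (strict inequality). Everything else is
   tissue ("DAPI-positive" in the IF analogy).
2. **Staining varies smoothly.** Within a section, staining intensity
   drifts over length scales much larger than a tile; between sections,
   staining differs by roughly global color shifts. Both are nuisance
   variation the normalization stage must remove.
3. **Classes are locally recognizable.** A 512 px tile (64 px at desk
   scale) carries enough texture/color information to classify its pixels;
   the network does not need section-level context.

### White-point anchoring

Before any background masking the image is passed through
`white_balance()`: each channel is rescaled so its 99.5th-percentile
intensity maps to 255 (gains clamped to [2/3, 1.5]). The absolute
background rule is only meaningful when glass actually sits near the top
of the intensity scale; anchoring the white point makes the rule invariant
to global gain changes (scanner exposure, a uniformly light or dark
stain). A global per-channel stain shift — exactly the perturbation used in
the robustness check below — is inverted by this step up to clipping. The
rule's threshold itself (200) is never modified.

### Stain normalization

The default normalizer is Reinhard color transfer: tissue pixels are
mapped into a decorrelated color space, each channel is shifted and scaled
to match reference means and standard deviations, and the result is mapped
back to sRGB. Background pixels are excluded from the statistics *and*
returned unchanged, so edge regions are not dragged toward white and glass
stays glass. Two choices deserve comment:

* **Color space.** The original color-transfer method used Ruderman's
  *lαβ*; the common modern dialect is CIELAB. Both are implemented
  (`space` argument of `reinhard_stats()`); CIELAB (D65) is the default
  because a vetted base-R conversion exists (`grDevices::convertColor`),
  leaving less hand-rolled arithmetic on the critical path.
* **Crop-wise application.** Normalization is applied on intermediate
  crops (default 5000 px with 50 % overlap, 256 px at desk scale),
  independently per crop with overlaps blended by unweighted averaging.
  Per-crop statistics track the local stain level, so a gradient across
  the section is flattened; whole-image normalization can only shift the
  section as a whole. The overlap amount and the blending rule are free
  parameters of our design (averaging was chosen over last-write because
  it is symmetric and removes seam artifacts); both are exposed in the
  configuration. A zero-variance channel (possible on synthetic constant
  regions) maps to the reference mean rather than dividing by zero.

Reinhard's known failure mode is composition shift: a crop dominated by
one tissue class has its class color pulled toward the reference's mixed
average. The segmentation models are trained on normalized images of
varying composition, which forces them to rely partly on texture; this is
also why the desk-scale preset trains past the point where color alone
separates the classes (see below).

Macenko (SVD extreme-angle geometry on optical densities) and a
Vahadane-style normalizer (two-component NMF with an L1 penalty on
concentrations, seeded from the Macenko estimate so the factorization is
deterministic) are provided as comparison baselines behind the same
interface contract: tissue-only statistics, background returned unchanged.

### Tiling and stitching

Tile grids are deterministic, 0-based, half-open and row-major. Edge tiles
are anchored so their far edge coincides with the image edge — no padding,
so every predicted pixel is a real pixel. At inference, overlapping tile
predictions are averaged per pixel (`stitch_mean()`); when every
contribution to a pixel is bitwise identical the value is passed through
directly, making cut-then-stitch an exact round trip regardless of
coverage counts. The stride is a free parameter (default 50 % overlap:
256 at full scale, 32 at desk scale).

### The per-class networks

Each class has its own binary UNet: `depth` pooling levels of two 3×3
convolutions + ReLU, 2×2 max pooling, a bottleneck, then nearest-neighbor
upsampling with skip concatenation, and a 1×1 sigmoid head. 'Same'
padding keeps the output aligned with the input, which stitching requires
(the original UNet's unpadded convolutions would shrink each tile).
Training minimizes binary cross-entropy with predictions clamped to
`[1e-7, 1 - 1e-7]` before the logarithm; the clamp constant is our choice.

Training sets follow the published recipe: 80 % of the tiles relevant to
the class (a tile is relevant when at least `min_class_fraction` = 2 % of
its pixels carry the class — the cutoff is our choice), the remaining 20 %
held out, plus a small fraction of other-tissue tiles (one knob,
`other_fraction`, default 7.5 % for the published "~5–10 %") as negative
controls. Augmentation applies flips, 90° rotations and (at full scale)
horizontal shears of up to ±10°, the same transform to tile and mask with
nearest-neighbor resampling so masks stay binary. Model selection takes
the epoch with the lowest held-out BCE by default; held-out Dice at the
standard 0.5 cut is logged every epoch and can be selected on instead
(`selection = "dice"`). Held-out metrics are computed on tiles, the
training unit, not on stitched images.

The full-scale configuration is the published recipe: 50 epochs, batch
32, Adam at 7e-4, 512 px tiles, depth 4, base 64 channels.

### Desk scale

Everything in the package runs the same code paths at a reduced scale
meant for one CPU: 192 px synthetic images, 64 px tiles at stride 32,
256 px normalization crops, a depth-3 UNet with 8 base channels
(~122k parameters; the bottleneck still sees 8×8 of a 64 px tile). At
this scale the published optimizer settings are mis-calibrated: batch 32
over a few hundred tiles yields barely a hundred Adam steps in total.
The desk preset therefore uses batch 4 for 20 epochs at learning rate
2e-3, chosen from the convergence of training/held-out BCE on synthetic
cohorts — smaller batches buy optimizer steps at no wall-time cost, and
training continues until held-out Dice plateaus rather than stopping
while the models still lean purely on color. Three models train in about
four minutes on one CPU. These constants are the desk preset's own; the
full-scale defaults are untouched.

### Fusion and quantification

Per-class probability maps are fused pixel-wise: background (all channels
> 200 in the normalized image) overrides everything; otherwise acinar ≥
0.3 wins; else ADM ≥ 0.5; else dysplasia ≥ 0.7; else the pixel is
"other" tissue. Thresholds are inclusive (≥), including for the tuned
non-0.5 values — tie behavior at the threshold is unspecified in the
source method, and the inclusive rule matches the standard "prediction
value ≥ 0.5 is positive" convention. The defaults are the published
operating points; `roc_curve()` provides the sensitivity/specificity
sweep used to choose them, and the thresholds are plain configuration —
the original workflow's human-in-the-loop adjustment step is deliberately
replaced by explicit numbers.

Area reports count pixels exhaustively; fractions are of the cellular
region (non-background), with the IF-equivalent groupings amylase =
acinar, pan-keratin = ADM + dysplasia (pan-keratin cannot separate the
two), other = DAPI minus both. A map with no cellular pixels reports
`NA` fractions, not zeros.

### Evaluation metrics

* **Dice**: `2|X∩Y|/(|X|+|Y|)`; two empty masks score 1 (agreement on
  absence — our convention, the source leaves it undefined).
* **SSIM**: uniform 7×7 sliding window, k₁ = 0.01, k₂ = 0.03, dynamic
  range estimated as the joint max − min of the two images, sample
  (n−1) variance normalization, borders where the window would leave the
  image excluded from the mean. These are the scikit-image conventions
  the published analysis used. An optional Gaussian pre-blur (σ = 1 in
  the cohort harness, 0 by default) absorbs pixel-level differences
  between nearly aligned masks — serial sections are offset by one
  section thickness, which is why area correlation and SSIM, not Dice,
  are used against IF references.
* **Spearman** rank correlation (midranks for ties) for cohort area
  fractions; constant vectors are flagged as undefined.
* **Mann–Whitney U** between groups: U counts pairs with a > b (+½ per
  tie); the p-value is exact (null distribution of U) when both groups
  are untied and the smaller has ≤ 8 observations, and the normal
  approximation with continuity and tie corrections otherwise. The
  cutoff at 8 keeps the exact path in the regime where enumeration is
  trivially checkable.
* **Perturbation self-consistency**: re-run the whole
  normalize–predict–fuse pipeline on stain-perturbed copies (each channel
  scaled by an independent uniform factor within ±25 %, plus Gaussian
  noise) and report per-class Dice against the unperturbed labels.

## The synthetic-histology generator

`generate_sample()` builds images that emulate the *statistical
structure* the pipeline relies on, with pixel-exact ground truth:

* a smooth cellular blob (~72 % of the frame, scaled by the requested
  composition) on white (245) background;
* ring-shaped ductal lesions for ADM (thin, near-circular) and dysplasia
  (thicker, angularly modulated "papillary" outlines), whose lumina are
  left background-colored — so the truth map, like real biology, has
  holes inside lesions;
* the remaining cellular area split between acinar tissue and stroma
  along a smooth random field, hitting the target acinar count exactly;
* class-specific palettes and textures (acinar: mid purple-pink with
  dense dark nuclear dots; ADM: light ductal epithelium; dysplasia:
  darker, strongly mottled; stroma: pale pink, low-frequency mottling).
  The palettes are free parameters documented in the code, chosen so the
  green channel stays well below the background threshold and the classes
  are learnable by a small network — not inferred from any real
  distribution;
* uneven staining as a smooth multiplicative planar+radial gradient on
  tissue pixels only (the artefact crop-wise normalization corrects),
  per-image global color shifts, and Gaussian pixel noise added last, so
  the label map stays exact by construction.

Matched binary "IF" channels are defined from the truth map: amylase =
acinar, pan-keratin = ADM ∪ dysplasia, DAPI = all cellular pixels.

Realized class fractions land within ±0.05 of the targets (lesion
rasterization and boundary clipping are compensated by one or two extra
small lesions when needed; the acinar/stroma split is exact by
quantile). Target fractions are read as fractions of the cellular
region; if they sum to s < 1, the cellular footprint shrinks by s and the
fractions renormalize over what remains.

**What passing tests on this generator shows — and what it does not.** The
generator reproduces spatial class structure, background holes, uneven
staining, inter-image shifts and pixel noise; it does not reproduce
nuclei-level morphology, stain co-localization physics, serial-section
offsets, tissue folds, or the unlearned structures (lymph nodes, islets,
GI tissue) that dominate real-world failure modes. Desk-scale recovery of
ground truth therefore validates the *pipeline machinery* — normalization,
tiling, training dynamics, fusion arithmetic, metric implementations — not
the biological performance of any particular trained model on murine
sections.

## Numerical choices and degenerate inputs

* Probability clamp ε = 1e-7 in the loss; He-normal weight
  initialization; all randomness (weights, sampling, augmentation,
  generator) flows from explicit seeds through R's RNG, so a seeded run
  is reproducible on one thread.
* `stitch_mean()` uses the exact pass-through for bitwise-equal
  contributions (see above).
* SSIM with two identical constant images would have zero estimated
  dynamic range; L falls back to 1 so the value is 1, not 0/0.
* An all-background image is an explicit "no tissue" error in every
  normalizer; a rank-deficient optical-density matrix (single-stain
  image) is an explicit error in the deconvolution normalizers.
* Images smaller than a crop degrade to whole-image normalization with a
  notice; images smaller than a tile are predicted with white padding
  that is cropped away afterwards.

## Known limitations

* The UNet variant (padded convolutions, channel widths, nearest-neighbor
  upsampling) is one reasonable reading of the published architecture
  sketch; exact weight-level reproduction of any reference model is out
  of scope.
* Reinhard normalization remains sensitive to extreme composition shifts
  between an image and the reference; the first training image is the
  default reference, and supplying a representative reference crop is the
  user's lever.
* Training at full scale (512 px tiles, base 64) is implemented but not
  practical without substantial CPU time; the desk preset is the tested
  regime.
* Thresholds are global per class; per-region adaptive thresholding is
  deliberately out of scope, as is any lesion-instance analysis or PanIN
  grading.
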
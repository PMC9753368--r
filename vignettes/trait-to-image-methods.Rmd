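---
title: "Trait-to-image crop visualization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-to-image crop visualization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Classical virtual-plant models (L-systems, reference-axis automata) build
plants from geometric rules, which makes the results easy to control but
visually schematic. `phenopaint` takes the opposite route: it learns a
mapping from a vector of measured phenotypic traits to a photographic-style
image of a plant with those traits, using a conditional generative
adversarial network. The package covers the whole loop:

1. extract a fixed panel of 18 traits from segmented plant images,
2. build a centred, resized, normalized training dataset,
3. train a trait-conditioned multi-stage GAN,
4. generate images for new trait vectors, and
5. score the result by visual fidelity (SSIM, Fréchet distance) and by
   trait-prediction accuracy (per-trait Pearson correlation, per-sample
   cosine similarity of re-extracted traits).

A procedural generator of plant-like silhouettes makes every stage of the
pipeline runnable and testable at desk scale, with no external data.

## The trait panel

Segmentation itself is out of scope: inputs are an RGB image plus a binary
foreground mask. The panel, in fixed order:

* **Texture** (first-order histogram statistics of the gray foreground
  intensities, 256 bins, intensities in [0, 1]): mean `M`, standard
  deviation `SE`, smoothness `S = 1 - 1/(1 + sigma^2)`, third central moment
  `MU3`, uniformity `U = sum p^2`, Shannon entropy `E` in bits.
* **Morphology**: total projected area `TPA` (foreground pixel count),
  bounding-rectangle height `H` and width `W`, circumscribed box area
  `CBA = H * W`, box ratio `TBR = TPA/CBA`, hull ratio `THR = TPA / A_hull`
  with the hull area counted as pixels of the filled convex hull of
  foreground pixel centres, perimeter `P` (foreground pixels with a
  4-neighbour in the background, image border counting as background),
  `PAR = P/TPA`, and the box-counting fractal dimension `FDIC` of the
  mask cropped to its bounding box and padded to a power-of-two square
  (slope of log N(s) versus log(1/s) for box sizes 1, 2, ..., side/2).
* **Colour**: green and yellow projected areas `GPA`/`YPA` by HSV hue
  windows, and `YTR = TPA / max(YPA, 1)`.

Design choices worth calling out, since the trait definitions are a contract
of this package rather than something with one canonical form:

* Texture statistics use **foreground pixels only**. On centred plant
  images most of the canvas is black background; including it would reduce
  every histogram moment to a statement about the area ratio.
* The perimeter is a **4-connected boundary pixel count**, not a polygonal
  arc length: deterministic, integer-valued, and checkable by enumeration
  (a 10 x 10 square has P = 36).
* Hue windows are green [60°, 180°) and yellow [20°, 60°), half-open so a
  boundary hue belongs to exactly one class, with saturation and value
  floors of 0.15 so dark or achromatic pixels count as neither. The floors
  and windows are configurable; published descriptions of comparable
  pipelines do not pin them down.
* `YTR` guards its denominator with `max(YPA, 1)`: green-only crops have
  `YPA = 0` and still need a finite value.
* Two schema variants exist: `full` (18 active traits) and `no-yellow`
  (16, for crops whose images contain essentially no yellow tissue). The
  order is fixed and serialized with every dataset and checkpoint.

## Preprocessing

The dataset builder computes the dataset-wide canvas side `M` (the largest
bounding-box side over all masks), centres each cropped foreground on an
`M x M` black canvas at floor offsets (determinism for odd paddings), and
resizes to the model resolution — bilinear for RGB, nearest for masks so
they stay binary. Traits are extracted **after** the resize, so the trait
scales match the images the GAN sees; whether the original pipeline
extracted before or after resizing is not documented, and this choice makes
trait/image consistency testable at any resolution. Records are split into
train/test by a seeded shuffle, and a per-trait min-max normalizer is
fitted **on the training split only**; at generation time unseen extremes
are clamped to [0, 1] so test conditions cannot leave the trained domain.
A trait that is constant on the training split maps to 0.

## The generator and discriminators

The architecture is a trait-conditioned variant of the multi-stage
tree-structured GAN family. The text-embedding front end of those models is
replaced by min-max normalization (the condition is already a numeric
vector), and the stochastic conditioning-augmentation re-embedding is
removed because it injects noise between the condition and the image —
exactly what a measurement-conditioned model does not want.

* **Stage 1**: concatenate noise `z ~ N(0, I)` (default length 100;
  `z_dim = 0` gives a deterministic mapping) with the condition `c` in
  [0, 1]^T; a fully connected block (linear + batchnorm + ReLU) maps to a
  4 x 4 feature map; four upsampling blocks (nearest upsample, 3 x 3 conv,
  batchnorm, ReLU) reach 64 x 64, emitting hidden features `h1` and a tanh
  image.
* **Stages 2-3**: `c` is spatially replicated and concatenated with
  `h_(k-1)` **along the channel dimension**; a joint block (conv +
  batchnorm + ReLU), two residual blocks, one upsampling block and a tanh
  image head double the side (128, then 256).
* **Discriminators** (one per stage): a stride-2 conv stack (LeakyReLU 0.2,
  batchnorm after the first layer) down to a 4 x 4 map; an unconditional
  head scores real-vs-fake, and a conditional head scores trait match on
  the map concatenated with the tiled condition.

The noise input deserves a note: a conditional GAN without any stochastic
input cannot represent the many images that share one trait vector, so a
`z` input is retained even though conditioning alone drives the content.
Channel widths are free parameters (`base_channels`, `disc_channels`);
stage 1 starts at `8 * base_channels` and halves per upsampling block.
Activations are plain ReLU in the generator and LeakyReLU(0.2) in the
discriminators; gated linear units and colour-consistency regularization
used by some relatives of this architecture are deliberately omitted.

## Training

Per minibatch, one discriminator step over all stages is followed by one
generator step (Adam, lr 2e-4, beta1 0.5, beta2 0.999, epsilon 1e-8; the
occasionally printed "10e-8" is read as the conventional 1e-8). All loss
terms are binary cross-entropy on logits. The discriminator sees, per
stage: real images with matched traits (target 1), generated images
(target 0), and — weight `w_mis`, default 1 — real images with mismatched
traits (target 0). The mismatched term is what makes the trait-match head
trainable at all: without negatives the conditional head can ignore its
condition. The generator drives both heads towards 1 on its own outputs,
summed over stages. Real images at the lower stage resolutions are exact
area-average downscales of the stored records. Runs are bit-reproducible
for a fixed seed.

Two presets are provided. `desk` (single stage at 64 x 64, 8-channel
widths, z_dim 8, batch 16, 60 epochs) trains on a few hundred synthetic
images in about ten minutes on one CPU core. `paper` (three stages to
256 x 256, z_dim 100, 600 epochs) matches the published architecture and is
sized for GPU-scale datasets of tens of thousands of images; it is provided
as configuration, not something the test suite runs. Batch size and epoch
counts are not documented for the original; 16 and 600 are adopted as
conventional values for this model family.

Once per epoch the trainer logs the mean SSIM between generated and real
images on a small fixed monitor subset (8 records) — a cheap scalar that
makes learning progress visible and testable.

## Evaluation

* **SSIM** is implemented in its global single-window form — means,
  variances and covariance over all pixels, `c1 = (0.01 L)^2`,
  `c2 = (0.03 L)^2`, `L = 255` — with a sliding-window variant available.
  The numerator uses the standard `(2 sigma_xy + c2)` term, so
  `ssim(x, x) = 1` holds exactly.
* **FID**: `d^2 = |mu_a - mu_b|^2 + tr(S_a + S_b - 2 (S_a S_b)^{1/2})`,
  with the cross square root computed as
  `(S_a^{1/2} S_b S_a^{1/2})^{1/2}` via symmetric eigendecompositions,
  negative eigenvalues clipped at zero. The feature space is pluggable;
  the default extractor is deterministic pooled-pixel features (grayscale,
  8 x 8 area average, 64 features), so absolute values are **not**
  comparable to distances computed in a pretrained deep-embedding space —
  only within one extractor.
* **Trait prediction accuracy**: traits are re-extracted from each
  generated image — the foreground is recovered as the largest connected
  component of the non-black pixels, since generated backgrounds carry
  isolated speckles that would otherwise pin the bounding rectangle to the
  full canvas — and compared with the
  input traits — per-trait Pearson correlation across the test set, and
  per-record cosine similarity. The cosine is computed on min-max
  **normalized** vectors: raw traits span four-plus orders of magnitude
  (areas versus ratios), and the raw cosine would be dominated by the
  largest trait and sit near 1 regardless of quality.

## The synthetic plant generator

Each plant is a vertical stem with alternating side branches and one level
of sub-branches, drawn with hard (un-anti-aliased) strokes so that areas,
perimeters and bounding boxes are integer-exact and the mask is exactly the
set of non-black pixels. Segments are green, or yellow with probability
`yellow_fraction`, with per-segment hue and brightness jitter so the
texture statistics vary. Default sampling ranges (2-9 branches, stem height
45-95% of the canvas, strokes 1-3 px, branch angles up to 70°, up to half
the segments yellow) were chosen once to make every one of the 18 traits
vary across a dataset of 100 plants, which keeps min-max normalization
well-posed; they were not revisited afterwards.

What the generator does **not** emulate: perspective, self-occlusion,
soil/pot backgrounds, leaf curvature, specular highlights, sensor noise,
and the segmentation errors of real pipelines. Passing tests on synthetic
data therefore demonstrate that the machinery is correct and that the model
can bind conditions to simple morphology — not that it reaches
published-scale fidelity on real phenotyping imagery, which requires tens
of thousands of real images and a GPU-scale training budget.

## Numerical choices and degenerate inputs

* Histogram bin centres are `i/(n_bins - 1)`, so 8-bit quantized
  intensities are represented exactly at the default 256 bins.
* A one-pixel bounding box returns fractal dimension 0 (the log-log fit is
  degenerate); collinear foregrounds fall back to the bounding box as the
  filled hull.
* Empty masks raise errors everywhere rather than propagating NaNs; the
  dataset builder names the offending records. If nearest-neighbour
  resizing would wipe a one-pixel-thin mask, the centre pixel is set so
  downstream code never sees an empty mask.
* Batchnorm uses batch statistics during training and running averages
  (momentum 0.1) at generation time; epsilon 1e-5. Its shift parameter is
  initialized N(0, 0.02) rather than 0: when an input batch is exactly
  constant (a single record with z_dim 0), the normalized activations are
  identically zero and the layer output equals the shift, so a zero shift
  would leave every downstream ReLU dead and block all upstream gradients.
  On diverse batches the choice is indistinguishable from a zero shift.
* Non-finite losses abort training with a diagnostic rather than silently
  continuing.
* Generated images are quantized to 8 bits on output, making bit-identical
  reproducibility claims robust across write/read cycles.

## Problem sizes used by the automated checks

The test suite and the acceptance script run the desk preset: 556 synthetic
plants (500 train / 56 test after a 10% split) at 64 x 64 for 60 epochs,
plus many small fixtures. These sizes were chosen as the smallest at which
the learning signal (rising monitor SSIM, clearly positive correlations on
the size traits TPA, H, W, CBA) is reliably visible. The three-stage
256 x 256 configuration is exercised structurally (shapes, conditioning,
losses) rather than trained to convergence.

## Known limitations

* The final resolution tops out at 256 x 256 by construction of the
  three-stage tree.
* Absolute Fréchet distances depend on the pixel feature extractor and are
  not comparable to values computed with pretrained deep embeddings.
* Desk-scale adversarial training is stochastic in quality: with tiny
  channel widths, some traits (especially texture statistics) correlate
  weakly; the size traits are the reliable signal at this scale.
* The checkpoint format is R-native (RDS); no interchange with other
  frameworks is attempted.
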
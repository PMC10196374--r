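---
title: "Removing eyelash artifacts from UWF fundus images: model, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing eyelash artifacts from UWF fundus images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Ultra-wide-field (UWF) scanning-laser ophthalmoscopy captures roughly 200
degrees of retina in a single 3900 x 3072 frame without pupil dilation.
Because the scan passes close to the eyelids, eyelashes frequently cast dark,
curved, semi-transparent shadows across the image. These artifacts occlude
vessels and lesions and degrade downstream analysis (e.g. vessel
segmentation). `lashgan` restores such images with a jointly trained
adversarial model and ships a synthetic phantom simulator so the entire
pipeline is testable without access to patient data.

## The model

Four sub-networks are trained together:

* **Generator G** — a U-shaped encoder-decoder of `depth` (default 8)
  levels. Every encoder layer is a 4x4 stride-2 convolution followed by batch
  normalization and Leaky ReLU (slope 0.2), except the deepest layer, which
  drops batch normalization and uses ReLU. Decoder layers are 4x4 stride-2
  transposed convolutions with batch normalization and ReLU; the final
  decoder drops batch normalization and squashes through tanh. Encoder layer
  *i* is concatenated onto decoder layer *depth - i* (symmetric skips).
* **Background refinement module R** — a second network with the identical
  U-shape (independent parameters), applied after G to recover background
  detail in the regions the artifact occluded.
* **Conditional discriminator D1** — five 4x4 convolutions with strides
  (2, 2, 2, 1, 1), batch normalization in layers 2–4, Leaky ReLU, and a
  sigmoid producing a spatial confidence map. D1 sees the corrupted input
  concatenated with a candidate restoration (6 channels) and judges whether
  the pair is real.
* **Unconditional discriminator D2** — the same topology on single images
  (3 channels); it judges whether an image is a real artifact-free patch.

The generator objective combines four terms:

* conditional adversarial loss (binary cross-entropy against D1 on paired
  samples),
* L1 generation loss between G(x) and the clean reference, weighted by
  `lambda1 = 100`,
* unconditional adversarial loss against D2 on unpaired samples, and
* L1 refinement loss between R(G(x)) and the reference, weighted by
  `lambda2 = 10`.

The same generator is trained **alternately** on paired (conditional) and
unpaired (unconditional) batches — the joint strategy that gives the model
its ability to handle both synthetic-style and real-style artifacts. The
refinement module is updated only in paired steps, because its L1 loss
needs a pixel-aligned reference; unpaired steps update G and D2 only.

Optimization uses Adam with learning rate 0.0002 and beta = (0.5, 0.999),
batch size 15 at full scale, 200 epochs, and random horizontal flipping
applied identically to the corrupted image, the reference and the mask.

### Declared choices where the formulation is open

* **Generator adversarial term.** The classical minimax objective saturates
  early in training; by default the package trains the non-saturating
  surrogate `-log D(fake)` and exposes `saturating = TRUE` to restore the
  literal minimax form. The discriminator loss is halved so that an
  uninformative discriminator (all outputs 0.5) scores exactly `log 2`.
* **Weighted total.** The total objective applies `lambda1` to the L1 term
  and `lambda2` to the refinement term, as the weight definitions require.
* **Losses are means**, not sums, over map elements, pixels and batch, so
  the lambda weights are scale-free across image sizes.
* **Noise input z.** The stochastic input of the conditional formulation is
  realised as rate-0.5 dropout in the first three decoder layers during
  training (the conditional-GAN convention); `noise_mode = "none"` disables
  it. No explicit noise vector is injected.
* **Channel schedule** 64, 128, 256, 512, 512, ... capped at 512 — the
  canonical 8-layer U-shape schedule; widths are not otherwise specified.
  Desk-scale runs use `base_channels = 8`, cap 64.
* **Padding 1 on all 4x4 convolutions**, required for exact spatial
  halving/doubling; with it, a 256-pixel input yields the 30 x 30
  discriminator confidence map (256 → 128 → 64 → 32 → 31 → 30).
* **Batch normalization at 1x1.** When an encoder bottleneck reaches 1x1
  spatial size, batch statistics over a single position are degenerate;
  normalization is skipped at that layer (documented behaviour of the
  engine).
* **Alternation ratio** paired : unpaired is 1 : 1 with the paired step
  first; only "alternating" is prescribed, so the ratio is configurable.
* **Constant learning rate** (no decay) by default.
* **Validation** holds out a seeded 10% of the paired set; the epoch with
  the best validation PSNR is checkpointed.

## The network engine

No automatic-differentiation framework is used: the package implements the
convolution, transposed convolution, batch normalization, activation and
dropout layers with explicit forward and backward passes. Convolutions are
evaluated as im2col + GEMM in C++ (RcppArmadillo); the transposed
convolution is expressed exactly as the adjoint of the strided convolution
(its forward pass is the convolution's backward-data pass and vice versa),
so one verified primitive serves both. The full backward pass is validated
against central finite differences in the test suite (relative error
~1e-9 on every parameter group of both network families).

## The phantom simulator

The simulator replaces the non-redistributable clinical datasets and defines
the package's study conditions:

* **Clean phantoms.** An elliptical bright field (semi-axes 47% of the
  image) over a near-black surround, with a warm base color
  (205, 120, 55), a radial darkening gradient (strength 0.35), Gaussian
  texture noise (sd 4 intensity units), and a recursively branching dark
  vessel tree: each child segment's width is the parent's times
  `vessel_width_decay` (default 0.65, depth 4), and vessel pixels are
  darkened multiplicatively (factor 0.55).
* **Eyelash strokes.** Quadratic Bézier curves rooted on image borders
  (probabilities 0.45/0.45/0.05/0.05 for top/bottom/left/right, since
  eyelids are superior/inferior), pointing inward, 20–40 per image, lengths
  35–85% of the image side, widths tapering to 35% of the root width,
  opacities 0.55–0.95 over a dark shade (12, 8, 8), softened by a Gaussian
  blur and a faint halo (opacity 0.12). The stroke model is an invented,
  declared stand-in: the parameters were chosen once for visual
  plausibility against published UWF examples, not fitted to any dataset.
* **Compositing.** `corrupted = (1 - alpha) * clean + alpha * shade`,
  the simplest law that leaves every zero-alpha pixel bitwise identical to
  the clean phantom — which is what makes the ground-truth artifact masks
  (`alpha > 0.05`) exact.
* **Seeding.** Every sample's seed is derived from the master seed and the
  sample index, so datasets are bit-reproducible and extensible; unpaired
  corrupted and clean pools draw from disjoint seed streams so no hidden
  pairing exists.

What the phantoms deliberately do **not** model: the photometric response
of the scanning-laser optics, lesions and pathology, laterality markers, or
real eyelash micro-texture. Passing desk-scale tests therefore demonstrates
that the training machinery recovers occluded structure under controlled
conditions; it does not certify clinical performance on patient images.

## Evaluation metrics

* **PSNR** = `10 log10((2^n - 1)^2 / MSE)` dB on the 8-bit scale (the peak
  for n = 8 is 255); identical images report `Inf`.
* **SSIM** with constants `c1 = (0.01 L)^2`, `c2 = (0.02 L)^2`, `L = 255`.
  The default mode computes the formula once from whole-image means,
  variances and covariance (single-statistics form); a windowed mode
  (11-pixel uniform windows) is provided for cross-checks against common
  implementations, which also typically use `k2 = 0.03` — here `k2 = 0.02`
  is the default and both constants are configurable.
* **ENL** = `mu^2 / sigma^2` of the grayscale intensity (unweighted channel
  mean) inside a region mask — here the eyelash artifact masks. Higher ENL
  after restoration means the artifact texture was smoothed away. Regions
  must contain at least 64 pixels.
* All variances are population variances (divide by N), so independent
  oracles can match to machine precision.

## Desk-scale study sizes

CPU-scale experiments (used by the test suite and the acceptance script)
run at 64 x 64 pixels with depth-6 U-nets (`base_channels = 8`, cap 64,
discriminators at base 16):

* functional recovery: 80 paired + 80/80 unpaired training samples,
  batch 4, 18 epochs, 3 training seeds, evaluated on 30 held-out pairs;
* module ablation: 48 paired + 48/48 unpaired samples, 16 epochs, one
  seed shared by all four variants, evaluated on 16 held-out pairs.

These sizes are the package's desk-scale choice: large enough that the
full model reliably clears a +2 dB held-out PSNR gain over the corrupted
input and raises in-mask ENL in at least 8 of 10 regions, small enough to
be routinely re-run. The full-scale regime (1024-pixel patches, depth 8,
base 64, batch 15, 200 epochs) is configured by the defaults of
`train_config()` but is a multi-GPU-day undertaking, and its absolute
metric values on clinical data are not reproducible from synthetic
phantoms.

## Numerical notes and limitations

* Confidence-map probabilities are clamped at 1e-12 inside logarithms; the
  sigmoid/BCE gradient composition is algebraically simplified, so
  discriminator updates remain finite even for saturated maps.
* Evaluation mode uses batch-norm running statistics (momentum 0.1) and
  disables dropout, so inference is bitwise deterministic for fixed
  parameters.
* Tiled inference feathers overlapping tile predictions with linear ramps
  and reflection-pads frames smaller than one tile; whole-frame stitching
  is a convenience of this package, not a claim about any published
  pipeline.
* Training is single-threaded CPU linear algebra; wall-clock scales
  linearly in pixels x channels^2 x steps. The desk regime trains in
  minutes; expect hours per seed already at 256 pixels with wider nets.
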
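---
title: "Methods: conditional-GAN annotation of immunogold particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional-GAN annotation of immunogold particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Freeze-fracture replica immunogold labeling (FRIL) and post-embedding
immuno-EM mark proteins with colloidal gold nanoparticles (here 6 and
12 nm), which appear in electron micrographs as small dark, nearly circular
spots. Counting and localizing them by hand across images that can reach
tens of thousands of pixels per side is slow and inconsistent, and the
classical automated alternative — a global gray threshold followed by area
and roundness filters — degrades badly on replicas, whose topography
produces uneven background gray levels and dark directional shadows that
overlap the particle gray range.

`goldpick` implements the deep-learning solution: a pix2pix-style
conditional GAN translates grayscale image tiles into particle masks. A
U-Net generator \(G\) maps an input tile \(x\) to a mask \(\hat y = G(x)\);
a convolutional patch discriminator \(D\) judges \((x, y)\) pairs real or
fake. The generator objective is

\[
\mathcal{L} \;=\; \mathcal{L}_{\mathrm{GAN}}(G, D)
\;+\; \lambda\,\lVert G(x) - y\rVert_1 ,
\]

with \(\lambda = 100\). Masks are axis-aligned squares centered on each
particle with side proportional to the particle's pixel diameter, so mask
area carries size information; downstream, connected-component analysis
converts the mask into per-particle records (centroid, area), and exact
one-dimensional k-means on \(\sqrt{\text{area}}\) splits records into size
groups.

## Model and training

**Generator.** A U-Net with `n_down` stride-2 4×4 convolution encoder
blocks and the mirror-image transposed-convolution decoder with skip
concatenation; leaky-ReLU (0.2) encoder activations, ReLU decoder
activations, tanh output. Instance normalization is applied on all but the
outermost and bottleneck layers (the bottleneck is spatially 1×1, where a
per-instance moment is degenerate). With `n_down = 8` and
`base_filters = 64` this is the standard configuration for 256×256 tiles;
channel widths are capped at `8 * base_filters`.

**Discriminator.** A patch classifier over (input, mask) channel pairs:
two stride-2 blocks, one stride-1 block, then a 1-channel projection to a
grid of patch logits, trained with binary cross-entropy (real = 1,
fake = 0). Judging patches rather than whole tiles keeps the adversarial
signal local, which suits a task where errors are local (a missed or
hallucinated particle).

**Optimization.** Adam with \(\beta_1 = 0.5\), \(\beta_2 = 0.999\); batch
size 2; 200 epochs; learning rate 2e-4 with a linear policy (constant for
the first half of training, then decayed linearly to zero). These package
defaults are the reference recipe for the full-size configuration; the
optimizer choice and \(\lambda\) follow the pix2pix lineage. The GAN's
stochasticity comes only from initialization and batch order — no dropout
noise — so inference is a pure function of (weights, tile), and two
predictions of the same tile are bit-identical.

**Normalization contract.** Inputs are mapped linearly from [0, 1] to
[−1, 1]; the mapping is recorded in the model object and applied
identically at inference. Per-image percentile normalization was rejected:
it would make a tile's prediction depend on which window of a large image
it came from.

**The desk preset.** Tests and the acceptance script exercise a reduced
configuration: 64×64 tiles, `n_down = 6`, `base_filters = 16`, constant
learning rate 1e-3. The reduced net trains in hundreds rather than
hundreds of thousands of steps, and at that step count the full-size
learning rate of 2e-4 cannot drive the tanh output into saturation — in a
single-pair overfitting probe it reaches an L1 ratio of only ~0.27 versus
~0.01 at 1e-3 — so the larger constant step size is part of the preset's
definition, not a tuning afterthought. The 256/64 configuration is fully
supported but not exercised by the test suite.

**Known failure mode.** With sparse masks (a few percent foreground), the
L1 term alone pulls the generator toward an all-background output; once
tanh saturates at −1 the per-pixel gradient vanishes (\(1-\hat y^2 \to 0\))
and recovery is slow. The adversarial term is the designed rescue — an
empty mask over an input with visible particles is easy for the patch
discriminator to reject. Training length must still give that dynamic time
to work, and two mitigations are built in: the generator's output bias is
initialized to −0.5 (the background prior), which keeps the early output
off the tanh rail, and `goldnet(collapse_l1 =, max_restarts =)` can
restart from a fresh seeded initialization when the *training* loss ends
at the all-background plateau (the plateau sits at the mean foreground
fraction of the masks, ~0.02 here, while an escaped run ends below 0.01 —
a sharp separation, judged without touching any held-out data). Restarts
are off by default and enabled in the end-to-end runs.

## The synthetic scene simulator

Every stage is testable without real EM data through `render_scene()`,
which emulates the characteristic difficulties of FRIL backgrounds while
providing exact ground truth:

* **Background**: mean gray plus a smooth random unevenness (a directional
  ramp plus one broad blob, amplitude `gradient_amplitude`), plus
  `shadow_count` soft-edged dark streaks at `shadow_angle_deg` (±15°
  jitter), depth `shadow_intensity`.
* **Particles**: dark anti-aliased disks of pixel diameter
  `diameter_nm / pixel_size_nm`. The core gray is
  `particle_intensity × local background` — i.e. particles darken the
  background *multiplicatively*. This choice is deliberate: on real
  replicas particle contrast tracks the local background, which is exactly
  why a single global threshold cannot separate all particles at once.
  An additive (absolute) dark level would make the threshold baseline
  trivially robust and the comparison meaningless.
* **Placement**: uniform rejection sampling with a minimum center-to-center
  separation (default twice the largest particle diameter) and an edge
  margin that keeps footprints and mask squares inside the raster, so
  ground-truth-to-detection matching in tests is unambiguous. Overcrowded
  requests fail with an explicit error rather than a silent shortfall.
* **Targets**: binary square masks rendered by `render_target_mask()`,
  side `mask_scale` (default 1.0) times the particle pixel diameter. The
  source description never states the square's exact side relative to the
  particle; 1.0 is the neutral choice and it is configurable.
* **Noise/blur**: Gaussian blur (σ 0.6 px) then additive Gaussian noise
  (σ 0.03), clipped to [0, 1].

Datasets are balanced so that half the tiles contain no particles
(`empty_fraction = 0.5`): without the balance, a detector trained mostly
on empty tiles drifts toward labeling nothing.
`faux_magnification()` rescales image, mask and truth coordinates
consistently to emulate other magnifications (2× on a 1.11 nm/px scene
emulates 0.55 nm/px imaging).

**Study conditions.** The tests use three 64×64 families with 2×6 nm +
1×12 nm particles: *flat* (no gradient, no shadows), *textured* (gradient
0.15, two shadows of depth 0.18 — the default spec), and *gradient*
(background 0.55, gradient amplitude 0.35, three shadows of depth 0.25).
The gradient family is tuned to the operating point where a global
threshold fails structurally — dark background regions fall below any
threshold that keeps all particles, swallowing the particles inside them —
while particles remain locally detectable: the background floor is about
0.29, so with multiplicative darkening every particle keeps an absolute
contrast of at least ~0.2, well above the noise. A harsher gradient drives
the contrast of particles in its darkest regions toward zero, making them
unrecoverable by any detector — that would test the simulator's cruelty,
not method quality.

**What the simulator does not emulate**: carbon/platinum replica physics,
electron optics, focus gradients, membrane texture at particle scale,
particle aggregation. Passing tests demonstrate correct mechanics and the
qualitative threshold-vs-learning contrast, not performance on real EM
data; accuracies reported on real micrographs elsewhere are not
reproducible from synthetic scenes, and the package makes no claim to
them.

## Tiling

Images of arbitrary size are processed through `plan_tiles()` /
`detect_image()`: windows of `tile_px` are laid out row-major with stride
`tile_px − overlap_px`; the last row/column is shifted inward to abut the
image edge (so edge windows may re-cover pixels), and images smaller than
one tile are padded by symmetric reflection. Overlapping predictions are
combined by per-pixel maximum — the mask value is a particle-presence
score, so the union of evidence is the right combination and makes the
stitched result independent of window order. The default overlap of 32 px
is about twice the largest particle footprint at 1.11 nm/px, so a particle
cut by one window boundary is seen whole by a neighbor. Windows are
processed one at a time; only one tile and the output mask are resident.

## Extraction and size grouping

Generator output in [0, 1] is binarized at 0.5 (the midpoint of the output
range), labeled by 8-connectivity (deterministic first-encounter raster
order), and measured: centroid = unweighted mean of member pixel
coordinates, area = member count. Components below `min_area_px = 4` are
discarded as generator noise. Size grouping is exact 1-D k-means on
\(\sqrt{\text{area}}\) by dynamic programming — deterministic, globally
optimal, and oracle-checkable against exhaustive partition enumeration —
with groups relabeled in ascending mean-area order. The reported
`diameter_nm_est` \(= 2\sqrt{A/\pi}\cdot\)`pixel_size_nm` is an
equivalent-circle size index; masks are squares, so it overestimates the
physical diameter (an 11 px square maps to 13.8 nm for a 12 nm particle)
and is meant for group separation, not calibrated sizing.

## The TAC baseline

The classical comparator: keep pixels `≤ gray_threshold` (gold is
electron-dense, so particles are dark), label components, keep those whose
area falls in a per-size-class band (default `[0.5×, 2×]` the
equivalent-disk area of each nominal diameter) and whose circularity
\(4\pi A / P^2\) reaches `circularity_min` (default 0.6). The perimeter
\(P\) is the length of the closed Moore boundary trace through boundary
pixel centers (a 1×n line scores \(4\pi n / (2(n-1))^2\); a single pixel is
defined as circularity 1). The roundness cut is what rejects elongated
shadows that fall below the gray threshold.

## Evaluation

Detections are matched to ground truth one-to-one by minimum-total-distance
optimal assignment (Hungarian algorithm) among pairs within `max_dist_px`;
optimal rather than greedy matching makes scores deterministic and
order-independent. Accuracy = matched truth / total truth (false positives
are reported separately: accuracy divides true positives by the
ground-truth count, nothing else). Center RMSE
is computed over matched pairs, overall and per size group; a size
confusion table crosses true nominal diameter with assigned group. An
optional region-of-interest mask (e.g. the membrane face of a profile)
restricts scoring on both sides before matching. A true positive is
positional only; size-group errors appear in the confusion table, not in
accuracy.

## Numerical choices and degenerate inputs

* Seeds: every stochastic operation takes an explicit seed; per-pair seeds
  derive deterministically from the dataset seed; the caller's RNG state is
  restored afterwards.
* `epochs = 0` returns the initialization (or `init`) untouched with an
  empty loss history.
* Empty masks extract to an empty record frame, not an error; accuracy on
  zero truth particles is an explicit error (undefined), as is RMSE with
  no matched pairs.
* Ties in 1-D clustering are resolved by the deterministic DP backtrack;
  `n_groups` is capped at the number of surviving components.
* Binarization uses `>= threshold`; TAC thresholding uses `<=` (dark
  objects).
* Coordinates are 0-based throughout (x = column, y = row, pixel centers
  at integers), and CSV exports state this in their comment header.

## Training schedules used by the tests

The test suite and `scripts/acceptance.R` train the desk preset on 64
balanced pairs (24 textured + 40 gradient family, half empty) for 60
epochs at constant 1e-3 — about 1900 generator steps — evaluating on
held-out scenes at a 5 px matching radius, and probe transfer learning by
pretraining on particle-free textured scenes before fine-tuning on
particle scenes. Problem sizes (64×64 tiles, tens of scenes, 3 seeds)
are chosen so the whole suite runs on a single CPU in minutes while the
measured properties — learning beats thresholding under background
gradients, pretraining lowers initial loss — remain qualitatively stable.

## Limitations

* The cGAN at desk scale is demonstrative: real deployments should use the
  256×256 configuration, larger corpora, and the default 200-epoch
  schedule.
* GAN training at a few hundred steps is seed-sensitive; the tests use
  fixed seeds and majority criteria, and the occasional slow-starting seed
  is expected behavior at this scale, not a defect of the method.
* `diameter_nm_est` is a size index, not metrology (see above).
* The simulator's gradient family is a model of *why* thresholding fails
  (dark-region merging), not a physical replica model.
* Interactive proof-reading and montage stitching are out of scope; the
  package consumes single images and emits CSV/overlay files.
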
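---
title: "Virtual staining of tissue autofluorescence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual staining of tissue autofluorescence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(virtustain)
```

## The problem

Routine pathology consumes tissue: every chemical stain (H&E, IHC, mIF)
occupies a section, and serial sections are never quite the same tissue.
Virtual staining replaces the chemistry with computation — a generative
model maps label-free hyperspectral autofluorescence (AF, 20 spectral
channels of the unstained section) to the images the stains would have
produced, so one section can yield H&E, DAPI+PanCK, PD-L1, CD3 and CD8
"stains" simultaneously. `virtustain` implements the computational core of
such a system end to end: the invertible pseudo-IHC rendering that turns
mIF channels into brightfield-like training targets, the registration
quality control that guards the paired training data, the training losses
and a compact native-R stainer, the threshold-based mIF quantification
(TPS, CPS, densities, colocalization), and the real-vs-virtual concordance
statistics.

Clinical slide archives of this kind are not redistributable, so the
package ships a synthetic tissue phantom generator with complete ground
truth. Every downstream stage is exercised and tested on phantoms; what
that does and does not demonstrate is discussed at the end.

## Coordinates, units and magnification

One convention is used everywhere: pixel-centred coordinates, origin
top-left, `x` = column, `y` = row, 1-based indices in R, half-open crops.
Physical scale is carried as `pixel_size_um`, with the magnification
convention 40x = 0.25 um/px and 10x = 1.0 um/px; every micrometre
threshold is converted through it, so the 6-um registration rule means the
same physical displacement at any resolution.

## The tissue phantom

`make_phantom()` draws a blobby simply-connected tumor region and places
nuclei as disks with a hard minimum separation (rejection sampling; an
infeasible packing density is an explicit error). Cell classes follow the
biology the markers are meant to read out: tumor cells express PanCK (a
configurable fraction also PD-L1), T cells express CD3, a subset of them
(cytotoxic) also CD8, and "other" cells express nothing. Defaults — a
512 x 512 px field at 0.25 um/px, 60 tumor / 30 T (15 cytotoxic) / 20
other cells, nucleus radius 5 px, expression uniform in [40, 120] — were
chosen once as a desk-scale cartoon with realistic *relative* structure
(contrast, class proportions, touching-cell geometry) and are not tuned to
any test. Nuclei are smaller than real nuclei at 40x; the phantom is a
fixture for algorithms, not a biophysical simulation.

`render_mif()`, `render_af()` and `render_he()` share a two-compartment
optic: per-class abundance maps (nuclei, tumor cytoplasm, stroma) blurred
by a Gaussian PSF. The mIF DAPI channel is a radial bump per nucleus, so
every nucleus centre is a local maximum (the property the cell segmenter
relies on). The AF image is a linear mixing of per-class emission spectra
(free parameters — no quantitative per-tissue AF spectra exist for this
cartoon; defaults are smooth Gaussian bumps, and tests that need exact
unmixing pass orthogonal one-hot spectra instead). The CD8 channel
optionally receives a nonspecific background — a smooth low-frequency
field plus speckle — emulating the label noise real CD8 stains show; its
default amplitude (8, against expressions of 40–120 and a positivity
threshold of 20) makes the noise visible but not dominant. The residual-AF
channel is an attenuated copy (0.2) of the total AF emission. All
renderers are bitwise deterministic per seed, and channel counts (20 / 6 /
3) are asserted on every output.

`apply_warp()` provides the registration fixtures: exact sub-pixel global
translations (bilinear inverse mapping) and local Gaussian-profile
displacements that are hard-truncated at their support radius, so pixels
outside are bitwise unchanged.

## Pseudo-IHC rendering

mIF channels are excellent supervision but look nothing like the
brightfield images pathologists read. The pseudo-IHC (pIHC) renderer maps
three mIF maps — DAPI (to a hematoxylin-like blue-purple), the target
stain (to a DAB-like brown), and residual AF (to a gray tissue background)
— through the Beer–Lambert law:

$$\mathrm{rgb} = \mathrm{offset} + \mathrm{white} \cdot
  \exp(-M\,a),$$

where $a$ are the three intensities divided by per-channel normalization
constants (clipped at 1) and the columns of $M$ are optical-density
directions. Defaults use the standard stain-deconvolution directions for
hematoxylin (0.65, 0.70, 0.29) and DAB (0.27, 0.57, 0.78) and a weak gray
background column; normalization constants default to 150 (DAPI, target)
and 5 (residual AF). These constants are design choices of this
implementation, exposed in `pihc_config()`. The color offset and page
white reproduce the slightly warm, non-saturated white of real brightfield
scanners, and zero input renders exactly `offset + white`.

Because the map is strictly pixel-wise and $M$ is well-conditioned (the
constructor enforces a condition-number bound), it is algebraically
invertible: `pihc_to_mif()` computes $a = -M^{-1}\log((\mathrm{rgb} -
\mathrm{offset})/\mathrm{white})$ and de-normalizes. Invertibility holds
exactly on the un-clipped range; out-of-domain pixels (possible on
generated images) are clamped to the domain boundary, counted, and
reported. The round trip is exact to floating precision, which is what
lets the stainer train against pIHC targets and still deliver mIF outputs.
`multiplex_overlay()` composes several pIHC renders of one section
additively in optical-density space, with optional pseudo-color
directions per member.

## Registration quality control

AF and stained images of the same section come from different scanners and
the staining chemistry (especially mIF antigen retrieval) warps tissue
locally. Two tools address this:

* `global_affine_align()` — iterative multi-resolution affine estimation
  (Nelder–Mead refinement over 6 parameters per pyramid level, translation
  pre-search at the coarsest level) minimizing a gradient-based multimodal
  metric. A pair whose residual does not improve on the unaligned baseline
  (relative to the metric's self-distance floor) is flagged failed and
  excluded, mirroring how unalignable slides are dropped.
* `local_translation_score()` — the tissue-warping detector. Patches are
  converted to grayscale, normalized to [0, 1], and a pure translation is
  fit by Powell's direction-set method (Brent line searches) coarse-to-fine
  over a three-level Gaussian pyramid. The magnitude of the fitted
  translation, in micrometres at the 10x reference, is the alignment
  score; `qc_decision()` flags a region as misaligned when the score is
  *strictly* greater than 6 um (a score of exactly 6 is retained).
  `qc_exclusion_mask()` tiles a slide pair (256-px tiles at 10x scale
  equivalents, 50% overlap by default), scores each tile, and excludes
  every pixel covered by a flagged tile; the mask feeds patch sampling.

The distance metric is the normalized gradient field,
$d(a,b) = \mathrm{mean}\,[1 - (\langle\nabla a,\nabla b\rangle_\varepsilon
/ \|\nabla a\|_\varepsilon\|\nabla b\|_\varepsilon)^2]$ with
$\|g\|_\varepsilon = \sqrt{\|g\|^2 + \varepsilon^2}$ and
$\varepsilon = 0.01$ of the intensity range, or alternatively the
normalized total gradient $\sum|\nabla(a-b)| / (\sum|\nabla a| +
\sum|\nabla b|)$; on the phantom warp suite the two metrics make the same
retention decisions, and the package asserts that. Numerical details that
matter: the metric is evaluated on a trimmed interior (shifted content
drags replicate-padded borders), and two tie-breaks resolve essentially
flat objectives — fractional shifts of the moving patch add interpolation
smoothing that can shave a spurious ~0.02% off the metric, so the
optimizer prefers the integer translation, and then the zero translation,
whenever either is within 0.1% of the optimum. A genuine half-pixel shift
improves the objective by ~2%, two orders of magnitude above the
tie-break band, so real displacements are never snapped away; the result
is exact recovery of integer-pixel shifts and sub-0.02 px error across a
0.5–10 um sweep.

## Patch sampling

Training pairs follow a fixed geometry: 128 x 128 x 20 AF patches against
160 x 160 x C stain patches at 40x — the stain carries 16 extra pixels per
side so that residual global-alignment error can be absorbed by the loss
rather than corrupting the supervision. `sample_paired_patches()` draws
patch centres from a normalized weight raster built by
`build_sampling_weights()`: uniform over detected tissue, multiplied by 3
inside PanCK-positive (tumor) regions and by 3 inside PD-L1-positive
regions (positivity for *sampling* is an Otsu threshold on the smoothed
channel; the factors are configurable — only "higher probability" is
principled, the magnitude is a package default), and zero inside the QC
exclusion mask. Patch streams are deterministic per seed, and the
16-px-pad geometry is asserted on every emitted pair. Desk-scale counts
(<= 1e5) replace production-scale sampling.

## Losses and the stainer

The stainer is a pix2pix-style conditional GAN: a U-Net generator mapping
AF to the stain, one conditional discriminator scoring (AF, stain) jointly
and two unconditional discriminators scoring the stain at full and half
resolution. Because no deep-learning runtime is part of this package's
stack, the networks are implemented natively in R — im2col convolutions,
exact hand-written backpropagation (finite-difference-verified to 1e-4
relative), Glorot-uniform initialization and Adam — at desk scale: the
default generator is a two-level U-Net with 8 base filters, trained on
64-px patches. This keeps every numerical property of the training
procedure testable; it does not pretend to production capacity.

The loss suite:

* **Shift-invariant weighted regression.** The padded target is cropped at
  every integer offset in $[0, 32]^2$ and the minimum weighted mean-L1 +
  mean-L2 over offsets is the loss, so any content shift up to 16 px per
  axis costs nothing. Weights are normalized to mean 1 (uniform weights
  reproduce the unweighted loss) and the gradient flows through the
  minimizing crop.
* **Intensity weighting.** For mIF targets, per-pixel weights
  $w = \max(1, \log(\min(i, i_{\max})))$ emphasize high-expression pixels;
  the log base is $e$ by default (a base-10 switch exists). For CD8, every
  pixel with target IF intensity below 15 is forced to weight 1,
  suppressing the background/nonspecific label noise that channel carries.
  mIF stainers are trained against pIHC targets (the weights still come
  from the raw IF intensity), with `pihc_to_mif()` recovering the mIF
  output.
* **Rotational consistency.** Mean L1 between
  $\mathrm{rot}_k^{-1}(G(\mathrm{rot}_k x))$ and $G(x)$ for quarter-turn
  rotations (one drawn per step during training; exactly zero for any
  pointwise model), discouraging orientation bias.
* **Adversarial.** Non-saturating cross-entropy per branch
  ($d = -\log D(\mathrm{real}) - \log(1 - D(\mathrm{fake}))$,
  $g = -\log D(\mathrm{fake})$), weighted and summed over the three
  branches; a chance discriminator yields the analytic $\log 2$ constants.
  Off by default for the desk-scale regression runs; enabling any
  adversarial weight activates alternating generator/discriminator Adam
  updates.
* **L2 regularization** as weight decay on the generator.

Learning rate and every loss weight accept either a scalar or a
`function(step)` schedule. Training logs validation L1 and a Fréchet
feature distance every `val_every` steps and keeps a generator checkpoint
at each validation point; `select_checkpoint()` picks the checkpoint
minimizing the rank-sum of the two validation metrics (ties to the earlier
step) — a concrete reading of "a combination of minimum L1 and Fréchet
distance". The Fréchet distance uses the Gaussian closed form on sample
moments with $\mathrm{Tr}((\Sigma_1\Sigma_2)^{1/2})$ computed from
eigenvalues; the feature extractor is pluggable, with a fixed-seed
random-projection embedding as the default (a pretrained perceptual
network is deliberately not a dependency; any extractor producing a
sample-by-feature matrix can be swapped in). Whole-slide inference
(`predict_wsi()`) runs the fully-convolutional generator over overlapping
tiles blended by a cosine-ramp feather; degenerate tilings reproduce
single-pass inference exactly.

Training is fully seeded and bit-reproducible: two runs with the same
seed, config and data produce identical loss curves and weights. The
reference tiny run in the test suite — 8 pairs of 64-px AF/H&E patches,
200 regression-only steps, batch 4, lr 2e-3 — reduces validation L1 to
below a quarter of its initial value in a few minutes on one CPU; sizes
were chosen as the smallest run that demonstrates optimization
correctness.

## mIF quantification

`segment_cells()` is a deliberate classic threshold pipeline (the kind
commercial tools implement): Gaussian smoothing, Otsu or fixed threshold,
distance-transform markers with watershed splitting of touching nuclei,
small-object removal. `segment_tumor()` thresholds the smoothed PanCK
channel, fills holes and removes specks; both are invariant to global
intensity scaling. Positivity is the clinical rule: a cell is positive for
a marker iff the mean marker intensity over its segmented pixels reaches
an explicit per-marker threshold — thresholds are configuration, never
auto-tuned. Measurements per ROI: PanCK-positive area (mm^2), cell
densities (cells/mm^2), positive-cell percentages (not for DAPI, whose
percentage is definitionally 100),
$\mathrm{TPS} = 100\cdot\mathrm{PD\!-\!L1^+\ tumor} / \mathrm{tumor}$, and
$\mathrm{CPS} = 100\cdot(\mathrm{PD\!-\!L1^+\ tumor} +
\mathrm{PD\!-\!L1^+\ non\text{-}tumor}) / \mathrm{tumor}$, capped at 100
per clinical convention, with "immune cell" read as any segmented
non-tumor cell. TPS/CPS with zero tumor cells are explicit `NA` with a
reason, never silent zeros. Colocalization (CD3&CD8 for cytotoxic T cells,
CD3&PD-L1 for PD-L1+ T cells) counts cells positive for both markers.
Three ROI definitions are supported: the whole detected tissue, the
real-stain tumor mask applied to both sides, and each side's own
(respective) tumor mask.

## Concordance statistics

`dice_score()` is $2|A\cap B|/(|A|+|B|)$ with the empty-empty case defined
as 1 (logged) and empty-vs-nonempty as 0. `merge_combined_tumor()`
collapses the six LUAD growth-pattern categories into one combined-tumor
class (pixel counts conserved — asserted), for analyses involving
non-LUAD cases. `luad5_subset()` keeps cases whose subtype area strictly
exceeds 5% of their total tumor area ("exceeds" read as strict;
zero-tumor cases are excluded with a warning). `pearson_ci()` implements
the Fisher-z interval directly (cross-checked in tests against
`stats::cor.test`), with correlations within 1e-12 of ±1 snapped to ±1.
`paired_summary()` joins real and virtual measurement sets by case, ROI,
measure and marker and reports r with CI, mean |difference|, and the
pairwise-dropped count for undefined entries.

## What the phantom tests show — and what they cannot

Passing this suite demonstrates that the algorithms are implemented
correctly: the renderer is invertible to 1e-6, the QC flips exactly at the
6-um rule, the loss absorbs exactly the padding it promises, training
optimizes and reproduces bitwise, quantification recovers planted ground
truth, and the statistics match closed forms. The phantoms do not contain
real AF spectra, stain chemistry variation, scanner optics, out-of-focus
regions, or the morphological diversity of NSCLC; no claim about clinical
virtual-stain fidelity follows from these tests, and the headline
concordances on real cohorts are out of reach without the original slides.

## Known limitations

* The global affine module estimates and scores the transform but the
  package performs no deformable correction — warped regions are excluded,
  not fixed.
* The native-R stainer is desk-scale; kernel counts, schedules, attention
  gates and production batch sizes are config surface, not defaults.
* The random-projection Fréchet embedding measures distributional drift in
  pixel space, not perceptual similarity.
* CPS's immune-cell definition (any non-tumor segmented cell) is one
  defensible reading of a rule whose operational details vary between
  laboratories.
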
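---
title: "Methods: synthetic imaging flow cytometry and HSC/LSC discrimination"
author: "ifcstem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic imaging flow cytometry and HSC/LSC discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Leukemic stem cells (LSCs) in acute myeloid leukemia co-reside with healthy
hematopoietic stem cells (HSCs) in the CD34+CD38- marrow compartment.
Immunophenotypic LSC markers such as CLEC12A are informative but
heterogeneous across patients, which motivates a complementary,
morphology-based discrimination: imaging flow cytometry (IFC) records a
brightfield (BF), side-scatter (SSC) and several fluorescence images per
cell, and a convolutional neural network (CNN) can be trained to separate
CLEC12A+ LSCs from healthy HSCs using image content alone.

Patient-level IFC data of this kind are not publicly distributable, so the
package re-implements the full analysis pipeline against a fully synthetic,
seeded event generator with known ground truth. Every downstream stage —
masks and features, spillover compensation, the eleven-step gating
sequence, class balancing and splitting, the seven channel-combination CNN
models and the metric stack — is the real analysis code; only the photons
are simulated.

## The synthetic event model

One event is a nine-channel image stack (Ch01 BF, Ch02 viability, Ch03
CLEC12A, Ch04 CD14, Ch06 SSC, Ch07 DNA, Ch08 CD45, Ch10 CD38, Ch11 CD34)
on a 64 x 64 px frame at 0.3 um/px (an emulation of 60x magnification)
with a 12-bit ADC (`adc_max` 4095). Cells are soft-edged elliptical discs:

* **Brightfield**: bright background (offset 3000 counts, read noise
  12 counts) with a darker cell disc (`edge_depth`) carrying
  per-pixel multiplicative texture (`bf_texture_sd`).
* **SSC**: sparse bright granules; a Poisson count (`granule_lambda`)
  of unit-mass 3 x 3 stamps with log-normal amplitudes
  (`granule_brightness`).
* **DNA**: a nuclear disc (`nuclear_fraction` of the cell radius) with
  relative chromatin texture (`dna_texture_rel`), scaled to the event's
  sampled DNA intensity.
* **Fluorescence**: per-event integrated intensities drawn log-normally per
  population and channel, spread over the cell interior; CD45 is rendered
  on a membrane ring just inside the optical boundary. The seven
  fluorescence channels are mixed per pixel by a known spillover matrix
  before background, noise and quantisation.

Stochastic structure is drawn on a cell-local patch, so re-rendering the
same latent draw at a shifted integer centre translates the image exactly;
this is what makes the translation-invariance tests of the feature module
exact rather than approximate.

Artifacts are first-class: doublets (two touching cells), out-of-focus
events (Gaussian blur, sigma 3 px), saturated events (pixels clipped to
`adc_max`), dead cells (high viability-dye uptake), debris (sub-cellular
blobs) and an unstable-flow window (an event-rate burst, by default 4x
between 20 s and 25 s of a 120 s acquisition). Ground truth records every
label and flag together with the sampled latent parameters.

### Class differences and their ordering

The magnitudes of HSC/LSC morphological differences are not quantified in
the literature this emulates; only their ordering (BF > DNA > SSC
separability) is. The defaults encode that ordering once and are not meant
to be tuned per experiment:

* BF: LSCs are larger (4.0 vs 3.4 um radius), deeper and more textured.
* DNA: LSC chromatin texture is coarser (0.85 vs 0.60 relative amplitude)
  and DNA intensity higher; the nuclear *radius* is deliberately matched
  between the classes (`nuclear_fraction` 0.63 vs 0.74 against the
  differing cell radii), so the DNA channel carries texture and intensity
  information rather than restating cell size.
* SSC: a mild granule-count difference (5.8 vs 5.0), the weakest cue.

Per-patient heterogeneity is additive offsets on the LSC morphology means
(radius, granule density, chromatin texture, brightfield texture and cell
darkness), one profile per synthetic patient. Patient `P1` is shifted
towards the HSC phenotype in *all* brightfield-visible parameters — every
BF cue has to move, otherwise a CNN simply reads the remaining one — so
BF-based classifiers recall its LSCs worst: the planted analogue of the
patient-to-patient recall spread the analysis is designed to expose.
`P1`'s nuclear *fraction* is not shifted, so DNA-aware models partly
rescue it, mirroring the qualitative behaviour reported for multi-channel
models.

### Controls

`make_controls()` emits, per sample, a fluorescence-minus-two (FM2) store
(CD38/CLEC12A generated at background only), an unstained store and a
DNA-dye-only store, plus seven bead-style single-stain compensation
stores. Two deliberate choices:

* **Autofluorescence is channel-specific and equals the negative-population
  staining level** (e.g. 250 counts on CD38, 120 on CLEC12A). This makes
  the FM2-blanked channels a faithful anchor for positivity: their
  compensated distribution coincides with the stained sample's negatives.
* **Single-stain controls are bead-like** with near-zero off-channel
  autofluorescence. Regression through the origin picks up any positive
  off-channel offset as a spurious slope of order
  `E[auto] * E[x] / E[x^2]`; cellular autofluorescence would bias the
  spillover estimates by roughly +0.007, beads keep the bias below 0.001.

The DNA (Ch07) spillover column is scaled per sample (uniform 0.8–1.3,
derived deterministically from the seed and sample id) to emulate
sample-dependent DNA signal strength; each sample's DNA-only control is
used to re-estimate that column before compensation.

## Feature definitions

The commercial instrument's feature definitions are unpublished, so the
package fixes open re-definitions and uses them consistently on both sides
(generator-derived expectations and gating thresholds):

* **Gradient RMS** (focus score): RMS of the central-difference gradient
  magnitude over the mask, edges replicated. Additive-invariant; 0 for an
  empty mask.
* **Cell mask**: Otsu threshold on |pixel - background mode|, morphological
  closing, largest connected component; an empty mask is a valid, flagged
  outcome for blank frames.
* **Membrane mask**: `dilate(mask, 1)` minus `erode(mask, ring_width - 1)`
  (default width 3 px).
* **Area**: pixel count x pixel area. **Aspect ratio**: minor/major axis
  from second-order mask moments with a 1/12 unit-square correction (an
  axis-aligned 2:1 rectangle gives exactly 0.5). **Circularity**:
  mean/sd of boundary-pixel distances from the centroid (large = round); a
  single-pixel mask gets the `Inf` sentinel. Boundary pixels are mask
  pixels with at least one non-mask 4-neighbour.
* **Intensities**: background-subtracted mask sums (background = median
  outside the dilated mask, per channel), clipped at zero;
  `raw_max_pixel` and `saturation_count` are computed on the uncompensated
  rasters over the whole frame. Membrane-ring sums are computed for all
  seven fluorescence channels so the ring vector can be compensated with
  the same matrix as the whole-cell vector — compensating the CD45 ring
  with a whole-cell correction factor would wrongly deflate it whenever
  nuclear DNA spill dominates the whole-cell correction.

## Compensation

The spillover matrix entry `S[i, j]` is the no-intercept least-squares
slope of channel-*i* intensity on channel-*j* intensity over channel *j*'s
single-stain events ("best-fit linear regression"); the diagonal is 1,
negative slopes clip to 0. Compensation replaces each event's intensity
vector `x` by `solve(S, x)`; negative compensated values are retained, and
saturation statistics are never compensated. Through-origin slopes are
scale invariant, so control staining brightness is immaterial.

## Gating

Eleven ordered gates: focus; unsaturated (raw max < 4096 and saturation
count < 1 in every fluorescence channel); stable flow; singlet (area
window and aspect-ratio floor); live (viability dye at or below the
live/dead valley — "negative-to-dim" is inclusive of the valley);
nucleated (DNA+); CD45-low/SSC window on the membrane CD45 intensity;
CD14-; CD34+CD38-; CLEC12A+ (AML samples only); circularity strictly
above 5 (a value of exactly 5 is excluded). Gates short-circuit: an event
failing gate *k* is recorded as not-evaluated for later gates, and the
report telescopes (each gate's child count is the next gate's parent
count). Because each gate is a pure per-event predicate, the surviving set
equals the unconditional conjunction; reordering the artifact gates
changes per-gate counts but never the final population.

Thresholds come from three places:

* **FM2-anchored**: CD38 and CLEC12A positivity at the 99.5th percentile
  of the compensated FM2 intensities (the quantile is configurable; the
  anchoring control is fixed).
* **Data-derived**: the live/dead valley is found on the density of
  `log1p` viability intensities — the positive (dead) mode is the
  rightmost peak holding at least 5% of the maximum density, the negative
  mode the highest peak at least 2 log-units to its left, and the cut is
  the density minimum between them, floor-bounded by the unstained 99th
  percentile. A unimodal distribution falls back to the unstained bound
  with a warning. The 2-log separation requirement exists because weak
  viability signal quantises to a zero-inflated negative mode whose
  shoulder bumps must not be read as the dead population. Unstable-flow
  windows are 1-s bins whose event count deviates more than 5 robust SDs
  (1.4826 x MAD) from the median bin count, merged into intervals.
* **Configured defaults**, matched once to the default generator scales:
  focus floor 85 (between the blurred mode, at most ~80, and the sharpest
  in-focus cells, ~90+), singlet area 12–110 um^2 with aspect ratio at
  least 0.70, membrane CD45 in [1000, 22000] with SSC at most 18000, CD14
  positivity at 6000, CD34 at 2500.

## Cohort bookkeeping

Balancing by under-sampling uses iterative water-filling: samples whose
availability is below the current equal share contribute everything; the
remainder is split equally among the rest, and the integer remainder goes
one-per-sample to the uncapped samples with the *largest* availability
(ties by ascending sample id). This tie-break is the one that reproduces
the reference allocation in which the sample with the smallest uncapped
pool receives the smaller share; distributing by ascending id alone cannot.
The 80/10/10 split takes round-half-up n/10 for validation and test and
the remainder for training (8818 -> 7054/882/882), stratified per class,
drawn uniformly without replacement under the run seed. The per-patient
holdout is every gated LSC not drawn into the balanced pool; a patient
whose whole pool was drawn has an empty holdout.

## The CNN

A small VGG-style network: blocks of 3 x 3 same-padding convolutions with
ReLU ending in 2 x 2 max-pooling, then a dense ReLU layer and a softmax
pair. Defaults: three blocks of one convolution each with 8/16/32 filters,
dense width 64, input 32 x 32 (the 150 x 150 cap is honoured as a
maximum), Adam at 1e-3, batch 32, at most 30 epochs, early stopping when
validation accuracy has improved by less than 0.002 for 5 consecutive
epochs, with best-validation-epoch weights retained. The engine is written
in C++ (single precision, im2col + GEMM) and is seeded end to end: weight
initialisation and per-epoch shuffling derive from one generator, so a
fixed seed reproduces the accuracy curves byte-identically. The deeper
two-convolutions-per-block 16/32/64 variant remains available through the
specification object; the default was chosen so that the full seven-model
comparison trains on a single CPU in minutes, which is the regime this
package targets.

Inputs are prepared by stacking the requested channels in fixed
(Ch01, Ch06, Ch07) order, centring on the cell-mask centroid, symmetric
zero-padding or centre-cropping to the input size, and dividing by
`adc_max`.

## Problem sizes

The reference experiments run by the tests and the acceptance script use:
2000-event single-stain controls for spillover recovery; a 5000-event AML
cohort (with 500-event per-sample controls) for gating purity/recovery;
1500 events per class (HSCs from one pool, LSCs from five patient pools of
420) for the seven-model comparison, split 80/10/10; 1000 events per class
for the chance-level control, evaluated on a fresh 500-per-class draw; and
the undrawn 600 LSCs as the per-patient holdout. These sizes are the
package's reference study conditions; the generator scales to larger
cohorts with the same configuration object.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis relies on — bimodal
marker distributions with control-anchored boundaries, ordered class
effects in BF/DNA/SSC, artifact events that the early gates must remove,
per-patient heterogeneity — but not the optics of a real instrument: no
camera noise model beyond Gaussian read noise and quantisation, no
point-spread function (out-of-focus is a flat Gaussian blur), no
autofluorescence spectra, no spatial marker colocalisation beyond the
membrane/nuclear layouts, and cell morphology far simpler than real
hematopoietic cells. Passing the suite therefore demonstrates that the
pipeline's logic is correct and self-consistent under known truth — it
does not certify classifier accuracy on real marrow samples, where the
published per-patient spread shows exactly how strongly morphology can
drift.

## Known limitations

* Compensation acts on scalar per-event intensities, not per-pixel
  rasters; the CNN's image channels (BF/SSC/DNA) are never compensated.
  Gating decisions ride on intensities only, so this is sufficient for the
  pipeline's decisions, but pixel-level crosstalk in the DNA image is not
  removed before classification.
* The live/dead valley finder assumes the two stain states are orders of
  magnitude apart; stains with genuinely overlapping states would need a
  mixture-model split instead.
* Water-filling reproduces the reference allocation's multiset; which
  individual sample receives the +1 remainder is a convention (largest
  availability first) that a different laboratory log could contradict.
* The CNN is deliberately small; it is the analysis design that is under
  test, not a state-of-the-art architecture.
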
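---
title: "Quantifying silver-enhanced AuNP biodistribution from histology"
author: "AuNPquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying silver-enhanced AuNP biodistribution from histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Antibody-functionalized gold nanoparticles (AuNPs) accumulate in tumors and
clearance organs after intravenous injection. On histological sections the
particles themselves are invisible at brightfield scale, but silver
enhancement deposits metallic silver on the gold and renders each particle
aggregate as a dark, high-optical-density blob against tissue counterstained
with Nuclear Fast Red. Quantifying biodistribution from such sections means
turning calibrated section images into:

* **positive-pixel density** — silver-positive pixels per mm² of delineated
  tissue;
* **percent-positive signal** — positive pixels as a share of the region of
  interest (ROI);
* **deposit-size distributions** — areas (µm²) of individual deposits,
  identified as connected components, histogrammed per organ.

The pipeline in this package follows a four-stage procedure: weak-label
bootstrapping by color thresholding, neural segmentation trained on those
weak labels under a slide-level k-fold rotation, overlap-aware
re-concatenation of patch masks, and connected-component quantification.

## Coordinate and calibration conventions

All grids are indexed `[row, col]`, 0-based for anchors and bounding boxes;
polygon vertices are `(x = col, y = row)` pairs in pixel units, and a pixel
belongs to a polygon when its *center* (integer coordinate + 0.5) lies
inside under the even-odd rule. Calibration is a single isotropic
microns-per-pixel value (`mpp`); anisotropic images are rejected because
every reported quantity is an area. `mpp` is required user metadata — scan
resolution is never inferred from image content.

## Stage 1: weak labels by dynamic color thresholding

Silver deposits are achromatic and dark; Nuclear Fast Red is red-dominant
and much brighter. A pixel of a patch is raw-positive iff

* luminance `(R+G+B)/3` ≤ `min(dynamic cut, maxLuminance)`, where the
  dynamic cut is the patch's `luminancePercentile` luminance quantile
  (default 5th percentile) and `maxLuminance` defaults to 110/255 — the
  absolute cap keeps near-empty patches from thresholding into background;
* red/green ratio < `minChannelRatio` (default 1.35) — dark but
  red-dominant pixels are counterstain, not silver.

Morphological opening then closing with square 3×3 kernels (opening first
to suppress speckle, closing second to bridge pinholes) cleans the raw
mask. Morphology uses border replication: pixels beyond a patch edge do not
erode structures touching the edge, which keeps overlap margins consistent
between neighbouring patches.

Several threshold parameterizations are run per patch and the best mask is
chosen by *consensus*: the candidate with the highest mean pairwise IoU
against the other candidates wins, ties broken toward fewer positive
pixels. The default candidate grid varies the dynamic percentile (5, 15,
30): on signal-dense patches a low percentile truncates genuine deposits —
the cut lands inside the deposit luminance range, and because brightness
varies per deposit, whole deposits vanish — so the truncated mask
disagrees with the fuller candidates and consensus discards it. This is
the reproducible analogue of rejecting visibly undersegmented masks by
eye. An explicit correction mask, when supplied, overrides the selection
verbatim, which is the hook through which manual corrections re-enter the
pipeline as data.

## Stage 2: segmentation under a slide-level fold rotation

A compact U-Net-style fully convolutional network is trained on the weak
labels with pixelwise binary cross-entropy. The architecture has `levels`
encoder stages (default 4), each a single 3×3 convolution + leaky ReLU
(slope 0.1) followed by 2×2 max pooling; feature channels double per
stage starting from `baseChannels` (default 16), so the default
bottleneck carries 16 × 2⁴ = 256 channels — the doubling rule fixes the
deepest width once the start and depth are chosen. The decoder mirrors
the encoder with nearest-neighbour upsampling, skip concatenation, and
one 3×3 convolution per stage. The 1×1 sigmoid head sees the first-level
decoder features *plus an input-level skip* (the raw normalized color
channels): deposit boundaries in silver-stained material are sharp to the
pixel, and without the input skip the head only sees conv-smoothed
features and systematically erodes deposit rims. Probabilities are
binarized at 0.5 (config-exposed; nothing in the procedure calibrates it,
so the symmetric default is used).

Slides — never patches — are partitioned into k folds (default k = 3;
with 42 slides each rotation trains on 28 slides and segments the held-out
14). Patches of one slide are strongly correlated, so patch-level splits
would leak; the fold-leak guard in `segmentPatch()` refuses to segment a
training-fold slide unless explicitly overridden. Held-out inference is
what makes the output a learned segmentation rather than a replica of the
threshold-derived training labels.

Training uses Adam with bias correction and a per-epoch learning-rate
decay of 0.8 — positive pixels are ~1% of the data, so late-epoch
gradient noise from near-empty batches would otherwise keep the decision
boundary oscillating around the binarization threshold. The head bias is
initialized at the log-odds of the weak-label positive prior, so the
initial output matches the base rate and early gradients build positive
(deposit) evidence instead of re-deriving the background class. After
training, agreement with the weak labels is checked on a subsample of the
model's own training patches; a run that failed to learn (IoU against its
training labels below 0.5) is restarted once from a derived seed — a
convergence safeguard that never touches held-out data. All weights, the
patch sampling, and the shuffling derive from one seed, so the loss
trajectory is reproducible on single-threaded numerics. The training set
is drawn from the tiling patches of the training-fold slides, subsampled
(or crop-sampled with replacement when the cohort is smaller than the
target count) to `targetTrainPatches` square crops of `trainPatchEdge`
pixels, each augmented with random flips, quarter-turn rotations, and a
global brightness factor in [0.7, 1.4] — silver-deposit optical density
varies about three-fold between deposits, so shade invariance is part of
the concept being learned, and the rare bright-small-deposit stratum
would otherwise be data-starved at simulation scale. Uniform patch
sampling is deliberate: positively-weighted sampling was evaluated and
consistently degraded held-out agreement by distorting the background
statistics the network sees.

Numerically, training and inference run in single precision through
compiled kernels (im2col + GEMM convolutions); a double-precision R
implementation of the same network is kept as the reference
implementation, and the test suite checks that the two agree (gradients
to ~1e-4 relative) and that backpropagation matches finite differences.

## Stage 3: stitching without double counting

Patches overlap (default 1000 px patches with 100 px overlap; the overlap
guarantees any deposit narrower than the overlap lies wholly inside at
least one patch). At re-concatenation every section pixel takes its value
from exactly one patch — the one whose center is nearest, ties toward the
earlier anchor in row-major order — i.e. overlap margins are
center-cropped. This makes stitching a *left inverse of tiling*: cutting
any mask into patches and stitching them back is bit-exact, which is the
testable form of "no boundary effects, no double counting". Padding (for
images smaller than one patch) is bottom/right and is cropped away before
any quantification.

## Stage 4: quantification

Connected components use 8-connectivity by default (a deposit touching
diagonally is one physical aggregate; 4-connectivity is available).
Component ids are deterministic, ordered by bounding-box top-left.
Densities divide by ROI area; percent-positive divides by ROI pixel count —
the ROI is the only delineated reference object, so it is the denominator
for both reported quantities. Size histograms use left-closed bins with
default edges 0.25, 0.5, 2, 10, 50, 200, ∞ µm², bracketing the ~1 µm²
(single-cell organelle scale) and ~25 µm² (macrophage scale) deposit
classes; components smaller than the first edge are counted into the first
bin so that counts and areas are always conserved. The per-organ dominant
bin is the arg-max count, ties toward the larger-area bin, `NA` for organs
without deposits.

## The synthetic cohort: what it emulates and what it does not

No public imaging data accompanies this kind of study, so the package
ships a generator whose output is the test bed for every stage. A
synthetic section is a pale pink tissue background scattered with
red-dominant nuclear-counterstain ellipses, plus dark achromatic deposit
ellipses whose areas are drawn from a log-normal mixture. Deposits are
non-overlapping by construction (rejection sampling with an 8-neighbourhood
separation of one pixel), so the planted component count and areas are
exact; the ground-truth mask is the union of deposit pixels *before*
channel noise, which perturbs color only, never geometry.

Default conditions, chosen once:

* `mpp = 0.25` µm/px — a 40× scan scale. The analysis resolves individual
  ~1 µm² deposits; at coarser scales such a deposit is ≤ 4 px and the 3×3
  opening destroys it.
* Organ presets ranked tumor > spleen > liver > intestine > lung > kidney >
  heart with densities 1300/260/180/120/75/35/10 deposits per mm². The
  ordering follows the organ ranking reported for antibody-targeted AuNPs
  (tumor far highest; spleen and liver next; muscle at the detection
  floor); adjacent ratios are spaced more widely than the reported
  near-ties so that the family's strict ranking is statistically
  identifiable at simulation scale.
* Size mixtures: tumor 60% at 25 µm² + 40% at 1 µm² (large spots dominant
  with a secondary small class); liver/spleen mid-weighted around 8 µm²
  (macrophage uptake); intestine/lung/kidney/heart dominated by ~1 µm²
  deposits.
* Palette: background (235, 200, 210), counterstain (200, 120, 145) —
  red-dominant so the color veto has something to veto — deposit
  (40, 42, 45) with per-deposit brightness jitter, luminance well below
  80/255. Channel noise sd 8 (8-bit units).

The generator reproduces the features the method depends on — dark
achromatic deposits, red-dominant counterstain, calibrated scale, slide
replication — and deliberately not the features it does not: real stain
variation between scanners and batches, tissue texture, out-of-focus blur,
overlapping or diffuse deposits, section artefacts. Passing tests
therefore demonstrate the pipeline's internal correctness and its recovery
of known ground truth under realistic contrast, not performance on any
particular scanner's output.

## Simulation-scale configuration

The default `pipelineConfig()` is sized for a single desktop CPU: 42
slides of 512×512 px, 256-px tiles with 32 px overlap, a 2-level /
4-base-channel model, 150 training patches per rotation, 10 epochs,
learning rate 1e-2, batch size 2. These are the package's own test-scale
study conditions; a faithful-scale run (1000-px patches, 4-level /
16-channel model, ~5000 training patches) uses the same code paths through
the same arguments. The small model is sufficient here because synthetic
deposit/background contrast is essentially a color classification problem
with local context; the faithful model's extra capacity addresses real
histology variability that the generator does not emulate.

## Numerical choices and degenerate inputs

* Quantile type 7 (R's default) for the dynamic threshold cut.
* Sub-pixel ellipses rasterize to at least one pixel (the pixel under the
  center), so planted components are never empty.
* Rejection sampling for deposit placement errors out with advice to lower
  the density after a bounded retry budget rather than looping forever.
* `IoU(∅, ∅) = 1`: two empty masks agree perfectly; this matters for
  organs at the detection floor.
* Zero-deposit sections propagate cleanly: empty component tables,
  all-zero histograms, `NA` dominant bin, densities of 0.
* Inference pads inputs to a multiple of 2^levels by edge replication and
  crops the output back; training instead requires divisible crop edges,
  failing fast with a clear message.
* Adam: β₁ = 0.9, β₂ = 0.999, ε = 1e-8, with the standard bias-corrected
  step size.

## What the simulation scale can and cannot measure

On the default cohort the pipeline recovers per-organ densities within
about −5% to −11% of planted ground truth for the signal-dense organs
(tumor, spleen, liver, intestine, lung are all biased slightly low because
weak labels, and hence the network, under-cover deposit rims), preserves
the organ ranking, and beats the thresholding bootstrap's held-out IoU on
every organ. For the sparsest presets the per-organ estimate is, by
construction, at the mercy of single deposits: kidney realizes only a few
deposits per six-slide cohort at this section size, so one missed bright
16-px deposit moves the organ mean by more than 15%, and dominant-bin
calls with knife-edge count margins (6:5) can flip. This is a sample-size
property of the simulation scale, not of the method — the same pipeline
measured on ground-truth masks recovers densities and histograms exactly,
and the bias shrinks with section area and replicate count. Conclusions
about organs near the detection floor should be drawn from pooled areas,
not per-organ means, at this scale.

## Known limitations

* The weak-label dialect (percentile cut + cap + red/green veto) is one
  concrete realization of "color-channel-specific dynamic thresholding";
  on real slides its parameters would need retuning per staining batch.
* Manual mask selection and correction are replaced by consensus selection
  with an override hook; the hook preserves the manual step as data but
  nothing in this package reproduces expert judgement.
* Components clipped by the ROI boundary are counted with their in-ROI
  area only, which slightly deflates the size histogram near borders.
* The synthetic generator's realism limits are listed above; in
  particular, claims about relative organ densities transfer to real
  tissue only insofar as real contrast resembles the simulated one.
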
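---
title: "Methods: OCT semantic segmentation and biomarker quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT semantic segmentation and biomarker quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octseg)
```

## Scope and model

`octseg` implements a complete desk-scale pipeline for pixel-wise semantic
segmentation of retinal OCT B-scans in neovascular age-related macular
degeneration (nAMD) and for the longitudinal statistics built on top of the
segmentations. The pipeline has five stages: an annotation/label layer, a
U-net style segmentation network with softmax-averaging ensembles,
pixel-concatenated F1 evaluation with inter-annotator concordance,
volumetric biomarker quantification with ETDRS central subfield thickness,
and cohort statistics (timepoint t-tests, multiple regression of 12-month
visual acuity). Because clinical OCT scans cannot ship with a package, a
synthetic phantom and cohort generator is a first-class module: every stage
is exercised end-to-end on data whose ground truth is known exactly.

### Label taxonomy

Eleven foreground classes follow the AAO consensus nomenclature for nAMD
biomarkers: ERM, NR, RPE, IRF, SRF, SHRM, dPED, fPED, Fibrosis, Choroid,
PHM. A twelfth background class (code 0) covers not-evaluated pixels
(vitreous, image crop). The softmax head needs a class for every pixel, so
background is trained and predicted like any other class but excluded from
every reported F1.

### Rasterization

LabelMe-style polygon annotations are rasterized with the even-odd rule
applied to pixel centres at half-integer coordinates; pixels whose centre
lies exactly on an edge count as inside. Overlapping polygons resolve by
painter's rule (the later shape in document order wins). How human
annotators resolve overlaps (e.g. fibrosis drawn inside an fPED) varies
between annotation workflows; painter's rule is this package's
convention, chosen because it is deterministic and matches common
rasterizers. Masks
are resized with nearest-neighbour interpolation only - bilinear
interpolation of class codes would invent classes.

## Network architecture and training

The network is declared by `model_spec()` and realized by `build_network()`:

* encoder: `n_poolings` blocks of (3x3 conv, batch norm, ReLU) x 2 followed
  by 2x2 max pooling; filters start at `base_filters` and double after
  every pooling, capped at `filter_cap`;
* a single conv-BN-ReLU bottleneck at the cap, with dropout
  (default 0.2) between encoder and decoder;
* decoder: `n_poolings` repetitions of (2x2 transposed convolution halving
  the filters, concatenation of the matching encoder skip, conv-BN-ReLU x 2);
* a 1x1 convolution and per-pixel softmax head.

With the defaults (256 px input, 64 base filters, 5 poolings, cap 1024) the
contracting path holds eleven convolution layers - five blocks of two plus
the bottleneck - which is the unique reading that reconciles "eleven
convolutions", "five max poolings", "first layer 64 filters, doubled after
every pooling" and "maximum 1024 filters": the doubling is capped at 1024
after the fifth pooling, at 8x8 spatial resolution. Skip connections are
concatenations (standard U-Net). Decoder filters halve after every
transposed convolution (512, 256, 128, 64, 32 for the defaults), then the
1x1 head. All convolutions are He-normal initialized and padded to
preserve spatial size.

Training minimizes categorical cross-entropy over all pixels with Adam at
learning rate 0.001. Epoch budget and early stopping are package choices:
at most 100 epochs with early stopping on validation loss at patience 10.
The batch size default is 8
(gradient accumulation over images); the bundled acceptance runs use batch
size 1, which at these training-set sizes gives many more optimizer steps
per epoch at identical cost and converges correspondingly faster.
`validation_score` is the macro-averaged foreground F1 on the validation
set at the best (lowest validation loss) epoch, and ranks models for the
top-k ensemble.

### The engine

No deep-learning framework is assumed: the package ships a compact,
fully vectorised CNN engine in base R. Feature maps are `(H*W) x C`
matrices; convolutions are im2col gathers followed by BLAS GEMM, and the
input gradient of a convolution is computed as a convolution with the
180-degree-rotated, channel-swapped kernel, so forward and backward are
both single GEMMs per layer. All gradients are verified against central
finite differences in the development checks. Two numerical choices
deviate from framework defaults and are deliberate:

* **Per-image batch normalization.** Normalization statistics are computed
  over each sample's own H x W pixels per channel, in training and at
  inference. With minibatch-as-accumulation training this is the coherent
  choice, it removes the train/test statistics mismatch of running-moment
  BN, and it keeps inference deterministic. Running moments are still
  tracked for reporting.
* **Determinism contract.** Fixed-seed runs are bit-reproducible on one
  machine/BLAS configuration; determinism across BLAS builds is not
  promised (floating-point reduction order may differ).

### Ensembles

`make_loo_plan()` implements the leave-one-out scheme: for each test image
the remaining test images join the training roster and `models_per_test`
models (default 5) are trained, differing only by seed; a test image never
contributes to a model that predicts it. With 36 test images this yields
180 models; the inter-annotator comparison uses the 10 models with the best
validation scores. `ensemble_predict()` averages member softmax stacks
arithmetically and takes the per-pixel argmax, ties broken toward the
lowest class code (deterministic and member-order-free).

## Evaluation

`f1_per_class()` accumulates TP/FP/FN over all pixels of all images before
computing per-class precision/recall/F1 ("pixel concatenation"); no
per-image averaging and hence no between-image SDs. A regression test
documents, on a constructed counterexample, that pixel concatenation and
per-image averaging agree only when per-image class prevalence is constant.
Classes absent from both truth and prediction are reported as undefined
(`NA`) and excluded from macro averages, never scored 0 or 1. The
concordance report scores each annotator and the model ensemble against a
consensus annotation, restricted by default to the ambiguous lesions SHRM,
fPED, dPED and Fibrosis. For synthetic fixtures the consensus is a
per-pixel majority vote with an expert-override hook; a human consensus
panel cannot be reproduced algorithmically, so the vote is explicitly a
testing stand-in.

## Quantification

Class volume = voxel count x (axial x lateral x B-scan spacing). Volumes
are computed in cubic micrometres and reported in mm^3 by default; the
source tables print volumes in "µm^3" at magnitudes around 0.01-0.93,
which is not physically consistent for retinal volumes, so the package
treats cohort volumes as abstract units - every downstream statistic is
scale-invariant. Central subfield thickness C0 averages column thickness
(pixels in the retina classes x axial scale) over all A-scan columns
within the 1 mm-diameter ETDRS central disc around the fovea. The retina
class set defaults to {NR, IRF, SRF, SHRM, RPE}, the common
ILM-to-Bruch's convention; it is configurable. The fovea centre comes from
metadata or defaults to the volume's geometric centre - no fovea detection
is attempted. Visit-to-timepoint interpolation assigns the nearest visit
within tolerance windows of +/-45 days (months 0 and 3) and +/-90 days
(month 12), ties to the earlier visit; the window widths are package
defaults.

## Cohort statistics

Qualitative acuity categories convert to logMAR by the established
constants: counting fingers = 1.98, hand movement = 2.28; decimal acuity v
converts as -log10(v). Timepoint comparisons are two-sided
independent-samples t-tests - independent, not paired, following the
source's explicit choice despite the longitudinal design - with no
multiplicity correction by default (a Bonferroni flag exists). Welch's
form is the default because the month SDs differ up to six-fold; the
pooled form is a flag. Normality is assumed on central-limit grounds; no
normality test is run. The 12-month VA model is OLS on the 11 baseline
markers with intercept. The CRT coefficient applies per millimetre of
CRT: the default coefficient (b = 0.17) sits alongside CRT values near
220 µm, which is only dimensionally plausible per millimetre, and the
per-mm convention keeps the simulated VA contributions realistic.

## The synthetic generator

`simulate_bscan()` builds layered phantoms from smooth 1-D boundary curves
(retina top, Bruch's membrane, choroid base) with a lesion menu: IRF cysts
as ellipses inside the retina, SRF/SHRM/fibrosis as half-ellipse pockets
in the subretinal space, dPED/fPED as domes elevating the RPE, ERM/PHM as
1-2 px membranes. Half-ellipses and thin curves are the simplest shapes
that still exercise thin-structure segmentation. Masks are exact by
construction and anatomical ordering (membranes above retina, IRF inside,
SRF/SHRM between retina and RPE, PED below the RPE, choroid below) is
assertable per phantom. Pixel intensity is the class mean plus Gaussian
noise (SD 0.03 by default), clipped to [0, 1]; means are loosely ordered
like real reflectivity (fluids dark, fibrosis/RPE bright) but kept
separated. The generator deliberately does **not** emulate OCT speckle
statistics, vendor-specific appearance, shadowing or signal roll-off; a
model that segments these phantoms has demonstrably learned shape and
intensity cues end to end, but nothing here certifies performance on
clinical scans.

`simulate_annotator()` emulates inter-annotator disagreement by
boundary-localized morphological perturbation (EBImage dilation/erosion of
the ambiguous lesion classes by a disc of radius = disagreement level).
Dilation claims only foreground pixels, erosion backfills from the nearest
label in the column, so background topology is preserved; level 0 is the
identity and concordance F1 is non-increasing in the level by construction.

`simulate_cohort()` draws marker volumes per eye and timepoint from
normals truncated at zero; several published SDs exceed their means
(e.g. SRF 0.08 +/- 0.25), so untruncated draws would go negative.
Truncation shifts realized means upward; `cohort_moments()` returns the
exact realized moments and recovery tests compare against those, not the
nominal parameters. Timepoints are drawn independently, mirroring the
independent-samples tests downstream, even though real eyes are paired.
Month-12 VA is the linear model on baseline markers plus Gaussian noise
with SD 0.42 - a value derived from the published standard errors
(the IRF coefficient SE of 0.29 at n = 336 with sd(IRF) = 0.08 implies a
residual SD near 0.42, and the month-0/month-3 VA comparison p = 0.003 at
n = 378 implies the same per-group SD).

## Problem sizes and statistical design of the bundled checks

The bundled acceptance runs use desk-scale problem sizes chosen as the
package's own defaults: learnability is demonstrated on fifty 64 px
phantoms (40 train / 10 validation) with an 8-filter, 3-pooling network -
at 64 px input, three poolings keep an 8x8 bottleneck, the same bottleneck
geometry as the full 256 px/5-pooling network - trained for 80 epochs at
batch size 1;
statistical checks use replicate cohorts of n = 378 eyes. One published
significance pattern cannot be reproduced as a joint event at these
parameters: ERM, dPED and PHM have identical month-0/month-3 parameters
(exact nulls), so each is "non-significant" in only ~95% of replicates,
and the Choroid shift (0.93 vs 0.96 at SD 0.41) has ~17% power. The test
suite therefore checks per-marker agreement rates with bounds fixed in
advance by this power analysis: at least 95% for the four high-power
significant markers (IRF, SRF, SHRM, CRT), at most 15% false-significance
for the exact nulls, at most 35% for Choroid.

## Known limitations

* Phantoms are not clinical OCT; passing tests show the pipeline learns
  and quantifies correctly, not that it matches published F1 on patients.
* The engine is CPU-bound base R: suitable for tens of small images, not
  for 256 px clinical training runs.
* Per-image batch normalization departs from framework BN; models trained
  here are not weight-compatible with framework implementations.
* Only the central ETDRS subfield (C0) is computed, not the 9-sector grid.
* Proprietary acquisition formats (Heidelberg .e2e/.vol, DICOM) are out of
  scope; I/O is PNG/TIFF, JSON, YAML and CSV.
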
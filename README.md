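# octseg

Semantic segmentation and biomarker quantification for retinal OCT in
neovascular age-related macular degeneration (nAMD).

Clinical decisions in nAMD are guided by biomarkers visible in OCT
B-scans: intraretinal and subretinal fluid, subretinal hyperreflective
material, pigment epithelial detachments, fibrosis, membranes. Measuring
how these change under anti-VEGF therapy across thousands of scans
requires pixel-wise segmentation. `octseg` provides the full pipeline as
an R package:

* an 11-class annotation scheme (AAO consensus nomenclature: ERM, NR,
  RPE, IRF, SRF, SHRM, dPED, fPED, Fibrosis, Choroid, PHM) plus a
  background class, with LabelMe polygon rasterization and palette PNG
  mask I/O;
* a U-net style encoder-decoder segmentation network - with the default
  geometry: 11 contracting-path convolutions, five 2x2 max poolings,
  a 1024-filter bottleneck at 8x8 from a 256 px input, dropout 0.2,
  trained with Adam at learning rate 0.001 on categorical cross-entropy -
  implemented as a self-contained vectorised CNN engine in base R;
* leave-one-out test-time ensembles (per test image, the remaining test
  images join the training set; softmax stacks are averaged) and top-k
  validation-ranked ensembles;
* pixel-concatenated per-class F1 evaluation and annotator-vs-consensus
  concordance reports;
* volumetric quantification (class volume = voxel count x voxel volume)
  and ETDRS central subfield thickness C0 (mean retinal thickness over
  the 1 mm central disc);
* cohort statistics: logMAR conversion (counting fingers = 1.98, hand
  movement = 2.28), independent-samples t-tests between months 0/3/12,
  and OLS regression of 12-month visual acuity on the 11 baseline
  markers;
* a synthetic OCT phantom and cohort generator so that every stage runs
  and is tested end-to-end without patient data.

The core statistic throughout is the per-class F1 score
F1 = 2TP / (2TP + FP + FN), computed over pixels concatenated across
images, with the background class excluded.

## Worked example

Simulate phantoms, train a small network, ensemble, evaluate and quantify:

```r
library(octseg)

ph    <- phantom_params(image_size = 64)
pairs <- lapply(1:50, function(i) simulate_bscan(ph, seed = i))

spec <- model_spec(input_size = 64, base_filters = 8, n_poolings = 3,
                   batch_size = 1, max_epochs = 80, patience = 80, seed = 11)
model <- train_unet(pairs[1:40], pairs[41:50], spec)  # ~6 min on one CPU
model
#> trained U-net: input 64, 12 classes, 80 epochs, validation macro-F1 0.823

preds <- lapply(41:50, function(i)
  probs_to_mask(predict_softmax(model, pairs[[i]]$image)))
f1_per_class(preds, lapply(pairs[41:50], function(p) p$mask))[, c("class", "f1")]
#>       class        f1
#> 1       ERM 0.9891697
#> 2        NR 0.9960000
#> 3       RPE 0.9672699
#> 4       IRF 0.8807854
#> 5       SRF 0.9402697
#> 6      SHRM 0.7075472
#> 7      dPED 0.5664336
#> 8      fPED 0.8807631
#> 9  Fibrosis 0.1269841
#> 10  Choroid 0.9992969
#> 11      PHM 0.9966555
```

The layered anatomy and fluid pockets segment almost perfectly; the
classes that stay hard - fibrosis sitting on the similarly bright RPE,
drusenoid vs fibrovascular PED - are exactly the ambiguous lesion pairs
the generator encodes with overlapping reflectivity. The macro average,
0.823, is the model's `validation_score`, which also ranks ensemble
members for `select_top_models()`.

Volumetry and cohort statistics:

```r
geom <- volume_geometry(n_bscans = 1, axial_um_per_px = 1900/64,
                        lateral_um_per_px = 6000/64, bscan_spacing_um = 120)
central_thickness_c0(list(pairs[[41]]$mask), geom)
#> [1] 513.5938   # µm, phantom retina under the central 1 mm disc

cohort <- simulate_cohort(cohort_params(n_eyes = 378), seed = 1)
timepoint_ttests(cohort, "SRF", pairs = list(c(0, 3)))[, c("marker", "mean1", "mean2", "p")]
#>   marker     mean1      mean2            p
#> 1    SRF 0.2307363 0.07433247 2.046786e-47
```

The simulated subretinal-fluid collapse between baseline and month 3 is
overwhelmingly significant, reproducing the qualitative treatment effect
the cohort parameters encode. (Baseline mean 0.23 exceeds the nominal
0.08 because volumes are drawn from normals truncated at zero; see the
methods vignette.)

A thin CLI wraps the same functions
(`inst/cli/octseg pipeline --config cfg.yml --seed 1`), with commands
`simulate`, `train`, `predict`, `evaluate`, `quantify`, `analyze` and
`pipeline`; every run writes a `manifest.yml` making it reproducible.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "octseg", load_package = "installed")'
```

The suite includes brute-force oracles (point-in-polygon rasterization,
confusion-matrix F1, textbook t statistics), property tests (volume
conservation, softmax normalization, anatomical ordering of phantoms) and
an end-to-end learnability check.

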
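# chiasmseg

Detection of malformed optic chiasms from T1-weighted MRI by the failure
of a segmentation network trained only on normal anatomy.

## The problem

The optic chiasm — the X-shaped midline crossing of the optic nerves — is
malformed in congenital misrouting disorders such as albinism: the chiasm
body and optic nerves are narrower and the angle between the optic tracts
wider than in controls. Detecting this from a routine anatomical scan is
clinically valuable (functional misrouting tests are burdensome for
exactly these patients), but malformed-chiasm datasets are far too small
to train a classifier directly. `chiasmseg` implements the
segmentation-failure strategy: train a 3D U-Net to segment *normal*
chiasms, then flag a new subject by the poor overlap — Dice similarity
coefficient,

    DSC(A, B) = 2 |A ∩ B| / (|A| + |B|),

between the network's mask and a reference mask. A network that has only
ever seen normal chiasms segments malformed ones badly, and that failure
is the diagnostic signal.

The package is aimed at neuroimaging methodologists: it contains the full
pipeline as composable R functions plus a synthetic phantom generator, so
every stage runs and is testable on one CPU with no imaging downloads.

## What is inside

* **Atlas-mask correction** (`correct_mask()`): upgrades noisy
  atlas-derived chiasm masks using the intensity percentiles (66th–98th)
  of the voxels inside the initial mask, an in-plane extended bounding box
  (5 voxels, left–right and posterior–anterior only), largest-cluster
  extraction, and a one-voxel dilation.
* **3D U-Net** (`build_unet()`, `unet_forward()`, `train_unet()`): five
  resolution levels, channels 10–20–40–80–160, two 3×3×3 convolutions per
  block each followed by per-channel normalization and ReLU, 2×2×2
  max-pooling and up-convolutions with skip concatenation, two-channel
  voxelwise softmax head — exactly **2,206,482** trainable parameters,
  verified against a closed-form count
  (`unet_parameter_count_formula()`). Forward and backward passes are
  native C++ (single precision, im2col + BLAS); training is mini-batch
  Adam (batch 2) on the soft-Dice loss.
* **Augmentation** (`augment()`): max-intensity normalization, random
  flips, random crop to 160³, random rigid affine (±15°, ±20 voxels,
  cubic b-spline for images, nearest neighbor for masks).
* **Inference** (`predict_probability()`, `extract_cnn_mask()`):
  probability map, threshold (default τ = 1.0, read as `p ≥ 1 − 1e-6`),
  largest suprathreshold cluster with no anatomical prior.
* **Evaluation & statistics** (`slice_restricted_dsc()`,
  `evaluate_cohort()`): Dice restricted to axial slices where the manual
  reference is present; mean ± SEM summaries; D'Agostino–Pearson-gated
  two-sample tests (pooled t-test / Wilcoxon rank-sum) with Bonferroni
  familywise correction over the 10-test comparison plan
  (`comparison_plan()`).
* **Classification** (`fit_svc()`): C-SVC with polynomial kernel on the
  one-dimensional DSC feature, four confusion metrics, explicit
  `in_sample` flag.
* **Phantom generator** (`make_phantom()`, `make_cohort()`): seeded
  X-shaped chiasm phantoms with partial volume, vessel-like hyperintense
  blobs, Gaussian noise, corrupted atlas-like masks (calibrated to mean
  DSC ≈ 0.57 against ground truth), and malformed variants (chiasm width
  × 0.5, nerve width × 0.7, tract angle + 30°).

See the methods vignette (`vignettes/chiasm-detection.Rmd`) for the models,
parameter choices and limitations.

## Worked example

The desk-scale experiment reproduces the pipeline's logic end to end on
phantoms — 40 normal training phantoms with corrupted-then-corrected
masks, a base-width-4 network, and 10 held-out normal + 10 malformed test
phantoms (about 15 minutes on one CPU core):

```r
library(chiasmseg)
ex <- run_phantom_experiment(master_seed = 11)
print(ex)
```

```
Mask correction: initial 0.572 -> corrected 0.893 (mean Dice, n=40)
Mean control Dice by threshold: 0.25: 0.901  0.50: 0.918  0.75: 0.934  1.00: 0.411
Selected threshold: 0.75
Network Dice: control 0.934 +/- 0.005 (n=10), malformed 0.861 +/- 0.006 (n=10)
Rank-sum control vs malformed: W = 100, raw p = 1.083e-05
C-SVC (polynomial kernel) on the Dice feature  [in-sample evaluation]
boundary (decision-function zero crossings): 0.9005
counts: TP=10 TN=10 FP=0 FN=0
accuracy 1.0000  precision 1.0000  recall 1.0000  specificity 1.0000
```

Reading the output: the correction algorithm lifts the corrupted atlas-like
masks from Dice ≈ 0.57 (the calibrated quality of raw atlas masks) to ≈
0.89 against ground truth; the binarization threshold is then selected
empirically on the held-out controls (0.75 here — at a desk-scale training
budget the predictions are not saturated enough for thresholding at 1.00,
so that setting collapses; see the vignette); and the control-trained
network segments held-out *normal* phantoms better than *malformed* ones —
the rank-sum p-value tests that contrast, and the in-sample support-vector
classifier summarizes how separable the two groups are on the Dice feature
alone. The absolute Dice values are phantom-scale numbers, not clinical
claims; the direction of the contrast is the scientific content.

Individual stages are ordinary functions:

```r
s   <- make_phantom(phantom_params(seed = 7))        # synthetic subject
ini <- corrupt_to_initial(s, corruption_seed = 1)    # atlas-like mask
cor <- correct_mask(s$volume, ini)                   # seven-step correction
dsc(ini, s$manual_mask); dsc(cor, s$manual_mask)
```

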
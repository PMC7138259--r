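---
title: "Segmenting overlapping cell-culture structures with per-class binary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting overlapping cell-culture structures with per-class binary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapseg)
```

## The problem

Phase-contrast microscopy of cancer cell cultures grown on *in vitro*
vascular structures shows semitransparent objects: vascular tube networks,
individual noninvasive and invasive cells, spheroids, invasive spikes on
spheroid rims, and granular cell matter around spheroids. Because the
structures are semitransparent they visually *overlap*, so a pixel can
legitimately belong to several classes at once. Segmentation is therefore a
**multilabel** problem with mutually non-exclusive classes — a per-pixel
softmax over all classes is structurally wrong, since it forces exclusivity.

The approach implemented here sidesteps that: it trains **one specialized
binary encoder–decoder network per class**. Each network has two output
channels per pixel — the target class and "everything else" — and a two-way
softmax turns the pair into a foreground probability. Ground truth is kept
as one binary mask per class; composite color images are derived
visualizations only, because color-coding overlapping classes is lossy.

The fixed schema is six foreground classes plus background, in the order
P (vascular structures), S (noninvasive cells), I (invasive cells),
IP (invasive spikes), O (spheroids), R (perispheroid cell matter).

## Dataset construction: balanced tile sampling

Full frames (1392 × 1040 at full scale) exceed what an encoder–decoder and
its training memory budget handle comfortably, so training operates on
square tiles (512 px at full scale). For each class and frame, the frame is
scanned on a stride grid; each tile origin is *positive* if its footprint
contains at least one foreground pixel of the class, otherwise *negative*.
At most 20 positive tiles per frame (the cap) are drawn uniformly without
replacement, and the same number of negatives, giving a balanced per-class
training set. Tiles may overlap each other — overlapping draws yield
differently aligned views of the same objects, which acts as a free
augmentation. No oversampling or undersampling across classes is needed,
because every class trains its own network.

Design choices the protocol leaves open, decided here once:

* **Candidate generation.** "Scanning" the frame is stride-agnostic; we use
  a dense row-major scan at a configurable stride (default 64 px), with the
  final origin in each axis clamped to `dimension − tile_size` so the scan
  reaches the border. On a 1392 × 1040 frame with 512-px tiles at stride
  256 this gives origins {0, 256, 512, 880} × {0, 256, 528} — 12 candidates.
* **Which positives to keep.** A seeded uniform draw without replacement,
  derived per frame and class, so the choice is reproducible, unbiased, and
  independent of processing order.
* **Positivity threshold.** One foreground pixel (configurable via
  `min_positive_pixels`); the protocol states no minimum.
* **No deduplication** of heavily overlapping positive tiles is performed.

## Augmentation

Augmentation is applied jointly to tile and mask: a random quarter-turn
rotation, independent horizontal/vertical flips, then an additive brightness
offset on the image only (default ±10 % of the intensity range, clipped to
[0, 1]). Rotations are restricted to quarter turns deliberately: arbitrary
angles would interpolate the binary mask and there is no principled
interpolation rule; quarter turns are lossless and label-exact. Whether the
original brightness jitter was additive or multiplicative is unknown; the
additive choice is isolated behind one function. An optional gamma
transform (off by default) is available, since contrast robustness is a
known weakness of intensity-thresholded spheroid interiors.

## Network

A classic U-Net topology: `depth` encoder levels of two 3 × 3 convolutions
(ReLU) and a 2 × 2 max-pool, a two-convolution bottleneck, and a mirrored
decoder of 2 × 2 stride-2 transposed convolutions with skip concatenation
along the channel axis, ending in a 1 × 1 convolution to 2 channels.
Convolutions are SAME-padded so the output size equals the input size —
required because stitched inference averages full-tile predictions with no
crop bookkeeping. Weights are Glorot-uniform initialized from a seed;
biases start at zero. Defaults kept deliberately plain because the original
modification list is unknown: ReLU activations, no normalization layers,
transposed-convolution upsampling. Depth and width are configuration knobs;
the full-scale preset uses depth 4 / 64 base filters, the desk preset
depth 2 / 8 base filters on 64-px tiles.

The forward and backward passes are implemented in RcppArmadillo using
im2col + GEMM convolutions (BLAS-backed); gradients are verified against
central finite differences in the test suite.

## Loss, weighting, and schedule

The objective for a batch $K$ is

$$C = \sum_{\text{pixels}} r_{l(p),K}\, d(p) \;+\; \lambda \sum_w w^2,$$

where $d(p)$ is the two-way softmax cross-entropy at pixel $p$, $l(p)$ is
the pixel's ground-truth label (target class or "everything else"), and the
pixel-wise batch weight is $r_{l,K} = c_K / c_{l,K}$ — total batch pixels
over pixels carrying label $l$. Both labels therefore contribute equal
total weight ($r_{fg} c_{fg} = r_{bg} c_{bg} = c_K$), neutralizing the
foreground/background imbalance inside every batch. The sum (not mean)
over pixels is the objective; a `reduction` switch exists for scale
experiments. Interpretation notes:

* The weighting is applied *per pixel* by the pixel's own label — the
  alternative reading (weighting class-summed mean losses) is rejected as
  contradicting the pixel-wise formulation.
* A label absent from a batch gets weight 0 (the division is undefined);
  the batch is flagged degenerate.
* $\lambda = 0.001$; the L2 penalty covers convolution kernels only, not
  biases (a conventional choice; unspecified in the original protocol).
* Adam with library-default moments ($\beta_1 = 0.9$, $\beta_2 = 0.999$);
  learning rate $10^{-5}$ decayed by the staircase schedule
  $\mathrm{lr}(s) = \mathrm{lr}_0 \cdot 0.9^{\lfloor s/10000 \rfloor}$.
* Training runs a **fixed** number of epochs (1000 at full scale) and the
  final epoch's weights are used. There is no validation split and no
  best-on-test selection: selecting weights on the data used for the final
  metrics would bias them. An optional monitoring set can be logged in the
  history but never influences the result.

## Inference: overlapping-grid stitching

A plain disjoint tile grid produces visible seams at tile borders. Instead,
full-frame prediction uses 30 linearly spaced tile origins per axis
(linspace from 0 to `dimension − tile_size`, rounded half away from zero;
duplicates after rounding retained so the count is exactly $30^2 = 900$ on
a full frame). Every tile is predicted and the per-pixel foreground
probabilities are averaged. Probabilities (post-softmax), not raw scores,
are averaged; logit averaging is available behind the stitcher's interface
by passing score tiles instead. The per-pixel count of contributing tiles
is kept as a *coverage* channel: border pixels are averaged least and carry
the residual edge artifacts, so coverage is surfaced rather than corrected.
Note that corner origins alone do not guarantee gap-free coverage — the
linspace spacing must not exceed the tile size; the stitcher flags
uncovered pixels explicitly.

Binarization at the operating point (default 0.5, chosen manually rather
than tuned on test data) uses a strict inequality: a pixel exactly at the
threshold is background.

## Evaluation

Per class: pixel confusion counts at the operating point, sensitivity
$tp/(tp+fn)$, specificity $tn/(tn+fp)$, Dice $2tp/(2tp+fp+fn)$, the ROC
over all thresholds, and its AUC (trapezoidal, equal to the Mann–Whitney
statistic). Conventions:

* A class absent from a frame's ground truth is reported with sensitivity
  0.0 and Dice 0.0 and a machine-readable `class_absent` flag — matching
  the reporting convention of the original evaluation tables — with the
  AUC undefined for that frame.
* The generic `dsc()` helper returns 1.0 when both masks are empty (nothing
  to find, nothing found), flagged `both_empty`; the *report* convention
  above overrides this for absent classes.
* The AUC confidence interval uses DeLong's variance estimate of the
  Mann–Whitney AUC (the original protocol names no CI method; its printed
  intervals are extremely tight, consistent with huge pixel counts and an
  asymptotic method). Pixels are treated as exchangeable — no
  spatial-correlation correction — so the intervals understate spatial
  uncertainty; a seeded stratified bootstrap is available as an
  alternative.
* The four-color error image (TP white, TN blue, FP black, FN red) and a
  green-to-red absolute-error heat overlay are emitted per class.

## The phantom generator

No image corpus ships with the package, so a seeded generator renders
frames that reproduce the *statistical* structure the method assumes, not
photorealism:

* tubes (P) as smoothed random walks with a dark profile;
* spheroids (O) as bright disks with dark rims;
* a granular halo (R) ringing each spheroid;
* spikes (IP) rooted on spheroid rims;
* small bright cells (S), a fraction deliberately placed on vessels so
  P ∩ S overlap is nonzero by construction;
* dark spindles (I) aligned along vessels — intentionally shape- and
  intensity-similar to P, reproducing the real confusion mode between
  invasive cells and vascular structures.

Intensities are drawn so classes are separable by shape and texture but not
by any single global threshold. What the phantoms do **not** emulate:
phase-contrast optics (halos, shade-off), focus drift, growth dynamics over
imaging days, and annotation subjectivity. Passing end-to-end tests on
phantoms therefore demonstrates that the pipeline's machinery — sampling,
weighting, optimization, stitching, evaluation — works as specified; it
does not certify performance on real microscope data.

## Study conditions at desk scale

The package's own test suite and acceptance script run the pipeline
end-to-end on one CPU. The desk preset fixes these conditions: 256 × 256
phantoms, 6 training + 2 held-out frames, 64-px tiles at stride 32 with a
positive cap of 6 per frame, a depth-2 / base-8 network, batch 3, 200
epochs, Adam at $10^{-3}$ with staircase 0.9 every 1000 steps,
$\lambda = 0.001$, an 8 × 8 inference grid, threshold 0.5, and the two
high-contrast classes O and P. The learning rate is scaled up relative to
the full-scale value because a desk run takes roughly 3 × 10³ optimizer
steps rather than several hundred thousand; all other loss and schedule
semantics are identical. Expected behavior, mirroring the full-scale
findings qualitatively: distinct-shaped classes (O, P) segment well, while
shape-confusable classes (I vs P) score worst.

```{r desk-run, eval = FALSE}
res <- run_pipeline(preset_config("desk", seed = 1), out_dir = "run_out")
res$report[res$report$frame == "pooled",
           c("class", "sensitivity", "specificity", "dsc", "auc")]
```

## Numerical notes and limitations

* Softmax and cross-entropy use max-subtraction; the loss is exact in
  double precision. Non-finite losses abort training with the epoch, batch
  and step named.
* Mask binarization accepts any nonzero value as foreground (0/1 and 0/255
  dialects).
* ROC ties are handled by midranks; AUC equals the exhaustive pairwise
  tie-aware probability to numerical precision (property-tested).
* Thresholding ties (probability exactly at the operating point) go to
  background by definition.
* Training the full-scale preset (depth-4 network on 512-px tiles, 1000
  epochs) is a multi-day GPU-class workload and is shipped as configuration
  only; the desk preset is the supported CPU path.
* Determinism: every stochastic step (phantoms, sampling, initialization,
  shuffling, augmentation, bootstrap) is seeded; reruns with the same
  configuration reproduce results to floating-point determinism on the
  same BLAS.
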
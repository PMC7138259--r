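# overlapseg

Multilabel segmentation of overlapping cell-culture structures in
phase-contrast microscopy, with one specialized binary encoder–decoder
network per class.

## The problem

Cancer cells cultured on *in vitro* vascular structures and imaged with a
phase-contrast microscope show six kinds of semitransparent structures:
vascular networks (**P**), noninvasively growing cells (**S**), invasive
cells (**I**), invasive spikes on spheroid rims (**IP**), spheroids
(**O**), and perispheroid cell matter (**R**). The structures overlap, so a
pixel may carry several labels at once — a single per-pixel softmax over
all classes is structurally wrong for this data. Instead, each class gets
its own U-Net-style binary network with two output channels per pixel
(target class vs everything else); ground truth is one binary mask per
class.

The pipeline around the networks:

- **Balanced tile sampling** — per class and frame, at most 20 positive
  512-px tiles (tiles containing the class) and equally many negatives,
  drawn from an overlapping stride scan.
- **Label-consistent augmentation** — joint quarter-turn rotations and
  flips, image-only brightness jitter.
- **Weighted loss** — summed two-way softmax cross-entropy with pixel-wise
  batch weights `r_l = c_K / c_{l,K}` (inverse label frequency in the
  batch), plus L2 (λ = 0.001):
  `C = Σ_pixels r_{l(p)} · d(p) + λ Σ w²`.
- **Training** — Adam, lr 1e-5 with staircase decay ×0.9 every 10,000
  steps, Glorot init, a fixed 1000-epoch stop, final-epoch weights (no
  best-on-test selection).
- **Stitched inference** — 30 × 30 linearly spaced overlapping tile origins
  (900 tiles per full frame), per-pixel probability averaging, coverage
  channel, threshold 0.5.
- **Evaluation** — per-class sensitivity, specificity, Dice (DSC), ROC/AUC
  with DeLong 95 % confidence intervals, four-color error overlays, and
  explicit absent-class flags.
- **Phantom generator** — seeded synthetic frames reproducing the
  overlapping-class structure (including the deliberate shape confusability
  of I and P), so the whole pipeline runs and is tested without microscope
  data.

The encoder–decoder, backpropagation and Adam are implemented in the
package itself (RcppArmadillo, im2col + BLAS convolutions); gradients are
verified against finite differences in the test suite.

## Worked example

A CPU-scale end-to-end run: generate phantom frames, train one network for
the spheroid class (O) and one for the vascular class (P), predict two
held-out frames with overlapping-grid stitching, and evaluate:

```r
library(overlapseg)
res <- run_pipeline(preset_config("desk", seed = 1), out_dir = "run_out")
res$report[res$report$frame == "pooled",
           c("class", "sensitivity", "specificity", "dsc", "auc")]
#>   class sensitivity specificity       dsc       auc
#>       O   0.9639232   0.9880533 0.9139590 0.9983344
#>       P   0.9853212   0.9501480 0.8567408 0.9953326
```

(About 7 minutes on one CPU; 200 epochs per class on 64-px tiles.) Read the
rows as: at the 0.5 operating point the spheroid network finds 96 % of
spheroid pixels (sensitivity) while keeping 99 % of non-spheroid pixels
clean (specificity); the Dice score 0.91 summarizes the overlap between
predicted and true masks; AUC near 1 means spheroid pixels rank above
background pixels at almost every threshold. The vascular class is slightly
harder (thin tubes), but both high-contrast classes segment well —
mirroring the qualitative full-scale finding that distinct-shaped classes
work and shape-confusable ones (I vs P) do not.

`run_out/` then contains the resolved config, per-class checkpoints and
training histories, 16-bit probability and coverage maps, thresholded
masks, four-color error overlays, and the report as JSON + CSV.

A shell entry point wrapping the same functions ships in
`inst/cli/overlapseg.R`:

```sh
Rscript inst/cli/overlapseg.R synth --preset desk --frames 10 --seed 1 --out synth_out
Rscript inst/cli/overlapseg.R run --preset desk --seed 1 --out run_out
```

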
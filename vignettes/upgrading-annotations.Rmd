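---
title: "Upgrading low-quality cell segmentation annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Upgrading low-quality cell segmentation annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep segmentation networks for cell images need many well-annotated
training samples, but expert delineation of every cell boundary is slow.
A cheaper annotation process — a hurried expert, a trainee, or a classical
algorithm such as thresholding — produces labels that are incomplete
(cells missing), incorrect (non-target objects included), or sloppy
(boundaries drawn too tight or too loose). Training directly on such
labels hurts the final model.

`segupgrade` implements a perturbation-removal strategy around that
trade-off. Given a small set `X_HQ` of images with high-quality instance
labels and a much larger set `X_LQ` with low-quality labels
(`|X_HQ| < |X_LQ|`), it:

1. corrupts the high-quality labels with a stochastic perturbation
   function `P` that emulates the errors expected in `X_LQ`;
2. trains an *upgrade network* `u` on pairs *(image ⊕ P(label) → clean
   label)*, so `u` learns the mapping from a low-quality annotation back
   to a high-quality one;
3. applies `u` to `X_LQ`, obtaining upgraded labels;
4. trains the final segmentation network `f` on `X_HQ` together with the
   upgraded set.

Because `P` is stochastic, one well-annotated image yields arbitrarily
many distinct training pairs, which is why a handful of high-quality
slices suffices.

## The perturbation model

Labels are per-pixel instance maps: 0 is background and each positive id
identifies one cell. Target cells carry ids from a set `L`; known
non-target objects (distractors) carry ids from a disjoint set `Λ`, held
in a separate footprint layer so a clean annotation knows about objects
it deliberately excludes. Three formal perturbations act on such maps:

* **Omission** (`perturb_omission`) deletes a uniformly chosen subset of
  target cells whose size is exactly `round(rω · |L|)`. Rounding is
  half-away-from-zero so the customary rates (0.2/0.3/0.5/0.7 on
  multiples of ten cells) are hit exactly.
* **Inclusion** (`perturb_inclusion`) writes a uniformly chosen subset of
  distractor footprints, `round(rϕ · |Λ|)` of them, into the label as
  false foreground.
* **Bias** (`perturb_bias`) redraws boundaries: per cell it picks erosion
  or dilation uniformly and a severity `q ~ Uniform{1..qmax}`, then
  applies `q` iterations of the operation with a fixed 3×3 all-ones
  structuring element. Dilation claims background pixels only, so
  instances never merge; a cell eroded to nothing disappears (logged).

Two further stages support emulating the errors of an undertrained
network's predictions: inclusion of a random fraction of the segments
found by Felzenszwalb's graph-based segmentation of the *image* (so false
structures follow real image boundaries), and salt-and-pepper noise on
the binarized label. `compose_perturbation()` chains the enabled stages
in the order omission → segment inclusion → inclusion → salt-and-pepper →
bias.

Design choices where the formal definitions leave room:

* The bias operation and severity are drawn **per cell**, not per image;
  per-cell draws give the upgrade network a richer error distribution to
  train against, and the per-image reading is recovered as a special
  case.
* After salt-and-pepper the map is binary; connected components are
  relabelled as instances so a subsequent bias stage can still act per
  cell.
* Dilation collisions resolve in ascending id order (first processed
  wins), keeping the map single-valued.
* `resample_policy` distinguishes the two uses of `P`: `"once"` freezes
  one corruption per sample (how a fixed low-quality set is made), while
  `"per_draw"` redraws at every training iteration (how upgrade training
  pairs are generated).

## The network

Both the upgrade and the segmentation task use the same encoder–decoder
with skip connections at equal resolution. Each block is two 3×3
convolutions, each followed by batch normalisation and ReLU; blocks are
separated by 2×2 max pooling on the way down and 2×2 transposed
convolutions on the way up. The output has two channels (background /
foreground) through a soft-max, and the loss is the soft Dice loss with
smoothing `1e-6`, averaged over the two one-hot channels. The upgrade
network receives the binarized perturbed label concatenated to the image
as an extra input channel — the minimal encoding of an (image, label)
pair.

No deep-learning framework is assumed: the forward and backward passes
are implemented in the package (im2col + GEMM convolutions in
RcppArmadillo, everything else vectorised R) and verified against finite
differences in the test suite. Optimisation is ADAM. Training holds out a
seeded validation fraction (default 20%) of the training data, scores it
after each epoch with the pooled hard Dice (the "validation score" is a
Dice score, higher is better), and stops once `patience` epochs pass
without improvement, restoring the best parameters. Input intensities are
scaled to `[0, 1]` by the dtype maximum. Spatial sizes that are not
divisible by `2^depth` are zero-padded internally and cropped on output.

Defaults follow the reference protocol — learning rate `1e-5`, batch 4,
patience 10, 80/20 split — and the architecture defaults to depth 4 with
64 base channels. The `tiny` preset (depth 3, 8 base channels) is the
desk-scale variant used throughout the tests and the acceptance script;
depth 3 at 64×64 already gives the bottleneck a receptive field covering
a whole target cell, and 8 channels keep a CPU training run under a
minute.

## The synthetic generator

The generator emulates virtual-microscope volumes with two cell
populations: large bright target cells (HL60-like nuclei, in-plane radius
6–9 px by default) and small distractor cells (granulocyte-like, radius
2–3 px). Cells are random axis-aligned ellipsoids in (row, col, depth),
so consecutive slices cut the same cells at neighbouring depths and are
strongly correlated — the suite checks that adjacent-slice Dice exceeds
the 10-slices-apart Dice. Intensities are background plus per-cell
levels, modulated by multiplicative low-frequency texture, Gaussian
blur, and additive noise; 16-bit grayscale by default, with an 8-bit
histology-like RGB mode. Placement is rejection sampling with 100 retries
per cell and a conservative separation test, which guarantees the
pairwise-disjoint footprints the omission/inclusion semantics assume;
slices without any target cell are dropped.

Two properties are built in deliberately. The blur creates soft boundary
ramps and the distractors are nearly as bright as targets, so no single
global intensity threshold segments the target class perfectly — the
thresholding baseline lands around 0.86–0.89 pooled Dice on default
volumes, leaving genuine headroom for learned models. And per-slice
instance ids for targets and distractors come from disjoint ranges
(targets from 1, distractors from 1001).

What the generator does **not** emulate: realistic microscope PSFs,
intensity statistics of any particular instrument, cell clustering or
touching cells, or annotation idiosyncrasies of human experts. Passing
the desk-scale benchmark therefore demonstrates the *mechanism* — that an
upgrade network trained on perturbed high-quality labels transfers to an
unseen corrupted set — not the exact Dice levels reported on external
microscopy collections.

## Desk-scale study conditions

The test suite and `scripts/acceptance.R` use one fixed benchmark: three
64×64 volumes of 24 slices; 20 high-quality slices selected from volumes
1–2 with the equidistant circular sampler; 16 slices corrupted once with
70% omission as the low-quality set; volume 3 held out for testing (its
own 70%-omission copy measures annotation quality). Training uses the
tiny preset with learning rate `2e-3`, batch 4, patience 6, and at most
25 epochs, with the total optimisation budget bracketed in gradient steps
(`min_steps = 120`, `max_steps = 160`) so that tiny training sets — where
an epoch is a single batch — and large concatenated sets receive a
comparable number of ADAM updates. Under these
conditions the upgrade network lifts 70%-omission annotations from
roughly 0.5 to 0.9 pooled Dice, and a segmentation network trained on
HQ + upgraded labels matches HQ-only training while clearly beating
LQ-only training and the thresholding baseline.

## Evaluation and statistics

* `dice_score` pools by default: one global ratio `2|A∩B| / (|A|+|B|)`
  over all pixels of a test set (the closest reading of a Dice
  "computed over the entire test set"); the per-slice mean is attached as
  an attribute. Two empty masks score 1.
* `threshold_baseline` sweeps 101 thresholds (steps of 1% of the dtype
  maximum), picks the lowest threshold maximising pooled training Dice,
  and reports test Dice. RGB images are reduced to their channel mean.
* `annotation_cost(n_hq, n_lq, k)` is the linear equivalent-low-quality
  count `k·n_hq + n_lq`, with `k = 5` as an illustrative default.
* `wilcoxon_compare` is the two-sided paired signed-rank test: exact for
  tie-free n ≤ 25, exact by sign-flip enumeration with average ranks for
  tied n ≤ 15, normal approximation beyond; all-zero differences return
  p = 1 with a warning.
* Experiment drivers reproduce the study designs at any scale:
  `run_scenarios` (LQ-only / HQ-only / HQ+LQ / HQ+upgraded / threshold
  over repeated runs), `run_capacity_grid` (upgrade quality vs number of
  annotated slices and volumes), `run_mismatch_grid` (training
  perturbation ≠ data corruption), `run_hq_degradation` (imperfect
  reference annotations), and `run_cost_tradeoff` (Dice vs equivalent
  annotation cost).

## Conventions and numerical choices

* Coordinates are (row, col), 1-based in R interfaces; patch windows are
  anchored so the final row/column window sits on the image edge and
  every pixel is covered.
* "Middle slice" of a section of length `m` is `start + floor(m / 2)`.
* Subset sizes in perturbations use rounding half away from zero (base
  R's `round` is banker's rounding and would be off by one cell at
  half-integer counts).
* Soft-Dice smoothing `1e-6`; batch-norm epsilon `1e-5`, momentum 0.1;
  He initialisation for convolutions.
* Ties in the threshold sweep resolve to the lowest threshold.
* All stochastic stages are seeded: the generator from its config, each
  composed perturbation from an internal counter derived from the spec
  seed (so a fixed spec yields a reproducible corruption sequence), and
  training from the train config (splits, shuffling, initialisation).
  Identical seeds give bit-identical volumes, corruptions, and training
  trajectories.

## Limitations

* The upgrade network is 2-D; volumes are processed slice by slice.
* Binary (single target class) segmentation only.
* The pooled Dice hides per-slice variation; both are reported, but
  instance-level metrics (merges, splits) are out of scope.
* Labels written as PNG are limited to 8-bit ids by the png package; use
  TIFF for more than 255 instances.
* With mild corruptions the perturbation function generates little
  variety, and the upgrade network has less to learn from — consistent
  with the framework's intended use on strongly degraded annotations.

## A minimal session

```{r}
library(segupgrade)

vols <- generate_volumes(synthetic_config(n_volumes = 3, seed = 42))
pool <- volumes_to_dataset(vols[1:2])
plan <- sample_slices(vols[1:2], 20, 2)
hq   <- pool[match(sprintf("v%02d_s%03d", plan$volume, plan$slice), pool$ids)]
lq   <- make_low_quality(volumes_to_dataset(vols[[3]]),
                         perturbation_spec(omission_rate = 0.7, seed = 9))

cfg <- train_config(learning_rate = 2e-3, batch_size = 4,
                    patience = 6, max_epochs = 25, seed = 1)
res <- run_pipeline(hq, lq,
                    perturbation_spec(omission_rate = 0.7, seed = 9),
                    cfg, net_config = model_config(preset = "tiny"))
res$report[c("pre_upgrade_dice", "post_upgrade_dice")]
```
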
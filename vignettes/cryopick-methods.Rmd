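---
title: "Particle picking with set-prediction transformers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle picking with set-prediction transformers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-particle cryo-EM reconstructs a 3-D protein density map from many
2-D projections of individual particles scattered across micrographs.
The first computational step — locating those particles — must cope with
very low signal-to-noise ratios, ice contamination, carbon film edges and
crowding, and its precision/recall trade-off propagates directly into the
quality of the downstream 2-D classification and 3-D refinement.

`cryopick` implements a complete picking pipeline around a set-prediction
detector: a convolutional backbone extracts a low-resolution feature map
from a denoised micrograph, a transformer encoder–decoder turns it into a
fixed-size set of `N` candidate detections, and training aligns that set
with the ground truth through an optimal bipartite matching rather than
through spatial anchors and non-maximum suppression.

## Denoising chain

`denoise()` runs, in a fixed order, with every stage individually
skippable:

1. Gaussian filter (`gaussian_sigma`, default 1 px),
2. standardization to zero mean / unit variance,
3. linear mapping to the 8-bit grayscale range,
4. fast non-local means (`nlmeans_strength` 10 on the 8-bit scale,
   template window 7, search window 21),
5. locally adaptive Wiener filter (5×5 window),
6. CLAHE (clip limit 2, 8×8 tile grid),
7. guided filtering, with the **CLAHE-enhanced image as the guide** and
   the Wiener output as the filtering input (radius 8, epsilon 0.01 on
   the unit scale),

followed by a final re-standardization so the detector always sees a
zero-mean, unit-variance image. The grayscale stage precedes non-local
means and CLAHE because both operators are conventionally defined on
8-bit images. Gaussian smoothing and CLAHE are delegated to `EBImage`;
non-local means (offset-loop over integral images), the Wiener filter and
the guided filter are implemented in the package because no installed R
package provides them. All parameter defaults follow the usual
conventions of the respective filters and are exposed in
`denoise_config()`; none of them is fitted to data.

## Detector

The backbone is a residual network (depths 18/34/50/101/152; bottleneck
blocks from depth 50). For a full 4-stage backbone the activation map has
1/32 of the input resolution and 2048 channels (bottleneck) or 512
(basic). Grayscale micrographs are replicated to three channels. Two
departures from the textbook design are deliberate:

* **Normalization.** Batch statistics are replaced by per-channel
  *instance* normalization computed over the valid (un-padded) spatial
  region. This keeps single-image inference identical to batched
  inference, needs no running statistics, and makes the padded-batch
  equivalence below exact.
* **Configurable truncation.** `backbone_stages < 4` keeps only the first
  stages (output stride 4·2^(stages−1)), and `base_width` scales the
  channel widths. Small micrographs need a finer token grid than stride
  32 provides; the desk-scale experiments use two stages (stride 8).

A 1×1 convolution projects the `C`-channel map to the transformer width
`d`; the grid is flattened into `H·W` tokens. Fixed 2-D sine/cosine
positional encodings (half the channels per axis, interleaved sin/cos
pairs) are added to the attention inputs of **every** layer, not only the
first. Two positional design choices deserve emphasis, because both were
decisive for convergence speed in our experiments:

* **Where the encodings enter.** The encodings are part of the full
  attention-layer input — queries, keys *and* values
  (`pos_in_values = TRUE`). The common alternative restricts them to
  queries and keys; then the attention output is a mixture of
  position-free content vectors, and the decoder can only infer particle
  locations indirectly, which is a known cause of slow box-regression
  convergence in this detector family. With position-carrying values a
  query reads the location of what it attends to directly.
* **Frequency base.** `pos_temperature` sets the geometric frequency
  ladder of the encoding. The conventional base of 10000 is tuned to
  feature grids hundreds of tokens wide; on the small grids of
  desk-scale micrographs almost all channels are then near-constant and
  positions are encoded by only a handful of dimensions. The desk
  experiments use a base of 20, which spreads informative frequencies
  across all channels of an 8×8 grid; the package default remains 10000
  for full-scale geometries.

The decoder transforms `N` learnable particle queries (randomly
initialized embeddings, updated by backpropagation) through self- and
cross-attention; shared feed-forward heads emit, per query, softmax
probabilities over {particle, no-object} and a sigmoid-squashed
normalized box `(cx, cy, w, h) ∈ [0,1]^4`. The sigmoid is the package's
choice of how to guarantee the normalized-box contract. Defaults
(`d = 256`, 6+6 layers, 8 heads, `N = 600`, dropout 0.1 applied after
every attention and feed-forward sublayer before layer normalization)
follow the detection-transformer lineage; all are configuration-exposed.

Batches of unequal images are zero-padded bottom/right (`pad_batch()`).
Valid shapes are propagated analytically through every stage, the padded
region is re-zeroed after each normalization and pooling step, and only
valid tokens enter the transformer — so a prediction computed inside a
padded batch equals the unbatched prediction to floating-point noise.
This is tested as an invariant.

## Matching and loss

Training minimizes a Hungarian loss. The ground-truth set is padded with
no-object entries to size `N`; the matching stage finds the permutation
minimizing the summed pairwise cost

* cost of a true particle against a slot: −p̂(particle) + box loss;
* cost of a padding entry: 0 (indicator semantics);

with box loss `λ_iou · GIoU + λ_L1 · ‖b − b̂‖₁` (defaults `λ_iou = 2`,
`λ_L1 = 5`, the conventional values for this family, configuration-
exposed). The matching deliberately uses the raw probability while the
loss uses its negative logarithm — the asymmetry is part of the method
and is preserved. The generalized IoU adds an enclosing-box penalty so
disjoint boxes still receive informative gradients; it lives in `[0, 2]`
and is computed in corner coordinates after clamping degenerate widths
and heights at 1e−6. The solver is an O(n³) shortest-augmenting-path
assignment in compiled code; ties between equal-cost assignments are
broken by solver order (tests compare costs, never permutations). The
loss then sums, over all `N` slots, the negative log-probability of the
matched class — multiplied by **0.1** for no-object slots ("down-weight
by a factor of 10", resolving the ambiguity of "factor" explicitly as
division) — plus the box terms for true pairs. With auxiliary supervision
enabled (default), the same matched loss is applied to every decoder
layer's output through the shared heads.

## Optimization

AdamW with two parameter groups: transformer/heads at `transformer_lr`
(default 1e−4) and backbone at `backbone_lr` (default 1e−5), weight decay
1e−4, 300 epochs with both rates divided by 10 after epoch 200. Weights
are Xavier-uniform initialized (bound `sqrt(6/(fan_in+fan_out))`),
biases zero, normalization scales one; the same seed reproduces identical
weights and identical loss histories. Global gradient-norm clipping at
0.1 is enabled by default. An 80/10/10 train/validation/test split helper
is provided; when a validation set is given, the checkpoint with the best
validation loss is kept.

## The synthetic-scene generator

`simulate_scene()` emulates the qualitative artifact structure of real
micrographs: dark soft-edged particles (disks, annuli for ring-like
complexes, or randomly oriented ellipses) on a brighter background,
large soft blobs of altered mean intensity standing in for ice patches, a
half-plane intensity ramp standing in for a carbon edge, and additive
Gaussian noise (optional Poisson-like shot noise behind a flag). Centers
are drawn by rejection sampling with a margin of one radius and a minimum
pairwise separation, capped at 10,000 attempts per particle before an
error naming the constraint. Identical specifications reproduce
bit-identical scenes.

Defaults define the desk-scale study conditions: 64×64 scenes, 15
particles of diameter 8 px, minimum separation 10 px, background 0.5,
particle contrast −0.25, noise sigma 0.2 (per-pixel SNR well below 1 on
the raw signal), two ice patches. These values were fixed once as a
plausible miniature of a crowded micrograph; they are deliberately *not*
physically accurate image formation — no CTF, no 3-D projection, no
structured noise spectrum — so passing tests demonstrate correctness of
the pipeline and learnability of the task, not performance on real
cryo-EM data.

## Desk-scale experiments

The test suite and the acceptance script train a miniature configuration:
depth-18 backbone truncated to two stages at base width 16 (stride 8,
i.e. an 8×8 token grid on a 64×64 scene), `d = 64`, 2+2 transformer
layers, 8 heads, feed-forward width 128, `N = 20` queries, positional
temperature 20, on 200 simulated scenes with 50 held-out scenes for
evaluation. Because the backbone is trained from scratch (there is no
pretraining at this scale), both parameter groups share one learning
rate (1e−3, dropped ×10 at epoch 48 of 60); dropout is disabled (the
model is far below the overfitting regime and determinism simplifies
testing); batch size is 4. Held-out picking quality is scored at the
half-diameter tolerance, and a second identical run on raw
(non-denoised) inputs checks the direction of the denoising ablation:
training on denoised scenes ends at a clearly lower loss. The desk budget (60 epochs in the test suite, 50 in the
reproduction script) was fixed as the package's choice; it reaches the
onset of the convergence phase, not its end (see the set-prediction
dynamics note under limitations), so the reported desk-scale F1 reflects
a partially converged detector. The concrete numbers are produced by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R` at run
time.

## Picking and export

At inference, slots whose most probable class is no-object are dropped;
the rest are rescaled to pixel coordinates (`x = cx·width`,
`y = cy·height`; 0-based pixel coordinates, origin at the top-left, x =
column). Following the confidence-percentile rule, only candidates with
confidence at or above the 25th percentile are retained — computed per
micrograph by default (the pooled per-dataset variant is a flag), with
linear interpolation between order statistics and an inclusive
threshold, so fully tied scores are all retained. There is no
non-maximum suppression anywhere and no fixed confidence floor. Retained
picks are written as one plain-text box file per micrograph and merged
into a single STAR file (`data_particles` loop with MicrographName,
CoordinateX, CoordinateY, AutopickFigureOfMerit) for import into
downstream refinement software. Any vertical-axis flip a specific
downstream tool may expect is out of scope and documented here rather
than applied.

## Evaluation metrics

`evaluate()` scores picked coordinates against ground truth with four
metrics. A pick is a true positive if it pairs one-to-one with a truth
center within `tolerance × diameter` (default 0.5, i.e. one radius — the
natural particle-scale criterion; configuration-exposed because the
original evaluation protocol does not pin it down). The pairing maximizes
the number of matches, then minimizes total distance, via the same
assignment solver. Precision, recall and F1 follow from the matched
counts; the Dice score is computed separately on rendered binary disk
masks (truth disks at their own radii, pick disks at the median truth
radius), which is why it is not identical to F1. Per-micrograph rows are
aggregated into an `"average"` row holding summed counts and unweighted
(macro) means of the four metrics. Zero-prediction micrographs report
precision 0 with an `undefined_precision` flag rather than NaN.

## Numerical choices and degenerate inputs

* Constant images: standardization centers without dividing by zero;
  the 8-bit mapping sends them to 0; CLAHE passes them through.
* Degenerate predicted boxes: widths/heights clamped at 1e−6 before
  GIoU.
* Probabilities are floored at 1e−300 before logarithms.
* Attention softmax subtracts row maxima; layer/instance normalization
  uses epsilon 1e−5.
* The matcher refuses non-finite costs, and training aborts with a
  diagnostic on a non-finite loss instead of continuing silently.

## Known limitations

* The simulator is a caricature of cryo-EM image formation; results on
  it say nothing quantitative about EMPIAR-scale data.
* The automatic-differentiation engine is deliberately minimal (enough
  ops for this architecture) and CPU-only; full-scale training of the
  default configuration is out of reach without hardware acceleration.
* Set-prediction detectors are known to converge slowly. At desk scale
  the model passes through a long "anchor-like" phase before
  cross-attention learns to localize; with the positional-encoding
  choices above, localization converges within one to two hundred
  epochs. A second, slower mode remains: when the query surplus is small
  relative to the particle count (here 20 queries for ~15 particles),
  the few surplus prediction slots always overlap real particles, their
  matched/unmatched labels keep churning, and the confidence scores
  separate true picks from duplicates only very slowly. The percentile
  filter then discards some well-localized picks, which bounds the
  attainable F1 on crowded desk-scale scenes well below what the
  localization quality alone would allow. The full-scale geometry
  (`N = 600` queries against at most a few hundred particles) does not
  have this inversion: surplus slots rest on background and the
  no-object class is easily learned.
* Only MRC (2-D), COCO JSON, box and STAR formats are handled; TIFF/EER
  movies, CTF metadata and everything downstream of the STAR file are
  out of scope.
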
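---
title: "Goal-directed channel attention: model, training regime, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-directed channel attention: model, training regime, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(focalgain)
```

## The model

`focalgain` implements a goal-directed (top-down) attention mechanism for
convolutional image classifiers. A frozen, pre-trained backbone is augmented
with a single trainable layer at a mid-level *insertion point*: one
non-negative gain $g_f \in [0, \infty)$ per convolutional filter $f$, shared
across all spatial positions. If $A_{h,w,f}$ is the insertion block's
activation tensor, the modulated representation is the Hadamard product

$$\tilde A_{h,w,f} = g_f \, A_{h,w,f},$$

which then flows through the unchanged remainder of the network. Gains start
at exactly 1 (identity), may grow without bound (amplified filters), and are
clamped at 0 after every optimiser step (projected gradient), so a
"switched-off" filter has a gain of exactly zero. Only the gain vector is
trainable; every backbone parameter is frozen, which the tests verify by
byte-level snapshots.

The *task* is specified by a target class set $\mathcal T$ and an attention
intensity $\alpha \in [1/N, 1]$, where $N$ is the number of classes. Training
minimises a class-weighted cross-entropy over the full $N$-way problem: an
image with true-class probability $p_i$ contributes

$$\ell_i = w_i \,(-\log p_i), \qquad
  w_i = \begin{cases} \alpha & y_i \in \mathcal T \\
  \frac{1-\alpha}{N-1} & \text{otherwise,} \end{cases}$$

summed (not averaged) over the batch, so $\alpha$ keeps its meaning as an
absolute class weight. $\alpha = 1/N$ weights all classes equally — the
no-selective-attention control; $\alpha = 0.5$ balances the target against
all non-target classes combined; $\alpha = 1$ ignores non-target classes
entirely. Intensities below $1/N$ (anti-attention) are rejected. The
canonical grid is `alpha_grid(N)`: $1/N$, $2/N$, $0.5$, $(N-1)/N$, $1$.

Each training epoch uses every target-class training image plus a fresh
random 10% of each non-target class, with each subsampled image up-weighted
by its class's inverse realised sampling fraction
(`subsample_correction()`), so the expected loss is unchanged by the
subsampling — a property the tests verify by Monte-Carlo. Validation loss
(the same weighted cross-entropy over the entire validation split, no
subsampling) is checked periodically; training stops when the relative
improvement is below 0.1% at two consecutive checks.

## Evaluation: signal detection

A trained model is scored as a detector of its target. Under the max
decision rule (`decide()`, ties broken toward the lowest class index), a
*hit* is a target response on a target-present trial, a *false alarm* a
target response on a target-absent trial. Test sets are balanced — equal
target-present and target-absent trial counts — which licenses the standard
normal-model quantities

$$d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\left(z(H) + z(F)\right),$$

with rates of exactly 0 or 1 replaced by $1/(2n)$ and $1 - 1/(2n)$ (the
usual finite-sample correction; the underlying study does not state its
handling of extreme rates, so we adopt the field default). Two stimulus
regimes are built in: *standard* single-label images, and *blended* images —
50/50 pixel averages of two images from different classes that carry both
ground-truth labels; a blended trial is target-present if either label is
the target. A directory loader (`load_challenge_set()`) admits user-supplied
challenge sets scored the same way.

Sweep-level statistics treat each (target class, intensity) cell as one
observation: a one-way ANOVA of d′ across intensity levels
(df $= (A-1,\; AC-A)$ for $C$ classes and $A$ levels) and a paired t test
across classes between the two best intensity columns (df $= C-1$).
Degenerate inputs (zero variance) are flagged rather than raised.

## The synthetic fixture world

`synthetic_spec()` defines a deterministic K-class image world (default:
K = 10 classes, 60 images per class, 32×32×3 pixels, pixel noise SD 0.05)
that stands in for a large photographic dataset. Each class is a family of
bright, localised blobs in a class hue over a dim grating at a class
orientation and frequency. Two design choices matter:

* **Localised features.** Class identity lives in spatially local structure
  (coloured blobs, oriented texture) rather than a global colour wash,
  because the blended-image experiment averages two images pixelwise: local
  features survive averaging at half contrast, the way photographed objects
  do, while a global hue wash would be destroyed (two hues average to a
  third).
* **Overlapping parameter ranges.** `similarity` (default 0.45)
  simultaneously contracts the class parameter centres and widens the
  per-image parameter jitter, so class ranges genuinely overlap and the task
  has irreducible Bayes error. At `similarity = 1` every class draws from
  the same distribution and a trained classifier falls to chance; at the
  default, the converged fixture backbone reaches ~86% validation top-1 —
  above the 80% floor the generator guarantees, yet clearly off ceiling,
  emulating a strong-but-imperfect pre-trained classifier. Without this
  (with separable classes) the frozen backbone is perfect on held-out data
  and goal-directed re-weighting has nothing to trade.

The fixture backbone (`build_fixture_backbone()`) is a three-block
convolutional network (3×3 same convolutions, ReLU, 2×2 max pooling;
16/32/32 filters) with a softmax head. The attention insertion point is the
output of the penultimate block — 32 filters, a mid-level representation.
When a block ends in pooling, modulation applies to the block's final
(pooled) output; the alternative (pre-pooling) is algebraically identical
for max pooling up to ties and is not separately implemented.
`prepare_fixture_world()` trains the backbone to convergence (default 80
epochs of Adam at 1e-3; residual training loss ≈ 0.02) before freezing it:
with an unconverged backbone even uniform class weighting has gradient
through the gains, and the $\alpha = 1/N$ control would drift away from the
all-ones identity, which is not the phenomenon under study.

## Fixture-scale training regime

`train_config()` defaults to the full-scale regime: Adam at learning rate
3e-4, batch size 16, at most 5000 epochs, validation checks every 2 epochs.
At full scale an "epoch" is tens of thousands of optimiser steps; in the
fixture world an epoch is ~7 steps, so that cadence neither trains nor
terminates sensibly. The reference sweep (`run_reference_sweep()`) therefore
uses a rescaled regime as its default `train_cfg`, chosen once from pilot
runs of training health (does the validation loss genuinely improve before
the plateau detector trips) and stated here as the package's study
conditions at fixture scale:

* `learning_rate = 0.01` — with 32 trainable gains and tiny epochs, 3e-4
  leaves the weights essentially unmoved within any realistic epoch budget;
* `check_interval = 20` — plateau checks spaced so each window covers a
  comparable amount of optimiser progress to the original every-other-epoch
  cadence;
* `max_epochs = 600` — complete target focus ($\alpha = 1$) drives its
  held-out target loss down geometrically, so its relative improvement never
  falls below 0.1% and only the epoch cap terminates it. The cap is the
  fixture's budget for how far overfitting to the target may proceed.

The stopping rule itself (0.1% relative improvement, two consecutive
checks), the 90/10 split, the 10% non-target subsample and the batch size
are unchanged.

Two open choices are resolved as follows: the final-epoch weights are kept
(no best-checkpoint selection — the validation split drives early stopping
only), and the subsample correction uses each class's realised sampling
fraction rather than the nominal 10%, which is exact when class sizes
differ.

## The reference sweep and what it shows

`run_reference_sweep()` trains one model per (target class, α) cell — 10 × 5
at defaults — and evaluates each on a per-target balanced standard test set
(all 10 target test images plus 10 sampled non-target images) and a balanced
blended test set (10 target-present and 10 target-absent 50/50 blends),
fixed across intensities so the intensity effect is measured on identical
stimuli. On the seeded reference run the package reproduces the qualitative
cost/benefit pattern: mean hit *and* false-alarm rates rise with α, the
criterion falls monotonically (increasingly liberal responding),
standard-set sensitivity d′ peaks at a moderate intensity and collapses at
complete focus, and the attention-weight distributions grow more extreme
with α (rising variance, filters driven to exactly zero). The acceptance
suite asserts exactly this pattern; the numeric values are fixture-scale
quantities, not the published full-scale statistics, which depend on the
original dataset and network and are out of scope here.

One sub-pattern does **not** reproduce at fixture scale, and the
corresponding acceptance assertion is expected to fail rather than being
weakened: on *blended* images, mean d′ at complete focus (α = 1) exceeds
mean d′ at balanced attention (α = 0.5). Two fixture-scale forces combine
against the full-scale ordering. First, the generator guarantees a backbone
at or above 80% validation accuracy; at that accuracy the α = 0.5-weighted
loss is already nearly minimised at the identity gains, so balanced
attention moves the weights little and gains little on blends (blended hit
rate 0.26 vs 0.23 for the control on the seeded run). Second, a 32-gain
layer on an accurate backbone cannot be driven into the degenerate
say-target-always regime, so complete focus pays only a bounded false-alarm
cost (F ≈ 0.4 on blends) while its amplified target channels detect blended
targets well (H ≈ 0.7) — at full scale the same α = 1 training pushes the
false-alarm rate high enough that sensitivity collapses. Widening the
insertion (24 → 32 filters) moved the α = 1 blended d′ in the expected
direction but nowhere near below the balanced value; closing the remaining
gap would require an appreciably less accurate backbone, which the
generator's accuracy floor rules out. The standard-set ordering, and every
other blended-set pattern (hits, false alarms, criterion), reproduce.

The retrain-final-layer baseline (`retrain_final_layer()`) trains the final
fully connected layer (warm-started from the backbone's own) with the
identical loss, sampling, seeds and stopping rule — the tests assert both
methods consume byte-identical epoch samples — and `compare_models()`
reports per-class paired Δd′ and Δc with paired t tests. At fixture scale
the comparison is *reported, not asserted directionally*: the published
superiority claim concerns the full-scale setting, and with 10 target
classes the fixture comparison is underpowered either way. The comparison is
run at α = 0.5, where the original comparison was made; other intensities
are an extension and labelled as such in the output.

## Numerical and degenerate-input conventions

* True-class probabilities are floored at 1e-12 before the log, so training
  losses stay finite; a non-finite epoch loss aborts with the epoch number.
* `decide()` breaks probability ties toward the lowest class index, making
  every reported metric deterministic.
* Degenerate statistics (zero between-group variance in the ANOVA, zero
  paired variance in the t test, constant weight vectors in the Spearman
  correlations) are flagged `NA`, never raised.
* All randomness flows from user-supplied integer seeds through
  deterministic per-epoch streams (seed, epoch) — the non-target subsample
  changes every epoch yet any run is bit-reproducible, and rerunning an
  experiment configuration produces hash-identical result files.
* Problem sizes used by the test suite and the acceptance script: the
  default K = 10 world (600 images), a converged 80-epoch backbone, the
  50-cell attention sweep, and a 10-cell retrain baseline at α = 0.5;
  smaller 5-class worlds exercise the training mechanics.

## Limitations

* The fixture world is parametric and low-resolution; it validates the
  mechanism's logic (weighted-loss attention training, SDT evaluation,
  analytics, baselines), not claims about photographic data.
* With 32 gains the capacity of the attention layer is far below the
  512-filter setting it miniaturises; effect sizes, the exact peak location
  on the α grid, and the attention-vs-retrain direction at fixture scale
  need not match the full-scale results.
* Per-target test sets are small (20 standard trials, 20 blended trials),
  so per-class rates are quantised at 0.05–0.1; conclusions are drawn from
  means over the 10 target classes.
* Spatial (per-position) attention, negative gains, multi-label targets
  beyond a set of class ids, and backbone fine-tuning are out of scope.
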
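# focalgain

Goal-directed channel attention for convolutional image classifiers, with a
full signal-detection evaluation harness.

## The problem

When people search for something specific — their keys, a particular dog
breed — prefrontal cortex reconfigures the visual system toward
goal-relevant features. That reconfiguration has a benefit (more hits) and a
cost (more false alarms to key-like non-keys). `focalgain` implements a
computational account of this trade-off for convolutional classifiers: a
single trainable attention layer inserted at a mid-level of a *frozen*
network, one non-negative gain per convolutional filter, shared over space.
With gains $g_f$ and insertion-point activations $A_{h,w,f}$, the modulated
representation is the Hadamard product $\tilde A_{h,w,f} = g_f A_{h,w,f}$;
everything else in the network stays fixed.

The gains for a target class $\mathcal{T}$ are trained at an *attention
intensity* $\alpha \in [1/N, 1]$ with a class-weighted cross-entropy over
the full $N$-way task,

$$\ell_i = \begin{cases}
  \alpha \, \mathrm{CE}(y_i, p(x_i)) & y_i \in \mathcal{T}\\[2pt]
  \tfrac{1-\alpha}{N-1} \, \mathrm{CE}(y_i, p(x_i)) & \text{otherwise,}
\end{cases}$$

so $\alpha = 1/N$ is a no-attention control, $\alpha = 0.5$ balances target
against all non-targets combined, and $\alpha = 1$ is complete target focus.
Models are scored as target detectors in signal-detection terms: hit rate
$H$, false-alarm rate $F$, sensitivity $d' = z(H) - z(F)$ and criterion
location $c = -\tfrac12(z(H)+z(F))$, on balanced standard test sets, on
50/50 *blended* images carrying two ground-truth labels, and on
user-supplied challenge directories. A retrain-the-final-layer baseline
trained under the byte-identical regime provides the transfer-learning
comparison, and weight analytics (variance, zeroed filters, adjacent-α
Spearman correlations) describe how the gains reorganise as intensity grows.

Everything runs end-to-end at desk scale on a built-in synthetic image
world (10 parametric texture/blob classes with controllable between-class
overlap) and a small trainable convolutional backbone — no downloads, fully
seeded. See the methods vignette
(`vignettes/goal-directed-attention.Rmd`) for the model, the fixture-scale
training regime and its rationale, and known limitations.

## Worked example

```r
library(focalgain)

# a 10-class synthetic world with a converged frozen backbone
world <- prepare_fixture_world(synthetic_spec(), seed = 1)
world
#> <fixture_world> 10 classes, 600 images; backbone val accuracy 0.860

# train attention for target class 3 at balanced intensity
fit <- train_attention(
  modulated_classifier(world$backbone), world$split,
  intensity_config(alpha = 0.5, n_classes = 10, target = 3),
  train_config(learning_rate = 0.01, max_epochs = 600, check_interval = 20)
)
glance(fit)
#> # A tibble: 1 x 8
#>   alpha target epochs stopped_reason final_train_loss final_val_loss n_zeroed weight_variance
#>   <dbl> <chr>   <int> <chr>                     <dbl>          <dbl>    <int>           <dbl>
#> 1   0.5 3         100 early_stop                0.208          0.983        0          0.0395

# evaluate as a detector of class 3 on a balanced test set
ts <- assemble_standard_testset(world$split, target = 3, seed = 99)
sdt_metrics(score_standard(
  decide(predict(modulated_classifier(world$backbone, fit$weights), ts)),
  ts$info$class, target = 3
))
#> # A tibble: 1 x 8
#>    hits misses false_alarms correct_rejections hit_rate fa_rate dprime criterion
#>   <int>  <int>        <int>              <int>    <dbl>   <dbl>  <dbl>     <dbl>
#> 1    10      0            0                 10     0.95    0.05   3.29         0
```

The hit rate 0.95 and false-alarm rate 0.05 are the 1/(2n)-corrected rates
for a perfect 10-vs-10 run; d′ ≈ 3.29 is the corresponding ceiling
sensitivity and criterion 0 means no response bias. The full sweep —
5 intensities × all 10 targets, standard and blended test sets, weight
analytics and ANOVA/paired-t summary — is one call:

```r
sweep <- run_reference_sweep(world = world, seed = 1)   # ~10 min, 1 CPU
tidy(sweep)          # one row per (target, alpha, test set)
glance(sweep)        # F / t summary
autoplot(sweep)      # mean H, F, d', c against alpha
plot_weight_distributions(sweep)
```

On the seeded reference run, mean hit and false-alarm rates rise with α,
the criterion falls from +0.11 to −0.41 (standard set), standard-set d′
peaks at a moderate intensity (≈3.14 at α = 0.5–0.9 vs 2.47 at α = 1), and
the attention-weight variance and zeroed-filter count grow with α — the
cost/benefit signature of goal-directed attention. One deliberate caveat:
at this fixture scale the complete-focus (α = 1) models remain the best
*blended*-image detectors, unlike the full-scale phenomenon; the vignette
discusses why (the 32-gain layer cannot degenerate a ≥80%-accurate backbone
far enough for the false-alarm cost to dominate on blends).

A YAML-config driven runner (`run_experiment()`, with a thin CLI in
`inst/exec/focalgain.R`) writes the whole results tree (weights, per-cell
CSVs, analytics, sweep statistics) deterministically and resumably.

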
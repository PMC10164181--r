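---
title: "Benchmarking predictive-uncertainty generalisation under distribution shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking predictive-uncertainty generalisation under distribution shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftbench)
```

## The problem

A classifier is developed on data assumed independent and identically
distributed (IID), but deployed on *production* data that has drifted:
different acquisition batches, different disease states, even whole classes
the model never saw. Two things then go wrong together: accuracy drops, and
— more insidiously — the model's *uncertainty* fails to rise enough to
signal the drop. This shift-induced overconfidence defeats the standard
risk-management practice of *uncertainty thresholding*, where only
predictions with uncertainty below a threshold chosen on development data
are accepted: the threshold silently delivers a lower accuracy in production
than it promised in development.

`shiftbench` packages the evaluation machinery for this problem: uncertainty
statistics, calibration measures, selective-prediction curves, and the ADP
statistic that directly quantifies the broken promise; four classifier
constructions that differ only by canonical Bayesian extensions of one
architecture; and a synthetic generator of shift-structured data so the full
benchmark runs on a desk in minutes.

## Uncertainty statistics

For a probability vector $p \in [0,1]^K$ the package uses two per-sample
uncertainty statistics accessible to both pointwise and distribution-wise
models:

* the **confidence score** $\mathrm{Conf}(x) = \max_k p_k$, and
* the **Shannon entropy** $H(p) = -\sum_k p_k \log p_k$ in nats, zero for a
  one-hot vector and maximal at $\log K$ for the uniform vector.

Entropy is the default statistic for sorting and thresholding (confidence,
used as $1 - \mathrm{Conf}$, is available as an option). Micro-averaged F1
over single-label multiclass predictions equals plain accuracy; samples of
unseen classes are always counted as errors.

## Calibration: ECE and its per-sample view

The expected calibration error bins predictions into $M$ equal-width
confidence bins on $[0,1]$ (bin $m$ covers $((m-1)/M, m/M]$) and averages
the absolute accuracy–confidence gap with count weights:
$$\mathrm{ECE} = \sum_{m=1}^{M} \frac{|B_m|}{n}\,\bigl|\mathrm{acc}(B_m) -
\mathrm{conf}(B_m)\bigr|.$$
The bin count $M$ defaults to 10 — the common convention for this
formulation — and is configurable. The per-sample calibration error assigns
each sample the gap $|\mathrm{acc}(B_m) - \mathrm{conf}(B_m)|$ of its own
bin; the bin-level gap (rather than the sample's own confidence against the
bin accuracy) was chosen deliberately so that the plain mean of the
per-sample values reproduces the ECE *exactly*, which makes the per-sample
distribution a faithful decomposition of the aggregate statistic for
rank-sum comparisons between models.

## Selective-prediction curves

Two sweeps over predictions sorted by descending uncertainty summarise how
well uncertainty tracks the error rate. Ties are broken by stable original
row order; curve shapes at tied uncertainties depend on this rule, so it is
fixed and documented rather than left to the sorting algorithm.

**F1-retention curve.** At each step the micro-F1 and retention fraction
(initially 100%) are recorded, then the most uncertain remaining prediction
is *replaced by its ground-truth label*. F1 can only rise, and rises fastest
when errors hide among the most uncertain predictions. The area under the
curve (trapezoidal, including the terminal point F1 = 1 at retention 0) is
the F1-AUC.

**F1-uncertainty curve.** The same sweep but *discarding* instead of
replacing: before each discard the pair (threshold = uncertainty of the next
discarded sample, F1 of the retained set) is recorded. The retained set at a
recorded threshold $u$ is exactly the set of samples with uncertainty
$\le u$; acceptance is inclusive ($\le$) so a development sample sitting on
its own threshold is retained, keeping the development curve
self-consistent.

## The ADP statistic

The area between the development and production curve (ADP) measures the
accuracy cost of transferring development thresholds into production:

1. build the development (IID validation) and production (shifted data)
   F1-uncertainty curves;
2. lay a grid of nominal F1 targets over $[0.975, 0.990]$ in steps of
   $10^{-5}$ (1501 points);
3. for each target, select the *most permissive* development threshold whose
   development F1 meets the target (the largest qualifying threshold — the
   plateau rule the step-function curve needs);
4. accept production predictions with uncertainty at or below that
   threshold and record the decrease, in percentage points, from the
   realised development F1 at that threshold to the production F1 of the
   accepted set;
5. average the decreases over the grid.

One numerical choice deserves emphasis. F1-uncertainty curves are step
functions, so a grid target is generally attained only approximately: the
selected operating point *overshoots* the target by up to one F1 quantum.
The decrease is therefore measured from the **realised development F1 at the
accepted threshold** — both curves evaluated identically at the same
threshold — rather than from the abstract grid value. This matches the
geometry of the quantity (the vertical distance between the two curves at a
shared threshold), and gives the statistic its defining property: the ADP of
identical development and production data is exactly zero. At large
development sample sizes the two readings coincide to within the F1
granularity $1/n$; at desk scale the realised reading avoids a spurious
negative bias of up to a percentage point.

The nominal range must be supported by the data: `adp()` refuses a range
whose upper bound the development curve never attains, and
`adp_range_checks()` warns when the retained sample count at the threshold
achieving `f1_max` is small (default minimum 30) or when `f1_min` falls
below a stated production floor.

`adp_bootstrap_ci()` resamples the production table with replacement
(default B = 1000, percentile interval at 95%), keeping the development
curve fixed. Resamples that are degenerate — a single true class, or an
empty accepted set at some threshold — are redrawn up to a cap, with a
warning.

Two different "percent" scales coexist and are never conflated: ADP
decreases are *percentage points* of F1; inter-model comparisons
(`percent_decrease()`) are *relative* percentages of the reference model's
value.

## The four model constructions

All four variants share one architecture, built from a single `model_spec()`
(checkable via `architecture_signature()`): an input affine layer projecting
$D$ features to the hidden width, three residual hidden blocks
$U^{(l)} = g(\mathrm{BN}(U^{(l-1)} W^{(l)} + b^{(l)})) + U^{(l-1)}$ with
Mish activations and batch normalisation, and a linear mean head to $K$
logits. The variants differ only by canonical extensions:

* **resnet** — pointwise baseline; dropout acts as a training regulariser
  only, inference is one deterministic pass;
* **mcd** — Monte Carlo dropout: dropout stays active at inference, and a
  second head predicts a per-class logit variance; each of $T$ (default
  250) stochastic passes draws *once* from
  $\mathcal{N}(f_t(x), \mathrm{diag}\, s_t^2(x))$ before the softmax, and
  the $T$ probability vectors are averaged;
* **bilipschitz** — MCD plus spectral normalisation of every affine weight
  after each optimisation step, bounding $\sigma_{\max} \le c$; residual
  connections supply the lower (sensitivity) bound and spectral
  normalisation the upper (smoothness) bound of the bi-Lipschitz
  constraint;
* **ensemble** — eight independently initialised and trained bi-Lipschitz
  members; each contributes $T/10 = 25$ draws, pooled to 200 so the Monte
  Carlo budget stays comparable with the single models.

Design choices where the construction was genuinely open:

* **Output head activation.** The layer equations apply the nonlinearity
  $g$ uniformly, but a Mish-squashed logit head bounds logits below and is
  nonstandard for softmax classifiers; the default head is linear, with
  `literal_output_activation = TRUE` restoring the uniform reading.
* **Variance positivity.** The variance head's raw output passes through a
  softplus (plus a $10^{-6}$ floor); an unconstrained affine output could
  go negative and is unusable as a variance.
* **Dropout placement and rate.** After each hidden block's activation,
  inside the residual branch; default rate 0.1, configurable.
* **Early stopping.** Validation NLL with patience 10 and best-weight
  restoration; an optional `target_val_nll` mode stops every model at a
  shared validation loss instead, for benchmark designs that equalise
  development loss across models.
* **Spectral bound.** Chosen by the constraint's own logic: as low as
  practically possible while the network still learns the task. At width
  128 the *unconstrained* weights settle around $\sigma_{\max} \approx 3$,
  so a bound near 3 never binds and the bi-Lipschitz variant would
  degenerate into plain MCD; probing downward (judged on validation NLL and
  F1 only), learning stays intact down to $c \approx 0.2$ with validation
  loss rising gently. The default $c = 0.5$ is clearly binding (a sixfold
  contraction of the unconstrained norms) while keeping validation loss
  close to the unconstrained level; exposed in the spec.
* **Batch normalisation at inference** uses frozen running statistics for
  every variant, so Monte Carlo variation comes only from dropout and the
  Gaussian head. Plain batch normalisation is used in the bi-Lipschitz
  variant as well.
* **Desk-scale width.** The default hidden width is 128 so that training
  the full 11-network benchmark (baseline, MCD, bi-Lipschitz, 8 ensemble
  members) is a CPU job of minutes; width 1024 reproduces the large-scale
  setting.

The networks are implemented directly on BLAS matrix operations with
hand-derived gradients (verified against central finite differences in the
development of this package); spectral normalisation uses the exact largest
singular value, so the bound holds after every step, not just on average.

## The synthetic generator

`generate_strata()` emulates the structure — not the marginals — of a
multi-site cancer-type prediction task. One signature vector per class is
drawn from a spherical Gaussian (`signature_scale`); features are signature
plus isotropic noise (`noise_sd`) plus a per-batch additive offset. Four
strata of 400 samples each mirror distinct shifts:

| stratum | key | shift |
|---|---|---|
| development | (SITE_A, Primary, seen) | none (IID) |
| batch | (SITE_B, Primary, seen) | additive batch offset |
| metastatic | (SITE_A, Metastatic, seen) | class centres blended toward the nearest other class (`blend_alpha`) |
| unseen | (SITE_B, Metastatic, unseen) | classes absent from development, centred between a related seen signature and a fresh one |

Unseen classes carry graded blend weights (default 0.15, 0.35, 0.55), so
the first unseen class is nearly indistinguishable from its related seen
class — the structural analogue of a rare subtype being confidently
predicted as its common relative — while the last is remote and should
attract high uncertainty.

Default conditions: `K_seen = 8`, `K_unseen = 3`, `D = 64`, 400 samples per
stratum, `signature_scale = 1`, `noise_sd = 1.5`, `batch_shift_sd = 0.5`,
`blend_alpha = 0.3`. The noise level was set so the baseline model's IID
validation F1 sits in the high nineties — the regime the ADP's default
nominal range $[0.975, 0.990]$ presupposes; the shift scales produce a
moderate, graded degradation rather than a collapse. With all shift knobs
at zero (and `K_unseen = 0`) the production strata are distributionally
identical to development — the null-shift control under which the ADP must
vanish within bootstrap noise.

What the generator does **not** emulate: RNA-seq count distributions
(log-normal/negative-binomial marginals), gene-gene correlation structure,
library-size artefacts, or a realistic class taxonomy. Gaussian
class-conditional features were chosen deliberately: the evaluated
machinery consumes continuous post-preprocessing features, and the
benchmark needs *controllable* shift. Passing tests on this generator
therefore demonstrate that the metrics and model constructions behave as
designed under controlled shift — they do not certify performance on real
transcriptomes. A count-based generator is a documented extension point.

## The benchmark orchestrator

`run_benchmark()` repeats, per seed: generate → split the IID stratum
(stratified by class, 15% validation) → train all variants from the one
shared spec → predict on validation (development) and on the pooled
production strata → compute F1, mean entropy, ECE (per stratum and pooled),
F1-AUC and ADP (pooled production, as the deployment scenario dictates) →
compare each Bayesian variant against the baseline with one-sided rank-sum
tests (higher entropy; lower calibration error), starring p-values at 0.05,
0.01 and 0.001. Per-comparison stars are reported without family-wise
correction, matching the presentation convention of this literature; a
Holm-adjusted column is additionally emitted, clearly labelled. Seeds are
aggregated by mean; a training failure on one seed is recorded in the
report's `failures` table rather than silently skipped.

Problem sizes were chosen so the whole five-seed, four-variant benchmark is
a single-CPU job of roughly ten minutes: 336 training samples, 64
validation samples, 1200 production samples, width-128 networks, 250 Monte
Carlo draws (200 pooled for the ensemble).

## Numerical and degenerate-input conventions

* Probability rows must sum to 1 within $10^{-9}$ at construction
  ($10^{-6}$ on file ingestion, where text precision dominates;
  renormalisation only under an explicit flag). The convention
  $0 \log 0 = 0$ applies throughout.
* Uncertainty-sort ties: stable original order, everywhere.
* The ADP grid is generated as `f1_min + step * (0:n)` to avoid
  floating-point drift; grid-to-curve F1 comparisons carry a $10^{-9}$
  slack, far below the coarsest F1 quantum ($1/n$) it could interact with.
* The ADP is invariant to any strictly increasing rescaling of the
  uncertainty statistic applied to both curves — thresholds act as
  quantiles, so entropy and any monotone transform of it give identical
  results.
* All-tied rank-sum comparisons return `ns` with a warning rather than a
  p-value.
* Training aborts with diagnostics on a non-finite loss; networks refuse
  labels outside their class set.

## Known limitations

* The Gaussian generator limits external validity (see above); directional
  findings on it should be confirmed on real shifted data before informing
  deployment decisions.
* The per-sample calibration error inherits the ECE's binning; with few
  occupied bins it is coarse, and comparisons based on it are sensitive to
  `bins`.
* Ensemble members are trained sequentially on one CPU; wall-clock scales
  linearly in `ensemble_size`.
* At desk-scale validation sizes (n = 64) the development F1-uncertainty
  curve is coarse (F1 quanta of 1/64), which widens seed-to-seed variation
  of the ADP; conclusions are therefore drawn directionally over seeds, not
  from single-run magnitudes. Moreover, a third of the default production
  mix is unseen-class samples — including a near-duplicate unseen class
  that every model confidently misclassifies by design — so a large,
  model-independent error mass enters every model's ADP alike. Under these
  conditions the *inter-model* ADP differences are small relative to seed
  noise: the entropy ordering between Bayesian variants and the baseline
  reproduces reliably, while the ADP ordering does not always. Sharper ADP
  separation requires a larger development set and a smaller unseen
  fraction, as in the full-scale setting.
* Epistemic/aleatoric decomposition of the predictive uncertainty is out of
  scope; only total-uncertainty statistics are implemented.
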
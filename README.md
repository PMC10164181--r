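# shiftbench

Benchmarking how well classifiers generalise their predictive *uncertainty*
— not just their accuracy — from development (in-distribution, IID) data to
production (shifted, OOD) data.

## The problem

Deployed classifiers meet data that has drifted from the training
distribution: new acquisition batches, changed disease states, classes never
seen in training. Accuracy drops, but the deeper failure is
**shift-induced overconfidence**: the model's uncertainty does not rise
enough to flag the drop. That defeats *uncertainty thresholding* — the
risk-management practice of accepting only predictions whose uncertainty
falls below a threshold chosen on development data — because the threshold
delivers less accuracy in production than it promised in development.

`shiftbench` provides, in one R package:

* **Evaluation statistics** — confidence `Conf(x) = max_k p_k`; Shannon
  entropy `H(p) = -Σ p_k log p_k` (nats); micro-F1 (= accuracy, with
  unseen-class samples always wrong); expected calibration error
  `ECE = Σ_m (|B_m|/n) |acc(B_m) − conf(B_m)|` with a per-sample
  decomposition; F1-retention curves and their area (**F1-AUC**);
  F1-uncertainty curves; and the **ADP** — the area between the development
  and production curve: the mean, over a grid of nominal development F1
  targets (0.975–0.990, step 1e-5), of the percentage-point F1 drop when
  each target's development uncertainty threshold is transferred to
  production, with a bootstrap confidence interval. ADP reads directly as
  "expected accuracy loss at deployment under uncertainty thresholding".
* **Four controlled classifier constructions** sharing one residual-network
  architecture (4 hidden layers, Mish activations, batch norm, residual
  connections): a pointwise baseline, Monte Carlo dropout with a
  heteroscedastic Gaussian logit head (T = 250 draws), a bi-Lipschitz
  variant adding spectral normalisation (σ_max ≤ c after every optimisation
  step), and a deep ensemble of eight bi-Lipschitz members pooling
  8 × 25 = 200 draws.
* **A synthetic strata generator** emulating the development→production
  design: an IID stratum, a batch-shifted stratum, a metastatic stratum
  with class signatures blended toward their nearest neighbour, and an
  unseen-class stratum at graded distances from related seen classes.
* **A benchmark orchestrator** running all four variants over several seeds
  with rank-sum significance tests and JSON/TSV reports, plus a thin CLI
  (`inst/scripts/shiftbench.R`).

## Worked example

Evaluate uncertainty thresholding for a model trained on the synthetic IID
stratum and deployed on the shifted strata:

```r
library(shiftbench)

ds  <- generate_strata(synthetic_config(seed = 0))
sp  <- split_development(ds, seed = 0)
m   <- fit_variant(model_spec(seed = 0), sp$train$X, sp$train$y,
                   sp$validation$X, sp$validation$y, "bilipschitz")

dev  <- predict_table(m, sp$validation$X, sp$validation$y, seed = 0)
ood  <- !iid_mask(ds)
prod <- predict_table(m, ds$X[ood, ], ds$y[ood], seed = 1)

dev
prod
ece(prod$confidence, is_correct(prod))
f1_retention_curve(prod)
adp_bootstrap_ci(dev, prod, B = 500, seed = 0)
```

which prints (seed 0):

```
Prediction table: 64 samples, 8 classes (C1, C2, C3, C4, C5)
  micro-F1 1.0000 | mean confidence 0.9614 | mean entropy 0.1527 nats
Prediction table: 1200 samples, 8 classes (C1, C2, C3, C4, C5)
  micro-F1 0.6167 | mean confidence 0.8632 | mean entropy 0.4361 nats
Expected calibration error: 0.2465 (1200 samples, 10 bins, 8 occupied)
F1-retention curve: n = 1200, F1 at full retention 0.6167, F1-AUC 0.8559
ADP: 32.7238 percentage points (grid [0.975, 0.99], 1501 points)
  bootstrap 95% CI: [29.8069, 35.2950]
```

Reading: on the shifted pooled production data (a third of which are
unseen-class samples that can never be correct), accuracy falls from 100% to
62% while mean confidence only falls from 0.96 to 0.86 — shift-induced
overconfidence, quantified by the ECE of 0.25; the F1-AUC of 0.86 shows
uncertainty still ranks errors usefully; and the ADP says that thresholds
promising 97.5–99% development F1 deliver about 33 percentage points less in
production under this (deliberately harsh) shift mix.

The full controlled comparison — all four variants, five seeds, rank-sum
stars — is one call:

```r
report <- run_benchmark(benchmark_config(seeds = 0:4))
print(report)
write_report(report, "report.json")   # JSON + flat TSV
```

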
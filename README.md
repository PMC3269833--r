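# switchscan

Genome-scale mining of **gene switches** — genes whose regulatory circuits
(positive self-activation, mutual repression) make their expression bistable,
so that cells sit in either an ON or an OFF state. Sampled across many
conditions, such genes leave a statistical fingerprint: a **bimodal**
expression profile. switchscan finds that fingerprint in genes × samples
expression matrices and connects it to phenotypes. It is written for
computational biologists analyzing large microarray/expression compendia, and
for systems biologists who want a reproducible, fully synthetic benchmark for
bistability detection.

## What it computes

* **ΔAIC bimodality score** — per gene, fit one Gaussian and a two-component
  Gaussian mixture (EM, multiple restarts) and compare by
  `AIC = 2k − 2 log L`:

  `ΔAIC = AIC₁ − AIC₂`

  Large positive ΔAIC ⇒ the profile is better explained as two expression
  states. Guaranteed `ΔAIC ≥ −6`, affine-invariant, exchangeable across
  samples.
* **Separation D** — for a target phenotype,
  `D = |μ₁ − μ₂| / √((σ₁² + σ₂²)/2)` between target and non-target samples;
  `D > 1.8` flags a phenotype-specific state.
* **Screening pipeline** — rank by ΔAIC → keep the top 10% → `D > 1.8`
  screen → independent paired-dataset validation (Fisher test on mixture-mode
  occupancy, BH-adjusted) → classification into **Type 1** (bimodal within
  the target phenotype) or **Type 2** (ON in nearly all target samples, OFF
  elsewhere).
* **Information gain** — `100·(H(X) − H(X|Y))/H(X)` with equal-frequency
  discretization of a gene's expression, measuring its phenotype-prediction
  value in percent.
* **Mode enrichment** — hypergeometric over-representation of condition
  categories inside a gene's ON or OFF mode.
* **Circuit simulators** — exact ODE models of a self-activating switch and a
  two-gene toggle (batched RK4, steady-state detection), plus a compendium
  generator with planted switch genes and ground truth, so the whole pipeline
  is testable without any external dataset.

## Worked example

Simulate a 100-sample toggle-switch compendium with planted graded and noise
genes, then score every gene:

```r
library(switchscan)

ds <- simulate_expression(circuit_toggle(),
                          sim_config(n_clones = 100, param_cv = 0.2, seed = 7),
                          extra_graded = 3, extra_noise = 2)
scores <- score_bimodality(ds$expression, seed = 7)
scores[order(scores$rank), c("gene_id", "delta_aic", "rank")]
```

```
  gene_id     delta_aic  rank
1 B             391.575     1
2 A             346.619     2
3 graded_extra1  11.224     3
4 graded_extra2   8.274     4
5 graded_extra3   6.214     5
6 noise_extra2   -4.337     6
7 noise_extra1   -5.778     7
```

Both toggle genes score ΔAIC ≈ 350–390 — their clone-sampled profiles split
cleanly between the two attractors near (9.90, 0.10) — while graded genes
(steady level proportional to the stimulus) land near the ΔAIC ≈ 6 support
boundary and pure-noise genes go negative. The same statistic on one gene,
with mode assignments and a plot:

```r
fit <- delta_aic(ds$expression["A", ], gene_id = "A", seed = 7)
glance(fit)   # delta_aic, component AICs, kurtosis, fitted separation
tidy(fit)     # low/high mode weights, means, variances
autoplot(fit) # histogram + fitted components
```

The full screen against a phenotype, on the built-in planted benchmark:

```r
comp <- simulate_compendium(seed = 1)   # 30 planted switches among 1,000 genes
calls <- run_switch_pipeline(comp$global, comp$annotations, "cancer",
                             validation_x = comp$validation,
                             pairs = comp$pairs, seed = 1)
dplyr::filter(calls, passed_screen, validated) |>
  dplyr::count(switch_type)
```

```
  switch_type     n
1 none            1
2 type1           9
3 type2          20
```

All 30 planted switches pass the screen and validation with no false
positives; 29 receive their true type (one Type 1 gene draws 86% of its
target samples into the ON mode, leaving its minor mode just under the 15%
threshold, so it is typed `none`).

A command-line interface wraps the same functions
(`inst/scripts/switchscan`): `simulate`, `score`, `infogain`, `screen`,
`validate`, `classify`, `enrich`.

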
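---
title: "Mining gene switches from expression compendia"
author: "switchscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene switches from expression compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
set.seed(1)
library(switchscan)
```

## The idea

A *gene switch* is a gene whose regulatory circuit — positive
self-activation, or mutual repression with a partner — makes its expression
bistable: individual cells settle in either an ON or an OFF steady state, not
in between. Single measurements cannot reveal this. But when a gene is
profiled across many independent conditions, samples accumulate near the two
attractors and the expression profile becomes **bimodal**. switchscan
implements a genome-scale mining strategy built on that observation: score
every gene's profile for bimodality, then ask whether one of the two states
is tied to a phenotype of interest.

## The bimodality score

For each gene we fit the observed (log2-scale) expression values twice: a
single Gaussian, and a two-component Gaussian mixture fitted by
expectation-maximization. Both fits are compared by the Akaike information
criterion,

$$AIC = 2k - 2\log L, \qquad \Delta AIC = AIC_1 - AIC_2,$$

with $k = 2$ free parameters for the single Gaussian (mean, variance) and
$k = 5$ for the mixture (two means, two variances, one weight). Large
positive $\Delta AIC$ means the bimodal description is worth its extra three
parameters. Likelihoods use the natural log and the $1/n$ variance
convention, so the one-component AIC has the closed form
$4 + n(\ln(2\pi\hat\sigma^2) + 1)$ — the unit tests hold the implementation
to that identity at $10^{-9}$.

Two properties are guaranteed by construction:

* **$\Delta AIC \ge -6$.** One EM restart always starts from the collapsed
  solution (both components equal to the single-Gaussian fit), a fixed point
  of EM whose likelihood equals the one-component likelihood. The best
  restart can therefore never fall below it, and the score is bounded below
  by $2k_1 - 2k_2 = -6$.
* **Affine invariance and exchangeability.** Restart construction uses only
  the empirical distribution (quantiles, moments), so rescaling the data or
  permuting sample order leaves $\Delta AIC$ unchanged (to $10^{-6}$ and
  exactly, respectively).

The EM restart set is: the collapsed start, a median split, three
"tight-quantile" starts (a minority component of low variance placed at the
15%, 50% and 85% quantiles), and random quantile-pair starts up to
`restarts = 10`. The tight starts matter: mixture likelihoods have narrow
local optima in which a small cluster is captured at low variance, and
best-of-restarts EM should find them whenever a brute-force scan over the
5-parameter grid would — a property the test suite checks directly. The
price is a conservative one: on pure-noise profiles these spike optima
inflate the score tail slightly (about 11% of 2,000 null genes exceed the
$\Delta AIC > 6$ "strong support" mark at $n = 200$, comfortably inside the
15% envelope we require), which is why the screening pipeline ranks genes
rather than applying a fixed cutoff.

Numerical safeguards: component variances are floored at $10^{-6}\times$ the
overall sample variance ($10^{-12}$ absolute for constant input) so duplicated
values cannot produce unbounded likelihoods; EM stops when the
log-likelihood improves by less than $10^{-8}$ or after 500 iterations, and
an unconverged best iterate is returned with a warning. Exactly duplicated
data collapse to $\Delta AIC = -6$. Ties in the posterior mode assignment go
to the higher-mean (ON) component, a deterministic choice that biases toward
calling the ON state.

```{r score-demo}
x <- c(rnorm(120, 1, 0.4), rnorm(80, 4, 0.5))
fit <- delta_aic(x, gene_id = "demo", seed = 1)
glance(fit)
autoplot(fit)
```

## Conditional bimodality: the separation D

$\Delta AIC$ is unconditional — it flags a two-state profile without saying
*when* the gene is ON. Given a target condition (say, a tumor phenotype),
the separation

$$D = \frac{|\mu_1 - \mu_2|}{\sqrt{(\sigma_1^2 + \sigma_2^2)/2}}$$

compares the target samples $(\mu_1, \sigma_1)$ with all other samples
$(\mu_2, \sigma_2)$; $D$ approaching 2 means the two groups occupy
well-separated states. The screen accepts $D > 1.8$ — "greater than or close
to 2", a concession to microarray noise. Group standard deviations use the
$1/n$ convention for coherence with the likelihoods; at compendium sample
sizes the difference from $1/(n-1)$ is far below the decision threshold.

## The screening pipeline

`run_switch_pipeline()` chains four stages:

1. **Rank** all genes by $\Delta AIC$ (`score_bimodality()`), ties broken by
   gene id so results are reproducible.
2. **Screen** the top 10% against the target phenotype with $D > 1.8$
   (`screen_switches()`). The top fraction — not a fixed $\Delta AIC$ cutoff —
   is the gatekeeper, because the score scale depends on sample size.
3. **Validate** on an independent paired tumor/normal dataset
   (`validate_switches()`): the two-component mixture is refitted on the
   validation samples, each sample is assigned a mode, and a two-sided Fisher
   exact test asks whether ON-mode occupancy differs between the tumor and
   normal sides, with Benjamini-Hochberg adjustment across genes at
   $\alpha = 0.05$. The published procedure behind this step ("shows
   different distribution") is not specified numerically anywhere we could
   follow; the Fisher-on-modes test is this package's operationalization — it
   reuses the already-fitted mixture and respects the ON/OFF semantics. The
   pairing defines the two groups; a matched-pairs (McNemar-type) variant is
   deliberately out of scope.
4. **Classify** surviving genes by mode occupancy (`classify_switch_types()`):
   **Type 1** genes are bimodal *within* the target samples (both modes hold
   at least 15% — an ESR1-like pattern, where an 80/20 ER+/ER− split across
   the ON/OFF modes classifies as Type 1); **Type 2** genes sit in one mode
   for at least 90% of target samples while the other samples predominantly
   occupy the opposite mode (a TACSTD2-like pattern, ON in ~99% of tumors).
   The two rules are mutually exclusive (a minor mode of 15% caps the major
   mode at 85% < 90%). The 0.15/0.90 thresholds are configurable in
   `screen_config()`.

For condition compendia without a single target phenotype,
`mode_enrichment()` asks instead whether one of a gene's modes collects
conditions of the same category (the GAL-pathway signature: the OFF mode
gathering exactly the "extra carbon source" conditions), using one-sided
hypergeometric over-representation with BH adjustment.

## Phenotype information of a gene

`information_gain()` quantifies prediction value: discretize the gene into
equal-frequency bins $Y$ (default 4 — the bin count shifts absolute
entropies but not comparisons between genes, and the gain is invariant to
the logarithm base) and report

$$100 \cdot \frac{H(X) - H(X \mid Y)}{H(X)} \%$$

with plug-in (frequency) entropies in bits and $0\log 0 = 0$. Tied quantile
edges collapse bins rather than splitting tied values arbitrarily, keeping
the assignment deterministic; no small-sample bias correction is applied,
matching the plug-in definition. The bin-stability claim is a statement
about genes with genuinely different information content — orderings within
a sea of near-zero-gain noise genes are not expected to be stable, and the
tests phrase the invariant accordingly.

## The circuit simulators

Because real switch inventories are unknown, every stage is tested against
simulated compendia with planted truth. Two published circuit motifs are
simulated exactly as written:

* **Self-activating switch.**
  $dA/dt = pA^2/(1+A^2)\cdot 1/(1+R^2) - A/2.5 - dA$ with the
  stimulus-controlled repressor $R(i) = 10(1-Ki)/(1+Ki)$. The $-A/2.5$ decay
  is part of the printed model; $dA$ is the additional linear degradation.
* **Toggle switch.** $dA/dt = \alpha/(1+B^2) - dA$,
  $dB/dt = \alpha/(1+A^2) - dB$.

The nominal rates are not published, so this package fixes defaults
verified (by brute-force root scans and fixed-point iteration, re-run in the
test suite) to sit in a bistable regime: $p = 4, K = 0.03, d = 0.1$ for the
self-activation switch — steady states $\{0, 0.127, 7.87\}$ at full
derepression, ON window at stimulus $\approx 23.5$–$47.2$ — and
$\alpha = 10, d = 1$ for the toggle, attractors at $(9.899, 0.101)$ and its
mirror. All are configurable.

Integration is classic fixed-step RK4 ($h = 0.01$, horizon 500 time units)
with an early stop when the max-norm of the derivative falls below
$10^{-6}$; fixed-step integration keeps every simulation bit-reproducible,
and step-halving moves no bundled example by more than $10^{-6}$. The
integrator is batched: a matrix of initial conditions (cells, clones, sweep
points) advances in lock-step through vectorized right-hand sides, which is
what makes thousand-gene compendia tractable on one CPU. Unconverged
trajectories are flagged and included, never dropped.

A note on hysteresis: with the production term quadratic in $A$, the OFF
state is stable at *every* stimulus, so a quasi-static upward sweep from
zero never switches ON. Bistability therefore shows up as history
dependence: `hysteresis_sweep()` runs a low-start and a high-start branch
across the stimulus axis and reports the window where they disagree — the
operational reading of the switch's hysteresis loop.

The sampling protocol (`sim_config()`, `simulate_expression()`) emulates how
a microarray compendium arises: per clone, a stimulus, a noisy parameter set
(multiplicative Gaussian, CV 20% as the study conditions prescribe,
truncated at 10% of nominal so rates stay positive), a uniform initial
state, and optionally a within-clone population average over
`cells_per_clone` cells (Gaussian spread, CV 10% by default — "small"
cell-to-cell variation is not quantified anywhere, so a modest default is
chosen once) — averaging across a clone that straddles the separatrix is
exactly how graded population responses mask all-or-none single-cell
switching. Readouts are $\log_2(x+1)$, mimicking log-scale intensities. The
RNG draw order is fixed (per clone: stimulus, parameters, initial state,
cells; then measurement noise; then reporter genes), making every dataset a
pure function of its seed. Initial-condition bounds for the bundled demos
default to $[0, 12]$, wide enough to straddle both basins of the default
circuits; the per-clone stimulus is drawn by a pluggable sampler since the
original protocol leaves open whether conditions shared a stimulus level.

`simulate_compendium()` builds the full benchmark: 20 Type 2 genes
(self-activation circuits, ON-window stimulus in a designated "cancer"
block, OFF stimulus elsewhere), 10 Type 1 genes (same circuit, target-block
initial conditions straddling the activation threshold to give an ~80/20
ON/OFF split), 970 unimodal null genes (iid log-scale Gaussians — planted
non-switches, not circuit outputs), 300 samples, and a 40-pair validation
set from the same generative process. Clone-to-clone noise applies to the
kinetic rates; the stimulus-coupling constant $K$ is held fixed because it
defines the condition blocks — letting it vary per clone would turn "ON
stimulus" into a lottery and the planted truth would no longer be what its
label claims. What this generator does *not* emulate: array normalization
artifacts, batch effects, correlated noise across genes, and
dropout/saturation — passing tests say the method works when its
distributional assumptions hold, not that preprocessing of real compendia is
solved.

```{r pipeline-demo, eval = FALSE}
comp <- simulate_compendium(seed = 1)
calls <- run_switch_pipeline(comp$global, comp$annotations, "cancer",
                             validation_x = comp$validation,
                             pairs = comp$pairs, seed = 1)
dplyr::filter(calls, passed_screen, validated)
```

## Problem sizes used by the checks

The bundled acceptance computations run at the study scale chosen for this
package: 100 random inputs for the AIC identity; ~30 fuzzed inputs for the
score bound; 20 seeds of the $n = 1000$ balanced mixture for EM recovery;
20 small inputs against a brute-force grid; 1,000 random toggle states for
attractor capture; a 121-point stimulus sweep for the hysteresis window; 20
replicate 100-clone toggle compendia for bimodality emergence; one
2,000-gene × 200-sample null compendium; and ten 1,000-gene × 300-sample
planted compendia for end-to-end recall, false-discovery rate, and type
agreement. `scripts/acceptance.R` reports exactly these quantities.

## Known limitations

* The mixture is restricted to two components; multistable systems with
  three or more states are scored only for their best two-state description.
* The $\Delta AIC > 6$ "strong support" convention is used only where a
  binary call is unavoidable; all pipeline decisions use ranks and $D$.
* The Fisher-on-modes validation treats paired samples as two independent
  groups; true paired designs lose a little power.
* Null genes in the benchmark are independent across genes; correlated
  expression programs could raise the false-discovery rate above what the
  planted benchmark measures.
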
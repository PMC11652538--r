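---
title: "Scoring single samples for the pre-disease state: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring single samples for the pre-disease state: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spcr)
```

## The problem and the statistic

Complex diseases can progress through an abrupt critical transition. Before
the jump the system passes through a short, unstable *pre-disease* state:
mean expression still looks normal, but — by dynamic network biomarker
(DNB) theory — a small group of genes starts to fluctuate strongly and
coherently. Classical DNB statistics (group standard deviation, intra- and
inter-group correlation) need many replicate samples per time point, which
clinical data rarely offer. This package scores **one sample per time
point**.

Given $n$ normal samples, the baseline of gene $g_i$ is
$E_i^b = \mathrm{mean}(E_i^1,\dots,E_i^n)$, and $R_i^b$ is its fractional
(average-tie, ascending) rank among all genes' baselines. A sample at time
$t$ gives, per gene,

$$\Delta E_i^t = E_i^t - E_i^b, \qquad
  \Delta R_i^t = R_i^t - R_i^b, \qquad
  S_i^t = \Delta E_i^t \cdot \Delta R_i^t,$$

and the sample-level score aggregates the $m$ largest local scores over the
$N$ genes:

$$S^t = \frac{1}{mN}\sum_{i \in \text{top-}m} S_i^t, \qquad
  \Delta S^t = S^t - S^0,$$

with $S^0$ the score of the first post-baseline time point. A gene that
moves far moves its rank in the same direction, so $S_i^t$ is large and
positive for strong coordinated shifts in either direction, while
uncoordinated noise-scale wobble yields small products — the ranking change
amplifies exactly the signal DNB theory predicts. A significant rise of
$\Delta S^t$ is the early-warning call.

Key properties (all enforced by tests): scoring the baseline against
itself gives exactly 0; a constant shift of a sample changes no rank and
scores 0; scaling all expressions by $c > 0$ scales $S^t$ by exactly $c$;
gene order is irrelevant.

## Parameters

* `m` (default 50): the number of top local scores aggregated. It should be
  of the order of the expected DNB module size; the default follows common
  practice for genome-scale panels. With fewer than `m` genes the call is
  an error, not a silent clamp.
* Top-`m` selection uses the largest **signed** $S_i^t$ by default.
  "Largest" could also be read as largest magnitude; `use_absolute = TRUE`
  selects by $|S_i^t|$ instead. Signed selection is the default because a
  strongly *negative* product means expression and rank moved in opposite
  directions, which is a tie-breaking artifact of near-unchanged genes, not
  a coordinated shift.
* `alpha` (default 0.05): the upper-tail mass of the calibrated threshold
  $\theta = \hat\mu + z_{1-\alpha}\,\hat\sigma$, where $\hat\mu$ and
  $\hat\sigma$ (sample SD) summarize the pooled ranking scores of normal
  subjects and $z_{0.95} = 1.644854$. $\theta$ lives on the original
  $\Delta S$ scale. Exceedance is strict ($\Delta S > \theta$).
* Expression scale: values are scored as-is; an optional `log2(x + 1)`
  transform is available at load/fit time. Ranks are scale-free, but
  $\Delta E$ (hence $S^t$) is proportional to the input scale, which is
  why $\theta$ must always be calibrated on the same scale it is applied
  to.
* Missing values are rejected at load time; there is no imputation.
* Gene universes of sample and baseline are intersected (with a warning)
  and $N$ recomputed; fewer than 2 shared genes is an error.

### Choosing alpha: rates versus localization

Two different questions hide behind $\theta$. *"Is this cohort's
per-time-point exceedance at its nominal level?"* is a rate question, and
$\alpha = 0.05$ is the right setting. *"At which time point did this
subject leave the normal state?"* is a localization question across all
$T - 1$ tested time points of a series; at per-point $\alpha = 0.05$ a
15-point null series exceeds $\theta$ somewhere roughly half the time
(real challenge-study data behave the same way: a sizeable minority of
asymptomatic subjects show spurious signals). The package's benchmark
experiments therefore use a family-wise (Bonferroni) setting
$\alpha = 0.05/(T-1)$ whenever the *time* of the signal is the quantity of
interest, and $\alpha = 0.05$ for exceedance-rate calibration. Both are
exposed through the single `alpha` argument.

### Threshold calibration pool

$\Delta S$ at the first post-baseline point is identically zero by
construction; these structural zeros say nothing about normal variability
and are excluded from the calibration pool. The pool should come from the
same cohort (same platform, same gene universe) that will be scored:
cohorts differ in how tightly gene means are packed, which sets the rank
volatility and hence the $\Delta S$ scale.

## Stage mode

Cross-sectional cohorts (tumor stages) have one group of samples per stage
and reference (tumor-adjacent) samples instead of longitudinal baselines.
`spcr_stages()` averages case samples within each stage into a
one-sample-per-stage course, scores it against the pooled reference
baseline, and calls the earliest stage at which the ranking score has
strictly increased for `min_consecutive_increases` (default 2) consecutive
stages with a cumulative rise of at least `min_relative_jump` (default 1)
times the range of the earlier scores. This rule is a heuristic
formalization of "a drastic, sustained increase after the first stage":
no threshold is calibrated because reference samples are few and noisy.
The rise is measured over the final `min_consecutive_increases` steps, and
at least two pre-run stages are required — otherwise there is no measurable
normal-phase fluctuation to compare against, and the rule would fire on
the first two noisy upticks of any series.

## The synthetic-data generators

### Factor model (primary test surface)

`simulate_factor_study()` plants, in the simplest sufficient form, the
statistical signature DNB theory predicts:

* every gene has a fixed mean level drawn from $N(7, 2)$ — a
  log2-microarray-like scale — plus i.i.d. $N(0, \sigma^2)$ observation
  noise ($\sigma =$ `noise_sd`, default 1);
* the baseline pool has `n_normal_samples` (default 10) normal samples;
* from `transition_index` (default 10 of 16 time points) onward, the
  `dnb_size` (default 20 of 200) module genes share the latent displacement
  $\lambda_k (1 + \eta_k)$, $\eta_k \sim N(0,1)$, where
  $\lambda_k = \texttt{dnb\_variance\_ramp} \cdot \sigma \cdot k$ grows
  with the number of post-transition steps $k$. The default ramp
  $\sqrt{3}$ makes the module SD exactly double at the first
  post-transition point ($\sqrt{\sigma^2 + 3\sigma^2} = 2\sigma$). The
  module's SD, pairwise correlation and mean displacement all rise with
  $k$; the rest of the genes stay stationary. A zero ramp reproduces the
  same-seed null study exactly.
* `n_null_subjects` adds same-cohort null time courses (shared gene-mean
  configuration) mirroring asymptomatic subjects; their pooled scores are
  the natural calibration set.

What this generator does *not* emulate: probe-level structure, batch and
array effects, heavy-tailed noise, correlated background modules,
between-subject baseline heterogeneity, and secular trends unrelated to
the transition. Passing the benchmark therefore shows that the statistic
detects the DNB signature under clean conditions at realistic sizes — not
that it is robust to every artifact of real cohorts.

### Michaelis–Menten network (secondary realism)

`simulate_network_study()` integrates a small stochastic regulatory
network in Michaelis–Menten form (Euler–Maruyama, default `dt = 0.01`,
burn-in 1000 steps, 2000 steps ≈ 20 time units of relaxation per recorded
sample, reflecting boundary at 0). Node 1 is a bistable auto-activator

$$dx_1 = \Big(a + q + \tfrac{8 x_1^2}{1 + x_1^2} - 4 x_1\Big)dt
  + \sigma\, dW,$$

whose basal rate $a \approx 0.5395$ is derived analytically (by solving
the tangency condition of the fold) so the saddle-node that annihilates
the low-expression state sits exactly at the control-parameter value
$q = 0$; the other fold sits near $q = -0.54$, so the low state exists on
the whole default sweep $q \in [-0.4, 0.2]$. The remaining nodes are
alternately activated by node 1 and repressed in a cascade
(Hill coefficient 2, $K = 0.5$), so the network reorganizes after the
transition. Approaching the fold from below, the driver's restoring force
vanishes and its stationary fluctuations grow — critical slowing down, the
dynamical origin of early-warning signals. The ground-truth transition is
the first grid point with $q \ge 0$; with 20 relaxation time units per
step, the passage through the fold bottleneck occasionally completes one
grid point late, which is visible as a jump localized at truth + 1. This
network is a deliberately small stand-in of the model class, not a
reproduction of any particular published system.

A practical note on detection here: the ranking score rises *gradually*
before $q = 0$ (that rise is real — the system is approaching the
tipping point), then jumps when the low state disappears. A calibrated
threshold flags the gradual rise early; the transition itself is best
localized as the time point with the sharpest score increase, which is
what the reproduction script reports.

### Null studies

`simulate_null_study()` is the stationary counterpart (no module, truth
index `NA`), used for specificity and calibration; with
`n_null_subjects` it produces whole null cohorts.

## Benchmark experiment sizes

The test suite and the reproduction script (`scripts/acceptance.R`) use:
100 random instances (up to 500 genes) for the exact top-`m`/full-sort
agreement check; 10,000 draws for threshold calibration; 100 factor-model
cohorts (200 genes, 20-gene module, transition at point 10 of 16, 8 null
subjects each) for transition recovery and signaling-gene enrichment; one
200-subject null cohort for specificity; and one 18-node network sweep.
These sizes give stable rates (recovery and enrichment move by a few
percent across seeds) while the whole suite runs in well under a minute.

## Numerical and degenerate-input conventions

* Ranks: `rank(..., ties.method = "average")`, ascending (rank 1 = lowest).
  Any consistent direction gives the same $|\Delta R|$; one must be fixed
  for reproducibility.
* Ties at the top-`m` cut and the top-fraction cut are broken by gene
  identifier; tied scores contribute equally to $S^t$ either way.
* Signaling-gene selection keeps $\lceil \text{fraction} \cdot N \rceil$
  genes, so any positive fraction yields at least one gene; the
  "common" filter keeps genes in at least `min_subjects` (default 5,
  i.e. "more than four") per-subject sets.
* `normalize_by_min()` requires strictly positive values (the minimum maps
  to 1); non-positive minima are an explicit error.
* Threshold calibration refuses fewer than 2 scores or zero variance;
  the standard-normal quantile is computed by `qnorm` (exact to machine
  precision).
* Simulations restore the caller's RNG state; identical config + seed
  gives identical studies.

## Known limitations

* The statistic is sensitive to any coordinated large shift, whether or
  not the shifting genes interact mechanistically; rank changes of
  non-interacting genes contribute noise to gene selection.
* $\theta$ assumes approximately normal pooled scores; heavy-tailed
  cohorts will mis-calibrate the nominal level.
* Stage mode has no calibrated null; its call is a heuristic and should be
  read together with the score curve.
* Per-subject baselines built from a single baseline sample inherit that
  sample's noise; pooled baselines trade subject specificity for
  stability. Both modes are available (`baseline_mode`).
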
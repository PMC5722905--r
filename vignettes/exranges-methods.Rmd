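---
title: "Rate-change significance features for network inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-change significance features for network inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `exranges`, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic benchmark does and does not
demonstrate.

## 1. The transform

### Slopes within series

A multi-series time course is a genes × samples matrix in which every
sample carries a `(series_id, time)` label — a series being one
self-contained time course (a tissue, a patient, a culture). For gene $g$
the rate of change over the step from time $t$ to $t+1$ **within one
series** is

$$C_g^{t} = \frac{X_g^{t+1} - X_g^{t}}{T_{t+1} - T_{t}},$$

attached to the *from*-sample $t$: the quantity of interest downstream is
"the expression level at $t$, weighted by the significance of what happens
next". Slopes never span series boundaries. A series flagged cyclic
contributes one extra wrap step from its last sample back to its first;
since the literal time difference $T_1 - T_N$ is negative and spans the
whole series, the wrap interval is instead the series' median
within-series gap (configurable via `wrap_interval`), which for an evenly
sampled series equals every other step's interval. Non-cyclic series of
$N$ samples contribute $N-1$ steps, so their last sample starts no step
and contributes no output column; we drop that column rather than impute
it. Total step count is therefore
$\sum_s (N_s - 1 + \mathrm{cyclic}_s)$.

### Gene-specific background and tail significance

All of a gene's slopes, pooled across series, form its background — the
gene's own history of rate changes, on its own expression scale, which is
what makes the resulting significance *rate normalized in a gene-specific
manner*. Pooling across series is deliberate: per-series backgrounds would
be tiny and would absorb genuine series-level differences in dynamics.

With `bootstrap = TRUE` (default) the reference multiset is a seeded
resample of `bootstrap_reps = 10000` draws with replacement from the
pooled slopes; in direct mode the pooled slopes themselves are the
reference, which makes p-values exactly reproducible by tail counting and
is what the oracle tests use. The bootstrap converges to the pooled
empirical distribution as $B$ grows, so the two modes differ only by
resampling noise of order $1/\sqrt{B}$.

A slope $s$ against a reference multiset of size $B$ is scored by its
smaller empirical tail with add-one smoothing:

$$p = \frac{\min(\#\{b \le s\},\, \#\{b \ge s\}) + 1}{B + 1}.$$

Two numerical choices live here:

* **Smaller tail.** An ECDF conditional of the form "if $P < 0.5$ take
  $1-P$" keeps the *larger* tail, bounding $p \ge 0.5$ and
  $|R| \le \log_{10} 2 \approx 0.301$ — which flattens the significance
  signal the transform exists to extract (extreme changes of either sign
  should be significant; the direction travels separately through the
  sign term). The package therefore uses the smaller tail by default and
  retains the larger-tail form as `tail = "literal"` purely for
  comparison.
* **Add-one smoothing.** An empirical tail can have mass 0, making
  $-\log_{10} p$ infinite. The $(+1)/(B+1)$ floor is the standard
  permutation-test correction; $|R|$ is then bounded by
  $\log_{10}(B+1)$ (4 for the default bootstrap).

The RANGES value is $R_g^t = -\log_{10}(p)\,\cdot\,\mathrm{sign}(C_g^t)$,
with $\mathrm{sign}(0) = 0$ so flat steps score exactly 0. ExRANGES
multiplies by the expression level at the step start,
$E_g^t = R_g^t \cdot X_g^t$.

Useful invariances, all property-tested: RANGES is unchanged by positive
rescaling of any single gene's expression and by global rescaling of the
time axis (ranks of slopes against their own background are
scale-invariant); ExRANGES scales linearly with per-gene expression
rescaling; $\mathrm{sign}(R)$ always equals the slope sign.

## 2. The inference engine

Edges are scored per target, in the manner of GENIE3: regress the target's
feature profile on all candidate-regulator profiles (the target excluded
from its own regulator set) with a random forest, and read each
regulator's score off the forest's importance measure. Columns are treated
as exchangeable observations, so the engine runs unchanged on expression
samples, RANGES steps or ExRANGES steps; the two feature types are never
mixed in one run.

Defaults and their reasons:

* `n_trees = 2000` regression trees per target; a reduced count (100) is
  appropriate for large target sets at some cost in score stability — the
  package's own benchmark uses 100–500.
* `importance = "permutation"`: mean increase in out-of-bag MSE when one
  regulator's values are permuted, i.e. the mean decrease in accuracy.
  Variance-reduction importance (`"variance"`) is available for
  cross-checking.
* `mtry = floor(sqrt(p))` regulators tried per split, configurable.
* `standardize = TRUE`: feature rows are centred and scaled to unit
  variance before fitting, so importances are on a common
  fraction-of-target-variance scale across targets.
* `normalize = FALSE`: per-target importances are *not* divided by their
  sum before pooling into the global edge ranking. Sum-normalization
  assigns every target a total edge mass of 1, which inflates the
  near-zero noise importances of unpredictable targets into scores that
  compete with genuinely supported edges; with standardized target
  profiles and permutation importance the raw scores are already
  comparable, and the planted-edge benchmark is the measurable case in
  point (it fails under normalization and passes without it). The
  normalized variant remains available.

Determinism is part of the contract: each target's forest is fitted
single-threaded with a seed derived from (root seed, target index), and
parallelism (`n_jobs`) only distributes targets across processes, so any
degree of parallelism yields bit-identical scores. Observation order is
canonicalized (columns sorted lexicographically by feature values) before
fitting, making scores invariant to column permutations of the input.
Edge rankings break score ties lexically by (regulator, target), so
everything downstream — ROC, recall — is reproducible. Degenerate inputs:
a constant target returns all-zero importances rather than an error; a
target left with fewer than two candidate regulators is an error.

## 3. Evaluation

Per-regulator ROC AUC is the Mann–Whitney statistic of positive versus
negative target scores (ties count ½, so an all-equal ranking scores
exactly 0.5), verified in tests against exhaustive pairwise comparison and
against an independent ROC implementation. Precision–recall curves are
evaluated at every distinct threshold with step-wise integration for
average precision. Recall-at-fraction reports the fraction of
gold-standard pairs among the top $\lceil f \cdot |E|\rceil$ ranked edges.

Variability profiling: the coefficient of variation is $sd/\mu$ across all
samples ($n-1$ denominator throughout); the within/between decomposition
reports the mean across series of the within-series SD against the SD of
per-series means. Functional cohesion: for each annotation category
represented in a target set, a hypergeometric upper-tail p-value of the
overlap within the chosen universe (by default the genes the inference run
scored, not the genome), summed as $\sum -\log_{10} p$ over those
categories. No multiple-testing correction is applied inside the score by
default — the score as classically defined sums raw p-values — but any
`p.adjust` method can be requested. Summing over *all* represented
categories (not only significant ones) keeps the score continuous in the
data; a category at $p = 1$ contributes nothing.

## 4. The synthetic benchmark

The generator plants known regulator→target edges behind the very
confound that motivates the transform: mRNA stability decoupling level
from transcription, plus series-level baseline offsets.

* **Regulator activity** (cyclic mode): $\exp$ of a fundamental sinusoid
  (period 24 h, amplitude drawn from 0.6–1.0) plus a first harmonic, with
  random phases, shared by all series — a common circadian-style drive —
  plus a per-regulator, per-series Ornstein–Uhlenbeck modulation
  (stationary SD 0.5, correlation time 4 h). The modulation is essential,
  not decorative: with a purely shared deterministic drive every
  regulator is an interchangeable encoder of clock phase, and no method
  can attribute a target to its specific regulator. The OU term is the
  regulator-specific signal a target integrates in every series.
* **Targets** follow $dY/dt = k(t) - \delta Y$ with
  $k(t) = \delta\,\bar{Y}\,(1 + w\,(d(t) - 1))$, where
  $d(t)$ is a saturating (Hill coefficient 1) response to the regulator's
  activity normalized to mean 1, $w$ is the regulation strength (0
  disconnects the edge; a repression variant flips the response), and
  $\delta \sim U(0.04, 0.12)\ \mathrm{h^{-1}}$ (half-lives ≈ 6–17 h,
  slow against the 24 h period) so levels lag and smooth the drive while
  rates stay coupled to it. Integration is explicit Euler with automatic
  sub-stepping ($\delta\,\Delta t \le 0.1$ and $\Delta t \le$ a quarter
  of the sampling interval), initialized at the quasi-steady state and
  burnt in for two periods; at large $\delta$ the trajectories converge
  to the quasi-steady-state limit $k(t)/\delta$, which the tests verify
  by correlation.
* **Decoys** follow independent smooth per-series curves (random period
  and phase), so they have realistic temporal structure but no
  cross-series consistency. **Observation layer**: a baseline of 10, a
  per-gene per-series offset $\sim N(0, 2^2)$ — dominating the
  within-series signal SD of order 0.3–1, as the between/within
  decomposition of the generated data confirms — and i.i.d. observation
  noise $\sim N(0, 0.1^2)$, floored at 0. Signal scale `target_mean = 3`.
  These levels were fixed while designing the generative model to realize
  the intended regime (offsets dominate; rate signal per 2 h step a few
  times the slope noise) and are the package defaults.

The default study conditions are 5 regulators × 20 targets each, 100
decoys, 6 cyclic series × 24 samples (2 h spacing over 48 h). On this
design the acceptance checks require ExRANGES features to recover planted
edges at mean per-regulator AUC above 0.8 and above the raw-expression
AUC in at least 4 of 5 seeds, with 100-tree forests to keep the suite
fast; `scripts/acceptance.R` runs one seed at 500 trees.

The null calibration sets regulation strength to 0 and scores the nominal
(now disconnected) target assignment. Because disconnected targets are
flat while decoys keep their smooth dynamics, a mixed universe would
measure that compositional difference rather than regulator leakage —
smooth decoys pick up slightly positive spurious importances — so the
null benchmark uses no decoys: positives and negatives are then
exchangeable and the mean AUC over 20 seeds is required to sit in
$[0.45, 0.55]$.

What passing these tests does *not* show: the generator has Gaussian
observation noise on an arbitrary intensity scale (no negative-binomial
count noise, no mean–variance coupling), deterministic kinetics (no
bursty transcription), single-regulator targets (no combinatorial logic),
and regulator mRNA that tracks regulator activity up to noise (no
post-translational regulation). Performance on the benchmark is evidence
that the implementation realizes the method's claimed advantage under the
stated confounds, not a prediction of AUC on any real data set.

## 5. Known limitations

* Uneven sampling is supported, but very heterogeneous step lengths make
  slope backgrounds mix heteroscedastic estimates (short steps have
  noisier slopes); the transform does not model this.
* Backgrounds need a reasonable number of pooled slopes per gene (tens at
  least) for the tail p-values to resolve; two-sample series give a
  3-point background and essentially binary significance.
* The engine scores marginal importance per target; strongly correlated
  regulators share credit, and edge signs (activation vs repression) are
  not called.
* Missing values, normalization and probe-to-gene mapping are
  out of scope: inputs must be complete non-negative matrices.
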
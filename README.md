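# exranges

Regulatory-network inference from time-series expression data using
rate-change significance features.

## The problem

Steady-state transcript abundance confounds transcriptional activity with
mRNA stability: a stable transcript can sit at a high level long after its
regulator has switched off, and tissue- or subject-level baseline offsets
often dominate the variance of a pooled multi-series time course. Both
effects weaken expression-level features as input to regulator→target
inference. The *change* in expression between consecutive time points is a
more direct readout of transcriptional activity — a target responds to its
regulator in the rate domain even when its level lags far behind.

`exranges` implements a feature transform that scores, per gene, how
significant each consecutive-step rate change is against that gene's own
history, and couples it with the expression level at the step start:

- **RANGES** — for gene *g* with expression *X* sampled at times *T₁…T_N*
  within each series, the step slope is
  *C_g^t = (X_g^{t+1} − X_g^t) / (T_{t+1} − T_t)*, computed only within a
  series (the wrap step *T_N → T₁* is added for cyclic designs). All of a
  gene's slopes, pooled across series, form its background; each slope's
  empirical tail probability *p* against a bootstrap of that background
  (10,000 draws with replacement, add-one smoothing) gives the signed
  significance *R_g^t = −log₁₀(p) · sign(C_g^t)*.
- **ExRANGES** — *E_g^t = R_g^t · X_g^t*: the expression level preceding a
  significant change, emphasized in proportion to that change's
  significance.

Either matrix (or raw expression) feeds a GENIE3-style tree-ensemble
engine: one regression forest per target gene on the candidate-regulator
profiles, scoring each regulator by the mean decrease in out-of-bag
accuracy when its values are permuted. Ranked edges are evaluated against
gold-standard target sets by ROC/PR analysis, recall at a top fraction of
predictions, coefficient-of-variation and within/between-series variance
profiling, and hypergeometric functional-cohesion enrichment.

A synthetic-data generator completes the package: planted regulator→target
edges behind a production–degradation model
*dY/dt = k·f(activity) − δ·Y* with gene-specific decay rates, cyclic or
drifting regulator activities, and between-series baseline offsets that
dominate within-series variance — exactly the confound the transform is
designed to defeat — so every stage is testable end to end without
external data.

## Worked example

```r
library(exranges)

ds <- assemble_dataset(simulation_config(seed = 1))
ds
#> SyntheticDataset: 205 genes ( 5 regulators, 100 targets, 100 decoys) x
#>   144 samples; 100 planted edges

R <- ranges(ds$expr, transform_config(seed = 1))
E <- exranges(ds$expr, R)
R
#> RangesMatrix: 205 genes x 144 steps (smaller tail, bootstrap B=10000 background)

sc <- infer_network(E, ds$regulators,
                    cfg = inference_config(n_trees = 100, seed = 1))
head(rank_edges(sc), 5)
#>   regulator  target     score
#> 1      REG4 TGT4_14 0.4106189
#> 2      REG1    REG3 0.3891347
#> 3      REG4  TGT4_2 0.3824394
#> 4      REG2 TGT2_14 0.3779891
#> 5      REG3 TGT3_17 0.3655067

recall_at_fraction(rank_edges(sc), ds$true_edges, 0.1)
#> [1] 0.58

uni <- setdiff(colnames(sc$scores), "REG1")
gs <- gold_standard("REG1", ds$true_edges$target[ds$true_edges$regulator == "REG1"], uni)
roc_auc(sc$scores["REG1", uni], gs)
#> ROC: AUC = 0.8905 (20 positives / 204 targets)
```

Four of the five top-ranked edges are planted ones; 58% of all planted
edges sit in the top 10% of ~1000 candidate edges, and REG1's targets are
recovered with AUC 0.89 — while the same engine on raw expression of the
same dataset stays near chance (see the methods vignette for why).

A command-line front end wrapping the same functions is installed at
`inst/cli/exranges` (`exranges simulate | transform | infer | evaluate |
run`, each with `--seed`, `--out-dir`, `--config`); every run writes a
JSON manifest with the effective configuration, input digests and
timings.

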
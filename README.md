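# mycnreg

Integrative inference of master-regulator networks in neuroblastoma-style
cohorts: from ChIP-seq binding peaks and dual-platform expression to
direct/indirect target calls, E-box usage, co-modulator inference, miRNA
differential expression and target scoring, TF–miRNA feed-forward-loop
motifs, convergently targeted genes, and survival stratification.

## Who this is for

Computational biologists studying a transcription factor that drives a
disease program — the motivating case is MYCN in neuroblastoma — who have
binding peaks for the regulator, expression profiles of the same cohort on
two platforms, a small-RNA perturbation experiment, and the standard public
resources (a multi-regulator binding-site catalog, miRNA-target databases,
a PPI network, survival annotations), and who want the whole integration as
a reusable, tested pipeline rather than a collection of one-off scripts.

## The model in brief

* **Direct targets**: genes both *bound* (a peak within the stranded window
  `[TSS − 10 kb, TSS + 2 kb]`, after requiring peaks to be co-occupied by at
  least one other regulator) and *correlated* (Spearman `|ρ| ≥ 0.3` with the
  master on **both** platforms). The correlation sign splits them into
  activated and repressed.
* **Co-modulators**: for a candidate regulator, samples are stratified into
  top/bottom 35% by its expression and each bound gene gets a conditional
  correlation difference `d_g = z(ρ_H) − z(ρ_L)` with
  `z(r) = atanh(r)·√((N−3)/1.06)`. The d-distribution of co-bound genes is
  compared to that of all bound genes by one-sided KS tests; a regulator is
  reported when the same direction is significant on both platforms.
* **miRNAs**: upper-quartile normalization, then an empirical
  differential-expression probability (the fraction of within-condition
  noise contrasts dominated by the feature's between-condition `(|M|,|D|)`
  signal), filtered at probability ≥ 0.6 and mean count ≥ 100; a miRNA is a
  direct target when its promoter (predicted TSS − 10 kb to precursor
  start) is bound or its host gene is bound.
* **Target graph**: miRNA→gene edges scored 1 if validated, else n/10 for n
  prediction databases (capped at 1), retained at confidence > 0.3.
* **Feed-forward loops**: 3-node (common targets of master and miRNA;
  hypergeometric) and 4-node (PPI links between the miRNA's
  correlated-but-unregulated targets and the regulated genes; permutation
  null of same-size draws). Genes convergently targeted by regulated miRNAs
  are found by hypergeometric tests with Benjamini–Hochberg correction.
* **Survival**: consensus k-means (k = 2, 1000 restarts, majority label)
  over the regulated-gene signature in non-amplified samples, compared by
  Kaplan–Meier curves and the log-rank test.

The methods vignette (`vignettes/mycn-regulatory-networks.Rmd`) documents
every numerical choice and what the synthetic generator does and does not
emulate.

## Worked example

Every input can be simulated with planted ground truth, so the pipeline's
answers are checkable end to end:

```r
library(mycnreg)

bundle <- simulate_bundle(seed = 42)       # all inputs + truth
res    <- run_pipeline(bundle, seed = 42)  # all stages

attr(res$regulation$calls, "counts")
#>       activated       repressed correlated_only      bound_only            none
#>              40              61              39              15             352
```

With 40 activated and 60 repressed targets planted, the caller recovers
40 and 61 (one background gene drifts in); the 39 `correlated_only` genes
are the planted TF-driven indirect layer. The four planted co-modulators
come back with their signs, and the null regulators stay silent:

```r
subset(res$comodulators, sign != "none")[, c("regulator_id", "sign")]
#>   regulator_id     sign
#> 1        REG01 positive
#> 2        REG02 positive
#> 3        REG03 negative
#> 4        REG04 negative
```

The canonical E-box is enriched in activated-gene promoters
(`OR = 25.4, p = 1.3e-11`), 10 of 10 planted differentially expressed
miRNAs are recovered as master-bound and called at probability ≥ 0.6, the
planted feed-forward loops test at `p < 1e-8` (3-node), and the survival
stage separates the two planted expression subtypes
(log-rank `p = 5.8e-05`, groups of 69 and 84 non-amplified samples):

```r
res$survival$logrank$p_value
#> [1] 5.84e-05
evaluate_recovery(res, bundle$truth)$direct_recovery
#> [1] 1
```

The package also bundles the printed knockdown differential-expression
table (45 miRNAs) and the regulated-miRNA table (24 miRNAs) as plain-text
fixtures; `mirna_knockdown_table()` / `regulated_mirna_table()` load them,
and `select_diffexp()` on the former reproduces its bookkeeping: 26
up-regulated, 19 down-regulated, 49 distinct stem-loop loci.

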
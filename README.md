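# cistromix

Integrative cistrome–transcriptome–clinical analysis for transcription
factor studies in cancer genomics.

## The problem

ETS-family transcription factors (GABPα, ERG, ETV1) bind a shared GGAA/T
core motif, yet occupy partly distinct genomic territories and drive
distinct programs in prostate cancer. Deciding whether two factors share
a cistrome, which genes a factor directly regulates, and whether that
regulation carries prognostic information requires stitching together
three data types:

1. **ChIP-seq peak sets** — compared by interval overlap
   ("≥ 1 bp" semantics on BED 0-based half-open coordinates), with
   hypergeometric and genomic-permutation significance;
2. **Perturbation expression profiles** — overexpression (OE) and
   knockdown (KD) contrasts whose *concordant* responders
   (OE-up ∧ KD-down) define a core regulated gene set;
3. **Clinical outcome** — immunohistochemistry H-scores or expression
   scores dichotomized at a quartile or an optimal cutpoint, tested by
   Kaplan–Meier/log-rank and Cox proportional hazards.

`cistromix` implements the full chain as composable, seeded, tested R
functions, plus a synthetic-data module that generates every input class
with *planted* structure (overlap fractions, promoter bias, effect sizes,
hazard ratios) so the entire pipeline is validated offline.

## The statistics at the core

* **Peak-set concordance**: entry (i, j) of the overlap matrix is
  100·|{peaks of set *i* overlapping set *j*}| / |set *i*| — row-set
  denominator, recorded in the object so heatmaps cannot transpose it.
  Significance by the hypergeometric upper tail
  P(X ≥ k) with a merged-union universe, and by a permutation null that
  redistributes each query interval uniformly on its own chromosome with
  length preserved, p = (1 + #{null ≥ obs}) / (1 + n_perm).
* **Peak-to-gene logic**: peaks anchor at their midpoint, genes at their
  strand-aware TSS; windows are strict (`distance < w`), defaults
  5/10/25/50 kb; GREAT-style closest-feature and region-binomial tests.
* **Differential expression**: a fully specified moderated t — per-gene
  pooled variance shrunk toward the global mean with fixed prior df,
  floored at the 10th-percentile sd, referred to t on residual+prior df,
  BH-FDR across genes. (A documented stand-in, not empirical Bayes.)
* **Survival**: Kaplan–Meier with Greenwood log–log 95% CI;
  Hyndman–Fan definition-8 quantiles, h = (n + 1/3)p + 1/3, for the
  first-quartile H-score dichotomization (boundary value → "low");
  two-group log-rank; maximally selected log-rank cutpoint (naive and
  permutation-adjusted p); Cox partial likelihood with Efron ties by
  Newton–Raphson (score test ≡ log-rank for an untied binary covariate).

## Worked example

```r
library(cistromix)
sp <- synthetic_spec(seed = 42, n_genes = 500, n_peaks = 800,
                     overlap_fraction = 0.88, promoter_bias = 0.8)
gg    <- gen_genome(sp)
gabpa <- gen_peakset(gg$genome, gg$genes, sp, name = "GABPA")
etv1  <- gen_overlapping_peakset(gabpa, 0.88, gg$genome, sp, name = "ETV1")

pairwise_overlap_matrix(list(gabpa, etv1))
#> OverlapMatrix (row_pct_of_row_set_overlapping_column_set)
#>       GABPA  ETV1
#> GABPA 100.0  60.2
#> ETV1   88.6 100.0

permutation_proximity_test(etv1, gabpa, gg$genome, n_perm = 999, seed = 42)
#> EnrichmentResult [permutation] observed=709 expected=3.682 p=0.001 (n_perm=999)

round(distance_distribution(gabpa, gg$genes)$fractions, 3)
#> 0.819 0.061 0.117 0.002   # promoter-biased, as planted (bias 0.8 + leak)
```

88.6% of ETV1 peaks overlap the GABPα set (planted fraction 0.88, within
binomial error at n = 800) and the permutation p hits its floor
1/(n_perm+1): far more overlap than the ~3.7 expected under random
placement. The distance profile recovers the planted 0.8 promoter bias.

Downstream, concordant DE and survival:

```r
ex    <- gen_expression(gg$genes, sp)
core  <- core_regulated_set(differential_expression(ex, "control", "OE"),
                            differential_expression(ex, "control", "KD"))
length(core$gene_ids)
#> 18                        # 25 genes planted at |log2 FC| = 2, 3 reps/arm

sv <- gen_survival(200, sp, score_link = "step")
optimal_cutpoint(sv$scores, sv$records)[c("cut", "chi2", "p_naive")]
#> cut 0.578, chi2 48.4, naive p 3.5e-12   # planted step at 0.6, HR 3
```

A full run (`simulate_inputs()` then `run_pipeline()`, or the CLI in
`inst/cli/cistromix.R` with subcommands `simulate` / `run-all`) writes
overlap matrices, enrichment tables, DE tables, core sets,
fraction-bound summaries, panel checks, KM curves and a manifest carrying
the config hash and seeds.

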
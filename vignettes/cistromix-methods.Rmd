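---
title: "Methods: models, conventions and design choices in cistromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in cistromix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromix)
```

This vignette is the package's own account of its statistical methods:
what each stage assumes, which tunable parameters matter, what the
synthetic generators do and do not emulate, and where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Interval model and overlap semantics

All peaks are BED 0-based half-open intervals `[start, end)`. Two
intervals overlap when they share at least one base; touching intervals
(`[0,10)` and `[10,20)`) share none and are **not** merged or counted as
overlapping. This makes every boundary case testable: "≥ 1 bp overlap"
is literally a shared-base count ≥ 1.

* `consensus_peaks()` implements the two-caller high-confidence rule by
  retaining the *first* caller's intervals that any second-caller peak
  supports. Which caller's coordinates survive is not dictated by the
  consensus idea itself; we keep caller 1's (preserving its summit and
  extent) and expose a symmetric variant, rather than inventing merged
  coordinates.
* `pairwise_overlap_matrix()` divides by the **row** set's size, and the
  object records that orientation, because a transposed concordance
  heatmap is a silent and common error. Duplicate intervals are counted
  once in both numerator and denominator — the only convention under
  which "duplicates count once" and "diagonal = 100" can hold together.
* Row clustering uses average linkage on 1 − Pearson correlation.
  Hierarchical clustering leaf order is not unique; we order children by
  (subtree size, then smallest leaf label) so heatmaps are reproducible
  across input orderings. A constant row has undefined correlation; it
  is assigned distance 1 to everything, with a warning, rather than
  erroring a whole matrix for one degenerate row.

## 2. Enrichment statistics

**Hypergeometric tail.** P(X ≥ k) for k overlapping peaks among draws
from a finite universe. Peak sets have no natural universe; by default we
use the number of intervals in the merged union of all sets being
compared, with an explicit override. This makes the test self-contained
and reproducible, at the cost of a universe that shrinks when peaks are
dense — which is why the permutation test below is the primary evidence
and the hypergeometric p is reported alongside its universe descriptor.

**Permutation ("proximity") null.** Each query interval is placed
uniformly at random on its own chromosome with its length preserved,
independently of the others; the statistic is the number of query
intervals overlapping the (merged) target set. The p-value uses the
add-one estimator (1 + #{null ≥ observed})/(1 + n_perm), so it is never
0 and never below 1/(n_perm + 1). Ties count toward the null ("≥"),
which is conservative. Two consequences worth knowing:

* the null preserves interval lengths and per-chromosome placement but
  not inter-peak spacing or chromatin accessibility — it answers "more
  overlap than random placement", not "more than expected given open
  chromatin";
* the statistic is an integer, so with small expected overlaps the
  discrete + conservative conventions push the realized type-I rate
  below nominal. The calibration test therefore uses a fixture whose
  statistic has standard deviation ≈ 7 (300 query intervals), where the
  discreteness penalty is small; with ~100 intervals the same test
  rejects at ≈ 2% rather than ≈ 5%, an artifact of resolution, not an
  error in the test.

**Region binomial.** GREAT-style: with fraction *f* of the genome
covered by (merged) annotation domains and *k* of *n* peak midpoints
falling inside, p = P(Bin(n, f) ≥ k). The midpoint is used as the
membership point because it is single and unambiguous.

**BH-FDR** is the exact step-up definition (cummin from the largest
rank), restored to input order, capped at 1.

## 3. Peak-to-gene logic

Peaks anchor at `floor((start + end)/2)`; genes anchor at the
strand-aware TSS — span start for `+` genes and the half-open span *end*
for `−` genes (consistent with half-open spans; the off-by-one is locked
by tests). Windowed assignment is strict (`distance < w`) because the
quoted thresholds ("< 25 kb", "within 10 kb") read as strict; defaults
5, 10, 25, 50 kb. A peak within the window of several TSSs is assigned
to all of them. Closest-feature ties break by smallest gene id. Distance
profiles bin closest-TSS distances into [0, 5 kb), [5, 50 kb),
[50, 500 kb), [500 kb, ∞) — the promoter-proximal / distal vocabulary of
ETS cistromes. Whether "near a gene" should measure to the TSS or the
gene body edge is genuinely open; the TSS is the default and a
`span` anchor is available in `assign_peaks_to_genes()`.

## 4. Differential expression stand-in

The package deliberately does not call limma. The documented stand-in
is a moderated two-sample t:

1. per-gene pooled variance s², residual df d = nₐ + n_b − 2;
2. shrinkage s̃² = (d₀·s̄² + d·s²)/(d₀ + d) toward the global mean
   variance s̄², with **fixed** prior df d₀ = 10;
3. sd floored at the 10th percentile of all moderated sds;
4. t referred to a t distribution on d + d₀ df, BH across genes.

An earlier iteration used a plain Welch t with only the sd floor. That
version provably cannot reach the stated sensitivity on the reference
simulation (50 of 1000 genes planted at |log2 FC| = 2, noise sd 0.5,
4 vs 4): Welch df ≈ 6 puts the planted p-values near 1.3×10⁻³, above the
BH line, and measured sensitivity was ~15%. The fixed-prior moderation
restores the df that replicated array designs actually warrant
(sensitivity ≥ 0.90 and null type-I within 5% ± 2% are both computed in
the acceptance suite). This is *not* empirical Bayes: d₀ is a constant,
not estimated from the marginal distribution of variances, and the
behaviour under strongly heteroscedastic genes will be more conservative
than limma's.

The core regulated set is the intersection of OE-up and KD-down calls at
an adjusted-p threshold (0.05 by default; 0.1 for integrative analyses).
Overlap percentages between gene sets use the **smaller** set as
denominator — the only convention reproducing the printed 19% from set
sizes 1825/1655 with 316 shared — and the raw ratios for both
denominators are returned alongside the rounded reporting value.

## 5. Survival methods

* **H-score** = intensity (0–3) × % positive nuclei, range 0–300.
* **Quantiles** use the median-unbiased Hyndman–Fan definition 8,
  h = (n + 1/3)p + 1/3 with linear interpolation, clamped to the sample
  range. The first-quartile dichotomization labels scores ≤ cut as
  "low" — the boundary belongs to the low group, locked by the printed
  "≤ 98" convention.
* **Kaplan–Meier** confidence intervals use the complementary log–log
  transform of the Greenwood variance: bounded in [0, 1] and the default
  of the field's reference implementation; undefined at S = 1 or 0 and
  reported as NA there.
* **Cox regression** maximizes the Efron-tied partial likelihood by
  Newton iteration with step-halving; convergence when max |score| <
  1e-8 within 25 iterations. The halving guard is *relative*
  (1e-9·(|ll|+1)): an absolute guard fires on machine-precision noise of
  a log likelihood of magnitude ~10³ and stalls convergence. Efron ties
  were chosen because month-granularity recurrence data tie heavily.
  Monotone likelihood (separation) is flagged and the last stable
  iterate reported with a warning rather than an error.
* **Optimal cutpoint** is a maximally selected log-rank scan over
  observed score values inside a quantile range (default 10–90%),
  i.e. recursive partitioning at depth 1. The returned naive p ignores
  the selection; a permutation-adjusted p (scores relabelled, seeded) is
  available and never smaller than the naive one. Deeper trees are out
  of scope.

## 6. The synthetic world

The generators state one simulated world and the tests measure recovery
in it; none of the defaults were chosen to make a test pass.

| parameter | default | why |
|---|---|---|
| genome | 2 × 50 Mb | two chromosomes exercise per-chromosome logic at desk scale |
| genes | 2000 × 10 kb | genic fraction ≈ 20%, typical promoter spacing |
| peaks per set | 2000, 200–400 bp | realistic ChIP peak widths, enough for ±2% overlap CIs |
| promoter bias | 0.8 | the promoter-enriched cistrome profile |
| overlap fraction | 0.88 | the concordant-cistrome magnitude |
| DE effect / fraction / noise | 2.0 log2 / 5% / sd 0.5 | clear perturbation on a minority of genes |
| replicates | 3 per arm | triplicate arrays (power tests use 4, as the reference simulation states) |
| HR / step / censoring | 3 at score 0.6 / 20% | strong prognostic step, moderate censoring |

Censoring is independent Uniform(0, m) with m solved numerically so the
expected censored fraction equals `censor_frac`. (Censoring each subject
at a uniform fraction of its *own* event time looks similar but is
informative — an immune fraction whose exit times scale with the planted
hazard — and biases Cox recovery; it was rejected for that reason.)

What the generators do **not** emulate: read-level noise and peak-caller
artifacts; probe effects and bead-level array structure (inputs are
gene-level); correlated genes (expression noise is iid); covariate
dependence between the survival score and other clinical variables. A
green recovery test therefore establishes that the pipeline's logic and
statistics are correct on data with the planted structure — not that the
methods are robust to every pathology of real ChIP-seq or array data.

Reproducibility: one master seed derives fixed per-generator child seeds
(`seed·7919 + stage offset, mod 2³¹−1`), so regenerating a single input
class does not disturb the others. All generators restore the caller's
RNG state.

## 7. Numerical and degenerate-input choices

* Empty consensus or core sets warn rather than error (legal, flagged).
* `pairwise_overlap_matrix` refuses empty sets by name; p-values are
  clamped to [0, 1]; permutation p ≥ 1/(n_perm+1) by construction.
* `cluster_matrix` on < 2 rows errors; degenerate k in
  `signature_projection` is truncated to the number of samples.
* The adjusted Rand index returns 1 when both partitions are the same
  degenerate partition (max index = expected index).
* Panel genes missing from the DE universe are reported and treated as
  not concordant, never as errors — a panel is an external list and may
  outrun the assay.

## 8. Known limitations

The hypergeometric universe for peak-level tests remains a modelling
choice with no ground truth; prefer the permutation p when the two
disagree. The permutation null ignores inter-peak spacing. The DE
stand-in's fixed prior df is a blunter instrument than estimated
moderation. The cutpoint scan reports an honest naive p but the
permutation adjustment is the defensible one. The pipeline assumes
gene-level expression input: probe-to-gene mapping is upstream.
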
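---
title: "Discovering embryonic germline/cancer genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering embryonic germline/cancer genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcgenes)
```

## The scientific problem

Tumors frequently reactivate transcriptional programs that are otherwise
restricted to the germline — the "soma-to-germline" model of oncogenesis.
Genes expressed in germ cells and tumors but silent in every healthy
somatic tissue (germline/cancer or *GC* genes, a refinement of the classic
cancer/testis antigen concept) are attractive therapeutic targets: because
no healthy adult tissue expresses them, targeting them should carry minimal
side effects. The most restrictive variant looks to the *embryonic*
germline: genes expressed in primordial germ cells (PGCs, the embryonic
precursors of gametes, isolatable from week 5.5–8.5 embryos) or in their in
vitro counterparts (PGC-like cells, PGCLCs), which are absent even from
adult germ cells — so targeting them should not even cost fertility.

`gcgenes` implements this discovery pipeline as reusable, tested
components: harmonization of heterogeneous expression compendia, the
threshold cascade that defines embryonic GC genes, tumor-breadth
subgrouping, bi-clustering of the gene-by-tumor-type matrix, a
single-sample rank-percentile signature score, signature-stratified
survival analysis, and protein-level validation rules. Because the original
analysis rests on consortium-scale downloads, the package ships a
synthetic-cohort generator with planted ground truth so that every stage is
verifiable at desk scale.

## The selection model

All thresholding happens on `log2(x + 1)`-transformed expression, after
per-dataset harmonization. A gene `g` is selected as an embryonic GC gene
iff all of the following hold (all inequalities strict):

1. **Germline expression**: `hpgc(g) > 0.72` OR `pgclc(g) > 0.50`, where
   - `hpgc(g)` averages same-stage replicates per sex, takes the minimum
     over developmental stages within each sex (the gene must be expressed
     throughout the sampled window), and returns the maximum of the female
     and male minima (either sex suffices);
   - `pgclc(g)` is the plain mean over PGCLC replicates.
2. **Somatic silence**: the maximum over healthy-tissue groups of the
   per-group maximum is `< 3.0`. Testis, ovary and the two transformed cell
   lines are excluded from this ceiling — otherwise no gene shared with the
   adult germline could ever pass.
3. **Tumor expression**: at least one tumor type's mean expression is
   `> 2.3`. The qualifying types are recorded per gene; their count is the
   gene's *tumor breadth*.

The numeric thresholds are fixed per-dataset constants (in the original
compendia 0.72 and 0.50 sit at the 33rd percentile of the germline
datasets). Because each dataset is thresholded on its own scale, differing
upstream normalizations (TPM-like, FPKM-like, variance-stabilized counts)
do not need to be reconciled — this is the reason the cascade compares
nothing *across* datasets except set membership.

Downstream, three derived gene sets matter:

- **pan-tumor** genes qualify in at least half the tumor types
  (`k = 17` of 33 by default);
- **single-tumor** genes qualify in exactly one type, with testicular germ
  cell tumors (TGCT) flagged specially since those tumors originate from
  the germline itself;
- the **embryonic-germline-specific** subset additionally requires
  adult-germ-cell and gonadal (testis/ovary) expression below a floor and
  gonadal-soma expression strictly below the gene's own germ-cell
  statistic — the genes expressed nowhere outside the embryonic germline.

## Harmonization choices

Two details of the transform chain are not fully determined by the source
material and are fixed here as package conventions:

- **Pseudocount**: the log transform is `log2(x + 1)`. It keeps zeros at
  zero, which matches the interpretation of the small germline thresholds
  (0.50, 0.72) as "just above background".
- **Order of operations**: gene-length correction
  (`expression / length * 1000`) is applied on the linear scale *before*
  the log transform, and only to the embryonic datasets (hPGC, PGCLC,
  gonadal soma, ESC) whose upstream normalization is not length-aware. The
  formula is linear, so applying it after a log transform would be
  incoherent.
- **Group summaries**: healthy tissues are summarized by the per-group
  *maximum* (the somatic filter must catch expression in any sample),
  tumor types by the per-group *mean* (tumor criteria describe the average
  patient). `summarize_groups()` exposes both.
- **Gene universe**: genes lacking a row in either required compendium are
  excluded, with the first missing dataset recorded as the reason; all
  ranks and percentiles are computed on the surviving universe.

## The signature score

The per-sample GC signature score ranks all `N` universe genes within a
sample (ascending, average ranks for ties), maps rank `r` to the percentile
`r / N * 100`, and averages the percentiles of the geneset members present.
The score lives in `(0, 100]`; the whole-universe geneset scores exactly
`(N + 1) / 2N * 100` in every sample, and a geneset holding only the
sample's top gene scores 100. Being rank-based, the score is invariant
under any strictly monotone transform of a sample's expression values —
the property that makes it comparable across heterogeneously normalized
samples. The exact percentile and tie conventions of the original hosted
implementation are unpublished; the convention above is this package's
single authoritative one, and reproduction of the original per-cell-line
scores is not attempted.

The correlation screen computes, per gene, the Pearson correlation with the
score across samples, with a two-sided p-value from the t distribution on
`n - 2` degrees of freedom; genes pass at `|r| > 0.5` and `p < 0.05` by
default. Constant genes are reported as skipped, not silently dropped.

## Survival analysis

Samples are dichotomized by signature score either at the **median** (ties
to the low group — the default) or by a **cutoff scan** that evaluates
every distinct score as a threshold and picks the minimizer of the
log-rank p-value. Scan p-values are nominal: the number of cutoffs tested
is reported alongside precisely because the scan is a multiple-testing
exposure, and no correction is applied. Kaplan–Meier curves and the
two-group log-rank test are delegated to the `survival` package; the test
suite pins their behavior to hand-computed product-limit and O/E/V tables,
including the convention that events precede censoring at tied times.

## Bi-clustering

The selected-gene × tumor-type mean matrix is row-Z-scored (population
standard deviation; constant rows map to zero) and clustered
agglomeratively with Euclidean distance and Ward linkage on both axes,
cutting to 5 gene clusters and 3 tumor groups by default. Two interpretive
choices are recorded: the Ward variant is `ward.D2` (Ward's criterion on
squared Euclidean distances), and clustering operates on the Z-scored
matrix — the original figure shows Z-scores only as colors, so whether raw
or standardized values were clustered is unstated. Cluster labels are
renumbered by size (largest first) for determinism.

## Protein validation rules

Two independent evidence routes, either of which validates a gene:

- **Categorical (immunohistochemistry-style)**: the protein is
  `not_detected` in every healthy tissue except the exempt gonadal ones
  (seminiferous tubules, ovary), AND at least one tumor type shows
  detection in at least 50% of investigated samples (inclusive at 6/12;
  panels hold at most ~12 samples).
- **Quantitative (mass-spectrometry-style)**: in at least one dataset the
  median tumor abundance *strictly* exceeds the median in matched normal
  tissue; equal medians do not count. Medians of even-length lists are the
  mean of the central pair (standard convention; the source is silent).

Genes with only one evidence type are judged on the available side.

## The synthetic world

`simulation_config()` states the simulated world; its defaults are not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | desk-scale stand-in for the ~16k-gene universe |
| `n_planted_gc` | 100 | planted positives, ~5% prevalence |
| `n_planted_embryonic_only` | 25 | a quarter of planted genes fully embryonic-restricted |
| `n_normal_tissues` | 54 | the real normal compendium's tissue count |
| `n_tumor_types` | 33 | the real tumor compendium's type count |
| `samples_per_group` | 4 | desk scale (real compendia have hundreds per group) |
| `expression_margin` | 1.0 log2 | planted separation from every threshold |
| `noise_sd` | 0.25 log2 | per-sample noise; margin/noise = 4 |
| `hazard_ratio` | 2 | planted high- vs low-signature hazard |
| `censoring_rate` | 0.3 | typical cohort censoring; uniform, independent |

Planted GC genes exceed the germline and tumor thresholds by at least the
margin and sit below the somatic ceiling by at least the margin *before*
noise; embryonic-only genes are additionally silent (below the floor minus
the margin) in adult germ cells and testis/ovary, with soma expression one
margin below their germ-cell level. Background genes fail at least one
criterion by the margin, with the failing subset randomized per gene so
every filter is exercised independently; the non-failing axes genuinely
pass, so single-criterion failures are informative. The PGCLC dataset
always has exactly two replicates, matching how the real inclusion
criterion was defined. Datasets are emitted on the linear scale, with the
inverse of the gene-length correction baked into the germ-cell datasets, so
harmonization is exercised end to end.

Survival times follow an exponential proportional-hazards model on the
median split of the planted-gene signature score. Censoring is drawn
uniformly on `[0, cmax]`, independent of event times, with `cmax` solved
numerically so the *expected* censoring fraction equals the configured
rate under the two-group hazard mixture — independence is what the
product-limit machinery assumes, so the generator honors it exactly.

Protein evidence is constructed noise-free: covered genes carry tables that
deterministically satisfy or violate the validation rules according to a
planted verdict, including the boundary cases (6/12 and 5/12 detection;
equal medians, built as permuted identical multisets so equality is exact
in floating point).

**What the generator does not emulate**: read-count sampling, batch
effects, tumor heterogeneity and purity, correlated gene modules beyond the
planted block structure, or informative censoring. A green test therefore
establishes that the pipeline's logic is faithful to its stated rules and
recovers structure of the assumed form — not that the thresholds are
optimal for real compendia, nor that real data meet the generator's
independence assumptions.

## Numerical and degenerate-input conventions

- All four cascade comparisons are strict, so a gene sitting exactly at a
  threshold is excluded (somatic, germline, tumor) by the printed rule.
- Ties at the dichotomization median go to the low group; scan mode breaks
  p-value ties toward the smaller cutoff (`which.min`).
- Constant expression vectors make ranking undefined: `signature_score()`
  warns and returns the tie-forced mid-percentile; `correlate_with_score()`
  skips such genes and lists them.
- Agglomeration ties are resolved by `stats::hclust`'s deterministic
  ordering; partitions are additionally stabilized by size-ordered
  relabeling.
- An empty gene universe, an empty effective geneset, one-group log-rank
  input, and all-equal scores are errors, not silent results.

## A worked run

```{r example, eval = FALSE}
cohort <- simulate_cohort(simulation_config(seed = 1))
run <- run_gc_pipeline(cohort)
run
#> <gc_run>
#>   universe: 2000 genes (0 excluded)
#>   selected GC genes: 100
#>   pan-tumor (breadth >= k): 32; single-tumor: 28; TGCT-only: 16
#>   embryonic-germline-specific: 25
#>   gene clusters: 27/23/22/16/12; tumor groups: 18/14/1
#>   correlated genes: 5 positive / 1 negative
#>   survival log-rank p: 0.0004406
#>   protein-validated among selected: 48
```

With the default margins the cascade recovers the 100 planted GC genes
exactly, the embryonic filter returns the 25 embryonic-only genes, and the
planted hazard ratio of 2 shows up as a small log-rank p on 132 tumor
samples. These numbers are recomputed — not asserted — by
`scripts/acceptance.R` and the test suite.

## Known limitations

- Real-data headline counts (672 selected genes, 89 embryonic-specific,
  201 protein-validated, ...) depend on specific consortium snapshots and
  are out of reach without those downloads; the package validates logic,
  not those totals.
- Gene-set enrichment, GO characterization of clusters, and cell-surface
  annotation are out of scope.
- The scan dichotomizer's p-value is intentionally left uncorrected (and
  labeled), mirroring the original figure's source; treat it as
  exploratory.
- Percentile diagnostics for thresholds are reported against the current
  universe but never used to re-derive the thresholds, which are
  authoritative constants.
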
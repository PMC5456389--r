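---
title: "Counting drug-induced differential expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting drug-induced differential expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistic

A drug-perturbation compendium supplies a probe-by-sample matrix of
natural-log fold changes (lnFC) of treated cell lines against matched
controls. A probe counts as *significantly up-regulated* in a sample when
its lnFC is strictly greater than 0.69 and *down-regulated* when strictly
below −0.69; the cutoffs are ln 2 rounded to two decimals, i.e. a two-fold
change either way, and boundary values are not events. The number of
samples in which a probe (or, after aggregation, a gene) crosses the cutoff
is its **differential expression number** (DEN), computed separately for
the up and down directions. Genes are then ranked by each directional DEN
and split into the frequently regulated top 15% (`up_h`, `down_h`) and the
remaining 85% (`up_l`, `down_l`); the 15% cutoff reflects the observed
shape of DEN distributions, which are heavy-tailed ("power-law-like"): most
genes respond to few treatments while a small set responds to very many.

The package then asks how the frequently regulated genes differ from the
rest: chromosomal clustering (pairwise midpoint distances within a set),
tissue expression specificity (TES, the largest expression value of a
profile divided by its sum across tissues: 1/T for a uniform profile over T
tissues, 1 for single-tissue expression), earliest expression stage (EES,
seven ordinal stages from embryoid body to adult), homologous gene number,
phyletic age, SNP density (SNPs in the genomic span per bp), disease-SNP
fraction, protein-interaction degree, and subcellular localization.

```{r}
library(denfreq)
fcm <- readFoldChangeMatrix("matrix.tsv")
counts <- countRegulation(fcm, denThresholds())        # 0.69 / -0.69
genes <- aggregateToGenes(counts, readProbeGeneMap("probe_map.tsv"))
partitionGenes(genes, "up", fraction = 0.15)
```

## Statistical comparisons

Group comparisons follow the tests conventional for each data type:
Mann-Whitney rank-sum for numeric features (distances, TES, homolog
number, degree), Pearson chi-squared (without continuity correction) for
categorical and ordinal tables (EES, phyletic age, subcellular classes,
per-chromosome disease-SNP fractions), two-sample Kolmogorov-Smirnov for
SNP density, Fisher's exact test for the overall disease-SNP 2×2 table,
Spearman correlation (p from the t approximation with n−2 df) for the
DEN-versus-feature trends, and the Wilcoxon signed-rank test for the
paired per-chromosome up-versus-down comparison — the only paired context
in the suite. Headline inference uses raw p-values; a Benjamini-Hochberg
column is always emitted alongside for transparency.

Numerical conventions that matter:

* Rank-sum and signed-rank switch to exact enumeration when the pooled (or
  nonzero-pair) size is at most 12 and there are no ties; beyond that the
  normal approximation with tie and continuity corrections is used. The
  switchover keeps the exact path small enough to verify against full
  enumeration while bounding runtime.
* Reported p-values are never 0: a vanishing p is floored at the smallest
  representable positive double and flagged `p_floor`.
* All rankings (partitions, top/last-N sets) order by count descending
  with ties broken by gene identifier ascending in the C locale, so a
  partition listing is byte-identical across platforms, locales and runs;
  `k = floor(fraction × N)` fixes the high-set size exactly.
* Probe-to-gene aggregation defaults to `max` — a gene is regulated as
  often as its most responsive probe — with `sum` and `mean` (rounded
  half-up) available. The choice matters only for multi-probe genes.
* Missing matrix cells are non-events, not errors; a sparse compendium
  column simply contributes fewer opportunities to every count.

### Why the pipeline's distance comparison uses a matched pairing

The natural reading of "compare chromosomal distances between gene sets by
a rank-sum test" enumerates all same-chromosome pairs in each set. Those
distances are not independent draws: two pairs sharing a gene are
positively correlated, and a U-statistic variance-inflation argument shows
the rank-sum test on all pairs is anti-conservative under the null — its
nominal p-values reject far too often even when high and low sets are
exchangeable. `chromPairDistances()` still implements the all-pairs
enumeration (with seeded uniform subsampling above `maxPairs`), but
`runFullAnalysis()` defaults to `distancePairing = "matched"`: a seeded
random gene-disjoint matching per chromosome (each gene in at most one
pair), which makes the distances independent and keeps the rank-sum test
calibrated while preserving the clustering signal. The all-pairs variant
remains available via `distancePairing = "all"` for descriptive use.

## Coordinate conventions

Internally every locus and variant lives in a `GRanges` — 1-based, closed
intervals, the single convention of the GenomicRanges stack. BED input is
converted on read (`start + 1`), GFF3 and VCF import natively, and
`width()` equals the BED length, so a BED record `chr1 100 200` becomes
`[101, 200]` with length 100 and a variant "at 0-based position `end`"
falls outside the span, exactly as in half-open arithmetic. Genes with
several records on one chromosome are merged to the spanning interval;
records on different chromosomes keep only the chromosome with the longest
span (with a warning) — the gene span, introns included, is also the
denominator of SNP density. Strand is read but never used. Disease-SNP
status requires a dbSNP identifier and at least one clinical-significance
label outside the exclusion set (protective, benign, likely benign,
uncertain significance, conflicting data from submitters, other, not
provided); labels are normalized to lower case with underscores before
matching because public exports vary in case and separators. Subcellular
classes use the four GO cellular-component terms directly annotated to a
gene (extracellular region GO:0005576, membrane GO:0016020, cytoplasm
GO:0005737, nucleus GO:0005634), with `NOT`-qualified annotations ignored
and no ontology-graph propagation — a deliberate choice that keeps the
classifier self-contained; a propagated annotation table can be supplied
in GAF form instead.

## The synthetic-data generator

Real compendium data cannot ship with the package, so every statistical
claim is exercised on synthetic data whose structure mirrors the analysis
assumptions:

* **Propensities.** Each gene draws an up- and a down-regulation
  propensity from a heavy-tailed law (default pareto(α = 1.5), lognormal
  available), rescaled into (0, 0.5) by the law's theoretical 99.9th
  percentile with the extreme tail saturating at 0.5. The scale is a fixed
  constant of the law, *not* a sample statistic: dividing by, say, the
  sample maximum would couple every gene in a dataset through one draw and
  induce a spurious dataset-level up-versus-down asymmetry that a paired
  test correctly — but unhelpfully — detects. Under the default law the
  top 15% of genes hold the majority of the total DEN, reproducing the
  heavy-tailed shape that motivates the 15% cutoff.
* **Events.** Regulation events are drawn once per gene × sample (a single
  uniform decides up / down / background), so the expected gene-level DEN
  is `nSamples × propensity`; all probes of a gene share its events and
  differ only in magnitudes, which makes the `max` aggregation policy
  exact. Background cells are drawn strictly inside the open threshold
  interval, so thresholding is never ambiguous at this scale.
* **Planted effects.** Features link to the *normalized propensity* `z` —
  van der Waerden normal scores of the propensity ranks, bounded even for
  heavy-tailed laws — through standard link functions: logit-linear for
  the dominant-tissue share behind TES and for the per-SNP disease
  probability, log-linear for the Poisson SNP rate, the expected
  interaction degree (a fixed-edge-count fitness random graph) and the
  negative-binomial homolog mean, and a proportional-odds shift for EES.
  Positional clustering contracts the spread of high-`z` genes around a
  per-chromosome center. Every link reduces exactly to the null when its
  effect size is 0, and effects are planted on propensity rather than
  realized DEN so recovery tests face realistic sampling noise. Subcellular
  class and phyletic age carry no planted link and act as always-null axes;
  each gene gets exactly one class so the class-by-group table is
  multinomial.
* **Baseline rates** are desk-scale choices a practitioner would call
  realistic: 100 treated samples, 79 tissues, 20 chromosomes of 100 Mb,
  gene spans lognormal around 20 kb, about 100 SNPs per typical span
  (conservative relative to dbSNP, and large enough that per-chromosome
  contingency cells stay in the regime where the chi-squared approximation
  is trustworthy, as they are for genome-scale data), 5% baseline
  disease-SNP probability, mean network degree 6.

What the generator does **not** emulate: real drugs, cell lines or batch
structure; probe chemistry and probe-level measurement error; correlated
co-regulation of gene modules; a real GO graph; linkage between SNPs.
Passing tests therefore demonstrate that the pipeline's statistics are
calibrated and its effects recoverable under the stated generative
assumptions — not that any particular biological conclusion transfers to a
specific compendium.

## Validation design

The test suite validates three layers, at problem sizes chosen to finish
comfortably on one CPU:

1. **Oracle equivalence.** Counting matches an explicit double loop on 100
   random matrices up to 50 × 100; each exact test matches its independent
   enumeration oracle (all rank assignments, all sign patterns, all tables
   with fixed margins, direct Σ(O−E)²/E, an ECDF sweep, rank-then-Pearson)
   to 1e-10 on 200 random small instances per procedure.
2. **Calibration.** On 500 null datasets (1000 genes, all effects 0) the
   rejection rate at α = 0.05 is computed *per test procedure*, pooling
   comparisons of the same type; each pooled rate must lie in
   [0.03, 0.07]. Pooling is a deliberate design choice: a single
   comparison's rate estimated from 500 replicates has a binomial standard
   error near 0.01, so banding ~60 individual comparisons at ±0.02 would
   fail with high probability even for an exactly calibrated suite,
   whereas pooled estimates have the precision the band implies.
3. **Recovery.** With unit effect sizes and 2000 genes, each of the seven
   planted associations (TES up/down, degree up/down, clustering,
   disease-SNP fraction, homolog number) must be detected with the planted
   direction at raw p < 0.05 in at least 95 of 100 seeds.

## Known limitations

* The paired per-chromosome up-versus-down comparison is offered with the
  signed-rank test by default; on real data the choice between paired and
  unpaired readings of a "Wilcoxon test" is ambiguous, and both are
  exposed.
* Chi-squared results on tables with any expected cell below 5 are flagged
  `low_expected` rather than suppressed; at genome scale the flag should
  never fire, but small custom gene sets can trigger it.
* TES is undefined (NA) for genes with all-zero profiles, and multi-record
  expression rows are averaged per tissue with negative values clipped at
  zero before scoring.
* The identifier space is opaque text; no translation between probe,
  symbol and database identifiers is attempted.
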
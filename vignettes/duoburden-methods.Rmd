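---
title: "Rare-variant candidate-gene burden analysis in mother-infant duos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant candidate-gene burden analysis in mother-infant duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoburden)
```

## The analysis problem

Most infant leukemia carries an *MLL* (*KMT2A*) rearrangement and strikingly
few somatic mutations; the *MLL*-negative cases are rarer still and largely
unexplained. One hypothesis is that such infants are born with an excess of
rare, functional germline variation concentrated in genes already known to
acquire somatic mutations in leukemia, so that fewer somatic events are
needed to complete transformation. Testing this requires non-tumor DNA from
the child, a way to tell inherited from non-inherited variation, and a
statistical comparison against candidate gene sets.

duoburden implements that analysis for the *duo* design: exomes of affected
infants and their mothers (no fathers), plus unaffected pediatric controls.
The pipeline is

1. **Filtering** — reduce each exome's called variants to rare,
   non-synonymous, predicted-deleterious candidates;
2. **Enrichment** — test whether a group's variant genes over-represent a
   candidate gene set (exact hypergeometric tail and permutation nulls);
3. **Duo analysis** — label each infant variant maternal or non-maternal and
   call compound-heterozygous genes;
4. **Ranking/reporting** — gene-by-individual variability matrices, top-gene
   rankings, and a gene-size correlation check;
5. **Simulation** — a synthetic duo-cohort generator with full ground truth,
   so every stage is testable without any sequencing data.

## The filtering cascade

`filter_thresholds()` holds the cascade's knobs. Defaults, with units:

| stage | rule | default |
|---|---|---|
| allele depth | reads supporting the alt allele, inclusive | ≥ 5 |
| position depth | total reads at the site, inclusive | ≥ 10 |
| genotype quality | phred-scaled GQ, inclusive | ≥ 10 |
| mapping quality | caller MQ, inclusive | ≥ 60 |
| consequence | retained classes | non-synonymous SNV, stop gain/loss, frameshift and in-frame indels, splice site |
| rarity | population MAF, strict | < 0.01 in every panel with data |
| deleteriousness | prediction votes | ≥ 1 algorithm (`any_vote`) |

Decisions worth spelling out:

* **Missing metrics fail.** A variant whose `AD` field is absent has an
  unknowable allele fraction; treating the per-allele floor as a hard
  requirement, it is dropped rather than assumed adequate.
* **Rarity is strict `<`**: a variant at exactly 1% is not rare. Absence
  from all panels counts as rare (a never-observed allele cannot be common).
* **Two rarity modes.** `all_panels` (default) removes a variant that any
  panel shows at ≥ 1% — the conservative reading when filtering against
  multiple databases; `any_panel` keeps it if one panel is below the cutoff.
  Both are exposed because "rare in either database" is genuinely ambiguous
  in common usage.
* **Vote combination.** Deleteriousness predictors disagree; `any_vote`
  (default) maximizes sensitivity, with `majority_vote` and `all_votes`
  selectable. A variant with no prediction at all passes — the filter
  removes *predicted-benign* variants, not unannotated ones.
* The cascade is idempotent and its stage counts are non-increasing by
  construction; both properties are tested.

## Enrichment testing

The group-level statistic is the **aggregate** overlap: the number of
distinct genes carrying ≥ 1 retained variant across the group's samples that
are also on the candidate list. Per-sample testing is possible with the same
functions but the aggregate is the primary statistic.

`hypergeometric_upper_tail(k, K, n, N)` computes `P[X ≥ k]` for
`X ~ Hypergeometric(N, K, n)` as an explicit log-space sum of
`C(K,j) C(N-K,n-j) / C(N,n)` — the one-sided Fisher's exact test. Enrichment,
not depletion, is the hypothesis, so only the upper tail is taken. The
implementation is validated against literal subset enumeration (every
`C(N,n)` subset counted) and against `phyper` at `1e-12`.

`permutation_enrichment()` offers two null schemes over the exome gene
universe:

* `resample_variant_genes`: draw as many genes as the group's variant-gene
  universe, record the overlap with the candidate set — "could this many
  candidate genes be variant by chance, given how many genes are variant?";
* `random_gene_lists`: draw a random candidate-sized list, record its
  overlap with the variant genes — "is this specific list special?".

Both draw **without replacement** (gene lists are sets). Under either scheme
the null overlap is exactly hypergeometric, which gives a closed-form
convergence oracle: at 200 000 iterations the empirical pmf must sit within
±0.005 of the analytic pmf pointwise. The empirical p-value is
`(r + 1) / (n_iterations + 1)`, never zero; a result more extreme than every
permutation reports `1/(n_iterations + 1)`. Default `n_iterations` is
100 000 and the default significance level is α = 0.005 — deliberately
stringent for testing a small number of pre-registered gene sets, making
multiple-testing correction across sets unnecessary (and out of scope).

**The sampling frame is explicit.** The exome gene universe (genes with ≥ 1
callable position) is a required input rather than something inferred,
because the analysis is only as honest as its frame; it is recorded in the
run manifest.

### Rate ratios and what they estimate

`enrichment_rate_ratio(a, b, c, d) = (a/b)/(c/d)` is deliberately a bare
formula; the scientific meaning comes from what is fed in.

* Feeding *candidate / total* counts per group reproduces the descriptive
  "cases are X times more likely" number computable from published per-exome
  averages. Note a subtlety: if candidate genes truly carry an enrichment
  factor *f* and make up a fraction *c* of the variant mass, the case total
  is itself inflated and this ratio converges to `f / (1 + c(f-1))`, not
  *f*.
* For **parameter recovery** the package therefore uses *candidate /
  non-candidate* counts (an odds-type ratio), which identifies *f* exactly.
  This is the estimator used in the recovery validation and
  `scripts/acceptance.R`'s `recovered_candidate_enrichment_multiplier`.

`bootstrap_rate_ratio()` resamples *samples* (not variants), respecting the
exome as the sampling unit, and builds the interval on the **log scale**
(`estimate × exp(±z·sd(log ratios))`): ratios at 10–25 samples per group are
right-skewed enough that plain percentile intervals under-cover.

On the published per-exome averages themselves: the AML computation
`(163.4/2549.9)/(27.5/582.8) = 1.36` rounds to the reported 1.4, but the
analogous ALL computation `(12.1/1264.4)/(1.9/582.8) = 2.94` does **not**
reproduce the reported 2.0. The exact derivation behind that figure is not
recoverable from the printed tables; the package implements the stated
formula and reports what it computes.

## Duo analysis

`attribute_origin()` labels an infant variant **maternal** iff its identity
key — `(chrom, pos, ref, alt)` after stripping `chr`, trimming shared allele
suffix/prefix, and adjusting position — occurs among the mother's retained
variants. Matching is presence-based: genotype (het/hom) is ignored because
buccal-derived calls at modest per-allele depth do not support confident
zygosity, and the downstream rule only needs presence. With no father
sequenced, *non-maternal* conflates paternal transmission and de novo
mutation; de novo rates (~1 coding mutation per exome) are far too low to
account for group-level differences, so non-maternal is effectively a
paternal-side label in aggregate.

`detect_compound_het()` calls a gene when an infant carries **≥ 2 retained
variants at distinct sites** in it, **≥ 1 maternal and ≥ 1 non-maternal**.
This is an unphased surrogate for a true trans configuration: one allele
demonstrably from the mother plus one demonstrably not present in her is
the strongest phase evidence a duo can give. It is stated prominently that
this is *not* read-backed or pedigree phasing; two non-maternal variants
(possibly cis on the paternal haplotype) never qualify. The "distinct
sites" clause is an explicit assumption: the same key observed twice is one
allele, not two.

Variants annotated to several overlapping genes count toward each gene
independently, consistent with per-gene duplication at ingest; gene-level
counting is the unit of every downstream statistic.

## Ranking and the gene-size check

`rank_top_genes()` orders genes breadth-first: individuals affected
(descending), then total variant count (descending), then symbol. Breadth
before depth matches what a recurrence heatmap is for — a gene variant in
most individuals matters more than one with many variants in a single
person. The order is total, hence permutation-stable. Mothers are displayed
on the infants' ranking (matched-row layout), not re-ranked.

`gene_size_correlation()` is the OLS R² of per-gene variant counts on coding
length — the sanity check that an apparent candidate-gene excess is not a
gene-size artefact (big genes collect more variants of every kind).
Zero-variance counts define R² = 0; fewer than 3 modeled genes or fewer
than 2 distinct lengths is an error, not a silent 0. Which length measure
to use (coding length here) is a choice the gene-model file makes explicit.

## The synthetic cohort generator

`simulate_cohort()` emulates the post-annotation variant tables the pipeline
consumes, never reads or alignments. Default design, chosen to mirror the
duo-study conditions the analysis targets:

* 12 ALL duos, 13 AML duos, 12 unaffected controls;
* 2 000 genes with log-normal coding lengths (meanlog 7.2, sdlog 0.6 —
  median ≈ 1.3 kb), 5% flagged candidates, independent of length;
* per-gene variant counts Poisson with mean
  `length_kb × baseline_rate × multiplier`, baseline 0.1/kb, multiplier 2.0
  on candidate genes in infants and 1.5 in mothers (mothers enriched "to a
  lesser degree"), 1 elsewhere;
* each infant variant is maternal with probability 0.5; transmitted
  variants appear **verbatim** (same key, same annotation) in the mother's
  table;
* planted compound heterozygotes: two genes in every AML infant (one
  candidate, one not) and one candidate gene in half the ALL infants;
* quality noise: position depth ≈ Poisson(43), allele fraction 0.5, GQ
  high; a configurable fraction of variants is forced to fail each quality
  stage (5%/3%/5%/4%) so every filter demonstrably bites;
* 15% of variants are "common decoys" with panel AF drawn on [0.01, 0.5];
  rare variants are absent from a panel with probability 0.7, otherwise
  AF ~ U(0, 0.01); 5% carry no deleteriousness prediction and 30% of
  predicted ones are benign.

Poisson-by-length is the minimal generative model that reproduces a weak
count/size correlation once rates vary by gene class. Coordinates are one
pseudo-chromosome with a 100 kb block per gene — only identity keys matter
downstream. Transmitted copies and planted variants are drawn with clean
(passing) quality: their presence *is* the ground truth under test, while
forced failures model assay noise on the background. When two samples
independently draw the same key, annotation columns are harmonized to one
canonical row per key (planted keys take priority), keeping annotations a
property of the variant rather than the sample.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: linkage and haplotype structure, batch- or
sample-correlated sequencing artifacts, realistic site-frequency spectra,
population stratification, candidate lists curated with a length bias, or
mosaicism. The generator validates the *machinery* (calibration, parameter
recovery, exactness of deterministic rules), not biological conclusions.

## Validation design and problem sizes

The test suite validates, among others:

* hypergeometric tail vs literal subset enumeration (all universes ≤ 8) and
  an exact counting oracle (all parameter combinations with N ≤ 25, 1e-12);
* permutation convergence at 200 000 iterations against the closed form;
* type-I calibration: 2 000 null cohorts (all multipliers 1.0) at 1 000
  permutation iterations each; the rejection count at α = 0.005 must fall in
  the exact binomial 95% acceptance region. Permutation p-values from the
  `(r+1)/(n+1)` convention are conservative under discreteness, which the
  binomial interval tolerates;
* parameter recovery: 200 cohorts cycling planted multipliers 1.5/3/5 at
  study-scale group sizes; bootstrap 95% CIs must cover the planted value in
  ≥ 90% of replicates;
* compound-het exactness: calls equal a brute-force three-clause oracle and
  recover every planted assignment on 100 random cohorts.

These sizes (4-duo null cohorts, 500-gene recovery cohorts, 1 000-iteration
nulls inside the calibration loop) are scaled to keep the full validation in
minutes while leaving each check statistically sharp; the convergence and
enumeration checks run at full resolution.

## Known limitations

* Compound-het calls are unphased surrogates; a maternal + non-maternal
  pair can still be cis if the "non-maternal" variant is a genotyping
  dropout in the mother. Deeper maternal coverage reduces, but cannot
  eliminate, this.
* Indel normalization trims shared allele prefixes/suffixes but cannot
  left-align through reference context (no reference genome is consumed);
  callers that emit unnormalized, context-shifted indels may defeat
  mother-infant matching.
* Panel versions for allele frequencies are whatever the annotation table
  carried; the package records panel columns as-is and does not pin
  database releases.
* The permutation schemes sample genes uniformly; gene-length-weighted
  nulls would be a natural extension and are intentionally out of scope.
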
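---
title: "Comparative variant analysis across small cohorts and continental panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative variant analysis across small cohorts and continental panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxpop)
```

## The problem

Pharmacogenetic variation is badly characterized in small, genetically
distinctive populations. When a panel of drug-pathway genes — here, 18
genes of the glucocorticoid pathway relevant to acute lymphoblastic
leukemia therapy — is exome-typed in two small Amazonian indigenous
cohorts (5 patients, 59 disease-free individuals) the natural questions
are comparative: which variants are private to these cohorts? At which
variants do their allele frequencies depart from the 1000 Genomes
continental panels (AFR, AMR, EAS, EUR, SAS)? And how far do the cohorts'
overall genetic profiles diverge from those panels?

`pgxpop` implements that comparative pipeline as reusable, tested
components. Because cohort-level exome genotypes of this kind are
restricted, the package also ships (i) a multi-population genotype
simulator, so that every stage can be exercised offline under known truth,
and (ii) transcriptions of the reference result tables for the
glucocorticoid-pathway panel (`load_study_table()`), which anchor the
deterministic stages (impact reconciliation, exclusivity logic, the
reporting rule, pairwise-PERMANOVA consistency).

## Impact classification and annotation summaries

Variant consequences live in a closed eleven-category vocabulary
(`consequence_categories()`), mapped to the four SnpEff-style severity
tiers by `classify_impact()`: stop gains and protein structural
interaction loci are High; non-synonymous coding changes Moderate;
synonymous, splice-region+intron and next-protein changes Low; intronic,
intragenic and UTR changes Modifier. The placement of "protein structural
interaction locus" in High is fixed by reconciling the reference panel's
two marginals: its six High calls can only be 1 stop gain + 5 structural
interaction loci, after which Moderate (38 + 1 = 39), Low (40 + 8 + 2 =
50) and Modifier (8 + 134 + 9 + 7 = 158) reconcile exactly.

```{r impact}
t1 <- load_study_table("table1")
cons <- t1[t1$dimension == "consequence", ]
tapply(cons$count, classify_impact(cons$category), sum)
```

`summarize_annotations()` tabulates a panel by mutation type, region,
consequence and derived impact. Percentages are rounded half-up to one
decimal. That convention is a deliberate choice: the packaged reference
summary is not internally consistent in its own rounding (134/253 prints
as 52.9, yet 27/253 prints as 10.7 and 50/253 as 19.8), and half-up
reproduces 16 of its 19 printed percentages — more than any alternative
single rule. The three discordant cells are treated as rendering slips in
the source table, not as a rule to emulate.

## Exclusive variants and inclusion filtering

`find_exclusive_variants()` reports a variant as exclusive to a target
cohort when its alternate-allele count is positive there and zero — with
at least one called allele — in every reference panel. Panels with zero
called alleles at a variant make it *unassessable* rather than exclusive;
a variant may be exclusive to several cohorts but is counted once in the
deduplicated union. On the packaged records this yields 9 + 5 listings and
a union of 13 distinct sites.

`apply_inclusion_filters()` encodes the upstream screening rule: a
genotype call is trusted at ≥ 10 reads; a variant is retained when carried
by ≥ 10 individuals *or* when flagged novel. "Presence in at least 10
individuals" is read as a carrier count (at least one alternate allele),
not an allele count — presence is a property of individuals — and the
novelty clause is a true override (OR), since reference-exclusive records
with frequencies near one carrier could only have survived selection that
way. Both readings are configurable in `selection_criteria()`.

## Standardized frequency contrasts

Allele frequencies are obtained by allele counting over called genotypes
only (`allele_frequency()`); missing genotypes shrink the denominator, so
a cohort of 59 individuals may legitimately present, say, 84 called
alleles at one variant. To compare cohorts of wildly unequal size, each
frequency is standardized to a fixed allele total — 118, the disease-free
reference cohort's allele count — as integer "yes"/"no" counts
(`standardize_counts()`; yes = round-half-up(af × 118)). Both sides of
every contrast pass through the same formula.

Each standardized 2×2 table gets a two-sided Fisher exact p
(`fisher_exact_two_sided()`): with margins fixed, the sum of
hypergeometric probabilities of all tables no more probable than the
observed one, with a 1e-7 relative tolerance guarding floating-point ties
— the convention of mainstream exact-test implementations. Multiplicity is
handled by Hochberg's step-up procedure (`hochberg_adjust()`, via
`stats::p.adjust`), by default within each variant across its six
comparisons; a `global` scope is available since the original correction
scope is ambiguous. Direction signs are
sign(AF~reference~ − AF~comparator~).

The reporting rule (`select_reportable()`) forwards a variant when its p
falls below 0.05 in at least 3 of the 6 comparisons *and* its impact is
High or Moderate; raw p-values are thresholded by default (adjusted values
are emitted alongside, the source convention being unstated). Applied to
the packaged comparison matrix:

```{r reportable}
sel <- select_reportable(comparison_long(load_study_table("table3")))
table(sel$reportable$impact)
```

## Distance-based divergence

Population profiles (populations × variant frequencies,
`population_profile_matrix()`) feed classical Torgerson MDS
(`classical_mds()`, via `stats::cmdscale`): eigendecomposition of the
doubly centered squared-distance matrix, coordinates scaled by the square
roots of the nonnegative eigenvalues. Euclidean configurations are
reproduced exactly; requesting more dimensions than there are positive
eigenvalues truncates with a warning.

PERMANOVA (`permanova()`) partitions the total squared dissimilarity,
SS~total~ = (1/N)Σ~i<j~ d²~ij~, into within- and between-group parts and
forms the pseudo-F = (SS~between~/(a−1))/(SS~within~/(N−a)); significance
comes from uniform label permutations with the add-one estimator
p = (1 + #{F\* ≥ F})/(1 + B), so p ≥ 1/(B+1) always. The defaults are
B = 999 permutations and Euclidean distances on dosage vectors: the
reference pairwise results are mutually consistent with individual-level
analysis (F = R²(n−2)/(1−R²) at the cohort sizes reproduces every printed
F within the rounding of R²), so entities are samples for PERMANOVA while
MDS operates on the population-level profiles. `pairwise_permanova()`
runs each unordered pair on its distance sub-matrix and Hochberg-adjusts
across pairs. The repeated p = 0.006 in the reference table is not
derivable from any stated permutation count and is not targeted; the
package reports raw and adjusted permutation p-values.

Missing dosages are handled in the distance step by pairwise-complete
features with proportional rescaling (the `stats::dist` rule); Bray-Curtis
requires complete data.

## The simulator as study stand-in

`simulate_panel()` draws, per locus, an ancestral frequency Uniform(0.05,
0.95) — bounded away from 0/1 so monomorphic loci do not dominate — and
per-population frequencies from the Balding–Nichols Beta model
Beta(p(1−F)/F, (1−p)(1−F)/F), whose mean is p and variance F·p(1−p);
genotypes are Binomial(2, q) and each call is masked missing i.i.d. The
defaults are the study conditions: populations of 5, 59, 661, 347, 504,
503 and 489 individuals, 253 variants over the 18 pathway genes,
consequence labels drawn with the reference panel's category proportions,
F = 0.15 for the two indigenous cohorts and 0.10 for the continental
panels (global human F~ST~ is on the order of 0.10; small isolated
founder populations drift further), and a 2% missing-genotype rate
(typical exome call rates; the real data's variable per-variant
denominators imply missingness without documenting a mechanism). One
master seed drives fixed per-stage streams, so a fixed seed gives a
bit-identical panel.

What the generator deliberately does **not** model: linkage
disequilibrium, selection, demographic history, real site-frequency
spectra, or structured (non-random) missingness. Passing tests therefore
demonstrate the correctness of the *methods* under a neutral,
independent-locus null — not that real exomes satisfy those assumptions.
A Weir-style ratio-of-sums estimator (`estimate_fst()`) closes the loop:
over 1,000 simulated loci it recovers a configured F of 0.05–0.2 within
±0.02.

## Numerical and design choices

* **Rounding**: half-up everywhere a printed table is reproduced
  (`round_half_up()`); `base::round`'s banker's rounding would turn
  97.5/118 into 98 in some cells and 96 in others depending on parity.
* **Fisher ties**: tables whose probability is within 1e-7 (relative) of
  the observed table's count as "as extreme".
* **Permutation p**: add-one estimator; identical seeds give identical p,
  and two-group sub-analyses in `pairwise_permanova()` derive their
  streams deterministically from the master seed.
* **Degenerate inputs**: an empty annotation panel summarizes to zero
  counts with `NA` percentages; a variant with all genotypes missing is a
  counting error; reference panels with zero called alleles make a
  variant unassessable rather than silently exclusive; `validate_config()`
  returns machine-readable issue codes and never throws.
* **Problem sizes in the test suite**: the statistical guarantees are
  checked at deliberately modest scale — e.g. PERMANOVA size calibration
  with 500 replicate 20+20 panels at 199 permutations, Fisher enumeration
  on 200 random tables with margins up to 118 — sizes at which the
  binomial/Monte-Carlo error bounds used by the tests are already sharp.

## Orchestration

`run_analysis()` chains the stages — input (simulation or VCF + population
map + annotation TSV), annotation summary, allele frequencies, exclusive
variants, standardized comparison with the reporting rule, MDS, pairwise
PERMANOVA — writing one TSV per stage and returning a run report from
which the run is reconstructible. `inst/scripts/run_pipeline.R` wraps this
in a small command-line interface driven by a YAML configuration.

## Known limitations

The exact 131-variant outcome of the original inclusion filter, the
headline Fisher p-values and the PERMANOVA p-values depend on cohort
genotypes and per-population frequencies that were never released; those
quantities are covered here by logic-level reconstructions (the reporting
rule on the packaged p-value matrix, the F/R² consistency identity) and by
simulation-based calibration, not by value matching. The consequence →
impact mapping, while forced by the marginal reconciliation, is inferred
rather than documented upstream; `classify_impact()` errors loudly on any
category outside the closed set so that a mismatched vocabulary cannot be
classified silently.
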
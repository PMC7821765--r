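---
title: "Rare-variant prioritization and molecular burden in VT gene-panel cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant prioritization and molecular burden in VT gene-panel cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtburden)
```

## The analysis this package implements

Targeted panel sequencing of cardiac risk genes in patients with
ventricular tachycardia (VT) produces a few thousand called variants per
cohort, most of which are common polymorphisms with no plausible role in a
rare arrhythmia phenotype. The analytic chain implemented here takes such a
call set — cases split into coronary-heart-disease VT (CHD VT), dilated
cardiomyopathy VT (DCM VT) and idiopathic VT (iVT) arms, plus an unaffected
population control group — and produces the standard descriptive outputs of
a prioritization study:

1. **Filtering cascade** (`run_cascade()`): remove variants with an allele
   frequency above 0.5% in a removal database (ESP6500, 1000 Genomes) or
   with dbSNP130 membership; remove synonymous SNVs; subtract every variant
   observed in the control arm; apply an explicit curation exclusion list.
   Each stage is accounted for in a `FilterTrace` whose counts must satisfy
   `n_input = n_removed + n_kept`.
2. **Consensus pathogenicity class** (`consensus_class()`): ten in-silico
   predictors (SIFT, both PolyPhen-2 models, LRT, MutationTaster,
   MutationAssessor, FATHMM, RadialSVM, LR, MetaSVM) each call a variant
   damaging or tolerated; the count of damaging calls maps to an ordinal
   class — at least 7 is class I (highest pathogenic potential), 4–6 class
   II, 1–3 class III, 0 class IV (benign).
3. **ACMG/AMP five-tier verdict** (`acmg_combine()`): weighted evidence
   codes (PVS1; PS1–4; PM1–6; PP1–5; BA1; BS1–4; BP1–6) are combined by the
   2015 guideline rule table into pathogenic / likely pathogenic / VUS /
   likely benign / benign, with conflicting evidence collapsing to VUS.
4. **Molecular burden** (`burden_table()`): per case arm and per cumulative
   severity threshold (class I; I/II; I/II/III), the number and percentage
   of patients carrying at least one qualifying variant, the cumulative
   carried instances, and instances per positive patient.
5. **Functional-category and per-gene summaries**
   (`category_distribution()`, `gene_frequency_table()`,
   `hgmd_carrier_table()`): variants stratified over seven gene categories
   (cell membrane, cytoskeleton, sarcomere, metabolism, intercalated disc,
   ion flux, nucleus) and per-gene carrier frequencies, overall and
   restricted to HGMD-listed variants.
6. **Subgroup statistics** (`normality_gate()`,
   `kruskal_wallis_pairwise()`, `carrier_test()`): Shapiro–Wilk gate at
   p > 0.05, Kruskal–Wallis with Dunn pairwise post-hocs under Bonferroni
   correction for the clinical covariates, and chi-square / Fisher exact
   carrier tests under the expected-count-below-5 rule.

## Counting conventions

Two counting units coexist and are easy to conflate:

* **unique variants** — rows of the variant table (e.g. an analysis set of
  ~307 after filtering);
* **carried instances** — (patient, variant) pairs; a recurrent variant
  carried by five patients contributes five instances.

Burden tables count *instances* in their cumulative columns and *patients*
in their positivity columns; the "% of all variants" denominator is the
subgroup's total carried instances across all classes. The pooled
functional-category table counts unique variants. These conventions are the
only ones under which every published-style percentage cell is internally
consistent, and they are enforced by the brute-force recount oracles in the
test suite.

Zygosity is carried through the genotype table but never used by a
statistic: all burden quantities are carrier-based.

## Missing annotation semantics

A reference frequency that was never observed is stored as `NA`, not 0.
The rarity filter treats a variant absent from every removal database as
rare — absence cannot exceed a cutoff — and the comparison is
strict-greater (`> 0.005`), so "remove above 0.5%" and "keep at or below
0.5%" coincide. ExAC is not a removal database by default; it participates
only in the class-wise frequency averaging. This separation matters: a
surviving (rare-by-filter) class IV variant can still show an appreciable
mean frequency through ExAC, which is why the class-wise mean frequency can
rise to ~2% in the benign class while every removal-database value stays at
or below 0.5%.

Missing predictor calls count as not damaging; the class bands are keyed to
the absolute damaging count, and `n_available` is surfaced so analysts can
gate on predictor coverage. The alternative (renormalizing bands to the
available calls) would make the class of a variant with one damaging call
out of one available call jump from III to I on coverage grounds alone.

## The synthetic cohort generator

`simulate_cohort()` exists so every downstream stage can be exercised and
audited without access to patient-level sequencing data. Its defaults
encode the study conditions this package targets, chosen once from the
published cohort structure:

* subgroup sizes 23 (CHD VT), 32 (DCM VT), 37 (iVT), 60 controls;
* a 96-gene panel and a raw pool of 2,400 unique called variants;
* `frac_common = 0.79`, `frac_synonymous = 0.25`, `control_overlap = 0.19`
  — chosen so the expected analysis set after the cascade is ~306 unique
  variants (realized runs land around 305–350, slightly above the
  expectation because the control subtraction removes only variants
  actually *carried* by the simulated controls, not every variant flagged
  as control-observed; the same is true of a real study);
* latent class mix (48, 70, 156, 33)/307, the column sums of the
  pooled category-by-class table;
* per-subgroup, per-class Poisson carriage rates equal to published
  cumulative instance counts divided by subgroup size (e.g. 13/23 class I
  instances per CHD VT patient). Under Poisson carriage the implied
  fraction of class-I-positive CHD VT patients is
  `1 - exp(-13/23)` = 43.2%, reassuringly close to the published 43.5%;
* HGMD accessions on 61/307 of rare variants, with carriage sampling
  enriched toward HGMD variants at an odds ratio of ~2.35 — the value
  implied by HGMD variants being a fifth of unique variants but more than a
  third of carried instances. This makes HGMD-carrier fractions land in the
  published 75–87% range;
* clinical covariates: age, BMI, QRS and QT are normal with the published
  per-arm mean/SD; LVEF, LA diameter and LV end-diastolic/end-systolic
  dimensions are scaled-logistic with location at the published median and
  scale `IQR / (2 log 3)` so the quartiles match. The published tables
  report exactly these two parameterizations, and the logistic choice keeps
  the quartile match exact without asserting an unreported skew.
* class-conditional reference frequencies: a latent lognormal per-variant
  frequency with class-specific mean targeting the published class-wise
  averages (0.000279, 0.00267, 0.00372, 0.0192 for classes I–IV), realized
  per database with a presence probability that increases with class
  number. The generator guarantees the strict I < II < III < IV ordering of
  expected class means, which is the property the tests assert; the
  absolute levels are matched loosely, since they also depend on
  presence/absence patterns the source tables do not report.

The generator simulates the latent class *first* and predictor calls
*second* — the inverse of the analysis direction — so that ground truth
exists for recovery tests: the ledger's latent class always equals the
class recomputed from the simulated calls when no calls are missing.

What the generator does **not** emulate: linkage/haplotype structure,
per-gene variant density (uniform across the panel by default, with a
`gene_weights` hook), pedigree structure, sequencing depth or call quality,
and any correlation between clinical covariates and genotype. Passing tests
therefore demonstrate the correctness of the *bookkeeping and statistics*,
not fidelity of any biological claim about real cohorts.

## Numerical choices

* **Rounding** is half-up everywhere percentages are printed (one decimal;
  two for instances-per-positive-patient), matching every recomputable
  published cell (10/23 → 43.5); base R's round-half-to-even would print
  43.4 in some cells.
* **Fisher's exact test** is two-sided by point-probability summation (sum
  of all tables with point probability at most that of the observed one);
  two-sided Fisher definitions differ, and this is the convention of
  `stats::fisher.test`, verified in the tests against hypergeometric
  enumeration over all margins up to 12.
* **Dunn post-hocs** use the tie-corrected rank z statistic with Bonferroni
  adjustment `min(1, m p)` over all `m` unordered pairs — the default
  pairwise output of the clinical statistics software the field typically
  uses. Quartiles are type-6, for the same reason.
* **Kruskal–Wallis p** is the chi-square reference p of the tie-corrected H
  statistic. On tiny groups the chi-square reference deviates from the
  exact permutation distribution (for {1,2,3} vs {4,5,6} the chi-square p
  is 0.0495 while the exact permutation p is 2/20 = 0.1); the tests pin the
  H statistic to exhaustive enumeration and the p to the chi-square
  reference, and the type-I calibration at n = 20 per group verifies the
  approximation where it is actually used.
* **Degenerate inputs**: constant samples are rejected by the normality
  gate; zero-margin contingency tables are rejected; an empty class yields
  an undefined (`NA`) mean frequency, never 0; a subgroup with zero
  positive patients has undefined instances-per-positive.
* **Left-normalization** of indels trims the shared suffix then the shared
  prefix (keeping one base, shifting the position), which is sufficient for
  exonic panel indels; no liftover or multi-allelic decomposition is
  attempted.

## Open design points and how they were resolved

* The published cascade's manual-curation step (337 → 307) has no stated
  criteria; it is externalized as a reproducible exclusion-list argument,
  empty by default.
* Whether class bands should be computed over available tools for variants
  with missing predictor entries is unstated in the source material;
  absolute counts with missing-as-tolerated were chosen (see above).
* When an ingested ClinVar-style assertion and the locally combined ACMG
  verdict disagree, both are kept and the ingested assertion wins by
  default (`prefer = "ingested"`), matching the practice of treating
  curated database assertions as the final verdict.
* A published per-gene DCM carrier frequency of 34.3% is not attainable as
  k/32 (11/32 = 34.4%); the package reports the arithmetic value.
* One published category-table cell (sarcomere, class II, "18.3%")
  contradicts its own row counts (34/120 = 28.3%, and the printed row sums
  to 90%); the package reproduces the arithmetic value.

## Problem sizes used in the checks

The acceptance-style checks rebuild published tables from their printed
integer cells (seconds), enumerate all 1,024 call patterns and all ACMG
code subsets up to size four, enumerate Fisher tables with margins up to
12, calibrate the Kruskal–Wallis type-I error on 10,000 exchangeable-null
replicates at three groups of 20, and run 200 full cohort replicates at the
default configuration (2,400-variant pools, 92 cases + 60 controls) for the
carriage-rate and class-mix recovery study, comparing recovered means
within three Monte-Carlo standard errors.

## A minimal run

```{r example}
sim <- simulate_cohort(sim_config(seed = 1))
rep <- build_report(sim$cohort, sim$control_ids, seed = 1)
rep$trace[, c("stage", "n_input", "n_removed", "n_kept")]
rep$class_distribution
head(rep$burden)
```

## Limitations

The package is descriptive by design: it implements no gene-collapsing
association tests (SKAT or burden regression), no genotype–phenotype
modeling, and no liftover or annotation computation — predictor calls,
conservation scores and ACMG evidence codes are consumed as inputs, as they
come from an annotation pipeline. Conclusions about real cohorts require
the real annotation inputs; the synthetic generator only guarantees the
pipeline's arithmetic is right.
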
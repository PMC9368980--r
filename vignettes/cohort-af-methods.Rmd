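---
title: "Cohort-specific allele frequencies for variant and gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-specific allele frequencies for variant and gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortAF)
library(dplyr)
```

## The problem and the model

Clinical-exome sequencing of rare-disease patients accumulates genomic data
that is usually consulted one case at a time. `cohortAF` treats a
heterogeneous single-center cohort as a resource in aggregate: patients with
diseases *unrelated* to the disease under study act as **pseudocontrols**
(PC), on the premise that, a few causal mutations aside, the genome of a
Mendelian-disease patient behaves like that of the general population. The
package is written around inherited retinal dystrophies (IRD) as the disease
subcohort, with two companion strata — other eye-related diseases (OERD) and
non-eye-related diseases (NRD, the pseudocontrols) — but every subcohort is
just a metadata predicate (`subcohort_spec()`), so the same machinery applies
to any disease group.

From the merged multi-sample calls the package computes, per variant and
subcohort, the allele number AN (called alleles over covered samples), allele
count AC, allele frequency AF = AC/AN, and homozygote count. Coverage is
carried explicitly so that a site that is *not covered* in a sample is never
mistaken for *not mutated*; this is why `load_cohort()` requires a per-sample
depth table or callable intervals next to the VCF.

Five analyses sit on top of the frequency database:

1. **Variant prioritization (MFVs).** For each case subcohort the per-variant
   statistic is the log2 fold change of the case AF over the pseudocontrol
   AF. Variants above the 90th percentile of the log2(FC) distribution are
   the subcohort's *most frequent variants* (MFVs); variants with FC > 0 at
   or below the threshold are the non-prioritized comparison group. A
   one-sided Fisher exact test asks whether deleterious variants (ClinVar
   pathogenic/likely pathogenic, or CADD_PHRED ≥ 30) are over-represented
   among MFVs relative to benign variants (ClinVar benign/likely benign).
2. **VUS reclassification (PS4).** A variant of uncertain significance whose
   log2(FC) is at least 1.5 earns the ACMG criterion PS4 (prevalence in
   affected individuals significantly increased over controls); the evidence
   set is then recombined by the package's ACMG engine and a move from class
   3 to class 4/5 counts as a reclassification.
3. **Gene prioritization.** Per gene, the log2(FC) distributions of its
   deleterious and benign variants are compared by a one-sided Wilcoxon
   rank-sum test (deleterious stochastically greater); genes need at least
   five variants on each side, and p-values are Benjamini–Hochberg adjusted
   across tested genes.
4. **Carrier frequency.** For recessive genes, CF% = 200 · ΣAC / maxAN over
   the gene's pathogenic variant set in the pseudocontrols, where maxAN is
   the largest per-variant AN among the selected variants (AN varies by
   coverage, so a single gene-level AN does not exist). The
   dominant/X-linked analogue drops the ×2 factor for hemizygous counting.
5. **Relatedness QC**, run before any frequency is computed, so duplicates
   and relatives cannot inflate the database.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pi_hat_threshold` | 0.35 | pairs sharing more of the genome IBD are resolved by removal |
| `an_drop_fraction` | 0.05 | lowest-AN variant fraction dropped (quality filter) |
| `popbias_quantile` | 0.90 | percentile of abs. solved-vs-non-solved log2 FC above which a variant is a population-bias suspect |
| `mfv_quantile` | 0.90 | MFV selection percentile of the case-vs-PC log2 FC |
| `vus_fc_threshold` | 1.5 | minimum log2 FC for PS4 injection |
| `cadd_cutoff` | 30 | CADD_PHRED at/above which a variant is deleterious |
| `fdr_alpha` | 0.05 | gene-level FDR significance level |
| `cf_min_solved` | 3 | solved-case support required to report a carrier frequency |
| `min_depth` | 10 | depth at which a site counts as callable |

All of these are the framework's standard operating points except
`min_depth`, which is a package choice: callability must be defined somehow
when the input is a depth table, and 10× is the conventional floor for
reliable small-variant genotypes in clinical exome data.

## Numerical and procedural choices

* **Quantiles** are everywhere the type-7 definition (linear interpolation
  between order statistics, R's default), and MFV selection uses a strict
  `>` against the threshold; the VUS selection reuses a published threshold
  with `≥`. Both choices are asserted in the test suite.
* **Zero-AF fold changes.** When one side of a ratio has AC = 0, its AF is
  replaced by the half-count surrogate `0.5/AN`. This keeps every fold
  change finite and monotone in AC, and a variant absent from cases simply
  has no fold change (the percentile is computed over variants observed in
  the cases — an unobserved variant cannot be "most frequent").
* **Population-bias filter** uses the *absolute* log2 FC between solved and
  non-solved cases: a frequency distortion in either direction suggests a
  population-origin artifact. Suspect variants are rescued when both AFs are
  below 0.1, since a genuinely rare variant cannot be a common-ancestry
  marker. The quality (AN) filter runs first, then the population filter.
* **Tie-breaks** in the AN filter are deterministic on the lexicographic
  variant key, and the filter removes exactly `floor(0.05 · V)` variants; a
  warning flags a tie run straddling the cut.
* **IBD estimation** is the uncorrected method-of-moments solution from
  identity-by-state counts, with allele frequencies taken from the
  post-pruning cohort itself rather than an external reference. Negative
  state probabilities are clamped to zero and the triple renormalized, which
  is standard practice but gives the estimator a small positive bias for
  truly unrelated pairs (about 0.016 at 5000 SNPs); this is far from the
  0.35 action threshold. The small-sample bias correction used by some
  toolkits is omitted — it is O(1/N) in the cohort size and immaterial at
  the scales the package targets.
* **Related-pair resolution** removes the *minimum necessary* samples: the
  sample participating in the most flagged pairs is dropped repeatedly
  (ties on lexicographic id) until no pair remains. Removing both members of
  a duplicate pair would discard usable data for no QC gain.
* **Wilcoxon p-values** are exact by enumeration when the two sets total at
  most 12 values without ties, otherwise the normal approximation with
  midrank tie correction and continuity correction is used.
* **ACMG engine.** Evidence strengths derive from the code prefix, and the
  standard combining rules apply, with two deliberate modifications. First,
  benign *supporting* codes (BP) do not veto an otherwise met pathogenic
  combination — several curated profiles carry a BP4/BP1/BP6 alongside
  PM-level pathogenic evidence, and in-silico supporting evidence should
  not neutralize curated moderate/strong evidence; stand-alone or strong
  benign evidence still forces a conflict (class 3). Second, the exact set
  {PS4, PM2} — cohort enrichment plus population absence and nothing else —
  stays class 3. Strict rules would call it likely pathogenic, but both
  codes are frequency-type evidence, and promoting a variant on frequency
  signals alone is circular; at least one orthogonal criterion is required.
  A consequence worth stating: because {PS4, PM2} sits in class 3 while
  {PS4, PM2, BP4} satisfies the ordinary rules (class 4), adding a benign
  supporting code can formally raise the class across this one boundary.
  The monotonicity property holds everywhere else and is tested with that
  single exception carved out.

## The synthetic cohort generator

`simulate_cohort()` produces every input the pipeline reads: a multi-sample
call set with per-cell coverage, sample metadata (disease group, diagnostic
status, sub-phenotype, sex), disjoint gene panels with inheritance modes, a
per-variant annotation table (ClinVar, CADD_PHRED, consequence, LOVD), and a
curated-VUS table with prior ACMG codes. Genotypes are drawn per variant
under Hardy–Weinberg equilibrium at the variant's subcohort AF — the base AF
from a scaled beta distribution for rare variants, uniform 0.1–0.5 for the
common SNP block used by relatedness QC — independently across variants
unless the LD copula mode is enabled. Planted case-enriched variants
multiply the base AF in the disease subcohort; planted duplicates copy
genotypes exactly and parent–child pairs transmit one allele. The default
sample counts (955 + 811 disease cases, 386 other eye-related, 3531
non-related) mirror the clinical cohort the framework was built around;
gene-panel sizes and variants per gene default to a compact bundle
(20/30/50 genes × 10 variants plus 2000 common SNPs) that a laptop simulates
in seconds. The common-SNP default reflects what relatedness estimation
needs: at a few hundred SNPs the method-of-moments estimator is too noisy to
keep unrelated pairs safely below a 0.35 threshold, while at 2000–5000 SNPs
(the order of what LD pruning leaves genome-wide) it is well separated.

What the generator does *not* emulate: linkage disequilibrium outside the
optional copula blocks, population structure and ancestry gradients,
sequencing batch effects, genotyping error, and any correlation between a
variant's frequency and its pathogenicity labels. Tests passing on these
cohorts therefore demonstrate the statistical machinery — calibration under
the null, recovery of planted signal, correct arithmetic — not robustness to
the full messiness of real clinical exomes; the population-bias filter in
particular can only be exercised against synthetic distortions.

## Problem sizes used by the test suite

The statistical acceptance checks run on scaled-down but structurally
faithful cohorts chosen as the package's own test sizes: null calibration
uses 120 replicates of 30 genes × 40 variants (1200 variants) with 400 cases
and 1200 pseudocontrols; planted-signal recovery uses 20 replicates of 50
genes × 30 variants with 500 cases and 1500 pseudocontrols and an 8× AF
multiplier on 20 deleterious variants of one gene; relatedness checks use
5000 common SNPs over 50 unrelated samples plus 2 planted duplicates and 2
parent–child pairs. Under the null the expected fraction of genes passing
FDR < 0.05 stays at the nominal level, and with the planted effect the MFV
flag recovers ≥ 80% of planted variants while the planted gene reaches
FDR < 0.05 in ≥ 90% of replicates.

## Known limitations

* The pseudocontrol premise fails for variants pleiotropically associated
  with several of the cohort's diseases; such variants deflate their own
  fold change.
* Carrier frequencies count alleles, not persons (a homozygote contributes
  twice, a compound heterozygote in two selected variants twice); the
  printed formula is followed exactly, and a person-wise count would need
  genotype-level aggregation that the formula does not perform.
* Gene symbols are matched as exact case-sensitive strings; no alias
  resolution is attempted.
* Input VCFs are assumed normalized (left-aligned, parsimonious);
  multiallelic records are split here, but no realignment is performed.
* X-chromosome handling requires a `sex` column; without it males are
  treated as diploid and X-linked carrier frequencies fall back to the
  diploid convention with a warning.
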
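---
title: "Genotype-aware diagnostic filtering with curated gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware diagnostic filtering with curated gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g2pfilter)
```

## The problem and the model

Diagnostic sequencing of genetically heterogeneous Mendelian presentations
(severe developmental disorders, hereditary cancer susceptibility, …) must
reduce tens of thousands of coding variants per exome to a handful a
clinical scientist can review. The filtering model implemented here rests on
curated panel entries that attach a *disease mechanism* to every
gene–disease association:

* an **allelic requirement** — the genotype configuration the locus needs to
  cause disease: `monoallelic` (one altered allele suffices), `biallelic`
  (both alleles), `hemizygous` (single-copy X locus), plus rarer modes
  (X-linked dominant and over-dominance, imprinted, mosaic, mitochondrial,
  digenic, uncertain);
* a **mutation consequence** — the mechanism class of pathogenic variants:
  `loss_of_function`, `activating`, `dominant_negative`,
  `all_missense_in_frame`, `utr_mutation`, `cis_regulatory`,
  `increased_gene_dosage`, `uncertain`;
* a **confidence** level: `confirmed` and `probable` entries are reportable
  for diagnosis, `possible` entries are not, and `both_rd_and_if` entries
  are reportable with an incidental-finding flag.

A variant is a *valid candidate* for an entry when it lies on the canonical
transcript (configurable), its Sequence Ontology consequence class is
admissible for the entry's mechanism, and its maximum allele frequency
across all populated reference sources (1000 Genomes, ESP, gnomAD, UK10K,
TOPMed cohorts, …) is strictly below the cut-off for the entry's allelic
requirement. A *finding* is emitted per (sample, entry) with at least one
qualifying variant, and is *requirement-satisfied* when the observed
genotypes reach the required configuration. Crucially, reporting plausible
**genotypes** rather than plausible variants is what keeps reports short:
one rare heterozygote in a biallelic gene is not reportable, so carriers of
single recessive alleles never clutter the output.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `maf_monoallelic` | 1e-4 | allele frequency | dominant causative alleles of severe early-onset disease are kept below the 1-in-10,000 population frequency; comparison is strict `<` |
| `maf_biallelic` | 5e-3 | allele frequency | recessive alleles segregate at higher frequencies in carriers; cut-off kept configurable because curation practice varies |
| `canonical_only` | TRUE | — | one representative transcript per gene standardises consequence reporting |
| `require_sift_polyphen_concordance` | FALSE | — | missense sub-filter (SIFT deleterious **and** PolyPhen damaging); off in the engine, used by the stricter burden analyses |
| `min_gq`, `min_mq` | 13 | Phred | Phred 13 ⇒ error probability 10^−1.3, i.e. just under 95% confidence (`phred_to_confidence(13)` = `r round(phred_to_confidence(13), 4)`) |
| `min_dp` | 5 | reads | guards genotype calls in low-coverage exomes |
| `min_ad_ratio` | 0.2 | fraction | heterozygotes with alt fraction below 0.2 are likely artefacts |

A MAF cut-off of exactly 0 means "not seen in any control database": only
alleles absent from every reference source pass. The engine applies the
monoallelic cut-off to every single-allele-sufficient requirement
(`monoallelic`, `hemizygous`, X-linked modes, `imprinted`, `mosaic`) and —
because neither threshold is defined for them anywhere — also to the
requirements it cannot assess (`digenic`, `mitochondrial`, `uncertain`),
whose findings are always emitted `not_satisfied` with a reason rather than
silently dropped.

## Consequence classification

Classes are assigned most-severe-wins: `lof` (stop gained, frameshift,
essential splice site, start lost, transcript ablation) ≻ `missense` ≻
`inframe` (in-frame indel, stop lost) ≻ `splice_region` ≻ `other`. The LOF
term set and the admissible-class table are config-overridable because
curation pipelines differ on edge terms; in particular
`splice_region_variant` is kept in the default admissible set for
loss-of-function genes (removable via `allowed_class_overrides`).
Loss-of-function genes also admit predicted-deleterious missense and
in-frame variants — dominant-negative missense alleles in haploinsufficient
genes are a recognised mechanism, and the burden analyses need the missense
stratum in LOF genes. UTR, cis-regulatory and gene-dosage mechanisms are not
detectable from coding consequences; entries carrying them fail validity
with `unsupported_mechanism`.

## Genotype aggregation and its assumptions

Biallelic satisfaction by "two or more distinct heterozygous sites" asserts
only a *possible* compound heterozygote: without trio data or long reads,
phase is unknown and cis configurations cannot be excluded, which is the
dominant source of false positives at biallelic loci in proband-only
analyses. Hemizygous logic needs sample sex, which VCFs lack; an optional
PED table supplies it and unknown sex is treated permissively (a
heterozygous call may satisfy a hemizygous entry for female or unknown sex).
Where several transcript annotations of one gene pass, the canonical one
wins, else the most severe class, with ties broken by transcript identifier
so output is deterministic.

## Quality control

Genotype calls failing any of GQ/DP/allele-balance/MQ thresholds are reset
to no-calls before filtering; an absent field never fires its rule (some
joint-called cohorts carry no per-call MQ). Sample-level screening counts
extreme heterozygotes (alt fraction outside [0.15, 0.8]) and rare
homozygotes (reference AF < 0.01) and excludes samples beyond the cohort
mean + 3 SD (excess extreme hets) or below mean − 3 SD (rare-homozygote
deficit), in a single pass. The SD flavour is population SD (divide by *n*),
with sample SD available by flag; at realistic cohort sizes the difference
is negligible.

## Background noise and the case:control statistics

Applying any panel to a population unselected for the disease yields
qualifying variants — the expected false-positive burden of the panel. The
statistics module quantifies it: carrier-burden 2×2 tables per
(requirement × consequence class) stratum with sample odds ratios,
two-tailed Fisher exact p-values and approximate 95% CIs (log-OR normal
theory with the Haldane–Anscombe 0.5 correction on zero cells — exact
conditional CIs would be an alternative; the approximation matches common
plotting practice), per-gene carrier proportions with counts of genes
higher-in-control and absent-in-control, the fraction of unique missense
variants with CADD > 30, per-sample variant-count distributions (SNVs and
indels reported separately, zero-count samples included), and control/case
mean-MAF ratios. No multiple-testing correction is applied across genes;
the intended use is panel sanity-checking, not gene discovery.

## Evaluation framework

Scoring is at variant granularity (sample, chrom, pos, ref, alt) against a
truth set; true positives must appear among qualifying variants of
requirement-satisfied findings. Specificity and the classical
false-positive rate are only defined against a caller-supplied negative
universe — there is no silent default, because "all possible negatives" has
no natural definition for variant filtering. The MAF sweep reuses a single
filtering pass at the loosest cut-off and re-thresholds post hoc (valid
because the frequency rule is the only swept criterion), re-aggregating
genotypes at each point; tests verify each point equals an independent full
run. The swept cut-off applies uniformly to all allelic requirements, a
defined generalisation of the original monoallelic-genes-only sweep.
Gene ranking for comparison with other prioritisers orders findings by
requirement satisfaction, then consequence severity, then ascending MAF,
then gene symbol — a documented convention, since no canonical output order
exists.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` writes a decomposed, CSQ-annotated multi-sample VCF with
planted causative genotypes (heterozygous for monoallelic entries;
homozygous or two heterozygous sites, 50:50, for biallelic; hemizygous on X
in males), background variants in panel genes at a calibrated rate, a PED
sex table and a truth set. Defaults: 60 cases and 60 controls (large enough
for carrier-burden contrasts, small enough for test-suite runtimes),
planted fraction 0.9 (most but not all cases carry a detectable cause),
background rate 2.0 qualifying variants per sample after filtering (the
order observed in population controls), allele-frequency spectrum with 60%
mass at 0 (unseen alleles) and a log-uniform 10⁻⁶–10⁻³ tail so both arms of
every MAF cut-off are exercised, and a 10% rate of deliberately low-quality
calls that the QC resets must remove. The generator inflates its raw
Poisson draw by the analytic acceptance probability
(`background_acceptance_probability()`), so the post-filter mean is the
configured rate; tests check the calibration on 200 controls within three
standard errors.

Coordinates live on a toy contig set (two autosomes and X) because
consequences are asserted via CSQ, not recomputed from a reference. The
generator does **not** emulate linkage disequilibrium or haplotype
structure, shared variants between samples (each generated variant has one
carrier), indel realignment artefacts, population stratification, or
annotation errors. Passing tests therefore demonstrate the correctness of
the filtering logic and the calibration machinery — not performance on real
cohorts, where causative-variant spectra, background rates and annotation
quality differ.

## Numerical and degenerate-input choices

* Frequency comparisons are strict `<`; a cut-off of 0 admits only AF = 0.
* Written allele frequencies are frozen to six significant digits so the
  generator's in-memory account and the re-parsed VCF agree exactly.
* All seeded generation uses a local Mersenne–Twister stream and restores
  the caller's RNG state; identical configurations give byte-identical
  files.
* Zero-variance QC metrics exclude nobody; empty strata yield flagged
  `NA` ratios rather than 0; variants without CADD scores are excluded from
  both numerator and denominator of the high-CADD fraction.
* An all-zero margin makes the odds ratio undefined (flagged), not an error.
* Undecomposed records (multi-allelic ALT or allele indices above 1) are
  rejected with the record's coordinates — normalisation is upstream's job.

## Problem sizes used by the tests

The suite runs on seeded synthetic cohorts of 120 samples (≈370 records) for
the oracle-equivalence and sweep checks, 200 control samples for the
background calibration, and smaller noiseless cohorts for recovery tests;
Fisher-test equivalence is checked exhaustively over all 2×2 tables with
every cell ≤ 4 plus several hundred random tables with totals up to 60.

## Known limitations

Phase-unaware compound-heterozygote calls overreport at biallelic loci;
digenic, mitochondrial and uncertain requirements are reported but never
satisfied; structural variants, CNVs and non-coding mechanisms are out of
scope; trio/de novo logic is absent (proband-only analysis); HPO-based
phenotype matching is not implemented. Gene identity is keyed on the gene
symbol after trimming — HGNC/Ensembl cross-reference reconciliation is the
panel curator's responsibility.
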
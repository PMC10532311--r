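---
title: "Methods: family-based co-segregation filtering and genotype-stratified expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based co-segregation filtering and genotype-stratified expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The problem

In a pedigree where a quantitative phenotype — here, plasma levels of
coagulation factor VIII (FVIII:C) and von Willebrand factor antigen
(VWF:Ag), both expressed as percent of a normal pooled-plasma standard —
appears in two consecutive generations, a plausible working model is a
single dominant variant carried by all affected members. Whole-exome
sequencing of the family then turns candidate discovery into a
deterministic filtering problem: among all called variants, keep those
whose genotype pattern matches the inheritance model exactly, i.e.
heterozygous in every affected member ("case") and reference-homozygous in
every unaffected member ("control").

`famseg` implements this workflow end to end: phenotype-based
stratification, VCF quality control, the dominant-model co-segregation
filter run independently against two trait stratifications, descriptive
summaries of the surviving variants, and a genotype-stratified expression
stage that asks whether carriers of a candidate variant differ in
transcript or miRNA levels.

## Case/control stratification

Subjects carry repeated measurements of up to four traits (FVIII:C,
FVIII:Ag, VWF:Ag, VWF:RCo) taken at different visits. For classification a
subject's level is summarized by the **maximum** of the series: clinical
reporting of these traits characterizes a subject by the highest level
observed ("up to X%"), and under the max summary every case in the bundled
family table satisfies its design threshold. `summarize_level()` also
offers `first` and `mean` for sensitivity analysis, but `max` is the
default and the summary the rest of the package assumes.

Classification uses strict inequalities on both sides: case if the
summarized level is `> threshold`, control if `< threshold`. The
thresholds are 150% for FVIII:C and 180% for VWF:Ag — literature cut-offs
near the upper normal limits of the respective assays. A level exactly at
the threshold is neither case nor control; the subject is excluded with
reason `at-threshold` rather than silently assigned, because the
classification rule as stated has no equality arm. Subjects without any
measurement of the trait are excluded with `no-measurement`; subjects not
analyzed by WES are carried in the table (the expression stage can address
them) but never partitioned.

The two resulting designs differ by a single subject (III-5: FVIII:C 198%
but VWF:Ag 145%), which is what makes running the filter twice
informative: the FVIII design has 7 cases / 5 controls, the VWF design 6
cases / 6 controls, and a variant can co-segregate with at most one of the
two partitions in this pedigree.

## VCF quality control

Two QC layers run before filtering, both configurable via `qc_config()`:

* **Site level** — a site is removed when it is multi-allelic (REF + ALT
  allele count > 2; removed, not split, since a split record could not
  carry the original call semantics), when its FILTER is not `PASS`, or
  when QUAL < 30. A missing QUAL fails: quality that cannot be certified
  is treated as insufficient. Each removal records exactly one reason,
  assigned in the priority order multiallelic → non-pass → low-qual.
* **Genotype level** — an individual call is masked to missing when its
  read depth is < 10 **or** its genotype quality < 20 (default
  `genotype_rule = "or"`). The literal conjunction reading ("and") is
  available as a switch, but it would keep a depth-3 call with GQ 25,
  which contradicts the intent of certifying calls; the disjunctive rule
  is the default. Missing DP or GQ values (or wholly absent fields) are
  masked for the same cannot-certify reason. Half-calls and phased
  separators are normalized before classification.

All thresholds are *strict*: a site with QUAL exactly 30, or a call with
depth exactly 10 and GQ exactly 20, is kept. QC never edits alleles,
positions or sample identity, and it is idempotent — re-applying it to its
own output removes and masks nothing.

The "sequencing quality score" of the site rule is read as the VCF QUAL
field, distinct from the per-genotype FORMAT/GQ; coordinates are 1-based
and contig names are used verbatim.

## The dominant co-segregation filter

For one design, each post-QC variant receives exactly one reason code, in
priority order:

1. `incomplete-call-rate` — any case or control genotype missing
   (post-masking). The call-rate requirement is 100% over the active
   design's cases ∪ controls; "absent in controls" is *not* satisfied by
   an uncalled genotype.
2. `case-not-het` — some case is not heterozygous. A hom-alt case fails
   under the default `case_genotype = "het"`; the `carrier` switch
   accepts het-or-hom-alt for reuse in settings where the dominant allele
   may be homozygous.
3. `control-not-homref` — some control is not reference-homozygous.
4. `survivor` otherwise.

Sites removed by site QC are carried into the report with reason
`failed-site-qc`, so every input variant is accounted for exactly once.
Survivor keys include REF and ALT, so different alleles at one position
are distinct variants. `run_dual_analysis()` runs the filter
independently under both designs and reports the union of distinct
survivors.

## Survivor summaries

Survivors are joined to an annotation table by exact
`(chrom, pos, ref, alt)`; survivors without an annotation row are kept
with class `unannotated`. Summaries reproduce the descriptive statistics
used for candidate sets of this kind:

* **Frequency class** — `novel` when absent from dbSNP, `rare` when
  MAF < 1%, `low_frequency` when 1% ≤ MAF < 5%, `common` when MAF ≥ 5%.
  These are the conventional population-genetics bins, and they reproduce
  every printed label of the bundled annotation table, including the edge
  value MAF 0.054 (common).
* **Region span** — `round((max − min) / 1000)` Kb over one contig. The
  bundled candidate sets span 56 Kb (FVIII approach) and 8350 Kb (VWF
  approach); 8,349,965 bp rounds to 8350, which is why the package
  reports 8350 rather than the looser "~8300" sometimes quoted.
* **Gene loci** — distinct gene labels. A compound label naming a
  co-transcribed cluster with a shared promoter (here `MIR143/145`)
  counts as one locus; under that convention the 20 bundled candidates
  map to 12 loci.
* **Consequence histogram** — counts over the closed vocabulary
  `intronic`, `synonymous`, `missense`, `five_prime_utr`, `upstream`.

## Genotype-stratified expression

### Family scale: qPCR relative quantitation

With RNA from a handful of family members, expression is compared via
qPCR and the 2^−ΔΔCt method: replicate Cts (two duplicates per sample)
are averaged, each sample's ΔCt is target minus reference-gene Ct, the
calibrator is the mean ΔCt of the reference-homozygous group, and
RQ = 2^−(ΔCt − calibrator ΔCt). By construction the calibrator group has
geometric-mean RQ 1. `family_expression_report()` compares carrier vs
non-carrier RQs with a Student's t-test and reports the median direction
and a significance flag. At n = 3 vs 3 the comparison is descriptive:
with a slight true effect the test has little power, and the report is
expected to state a direction without statistical significance.

### Cohort scale: matrix testing

For a population cohort with genotypes and a feature × sample expression
matrix, `diff_expression()` applies per feature:

1. **Low-expression gate** — skip the feature when the mean of its
   *unnormalized* count row is < 7; testing normalized values whose raw
   support is that thin is not meaningful.
2. **Outlier exclusion** — single-pass Tukey fences
   `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` on the pooled (both genotype groups
   together) values, with quartiles by linear interpolation between order
   statistics (R `quantile` type 7). Pooled single-pass exclusion, rather
   than per group or iterated, matches how a single exclusion event with
   a per-group breakdown is reported; the quantile rule is stated because
   exclusion counts can shift by ±1 subject under other quantile
   conventions. The multiplier `k` is configurable.
3. **Normality gate and test** — Shapiro–Wilk on the pooled
   post-exclusion values (one normality decision per feature, not per
   group); if p < α the two-sided Mann–Whitney U is used (exact for
   small tie-free samples, normal approximation with continuity and tie
   correction otherwise), else a two-sided Student's t-test. Direction is
   the sign of the carrier-minus-reference median difference.

Shapiro–Wilk supports at most 5000 pooled values; the function refuses
larger inputs explicitly rather than silently switching tests. A
(near-)constant pooled sample has no meaningful normality p-value and
falls back to the rank test.

## The simulator

Because the family's raw WES data are not publicly deposited, the package
generates every input at desk scale; all generated fixtures are synthetic
and labelled as such.

`simulate_family_vcf()` builds a 12-member multi-sample VCF in which each
planted variant realizes the co-segregation pattern of its designated
design (het in all cases, hom-ref in all controls, DP ≥ 10, GQ ≥ 20,
PASS, QUAL ≥ 30), and each decoy violates **exactly one** rule:
`het_in_control`, `het_in_subset_of_cases`, `missing_genotype`,
`low_depth`, `low_gq`, `non_pass`, `multiallelic`, or `low_qual`. Decoys
are placed on the candidate contig within a configurable window around
the planted region (positions drawn without replacement, excluding
planted positions) so span statistics stay exercised; ref/alt are random
distinct single nucleotides.

Two constructions deserve a note:

* Variants designated for **both** designs cannot exist in this pedigree:
  III-5 would have to be het (as an FVIII case) and hom-ref (as a VWF
  control) simultaneously. Such variants are therefore generated with the
  VWF pattern (III-5 hom-ref) and necessarily fail the FVIII design —
  the two survivor sets are disjoint, as they must be in this family.
* A naive one-sample perturbation of one design's pattern can
  accidentally *realize the other design's survivor pattern* (perturbing
  exactly III-5). Pattern-class decoys are therefore re-drawn (bounded
  retries) until they fail both designs.

All randomness flows from the single config seed, and the VCF writer is
deterministic, so identical configs produce byte-identical files.

`simulate_expression_cohort()` draws reference-homozygous samples from a
Gaussian baseline and shifts carriers *down* by `effect_delta` (the
direction of interest is reduced expression in carriers), with group
sizes defaulting to 386 vs 35 — the post-exclusion group sizes of the
cohort-replication regime — and an optional Poisson raw-count matrix
feeding the low-expression gate. `simulate_family_qpcr()` generates
duplicate Cts for the six profiled members with a default carrier shift
of +0.5 cycles (RQ ratio ≈ 0.71, a "slight" reduction), between-subject
SD 0.3 and replicate SD 0.15 — chosen as realistic qPCR noise scales; at
these settings the carrier effect is ≈ 1.1 pooled-SD on ΔCt, so a 3 vs 3
t-test detects it rarely (power ≈ 0.15) while the sign of the median
difference is usually correct (≈ 0.9), which is exactly the qualitative
regime the family stage is meant to illustrate.

### What the simulation does and does not show

The generator emulates the *logical* structure of the study inputs —
genotype patterns, QC fields, group sizes, effect directions — not the
biology of real data: no linkage disequilibrium or haplotype structure,
no read-level errors (miscall rate is 0 unless decoys introduce it), no
covariate structure linking phenotype to genotype, and Gaussian/Poisson
noise instead of empirical expression distributions. Tests passing on
simulated data therefore validate the *filtering and testing machinery*
(sensitivity 1.0 and specificity 1.0 under clean patterns, calibration of
the statistical gates), not the biological claims one could only examine
on the real cohort.

## Problem sizes and numerical choices

The bundled analyses and tests run at the study's own scale: 12 WES
members, 20 planted candidates among 500 decoys, cohort groups of 386 vs
35. Monte-Carlo checks use 500 replicates for null calibration of the
two-group test and 200 replicates for power at a 3-SD effect and for the
family-stage tendency checks; at these sizes the expected Monte-Carlo
error is well inside the asserted bands. Ties in the rank test are
handled by the normal approximation with tie correction; exact
enumeration is used only for small tie-free samples. Quartiles use linear
interpolation (type 7) throughout.

## Known limitations

* The phenotype stage performs classification only; covariate modelling
  (age, BMI, blood group) is out of scope.
* The filter implements the dominant model only; recessive or X-linked
  patterns are rejected with a clear message rather than approximated.
* Annotation is consumed from a table, never computed: no consequence
  prediction, pathogenicity scoring or gene prioritization.
* The cohort stage consumes matrices as provided; no normalization or
  quantification is performed, and eQTL analysis beyond the single-variant
  two-group comparison is out of scope.
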
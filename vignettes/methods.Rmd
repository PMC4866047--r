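---
title: "Models and methods behind mutlandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutlandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mutlandscape re-implements, as a tested library, the analytical core of a
somatic mutation-landscape study of a large targeted-sequencing
breast-cancer cohort: bespoke variant filtering, ratiometric driver
discovery stratified by oestrogen-receptor (ER) status, cancer-cell-fraction
and clonality inference, intra-tumour heterogeneity scoring, association
screens, and breast-cancer-specific survival modelling. This vignette
records the models, the parameter choices, and the design decisions taken
where the method description left room.

## Variant filtering

Candidate calls arrive as per-sample rows with strand-resolved read counts
and a caller quality score; the package never re-calls variants. Filtering
is two-level: *generic* rules remove sequencing artefacts, *somatic* rules
remove germline signal and noise using external resources. All rules are
evaluated independently and their reason codes accumulate, so the audit
trail lists every violated rule and the pass/remove partition provably does
not depend on rule order (a property the test suite checks by permuting the
rule list).

SNV rules and defaults (`filter_thresholds()`):

* caller quality < 6.95 (strict);
* position inside the MUC16 tandem-repeat window
  chr19:8,955,441–9,044,530, where mucin repeats cause misalignment;
* caller flags `nearby_gap_events` or
  `poor_mapping_regional_alternate_allele_mapq`;
* read-direction bias: two-sided Fisher exact test on
  [[alt_fwd, alt_rev], [ref_fwd, ref_rev]], Benjamini–Hochberg across the
  cohort at FDR 10⁻⁴;
* VAF < 0.1 or depth < 10 (both strict) **unless** the variant is a
  confirmed-somatic COSMIC mutation — low-VAF hotspot mutations are real
  and would otherwise be lost;
* population alternate-allele frequency ≥ 1% (inclusive for SNVs);
* presence in the normal pool at VAF ≥ 0.1, **unless** the variant is seen
  in more than two COSMIC breast samples, in which case it is removed only
  when observed in > 5% of normal breast tissue or > 1% of blood — the
  stringent rescue protects recurrent somatic mutations from pool
  contamination.

Indels swap the quality floor for the caller's `LowQual` flag, use the
caller's Phred-scaled strand-bias score (≥ 40, inclusive), add overlap
rules for simple repeats, microsatellites and homopolymer runs of six or
more bases, and apply the population-frequency rule *strictly* (> 1%). The
SNV/indel boundary asymmetry (≥ 1% vs > 1%) follows the method statement
as written; whether it was intentional there is unknowable, so both are
implemented literally and exposed as configuration.

Boundary semantics throughout follow the stated glyphs: "< 6.95" strict,
"⩾ 40" inclusive, "smaller than 0.1" strict, "more than two" means ≥ 3.
Resource lookups are locus-level (chromosome, position): on a synthetic
genome with randomly assigned alleles, allele-level keys would add
bookkeeping without exercising different logic.

The germline-pathogenicity classifier is a two-route rule engine:
ClinVar (probable-)pathogenic with a germline-type origin, vetoed by a
population frequency above 1%; or, for variants absent from ClinVar but
seen in one to six normal samples, an inactivating consequence (or a
Provean deleterious call for missense SNVs; frame- or splice-disruption
for indels).

## Ratiometric driver discovery

For each gene, *recurrent* mutations are missense SNVs and in-frame indels
whose (first affected) codon is hit by at least two mutations across the
cohort stratum; *inactivating* mutations are nonsense, frameshift and
splice-site variants. The ONC and TSG scores are these counts divided by
the gene's total coding/splice mutation count; silent and noncoding
mutations are excluded from the denominator (read-through SNVs count in
the denominator but in neither numerator). Classification, with
thresholds inclusive ("at least 20%"):

* oncogene: ONC ≥ 0.2, TSG < 0.05, ≥ 5 recurrent mutations;
* tumour suppressor: TSG ≥ 0.2 with ≥ 5 inactivating mutations, or the
  TP53-like pattern ONC ≥ 0.2 and TSG ≥ 0.05 with ≥ 5 recurrent plus
  inactivating mutations;
* otherwise unclassified.

Scores are computed independently in the ER+ and ER− strata (recurrence is
counted within a stratum) and a gene is a Mut-driver if it qualifies in
either. *Functional* mutations are those contributing to the qualifying
score — recurrent for oncogenes, inactivating for tumour suppressors, both
for genes with the TP53 pattern — and drive the per-sample matrices used
by every downstream association and survival model. The minimum-events
rule uses the sum of recurrent and inactivating counts for the mixed
(TP53-like) branch and the class-specific count otherwise.

## Clonality, MATH and copy number

The cancer cell fraction inverts the expected allele fraction of a
mutation present on one copy in a fraction CCF of tumour cells:

$$\mathrm{CCF} = \mathrm{VAF} \cdot
  \frac{p\,CN_{tum} + (1-p)\,CN_{norm}}{p}, \qquad CN_{norm} = 2.$$

The VAF point estimate and its 95% interval come from the Wilson score
interval (the binomial-interval default of the toolchain this follows;
Clopper–Pearson is available), and the CCF transform is applied to the
point and both endpoints, capped at 1 — reported CCFs of 1 with interval
1–1 are meaningful. A mutation is *subclonal* iff its CCF interval lies
entirely below 1. Multiplicity is fixed at 1: the formula models one
mutated copy, which biases CCFs upward at high-amplification loci; this is
a documented limitation, not a switch the estimator can infer from one
VAF.

MATH is the scaled median absolute deviation (constant 1.4826) of a
tumour's VAFs divided by their median, computed over all mutations coding
and noncoding, with tumours under five mutations excluded. The score is
kept on the unit scale because the downstream quartile comparisons are
scale-free; the ×100 convention of the original heterogeneity literature
is a switch. MATH is exactly scale-invariant in the VAFs.

Gene-level CNA calls take the longest-overlapping segment per gene:
amplification is a total of 5+ copies, homozygous deletion a total of 0,
and LOH a minor copy number of 0 with at least one copy remaining
(irrespective of total). The chromosomal-instability score divides each
segment's total by tumour ploidy, takes log₂, and counts segment length as
altered when the ratio is ≥ 0.4 or ≤ −0.5 (totals of zero always count as
loss); the score is the altered fraction of covered genome.

## ER/HER2 assignment

Expression of the marker gene (ESR1 for ER; the identical operation with
ERBB2 for HER2) is fit with a two-component Gaussian mixture with unequal
variances; the higher-mean component is "positive". The fit uses the
model-based EM of mclust, whose hierarchical initialisation is
deterministic — chosen over a k-means-seeded EM because it removes seed
sensitivity while fitting the same model class. Samples take the component
with the higher posterior (a posterior of exactly 0.5 goes to the
higher-mean component — the method's tie behaviour is unstated, and the
higher-mean default avoids guessing). Where IHC exists and disagrees with
the mixture, expression wins only when the posterior of the
opposite-of-IHC component is at least 5× that of the IHC component;
posterior probabilities, not densities, are compared. IHC remains the
default because it is the clinical gold standard. Fits require at least 20
expressed samples and reject constant expression as degenerate.

## Survival models

BCSS treats breast-cancer death as the event; deaths from other or unknown
causes are censored at death, everyone else at last contact. Covariates
follow the minimum-common-data coding: age ≥ 55, size ≥ 50 mm, nodal
status, and grade 3 vs 1–2 (three-level grade is a switch — the stated
coding does not pin grade's level structure). Cox models use Efron tie
handling (the method is silent; Efron is the better approximation and the
exact option remains available) with Wald intervals, complete-case per
model. The subtype-interaction design fits a single model with mutation,
membership and their product, and reports the three interpretable
contrasts — mutation outside the cluster, membership among wild-type,
mutation-and-membership versus neither — plus the Wald p of the
interaction; exactly those three terms are fitted, since the design is
described as univariable-with-interaction. The MATH analysis compares
Kaplan–Meier curves of the lower- and upper-quartile tumours by log-rank
test.

Degenerate inputs are flagged, not fitted: constant mutation indicators
and under-10-event models are errors; interaction strata with fewer than
five mutant or wild-type members in the cluster return a flagged result;
possible monotone likelihoods are flagged with diagnostics.

## The synthetic cohort

The generator (`cohort_config()` defaults) emulates the study conditions:
2,433 tumours, ~650-sample normal pool, negative-binomial depth with mean
150 (median near 152×), 76% ER+, a gene panel with hotspot-driven
oncogenes and truncation-dominated tumour suppressors at realistic
per-stratum frequencies, per-gene log hazard ratios, exponential
baseline survival with independent censoring, and artefact injection
(sub-threshold quality, MUC16 hits, caller flags, extreme strand bias,
low-VAF noise, common polymorphisms, normal-pool hits, and the COSMIC
rescue cases) at rates giving every filter positive and negative cases.
Purity is Beta(8, 2.5) (mean 0.76) and 90% of mutations are clonal with a
Uniform(0.1, 0.9) subclonal tail: these two values were calibrated once so
the declared filter operating characteristics (≥ 95% sensitivity for true
somatic calls, ≥ 95% artefact removal at default thresholds) hold — at
lower purity, subclonal mutations necessarily fall below the VAF floor, a
real behaviour of the filter worth remembering when interpreting it on
low-purity cohorts.

What the generator does *not* emulate: read-level errors (simulation is at
called-variant granularity), mutational signatures, copy-number structure
within chromosomes (one segment per chromosome), subclonal copy number,
multiplicity above one, and correlated mutation co-occurrence. Passing
tests therefore demonstrate the pipeline's statistical behaviour under its
own assumptions, not robustness to every artefact of real data.

Problem sizes in tests and the acceptance script are deliberate choices
balancing statistical resolution against turnaround: 200–300 tumours for
end-to-end and filter checks, 1,000 tumours × 20 seeds for driver
recovery (driver rate 0.10 per stratum, satisfying the ≥ 20 mutations per
gene precondition in the smaller ER− stratum; passenger rate 0.01,
matching the < 1% frequency of typical non-driver genes), n = 2,000 × 50
replicates for Cox coverage, 200 seeds for interaction type-I error.

## Numerical and statistical conventions

* Intervals are 1-based inclusive in files (MAF/ASCAT convention),
  half-open internally, so abutting segments do not overlap.
* The Wilson interval is computed in closed form and cross-checked in the
  tests against an independent route (`prop.test` without continuity
  correction).
* The CCF-recovery criterion is on the error of the *mean* estimate
  across simulated mutations: the per-mutation absolute deviation has a
  binomial noise floor (≈ 0.033 at CCF 0.8, depth 1,000) that no unbiased
  estimator can beat, so a per-mutation MAE bound below it would be
  unattainable by construction.
* Exact 2×2 p-values are the conditional two-sided sums (probabilities no
  larger than the observed table's); the tests verify them against a
  brute-force hypergeometric enumeration over all tables with n ≤ 25.
* Odds ratios are sample odds ratios, 0/∞ at empty cells; conditional
  maximum-likelihood ORs with exact intervals are available but printed
  exact-style intervals from other implementations are not treated as
  reference values.
* Multiple testing is Benjamini–Hochberg everywhere an FDR level is named.
* The IntClust enrichment default FDR is 0.01 (the stricter of the two
  levels the source material uses in different places), configurable.

## Known limitations

* Multiplicity-1 CCFs understate clonality at amplified loci.
* The strand-bias FDR is computed within the cohort analysed; filtering a
  single sample in isolation changes the BH denominator.
* The logistic and Cox screens are complete-case; with covariate
  missingness above a few percent, estimates shift toward the observed
  subpopulation.
* The pairwise exclusivity screen is the plain Fisher design — it does not
  correct for per-sample mutation burden the way permutation-based
  exclusivity tests do.
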
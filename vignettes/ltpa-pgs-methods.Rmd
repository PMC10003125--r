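---
title: "Methods: optimized count scores for leisure-time physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimized count scores for leisure-time physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical content of `ltpaPGS`: the models
and procedures, the assumptions behind them, the choices made where the
design was genuinely open, and what the simulation-based tests do and do
not demonstrate about real cohorts.

## The analysis in one paragraph

A small panel of candidate SNPs — each oriented so that its *effect
allele* is the one thought to promote leisure-time physical activity —
is genotyped in two populations. After panel QC (within-population
Hardy–Weinberg tests with exclusion, pairwise linkage disequilibrium,
between-population allele-frequency comparison with power), each SNP is
tested for association with four binary LTPA outcomes by logistic
regression adjusted for seven covariates. A forward procedure then
builds an *optimized polygenic score* (oPGS): the unweighted sum of
effect-allele counts over a greedily selected SNP subset. Individuals
are binned into four ordered predisposition categories on the score, and
a Jonckheere–Terpstra test asks whether activity volume (MET-min/week)
and frequency (days/week) rise monotonically across categories.

## Logistic association

`fit_logistic()` maximizes the Bernoulli likelihood by IRLS
(`stats::glm.fit`, convergence tolerance 1e-12, up to 100 iterations)
and returns the inverse observed information as the coefficient
covariance. Wald 95% CIs and p-values match the convention of
mainstream statistical packages for this design. Three defects are
surfaced as errors rather than numbers: rank-deficient designs,
constant non-intercept columns, and separation. Separation is declared
when any |coefficient| exceeds 15, the fit is numerically perfect
(log-likelihood above −1e−6), the score gradient norm stays above 1e−6,
or IRLS fails to converge; with a seven-SNP panel of common alleles,
separation indicates a data pathology worth inspecting, so no penalized
fallback is attempted. The gradient threshold of 1e−6 (rather than
something stricter) accommodates covariates kept on their natural
scales — waist circumference in cm multiplies gradient components by
~95.

Model fit is summarized by the Cox–Snell pseudo-R²,
`1 − exp(2(LL₀ − LL₁)/n)` against the intercept-only model, which is
the quantity the optimization procedure monitors.

The adjusted covariate set is fixed: age (years), sex (0/1), ethnicity
(0/1, second population), education coded ordinally 0/1/2 for
primary/secondary/higher, vehicle use (0/1), BMI (kg/m²), waist (cm).
The ordinal education coding is the simplest monotone choice; the
source tables report three levels without specifying a contrast.

## Score optimization

Candidates are ordered by ascending adjusted single-SNP p-value on the
combined two-population sample; ties break by larger |log OR|, then
lexical id. The first candidate is always accepted — the procedure
starts from the strongest SNP, with no significance gate. Each later
candidate is added to the scoring set tentatively; the trial score is
refitted, and the SNP is kept only if the p-value *strictly* falls and
R² *strictly* rises relative to the **best model so far** (not the
immediately preceding trial — with a greedy procedure the two coincide
except after a rejection, and comparing to the best-so-far is the
reading under which "strengthening the score's association" is
monotone). Equality on either criterion is a rejection.

Two properties follow by construction and are regression-tested: the
accepted trajectory is deterministic in its inputs, and every accepted
step improves both criteria. Under a fully null panel the joint
criterion is conservative — adding noise to a count score dilutes the
per-point effect, so acceptances beyond the first SNP are rare.

Effect-allele orientation is metadata, never re-estimated from data; a
fitted per-allele OR below 1 for a declared effect allele is worth a
warning in QC review but does not flip the coding.

## Score categories

Scores are small integers (0..2K for K SNPs), so categories are built
on integer values, not quantiles: starting from one bin per distinct
value, the extreme bin with the smaller count merges inward until the
target of four bins is reached, then any bin holding less than 10% of
individuals keeps merging inward (dropping below four bins with a
warning only if forced). On a uniform score over 0..5 this produces
0–1 / 2 / 3 / 4–5, which is also the grouping pattern reported in the
motivating study — one reason the integer-merge rule was chosen over
quantile cuts, which on discrete scores produce unstable, duplicated
boundaries. Ties in the merge rule resolve toward the lower tail.

## Trend and rank statistics

The Jonckheere–Terpstra statistic is the sum over ordered group pairs
of Mann–Whitney counts, ties half-weighted. For total n ≤ 20 (and at
most 200,000 distinct label arrangements) the exact permutation null is
fully enumerated; the two-sided p is twice the smaller tail, capped at
1. Beyond that gate the tie-corrected normal approximation is used
without continuity correction; its accuracy was checked worst-case over
the entire null support: for untied layouts with every group ≥ 3 it
stays within 0.02 of the exact mid-p. Groups of size 2 have null atoms
larger than that — no continuous approximation can track them, which is
exactly why the small-sample path enumerates. The arrangement cap
exists because three or more groups at n = 20 can exceed 10⁸
arrangements; every small-sample layout arising in practice (and in the
test suite) enumerates exactly.

Mann–Whitney follows the same logic: exact via the closed-form rank-sum
distribution when untied, exact via enumeration when tied and small,
normal approximation otherwise.

`templeton_normalize()` is the rank-based two-step transform used when
a Shapiro–Wilk gate (α = 0.05) rejects normality before mean/CI
reporting: fractional ranks to percentiles by the Hazen position
(r − ½)/n — which keeps percentiles strictly inside (0,1) and shares
mid-ranks across ties — then the inverse normal CDF, rescaled to the
input mean and SD. The trend tests themselves are rank-based and always
use raw values. Group means are reported with normal-approximation 95%
CIs (mean ± 1.96 SE) on the analyzed scale; the CI method in the source
tables is not stated, and this is the least-assumptive default.

Bonferroni correction divides α by the number of SNPs retained in the
oPGS (the independent polymorphisms actually tested downstream); the
displayed threshold rounds to three decimals (0.05/3 → 0.017) while
flagging uses the unrounded value.

Trend tables are produced both including zeros for non-participants and
restricted to participants. The including-zeros variant is the default
headline: the motivating study's trend-table group sizes sum to the
full genotyped sample, implying zeros were included there.

## Panel QC

* **HWE**: 1-df Pearson χ² of observed genotype counts against
  p², 2pq, q² at the estimated allele frequency — the test named in the
  source methods (an exact test would differ only at rare alleles).
  Exclusion at p < 0.05 in either population, configurable; monomorphic
  SNPs are flagged, reported, and never excluded on HWE grounds
  (no valid expectation exists).
* **LD**: two-locus haplotype frequencies by EM over unphased
  genotypes. Only double heterozygotes are phase-ambiguous; the E-step
  splits them between coupling and repulsion by current haplotype
  products. Equilibrium start, tolerance 1e−8 on haplotype frequencies,
  max 1000 iterations; a fully ambiguous degenerate sample stays at the
  equilibrium solution (D = 0), a deterministic tie-break. D′ uses the
  standard Dmax, r² = D²/(pA qA pB qB); pairs with r² ≥ 0.8 are flagged
  as linked (the threshold is a package choice — the study reports a
  conclusion, not a cutoff).
* **Frequency difference**: Pearson χ² on the 2×2 allele-count table
  (2n alleles per group), no continuity correction.
* **Power**: two-sided normal approximation for a difference of two
  proportions on allele counts with unpooled variance, calibrated
  against simulation in the tests; the online estimator used by the
  study does not document its internals, so a transparent standard
  formula is preferable to guessing at one.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions under which everything else is validated:

* two populations of 330 and 314 adults aged 20–64 (truncated-normal
  ages, mean 44/43, SD 11.5);
* seven candidate SNPs with population-specific effect-allele
  frequencies, in Hardy–Weinberg proportions within each population
  (genotype = sum of two Bernoulli draws); four SNPs
  (rs10252228, rs12612420, rs459465, rs10887741) are given clearly
  divergent frequencies, mirroring the reported between-population
  differences. The appendix frequencies of the motivating study are not
  printed anywhere, so the defaults are the package's own realistic
  choices; the three score SNPs' frequencies are set so the expected
  unweighted 3-SNP scores sit near 2.7 and 2.2;
* covariates with the reported structure: male share 0.44/0.25,
  education heavily shifted toward primary in population 2
  (0.20/0.61/0.19 vs 0.88/0.115/0.005), vehicle use 0.74/0.25, BMI
  ~27 (SD 5, truncated 15–60), waist ~95–96 cm (SD 13, truncated
  50–200);
* logistic outcome models per LTPA category with per-allele log-ORs of
  log(1.48), log(1.29), log(1.25) for the three causal SNPs on the
  general outcome (small effects, OR ≈ 1.2–1.5) and null effects for
  the rest; covariate coefficients act on centred scales (age − 42,
  BMI − 27, waist − 95) so intercepts are interpretable prevalence
  anchors;
* MET-min/week conditional on participation is log-normal (meanlog
  7.0/6.3/6.0/5.6 by outcome, sdlog ≈ 1) — right-skewed with the
  correct support, which is what makes the normality gate and the
  two-step transform exercise realistically; days/week is
  binomial(7, mean/7). Both are exactly zero for non-participants.
* no LD between SNPs by default (the motivating panel showed none); a
  separate phased two-locus generator (`simulate_linked_pair()`) exists
  solely to test the EM estimator against known haplotype truth;
* an inbreeding-style option (per population or per SNP) produces
  heterozygote-deficient genotypes to exercise the HWE exclusion path.

Seeding: one master seed; each stage (genotypes per population,
covariates per population, phenotypes) draws from a child seed
`(master × 10007 + stage) mod (2³¹ − 1)`, so a stage is reproducible in
isolation. Identical config + seed gives byte-identical output files.

**What the generator does not emulate** — and therefore what passing
tests do not establish about real data: the four binary outcomes are
simulated independently, so the logical nesting of "LTPA in general"
over its intensity categories (and the additivity of their MET values)
is not enforced; there is no household/colony sampling structure, no
genotyping error or missingness process (missing genotypes must be
injected explicitly), no linkage between panel SNPs by default, and
ancestry is reduced to per-population allele frequencies. Calibration
and recovery results under these conditions show the estimators are
correct, not that any particular real-world cohort meets their
assumptions.

## Problem sizes in the validation suite

The test suite validates: oracle equivalence (1000 random HWE triples
to 1e−9, 1000 logistic cross-product tables to 1e−6, exact rank-test
enumerations up to n = 12), null calibration of all four tests at
2000 replicates × n = 500 (band 0.05 ± 3·SE), parameter recovery of a
per-allele OR 1.5 at n = 20,000 (±0.05) with 95% CI coverage over 1000
fits at n = 2000, forward-selection sensitivity (a single causal OR-1.5
SNP among six nulls recovered in ≥ 90% of 200 replicates at n = 2000),
EM haplotype recovery at n = 5000 within 3 Monte-Carlo SEs, and
byte-identical end-to-end reruns at the full study size (330 + 314).
These sizes give Monte-Carlo bands tight enough to detect calibration
errors of a percentage point or two while the whole suite completes in
a couple of minutes.

## Known limitations

* Unweighted counts only; no beta-weighted or penalized scores.
* No Firth or penalized logistic fallback under separation.
* Dominance/recessive codings, interactions, and gene–environment
  terms are out of scope, as in the motivating design.
* The forward procedure is greedy and order-dependent by design; it
  reproduces the published selection behavior rather than optimizing
  over subsets.
* Two populations at most in the QC comparison path.
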
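---
title: "Methods: single-cohort characterization of kidney-function loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cohort characterization of kidney-function loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfrloci)
```

## Scope and model

`gfrloci` re-examines established kidney-function loci in a single
population cohort. The outcome throughout is the natural log of eGFRcrea,
the glomerular filtration rate estimated from serum creatinine with the
2009 CKD-EPI equation, winsorized at 15 and 200 ml/min/1.73m&sup2; before
the log. Creatinine is first cleaned of laboratory drift: instrument-level
mean shifts are removed as fixed effects, and participation-period shifts
are removed after shrinkage toward zero. The published workflow used a
`lme4` mixed model for this step; `normalize_scr()` instead applies a
method-of-moments variance-component shrinkage
(shift times tau&sup2;/(tau&sup2; + s&sup2;/n~j~)), which performs the same
first-moment correction without a mixed-model dependency. Periods with
fewer than two observations contribute no shift, and the grand mean is
preserved.

All association models are ordinary least squares adjusted for age, sex,
the first ten genetic principal components, and an intercept. A
kinship-adjusted mixed model (the usual safeguard in family-structured
cohorts) is deliberately not implemented: in the setting this package
models, PC-adjusted linear models are substantially equivalent, and the
synthetic cohorts the package generates contain no relatedness at all.
This is the package's single intentional methodological substitution.

### Locus re-association

Because a small cohort can show large, even sign-flipped, effect
fluctuations relative to a large meta-analysis, re-testing uses one-sided
tests in the direction reported by the meta-analysis after allele
harmonization (`one_sided_p()`); a wrong-direction estimate yields
p &gt; 0.5 rather than being mirrored. Loci are declared significant when
any variant in strong LD with the lead (squared dosage correlation
r&sup2; &gt; 0.8, strictly) and cohort MAF &ge; 0.005 passes the
Bonferroni family level 0.05/147 &asymp; 0.00034. The effective-test
rationale is checked by `effective_test_coverage()`: the fraction of the
variant correlation matrix's total variance carried by its top-k
eigenvalues (the absolute Pearson correlation spectrum is used; whether
the original analysis signed it is not documented, and the choice only
matters in the presence of systematic negative LD). Genomic control
lambda is the median association chi-square over 0.4549364. Lambda is a
meaningful null diagnostic only over a predominantly null variant set; on
a targeted panel of true loci it is inflated by construction, so the
calibration check in the test suite computes it over null simulations.

### Allele harmonization

Cohort dosages are flipped (2 &minus; d) when the cohort's counted allele
is the meta-analysis other allele. Strand-ambiguous A/T and C/G variants
cannot be oriented by alleles alone: they are frequency-matched when the
MAF is informative and dropped when MAF &isin; [0.4, 0.5], standard
harmonization practice. A dosage file that carries no allele labels is
used as-is.

### Cohort versus meta-analysis

`meta_subtract()` removes the cohort's contribution from fixed-effect
inverse-variance summary statistics by weight subtraction; it is the
exact algebraic inverse of two-study inverse-variance meta-analysis (a
property test holds it to 1e-12 relative error). Lambda-correction
options found in full meta-subtraction software are omitted: for effect
comparison at a handful of loci the plain algebra is sufficient, and a
sample-size-weighted z-score mode (`meta_subtract_z()`) covers inputs
without SEs. Variance explained per variant is the approximation
b&sup2;&middot;2p(1&minus;p)/var(y), with var(y) the variance of the age-
and sex-adjusted ln(eGFRcrea).

### Mediation screen

For each (variant, trait) pair, `run_four_steps()` fits the four
classical mediation regressions (total effect; trait-adjusted effect;
SNP&ndash;trait; SNP&ndash;trait adjusted for the outcome), each on its own
complete cases &mdash; per-trait sample sizes legitimately differ and no
imputation is attempted. Traits are rank-based inverse-normal transformed
(Blom offset (r&minus;3/8)/(n+1/4), average ranks for ties) before the
screen; when a trait carries an instrument annotation the transform is
applied within instrument strata, since its purpose is protection against
instrument effects. The exact quantile-normalization dialect of the
original workflow is not reproduced in its main text, so the Blom
inverse-normal transform &mdash; the most common choice in genetic
epidemiology &mdash; is the documented default.

A trait qualifies as at least a partial mediator when (i) the adjusted
SNP effect b&#8322; is an outlier of the panel of b&#8322; values across
all traits under the stringent Tukey rule &mdash; outside
[P&#8321;&#8320; &minus; 1.5 IQR, P&#8329;&#8320; + 1.5 IQR] with
IQR = P&#8327;&#8325; &minus; P&#8322;&#8325; &mdash; and (ii) the SNP
associates with the trait at 0.05/(70 traits &times; 11 loci) = 6.5e-5.
Percentiles use type-7 linear interpolation (R's default; the rule's
source does not state a type, and the choice moves the fences by at most
one within-panel gap). The tested value is included in its own panel,
matching "the distribution across all traits". Because the fences hang
off P10/P90 rather than P25/P75, they contain the classic Tukey fences:
the flag set is a subset of classic Tukey flags, which is what makes the
rule stringent. Percent change 100(b&#8322;&minus;b&#8321;)/b&#8321; is
displayed rounded to integers; internal values keep full precision. The
step-3 threshold is applied per test, as printed, without aggregating
multi-variant loci.

### Thyroid-function interaction

After removing individuals with thyroid cancer, kidney cancer, goiter,
thyroid surgery, or jointly missing TSH and therapy information, the
continuous model regresses ln(eGFRcrea) on dosage, TSH, their product and
the step-1 covariates; the product-term t-test is invariant to TSH
centering. TSH enters untransformed by default (`log_tsh = TRUE` is
available but off, since the tested exposure is quantitative TSH).
Thyroid status is hyperthyroid when TSH &lt; 0.4 uUI/mL or an antithyroid
drug is used, hypothyroid when TSH &gt; 3.8 uUI/mL or levothyroxine is
used; inequalities are strict, so values exactly at a threshold are
normal, and medication dominates the measured level. Categorical
interaction uses pairwise contrasts against the normal category (fitting
each contrast on the two categories involved) rather than a three-level
factor; the pairwise form keeps each contrast's null distribution exact
and skips empty strata cleanly. The interaction significance level is
0.05/11 loci. Two sensitivity checks are provided: a two-sided Wilcoxon
rank-sum comparison of dosages between individuals with and without
measured FT3/FT4 (exact for small samples without ties, normal
approximation with continuity correction otherwise, via
`stats::wilcox.test`), and municipality adjustment of the step-1 model.
The signed interaction coefficient is reported as estimated; the package
takes no position on the direction of effect modification.

## Synthetic cohorts and what they do (not) emulate

`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, with known ground truth for recovery tests.

* **Genotypes.** The lead variant is drawn under Hardy-Weinberg
  equilibrium (two Bernoulli(maf) haplotypes). Proxies use haplotype
  copy-with-mutation: each proxy haplotype copies the lead allele with
  probability q = &radic;r&sup2; and otherwise redraws Bernoulli(maf).
  This keeps dosages integer, columns HWE-consistent, allele frequencies
  equal, and realizes pairwise r&sup2; &asymp; q&sup2; &mdash; a Gaussian
  thresholding scheme would not preserve the first two properties.
* **Outcome.** ln(eGFRcrea) = 4.867 &minus; 0.007&middot;age +
  0.01&middot;male + &Sigma; &beta;&middot;SNP + mediator contributions +
  &gamma;&middot;SNP&middot;(TSH &minus; mean) + N(0, 0.16). The intercept
  and residual SD reproduce a median eGFRcrea near 92 ml/min/1.73m&sup2;
  with the dispersion implied by an IQR of roughly 81&ndash;103; the age
  coefficient mirrors the CKD-EPI age decay (0.993 per year). Age is
  uniform on [18, 80] (only median/IQR of the motivating cohort are
  documented, not a distribution); sex is Bernoulli with 55.1% female.
* **Creatinine.** Serum creatinine is back-derived by inverting CKD-EPI
  2009 at the generated eGFR. The inversion is closed-form: the equation
  is a strictly decreasing piecewise power law in creatinine, so each
  branch inverts analytically and the branch is chosen from the eGFR
  value at the knot scr = &kappa;. (Root-finding would add nothing but a
  tolerance.) Instrument (+0.02 mg/dl on one instrument) and small
  period shifts (SD 0.01) are then added so that `normalize_scr()` has
  real work to do.
* **Traits.** Each trait takes one of three generative roles: a direct
  SNP&rarr;trait path (pleiotropy), an outcome&rarr;trait path (trait
  downstream of kidney function), or a trait&rarr;outcome path combined
  with SNP&rarr;trait (a true mediator carrying fraction
  f = &alpha;&middot;&delta;/&beta;&#8321; of the SNP effect). The
  forward-mediation role exists precisely so that recovery tests can
  simulate a known mediated fraction. Null traits are independent noise;
  a shared-factor correlation structure among the 70 traits is not
  modeled, because no estimate of it is documented &mdash; an optional
  extension point, not a default.
* **Thyroid measures.** TSH is log-normal with meanlog log(1.38) and
  sdlog 0.5024, calibrated to a median of 1.38 uUI/mL and IQR
  0.98&ndash;1.93. FT3/FT4 are generated only when TSH &lt; 0.4 or
  &gt; 3.8 (missing by design). The log-normal bulk fit underweights the
  extreme-TSH tail relative to the population the package emulates, so
  default medication rates (levothyroxine 7.8%, antithyroid 1.0%) are
  calibrated such that `classify_thyroid()` prevalences come out near
  1.7% hyper / 88.5% normal / 9.8% hypo. Raw medication-user counts are
  therefore *not* realistic; the classification prevalences are the
  calibration target.
* **Exclusions.** Flags are sampled independently at rates 16, 1, 277,
  312 and 4 per 10,146. Independent sampling does not reproduce a
  particular flag overlap; the documented union of 416 (leaving 9,730) is
  reproduced exactly by the deterministic `exclusion_fixture()` instead.

What passing tests on these cohorts show: the estimators are unbiased and
calibrated under the generative model (linear effects, Gaussian noise,
HWE, no relatedness, missingness only where designed). What they do not
show: robustness to population structure, cryptic relatedness,
non-linear trait relationships, genotyping/imputation error, or
informative missingness beyond the TSH design — real-data features the
generator deliberately leaves out.

## Numerical and reproducibility choices

* All simulation runs under a caller-preserving seeded RNG
  (`with_seed`); regenerating with the same seed is byte-identical, and
  per-locus sub-seeds are derived deterministically from the main seed.
* Eigenvalues of correlation matrices are computed in double precision;
  values in (&minus;1e-10, 0) are clipped to zero, anything lower is a
  PSD error.
* Rank-deficient regression designs raise an error naming the collinear
  column rather than silently dropping it.
* One-sided p-values of summary statistics use the normal approximation
  (the summary-statistic convention); per-variant cohort fits use the t
  distribution at residual degrees of freedom.
* Output tables format p-values at 3 significant digits and effects at 6;
  full precision lives in the returned objects.

## Problem sizes

The test suite and acceptance script size their simulations for
single-CPU runs: mediated-fraction recovery at n = 10,000 over 200
replicates per fraction, type-I calibration at n = 400 over 2,000
replicates, end-to-end pipeline runs at n = 4,000 with a 30-trait panel,
and property tests at n &le; 10,000. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances (for example, binomial error
&radic;(0.05&middot;0.95/2000) &asymp; 0.005 on a 5% rejection rate).

## Known limitations

* The locus-significance machinery assumes harmonized, imputed dosages;
  no imputation-quality filtering or genotype-probability handling is
  implemented.
* The mediation screen is a statistical screen: it cannot separate true
  mediation from reverse causation or LD confounding, and the generator
  can (and does, in tests) produce outcome-downstream traits that the
  screen flags — this mirrors the method's real behavior, not a defect.
* Fixed-effect algebra only in meta-subtraction; heterogeneity and
  random-effects models are out of scope.
* The U-shaped (quadratic) TSH interaction hypothesis is addressed only
  through the two categorical contrasts, not a quadratic term.
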
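---
title: "Genetic risk scores and two-sample MR for leukocyte telomere length and cancer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores and two-sample MR for leukocyte telomere length and cancer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`grsmr` implements the analytic pipeline of a genetic risk score (GRS) and
two-sample Mendelian randomization (MR) study of leukocyte telomere length
(LTL) and cancer. The exposure instrument panel is a set of 17 independent
index SNPs associated with LTL in a European-ancestry GWAS of 78,592
individuals; the panel ships with the package as a tab-separated fixture
(`ltl_panel_path()`), with effect sizes oriented to *longer* telomere
length as published. Because telomeres shorten with age, the analysis
reports effects of genetically *shorter* telomere length:
`flip_to_shorter()` negates every effect size once (and refuses to do it
twice), leaving alleles, frequencies, standard errors and p-values
untouched.

## Instrument strength

For each SNP the instrument F statistic is the squared Wald ratio
$F = (\hat\beta/\mathrm{se})^2$, and the proportion of exposure variance
explained is $\mathrm{PVE} = F/(F + n - 2)$ with $n$ the exposure GWAS
sample size. The PVE relation is algebraically equivalent to
$\hat\beta^2/(\hat\beta^2 + \mathrm{se}^2(n-2))$, the variance share of a
single regressor in a simple linear regression; it reproduces every
published per-SNP PVE value at the printed precision, which is why it was
adopted. SNPs with $F < 10$ are flagged as weak; the packaged panel has
none (F from 27.9 to 205.4, mean 63.3, total PVE 1.37%).

## GRS construction

The raw score of individual $i$ is
$\mathrm{GRS}_i = \sum_j G_{ij}\hat\beta_j$, with $G_{ij} \in [0,2]$
counting effect alleles. The score is then standardized to mean 0 and
variance 1 within the analysis sample; Wald tests on the GRS coefficient
are invariant to any positive affine rescaling of the raw score, so the
choice of scale carries no inferential weight. Missing dosages are
mean-imputed at $2\times\mathrm{EAF}$ from the panel by default
(`drop_sample` removes incomplete samples instead); with complete data
the two policies coincide exactly.

Genotype QC removes variants with call rate < 0.95, minor allele
frequency < 0.01, or an exact Hardy–Weinberg test p-value < 1e-4. The
HWE test enumerates all heterozygote counts compatible with the observed
allele counts and sums the probabilities of configurations no more likely
than the observed one; the exact (rather than chi-square) form was chosen
because it behaves sensibly at the small sample sizes used in tests, and
no mid-p correction is applied. For the test only, dosages are rounded to
hard calls.

## Two-stage association models

Disease risk is modeled by additive logistic regression
$\mathrm{logit}(\mu_i) = \mathrm{GRS}_i\theta + X_i^T\alpha$ and
mortality by a Cox proportional-hazards model
$h(t_i) = h_0(t_i)\,e^{\mathrm{GRS}_i\theta + X_i^T\alpha}$ with Efron
handling of ties. Continuous covariates are z-scored before fitting;
binary covariates keep their 0/1 coding (the within-sample interpretation
of "standardized covariates" that keeps odds ratios per category
interpretable). Effects are reported as OR or HR per SD of the GRS with
Wald 95% intervals $\exp(\hat\theta \pm 1.96\,\mathrm{se})$. Batch runs
over many cancers share the cancer-free control pool, exclude outcomes
below 60 cases, apply Benjamini–Hochberg FDR across the batch, and
classify each association as significant (FDR < 0.05), suggestive
(p < 0.05 but FDR ≥ 0.05) or null. GRS-by-covariate interactions are
tested by refitting with a product term.

A caveat demonstrated by `analysis/02_grs_association.R`: in a
shared-control design, the cases of a strongly GRS-associated common
outcome are excluded from every other outcome's control pool, which
shifts that pool's GRS distribution. The bias is negligible when outcomes
are rare relative to the pool (the study's regime: hundreds to thousands
of cases against ~300,000 controls) but visible if a synthetic cohort
makes one cancer common.

## Harmonization

Outcome summary statistics are aligned to the panel's effect allele.
Exact allele matches keep the outcome effect, swapped alleles negate it,
and strand-complement representations are resolved the same way after
complementing. Palindromic (A/T, C/G) SNPs cannot be resolved by labels;
by default (`eaf_infer`) they are aligned by effect-allele-frequency
concordance when both frequencies fall outside the ambiguity band
[0.42, 0.58] and dropped otherwise — the default, rather than dropping
all palindromic SNPs, was chosen because the panel's strongest instrument
is T/A with EAF 0.24 and was evidently retained in the published
analysis. Instruments missing from the outcome are dropped without proxy
search. Harmonization is idempotent, and every drop is recorded with a
reason.

Before MR, an optional Bonferroni prescreen removes instruments whose
outcome association p-value is below $\alpha/k$ — a guard against gross
pleiotropy. Note its logic presumes the outcome association of a valid
instrument is weak; when a simulated causal slope is large and outcome
summary statistics are precise, the prescreen removes genuine
instruments, so the synthetic MR drivers disable it.

## The MR estimator suite

With harmonized pairs $(\hat\beta_{jX}, \hat\beta_{jY})$, the
fixed-effect IVW estimator is
$$\hat\theta = \frac{\sum_j w_j\hat\beta_{jY}\hat\beta_{jX}}
{\sum_j w_j\hat\beta_{jX}^2},\qquad
\mathrm{var}(\hat\theta) = \frac{1}{\sum_j w_j\hat\beta_{jX}^2},\qquad
w_j = \mathrm{var}(\hat\beta_{jY})^{-1},$$
which reduces exactly to the Wald ratio
$\hat\beta_{jY}/\hat\beta_{jX}$ at $k = 1$. Heterogeneity is measured by
Cochran's $Q = \sum_j w_j\hat\beta_{jX}^2(\hat\beta_{jY}/\hat\beta_{jX} -
\hat\theta)^2$ on $k-1$ degrees of freedom; the battery reports the
fixed-effect estimate when $Q$ does not reject at 0.05 and otherwise
inflates the SE by $\max(1, \sqrt{Q/(k-1)})$ (multiplicative random
effects).

Design choices where the cited methods leave formulas open:

* **Weighted median** — per-SNP ratios are ordered and the estimate
  interpolates the weighted empirical CDF at cumulative weight 1/2, with
  weights the inverse first-order variances of the ratios,
  $\hat\beta_{jX}^2/\mathrm{var}(\hat\beta_{jY})$; the SE is a parametric
  bootstrap (default 1,000 resamples, seeded, bit-reproducible).
* **Maximum likelihood** — bivariate normal likelihood with per-SNP true
  exposure effects as nuisance parameters, profiled out in closed form,
  leaving a 1-D profile likelihood in the causal slope maximized by
  bracketed search around the IVW start; the SE comes from the profile
  curvature. Without heterogeneity and with negligible exposure-side
  error it coincides with fixed IVW; with Table-1-scale exposure SEs it
  corrects a little regression dilution and may legitimately differ.
* **MR-Egger** — weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ with free intercept after orienting each SNP to
  $\hat\beta_X \ge 0$ (the intercept is meaningless without a fixed
  orientation). SEs use the unscaled weighted-design covariance inflated
  by $\max(1,\hat\sigma)$, with $t_{k-2}$ reference distributions; the
  intercept p-value is the pleiotropy test (p > 0.05 read as no
  directional pleiotropy). Constraining the intercept to zero recovers
  fixed IVW exactly.
* **MR-PRESSO** — the observed residual sum of squares against
  leave-one-out predictions, weights $\mathrm{var}(\hat\beta_{jY})^{-1}$,
  compared with a null distribution from parametric simulation of
  $\hat\beta_Y$ at the LOO fits (default 1,000 draws); the global p-value
  is rank-based with a +1 correction so it is never zero, and per-SNP
  outlier flags use level 0.05 with Bonferroni over $k$. At the default
  1,000 draws the smallest attainable per-SNP p-value (1/1001) lies
  below the Bonferroni threshold for $k \le 50$.
* **Leave-one-out** — the estimator (fixed IVW by default) applied $k$
  times omitting each SNP.

The battery's decision rule mirrors the study: an association is
**robust** only if the IVW, weighted-median and likelihood p-values are
all below 0.05, the Egger intercept p-value is above 0.05, and PRESSO
flags no outlier; it is **null** when the headline IVW p-value is not
significant, and **non_robust** otherwise. All estimators are invariant
to SNP ordering and to joint sign flips of
$(\hat\beta_{jX}, \hat\beta_{jY})$.

# Synthetic data: what it emulates

The generators reproduce the statistical structure the analyses assume,
so every stage is testable without restricted data.

* `simulate_genotypes()` draws independent Binomial(2, EAF) dosages at
  the panel frequencies — Hardy–Weinberg equilibrium with no LD, exactly
  as in the study's power simulations.
* `simulate_covariates()` draws X1 ~ Bernoulli(0.5), X2 ~ Normal(0,1)
  (the design says only "one binary, one continuous"; these are the
  plainest such choices), each entering with effect 0.5.
* `simulate_case_control()` builds a population (default 2,000,000) with
  case probability $\mathrm{logit}^{-1}(\eta)$,
  $\eta = \mathrm{GRS}\times\theta + 0.5X_1 + 0.5X_2$ with the GRS
  standardized within the population, then samples the configured case
  and control counts without replacement.
* `simulate_survival()` uses the inverse-probability transform
  $T = \left(-\log U / (\lambda e^{\eta})\right)^{1/\kappa}$ for a
  Weibull hazard $h(t) = \lambda\kappa t^{\kappa-1}e^{\eta}$ with shape
  $\kappa = 1$ and scale $\lambda = 0.01$ (with $\eta = 0$, exponential
  with median $\log 2/0.01 \approx 69.3$ time units). Exactly
  `round(censor_rate * n)` subjects (default 50%) are chosen uniformly at
  random and censored at a time uniform on $(0, T_i)$ — one concrete
  reading of "censored at random"; the GRS is standardized within the
  replicate by default (the population option exists because the study
  does not say which it used).
* `simulate_two_sample_summary()` resamples true exposure effects and
  exposure SEs from the panel, adds observation noise on both sides, and
  generates outcome effects $\theta\beta_X$ plus optional directional
  pleiotropy and heterogeneity (applied with the sign of the exposure
  effect, i.e. relative to the exposure-increasing allele, matching the
  Egger orientation convention) and an optional single displaced
  outlier. Outcome SEs derive from an effective outcome sample size via
  $1/\sqrt{2f(1-f)n}$; the default $n = 10{,}000$ reflects the
  case-limited effective size of a cancer GWAS with a few thousand cases
  against hundreds of thousands of controls
  ($n_\mathrm{eff} = 4/(1/n_\mathrm{case} + 1/n_\mathrm{control})$), so
  outcome SEs dominate exposure SEs as first-order IVW assumes.

What the generators do *not* emulate: linkage disequilibrium between
instruments, population stratification, sample overlap between exposure
and outcome GWAS, covariate-confounded pleiotropy, or genotype
missingness patterns of real arrays. Passing calibration tests therefore
certifies the estimators under the stated sampling models, not
robustness to those violations.

# Power harness

`power_survival()` and `power_case_control()` evaluate each
(size, effect) cell by repeated simulation and refitting, recording the
fraction of replicates whose GRS Wald p-value falls below
$\alpha = 0.05/30 \approx 1.67\times 10^{-3}$ (Bonferroni for 30 cancer
types), with exact binomial 95% intervals. A master seed spawns
per-replicate substreams, so every cell is independently reproducible
bit-for-bit; cells with more than 5% fit failures are flagged invalid.
The rejection test is the two-sided Wald test on the GRS coefficient
(the design says only "the p-value of GRS").

Problem sizes used by the shipped drivers and tests: the survival design
runs at the study grid (n = 100/300/500, effects 0.05/0.10/0.20, 1,000
replicates). For the case-control design the study-scale frame
(population 2,000,000, 300,000 controls) is available by configuration,
but the shipped driver uses a 200,000/30,000 frame: study-scale power is
saturated near 100% even at 50 cases, so the desk-scale frame is the
informative one.

A reconciliation note: under the design exactly as stated (standardized
GRS, 50% censoring, two-sided Wald at 1.67E-3), the survival power at
n = 300 computes to roughly 1% at HR 1.05 and 3% at HR 1.10 — below the
published 3.0% and 10.7%. Analytic approximation (non-centrality
$\theta\sqrt{d}$ with $d = 150$ events) agrees with our Monte-Carlo
values, and variants we examined (censoring that retains the event time,
one-sided testing) do not close the gap, so the difference likely
reflects an unstated choice in the original simulation. The harness
reports its cells with Monte-Carlo intervals and leaves the comparison
flagged rather than tuning the generator toward the published numbers.

# Numerical and degenerate-input policy

Zero-variance raw scores, single-class outcomes, all-censored cohorts,
constant interaction covariates, empty p-value vectors, and instrument
sets below each estimator's minimum ($k \ge 1$ IVW fixed, 2 random/ML/
LOO, 3 median/Egger, 4 PRESSO) raise immediate errors rather than
returning silent estimates; logistic fits additionally flag suspected
separation. Random draws are governed by explicit seeds everywhere, with
`with_seed()` restoring the caller's RNG state and `substream_seeds()`
deriving nested streams below $2^{31}$.
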
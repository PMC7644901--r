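# grsmr

Genetic risk scores and two-sample Mendelian randomization for leukocyte
telomere length (LTL) and cancer.

Telomeres shorten with each cell division, and telomerase is re-activated
in most tumors, so genetically predicted telomere length is a natural
exposure for cancer etiology. This package implements, as tested and
reusable R code, the full analytic pipeline of a GRS + MR study of LTL
and cancer risk/mortality:

* **Instrument panel handling** — the 17 independent LTL index SNPs from
  a 78,592-person exposure GWAS ship as a tab-separated fixture;
  functions load and validate the panel, re-orient effects to *shorter*
  telomere length, and score instrument strength
  (F = (β/se)², PVE = F/(F + n − 2)).
* **GRS engine** — genotype QC (call rate, MAF, exact Hardy–Weinberg
  test), VCF/TSV dosage input oriented to the panel effect allele, and
  the weighted, sample-standardized score
  GRS_i = Σ_j G_ij β̂_j.
* **Two-stage association** — logistic (`logit(μ) = GRS·θ + Xᵀα`) and
  Cox (`h(t) = h₀(t)·exp(GRS·θ + Xᵀα)`) models per SD of GRS,
  GRS×covariate interaction tests, shared-control batch runs with
  Benjamini–Hochberg FDR and significant/suggestive/null classification.
* **Two-sample MR suite** — summary-statistic harmonization (allele
  swaps, strand flips, palindromic SNPs by EAF concordance), Bonferroni
  pleiotropy prescreen, and the estimator battery: fixed/random-effects
  IVW
  (θ̂ = Σ wⱼ β̂ⱼY β̂ⱼX / Σ wⱼ β̂ⱼX², wⱼ = var(β̂ⱼY)⁻¹),
  weighted median, profile maximum likelihood, MR-Egger with intercept
  pleiotropy test, Cochran's Q, leave-one-out, and MR-PRESSO, combined
  under the study's robustness decision rule.
* **Synthetic cohorts and power** — HWE genotype, covariate,
  logistic-population case-control, Weibull survival and two-sample
  summary-statistic generators, plus Monte-Carlo power harnesses for
  both designs at α = 0.05/30 ≈ 1.67E-3.

The headline real-data results of the original study require restricted
UK Biobank/TCGA individual-level data and are out of scope; every stage
here is exercised end-to-end on synthetic cohorts instead.

## Worked example

```r
library(grsmr)

panel <- load_instrument_panel()          # 17 SNPs, longer-LTL orientation
summarize_instrument_strength(panel)[c("f_min", "f_mean", "f_max", "total_pve")]
#> $f_min  27.9  $f_mean  63.3  $f_max  205.4  $total_pve  0.0137

# GRS association on a synthetic cohort (see analysis/02_grs_association.R)
sp <- flip_to_shorter(panel)
gm <- simulate_genotypes(12000, sp$records$eaf, seed = 20201023)
colnames(gm) <- sp$records$rsid
```

Running the shipped drivers in order reproduces the whole analysis on
synthetic data; `Rscript analysis/02_grs_association.R` prints

```
Per-cancer association of the shorter-telomere GRS (per SD):
       outcome               OR        p      FDR       class
 melanoma_like 0.73 (0.67-0.81) 8.80e-11 2.64e-10 significant
 cancer_null_1 1.03 (0.93-1.15) 5.58e-01 5.58e-01        null
 cancer_null_2 0.88 (0.78-1.00) 4.75e-02 7.13e-02  suggestive
```

— the cancer generated with a protective GRS effect is recovered as
significant after FDR control, one null cancer lands at p ≈ 0.05
(classified only *suggestive*, which is exactly what the FDR layer is
for), and the other is null. `Rscript analysis/03_mr_analysis.R` runs
the MR battery on three summary-statistic scenarios; the causal one
(true slope −0.5) yields

```
-- scenario 'causal' (true slope -0.50): decision robust
          method  theta               OR        p
      ivw_random -0.565 0.57 (0.45-0.71) 1.15e-06
 weighted_median -0.544 0.58 (0.44-0.76) 1.05e-04
  max_likelihood -0.581 0.56 (0.47-0.66) 3.87e-11
           egger -0.198 0.82 (0.46-1.45) 5.09e-01
```

while the null scenario is declared `null` and the
directional-pleiotropy scenario is declared `non_robust` (its IVW
estimate is badly biased — the point of the sensitivity battery).
`Rscript analysis/04_power.R` reports, e.g., survival-design power at
n = 300 of 0.8% (HR 1.05), 3.3% (HR 1.11) and 31.0% (HR 1.22) at
α = 1.67E-3 over 1,000 replicates.

## Analysis drivers

| script | what it does |
|---|---|
| `analysis/01_instrument_strength.R` | per-SNP F/PVE table and panel summary |
| `analysis/02_grs_association.R` | QC → GRS → batch logistic association → FDR on a synthetic 3-cancer cohort |
| `analysis/03_mr_analysis.R` | harmonization + full MR battery on causal/null/pleiotropic scenarios |
| `analysis/04_power.R` | Monte-Carlo power grids for both designs |

Each writes tab-separated tables under `results/`.

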
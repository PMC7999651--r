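# statinpgx

Candidate-gene pharmacogenetic analysis of atorvastatin exposure, as a
tested, reusable R pipeline. The package is for pharmacologists and
biostatisticians analysing (or power-planning) healthy-volunteer
bioequivalence cohorts where genetic variation in drug transporters and
metabolising enzymes — above all the OATP1B1 uptake transporter encoded by
*SLCO1B1*, and CYP3A5 — drives several-fold differences in statin exposure
and, through it, myopathy risk.

It provides four things:

1. **A cohort simulator** (`simulation_config()`, `simulate_cohort()`):
   bioequivalence-style cohorts (by default 156 subjects in five 80 mg
   single-oral-dose trial arms) with demographics drawn from truncated
   normals, genotypes drawn in Hardy–Weinberg equilibrium, and
   concentration–time profiles from a one-compartment first-order absorption
   model, `C(t) = D·ka/(V_F(ka−ke))·(e^(−ke·t) − e^(−ka·t))`, with genotype
   effect multipliers calibrated to published group mean clearances
   (SLCO1B1 PF ≈ 0.45, CYP3A5 \*1/\*1 ≈ 0.47 relative to reference).
2. **Star-allele translation** (`translate_genotypes()`): missing-call
   imputation to homozygous reference, diplotype calling, and phenotype
   assignment (SLCO1B1 NF/DF/PF, CYP3A5 expresser status, CYP2D6 activity
   score with copy number, CYP2C19/CYP2B6 function pairs, merged SLC22A1 and
   ABCB1 haplotypes) from versioned definition tables shipped as data.
3. **A non-compartmental PK engine** (`run_nca()`): trapezoidal AUC,
   terminal slope λz by best-adjusted-R² window selection, extrapolation to
   infinity, `Cl/F = D/(AUC∞·W)`, `Vd/F = (Cl/F)/ke`, `t½ = ln2/ke`, with
   BQL handling and fit diagnostics.
4. **The two-stage statistics** (`univariate_screen()`,
   `multivariate_model()`, `hwe_test()`, `adr_incidence_test()`,
   `adr_logistic()`): log-scale t/ANOVA screening of dose/weight-corrected
   exposures (AUC/DW, Cmax/DW), a Bonferroni-corrected multivariate stage
   (α\* = 0.05/k), Hardy–Weinberg chi-square and exact tests, and ADR
   analyses with quasi-separation detection.

`run_pipeline()` drives everything end to end and writes cohort-style
summary tables plus a manifest with seed and checksums; a thin CLI wrapper
lives at `inst/cli/statinpgx.R`.

## Worked example

```r
library(statinpgx)

cfg <- simulation_config(seed = 1)   # the default 156-subject, 5-arm design
res <- run_pipeline(cfg)

res$tables$by_slco1b1[, c("level", "n", "auc_dw_mean", "auc_dw_cv", "cl_f_w_mean")]
#>   level     n auc_dw_mean auc_dw_cv cl_f_w_mean
#> 1 DF       44        150.      39.0       7621.
#> 2 NF      106        130.      47.9       9453.
#> 3 PF        6        283.      51.0       4237.
#> 4 Total   156        142.      50.6       8736.
```

The dose/weight-corrected exposure (AUC/DW, in kg·h·ng/(mL·mg)) rises from
normal- through decreased- to poor-function SLCO1B1 carriers — the PF group
sits at roughly 2.2× the NF mean — while apparent clearance per kg falls
correspondingly. The univariate screen flags the phenotype:

```r
u <- res$univariate
u[u$outcome == "auc_dw", c("group_var", "test", "p")]
#>          group_var  test        p
#> 1              sex     t 3.92e-01
#> 5          slco1b1 anova 4.12e-05
#> 6     cyp3a5_star3 anova 7.12e-03
#> ...
```

Two variables screen in for this seed (SLCO1B1 phenotype and the CYP3A5 \*3
genotype), so the multivariate threshold is α\* = 0.05/2 = 0.025, and the
pooled DF+PF term stays significant after correction:

```r
res$multivariate$auc_dw$coefficients
#>                term estimate         p significant_bonferroni
#> 1       (Intercept)   4.7773 3.62e-142                   TRUE
#> 2      slco1b1DF+PF   0.2253  3.67e-03                   TRUE
#> 3 cyp3a5_star3*1/*1   0.5830  1.09e-02                   TRUE
#> 4 cyp3a5_star3*1/*3  -0.0854  3.15e-01                  FALSE
```

The DF+PF coefficient is on the natural-log scale: carriers of a
reduced-function SLCO1B1 diplotype show `exp(0.225) ≈ 1.25`-fold higher
dose/weight-corrected exposure than NF carriers in this simulated cohort.

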
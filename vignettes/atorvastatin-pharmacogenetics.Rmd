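---
title: "Methods: simulation and pharmacogenetic analysis of atorvastatin exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and pharmacogenetic analysis of atorvastatin exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statinpgx)
```

## The scientific problem

Atorvastatin is dosed at a fixed strength (here 80 mg single oral doses in
healthy volunteers), yet its systemic exposure varies several-fold between
subjects. Part of that variability is dosimetric — lighter subjects receive a
higher mg/kg dose — and part is pharmacogenetic: atorvastatin is a substrate
of the hepatic uptake transporter OATP1B1 (encoded by *SLCO1B1*) and of the
CYP3A enzymes, and reduced-function variants raise exposure, which in turn
raises the risk of statin myopathy. `statinpgx` implements the full
candidate-gene analysis workflow for this setting:

1. **`simulation_config()` / `simulate_cohort()`** — generate
   bioequivalence-style cohorts with genotype-dependent pharmacokinetics, so
   every downstream stage is testable without subject-level data (which are
   not publicly deposited for studies of this kind);
2. **`translate_genotypes()`** — star-allele diplotype and phenotype
   translation from data-driven definition tables;
3. **`run_nca()`** — non-compartmental pharmacokinetic analysis;
4. **`univariate_screen()` / `multivariate_model()` / `hwe_test()` /
   `adr_incidence_test()`** — the two-stage statistical strategy with
   Hardy–Weinberg and adverse-drug-reaction analyses;
5. **`run_pipeline()` / `group_summary()`** — cohort-style summary tables and
   an end-to-end driver.

The defaults throughout are calibrated to the group-level summary statistics
of a reference cohort of 156 healthy volunteers from five atorvastatin
bioequivalence trials, shipped as data under
`system.file("extdata", package = "statinpgx")` and accessible via
`reference_summary()`.

## Non-compartmental analysis

For each subject the engine computes, in the conventional way:

* AUC to the last quantifiable point by the linear trapezoidal rule (a
  log-linear-down variant is available by flag but off by default, following
  the plain trapezoidal convention);
* the terminal rate constant $k_e$ by ordinary least squares of
  $\log C$ on $t$ over the log-linear terminal phase;
* $AUC_\infty = AUC_t + C_{last}/k_e$, with the extrapolated fraction flagged
  above 20%;
* $C_{max}$ and $t_{max}$ read directly from the profile (earliest time at
  the maximum on ties);
* $t_{1/2} = \ln 2 / k_e$, apparent clearance
  $Cl/F = D/(AUC_\infty \cdot W)$ and apparent volume
  $Vd/F = (Cl/F)/k_e$.

**Terminal window selection.** The log-linear window is chosen
deterministically: every candidate window of at least 3 points starting
strictly after $t_{max}$ and ending at the last quantifiable point is
fitted, and the highest adjusted $R^2$ wins. Two windows whose adjusted
$R^2$ differ by less than $10^{-4}$ count as tied and the longer wins. The
tolerance matters: with 10% assay noise a strict argmax systematically
selects lucky 3-point windows, which inflates $t_{1/2}$ (we observed a mean
of 12.8 h instead of the 9.1 h generating value before adopting the
tolerance) and destabilises the extrapolation.

**Below-quantification handling.** Pre-$t_{max}$ BQL samples enter as 0,
post-$t_{max}$ BQL samples are dropped, and the profile ends at the last
quantifiable point — the conventional single-dose defaults.

**Units.** With concentrations in ng/mL, dose in mg and weight in kg,
$Cl/F$ comes out in mL/(h·kg) and $Vd/F$ in mL/kg. Cohort tables in this
field typically print $Cl/F$ values of magnitude $9\times 10^3$ labelled
"L/h·kg"; back-calculation from AUC/DW shows such values are actually
mL/(h·kg). The package computes in consistent units and leaves rescaling
(e.g. $Vd/F$ to L/kg) to the presentation layer.

## Genotype-to-phenotype translation

All allele content lives in versioned TSV data files (panel, allele
definitions, phenotype maps), never in code, because allele definitions and
score cutpoints evolve:

* **Imputation.** Subjects genotyped on partial panels, and failed calls,
  are completed by assuming missing variants are "not mutated": the call
  becomes homozygous reference and is recorded in `imputed_rsids`. The
  operation is idempotent. The cost of this convention is visible in
  simulation: a masked loss-of-function homozygote re-enters the analysis as
  an apparent reference homozygote.
* **Diplotype calling.** Variant alleles are counted per defining site and
  assigned to the two haplotype slots in priority order (loss-of-function
  first); with several heterozygous single-variant alleles the trans
  configuration is assumed, the standard unphased convention. Overflows
  (more variant alleles than slots) are truncated by priority and flagged.
* **Phenotypes.** SLCO1B1 counts reduced-function alleles (0/1/2 →
  NF/DF/PF, with \*1B treated as normal-function); CYP3A5 expresser status
  requires at least one functional \*1 allele; CYP2D6, CYP2C9 and CYP1A2 use
  activity scores with data-driven cutpoints (the CYP2D6 score scales with
  gene copy number, so a double deletion scores 0); CYP2C19 and CYP2B6 use a
  function-pair lookup. Multi-variant transporter genes (SLC22A1, ABCB1)
  additionally get a merged haplotype label — wild-type, heterozygous (one
  variant allele), mutant (two or more) — and ABCB1 also under the reduced
  three-variant subset. For genes analysed per allele (e.g. SLC22A1 \*2),
  `star_genotype()` gives the \*1/\*1-style genotype with respect to one
  allele.
* **UGT2B7 rs7439366** is stored by nucleotide genotype; published star
  labels for this variant are used inconsistently across sources, so the
  star name is an alias, not ground truth.

## The synthetic cohort

The generator emulates the design that produces data like the reference
cohort: five single-dose trial arms (n = 14/30/39/37/36; four sampled at 20
points over 0–48 h, one ezetimibe co-formulation arm at 30 points over
0–72 h), a 85:71 female:male split, and demographics drawn from truncated
normals honouring the inclusion bounds (age 18–55, BMI 18–30; out-of-range
draws are redrawn). Genotypes are two independent allele draws per variant —
Hardy–Weinberg by construction — at frequencies taken from the reference
genotype-group sizes where available (e.g. the \*3 frequency 270/312 ≈ 0.865).

Concentration profiles follow a one-compartment first-order absorption
model, chosen as the minimal structure with closed forms that serve as
analytic test oracles:
$$C(t) = \frac{D\,k_a}{V_F\,(k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right),
\qquad k_e = \frac{CL_F}{V_F}.$$

Parameter choices, each calibrated once to the printed reference summaries:

* $CL_F$ = 638 L/h at 70 kg (scaling linearly with weight), so the
  reference-phenotype mean AUC/DW lands near 122.6 kg·h·ng/(mL·mg) after the
  log-normal variability correction, and total Cl/F per kg near
  9.1 L/h/kg;
* $V_F = CL_F/k_e$ with $k_e = \ln 2 / 9.1\,\mathrm{h}$, giving the printed
  mean half-life and a Vd/F near 120 L/kg;
* $k_a$ = 3.5 /h, placing $t_{max}$ at the printed 1.4 h on the sampling
  grid;
* between-subject log-normal CVs of 0.50 (CL), 0.45 (V), 0.45 ($k_a$). The
  CL value matches the *within-genotype* CV% of the reference tables
  (44.9–59.3%); using the *total* CV would double-count the genotype-effect
  variance once multipliers are layered on;
* the CL and V random effects are correlated at 0.8. Independent effects
  would make $k_e$ vary with both and give a half-life CV near 67%, far
  above the printed 28.6%; the correlation reproduces the printed
  dispersion;
* proportional assay noise CV 0.10, LLOQ 0.05 ng/mL (so the 72-h arm ends in
  BQL samples, exercising the censoring path);
* missing-call masking defaults to 0 because the reference study genotyped
  the primary-analysis variants in every subject; tests exercise imputation
  with explicit nonzero rates.

**Genotype effects.** Effect multipliers are calibrated as
group-over-reference mean Cl/F ratios (`calibrate_effect_multipliers()`):
SLCO1B1 PF ≈ 0.446, DF ≈ 0.78; CYP3A5 \*1/\*1 ≈ 0.473. By default a
multiplier acts on *bioavailability*, i.e. on $CL_F$ and $V_F$ jointly. The
reference tables adjudicate this choice: Vd/F falls across SLCO1B1
phenotypes in the same proportion as Cl/F, Cmax/DW rises in proportion to
AUC/DW, and $t_{1/2}$ is flat — the signature of a pre-systemic extraction
(F) effect. A clearance-only multiplier (available as
`genotype_effect = "clearance"`) would instead stretch the poor-function
half-life to ~20 h and leave Cmax untouched, contradicting the tables.

**What the simulator does not reproduce.** A one-compartment model with
$t_{1/2}$ = 9.1 h cannot simultaneously match the printed $C_{max}$
(≈ 39 ng/mL at AUC ≈ 167 ng·h/mL — that ratio requires multi-compartment
distribution). Simulated $C_{max}$ is ≈ 10 ng/mL; because all effects are
multiplicative, $C_{max}$/DW *contrasts* between genotype groups remain
valid, but absolute $C_{max}$ levels do not. The simulator also collapses
each subject's crossover periods to a single reference-formulation profile
(period/sequence effects are not reported group-wise in this field's
summaries, so there is nothing to calibrate them to), draws race
independently of body size, and does not model ezetimibe co-dosing kinetics
beyond the arm flag. Passing tests therefore demonstrate correctness of the
pipeline's algebra and inference under a plausible generative model — not
that the model captures every feature of real atorvastatin data.

## The statistical strategy

PK parameters are log-transformed for inference; AUC and Cmax are first
divided by the dose/weight ratio (AUC/DW = AUC·W/D) to remove the fixed-dose
body-size artifact. The strategy is deliberately two-stage to limit chance
findings:

1. **Univariate screen** — equal-variance two-sided t tests (two levels) or
   one-way ANOVA with Bonferroni-adjusted pairwise post-hocs (three or more
   levels) of each log outcome over each categorical variable. Group
   descriptives (n, arithmetic mean, CV%) are reported on the original
   scale. Levels with fewer than two observations are descriptive only;
   race strata rarer than 6 subjects are merged into a combined level.
2. **Multivariate stage** — one OLS model per log outcome containing every
   variable that screened in at p < 0.05, with the significance threshold
   Bonferroni-corrected to α\* = 0.05/k, k being the number of variables
   introduced. Reference levels are fixed (female, Caucasian, no ezetimibe,
   NF, \*3/\*3, \*1/\*1, wild-type) so coefficient signs are interpretable,
   and the SLCO1B1 decreased- and poor-function carriers are pooled into a
   single DF+PF term. Variables measured on under half the subjects are
   excluded (and logged); predictors whose indicators are linear
   combinations of earlier ones (the ezetimibe flag equals the ezetimibe
   arm) are dropped from the fit but still counted in k, since they were
   introduced. Bonferroni is applied exactly twice — in the ANOVA post-hocs
   and in α\* — and nowhere else; no FDR.

**Degenerate data** are handled deterministically: an outcome constant in
both groups gives t = 0, p = 1; zero within-group variance with differing
means is flagged rather than tested; rank deficiency in a direct
`multivariate_model()` call is an error naming the aliased columns.

**ADR analyses** use Pearson contingency chi-squares for incidence and
logistic regression for multivariate exploration. Events concentrated
entirely in one stratum (e.g. headache absent in males) produce
quasi-complete separation, where the maximum-likelihood log-odds diverges
(estimates like −19 with huge standard errors are artifacts of the
optimiser's stopping point, not data summaries). `adr_logistic()` detects
this, flags it, and offers a ridge-penalised fit (small L2 penalty via
glmnet) as a finite-coefficient fallback instead of reporting the divergent
number.

**Hardy–Weinberg testing** compares observed genotype counts to the
$p^2 : 2pq : q^2$ proportions expected from the sample allele frequencies
with a 1-df Pearson chi-square, plus an exact test that enumerates all
heterozygote counts compatible with the observed allele counts (validated
against a random-pairing Monte Carlo). Monomorphic variants are flagged
"no allelic variability" rather than tested. The two p values coincide near
the rejection region but can differ substantially in the bulk of the
distribution, because the exact test's discrete tail and the chi-square's
asymptotic tail are different functionals; deviation *decisions* agree away
from the boundary, and the test suite asserts exactly that.

## Numerical and design choices

* $t_{max}$ ties resolve to the earliest time; all window searches and level
  orderings are deterministic, so a fixed seed reproduces every output file
  checksum-for-checksum (`run_pipeline()` writes a manifest with MD5s).
* The λz fit requires at least 3 points after $C_{max}$ and a negative
  slope; profiles failing either are flagged and excluded from derived
  parameters rather than imputed.
* The exact HWE p value sums outcome probabilities no greater than the
  observed outcome's (with a $10^{-12}$ tolerance for ties).
* Problem sizes in the test suite: the demographics convergence check uses
  20 000 subjects, the genotype HWE check 10 000, parameter recovery 200
  simulated cohorts of 156, and the type-I calibrations 10 000 replicates —
  sizes chosen to make the Monte Carlo error small relative to the asserted
  tolerances while keeping the suite quick.

## Known limitations

* The phenotype tables cover the genes this analysis needs; they are not a
  complete clinical-grade allele catalogue (no CYP2D6 hybrid alleles or
  structural variants beyond copy number).
* The univariate screen treats subjects as independent; crossover structure
  within trials is not modelled (single-dose reference-formulation profiles
  only).
* With a 1.8% expected \*1/\*1 frequency, a 156-subject cohort carries on
  average fewer than three CYP3A5 \*1/\*1 homozygotes, so the power to flag
  the CYP3A5 term univariately in any single simulated cohort is modest —
  about one cohort in five has at most one \*1/\*1 subject and cannot test
  the contrast at all. Likewise, the ~2.5% poor-function SLCO1B1 frequency
  leaves roughly one cohort in fifty with no PF subject, so even the
  NF < DF < PF mean ordering cannot hold in every replicate. Both are
  properties of the study size and allele frequencies, not of the
  implementation, and the parameter-recovery results should be read with
  them in mind.
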
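# Synthetic bioequivalence-cohort generator: demographics, genotypes drawn in
# Hardy-Weinberg equilibrium, genotype-dependent one-compartment oral PK, and
# adverse-drug-reaction indicators. Defaults are calibrated to the reference
# atorvastatin cohort summaries shipped under extdata.

#' Default trial-arm structure
#'
#' Five single-oral-dose crossover bioequivalence trials: four 80 mg
#' atorvastatin arms sampled 0-48 h at 20 time points, and one
#' atorvastatin/ezetimibe 80/10 mg arm sampled 0-72 h at 30 time points.
#'
#' @return Tibble `arm`, `n`, `schedule`, `dose`, `ezetimibe`.
#' @export
default_trial_arms <- function() {
  tibble::tibble(
    arm = c("A", "B", "C", "D", "E"),
    n = c(14L, 30L, 39L, 37L, 36L),
    schedule = c("s48", "s48", "s48", "s72", "s48"),
    dose = 80,
    ezetimibe = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Default sampling schedules
#'
#' @return Named list of sampling-time vectors (h): `s48` (20 points,
#'   pre-dose to 48 h) and `s72` (30 points, pre-dose to 72 h).
#' @export
default_schedules <- function() {
  list(
    s48 = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 4, 6, 8, 12, 16,
            24, 30, 36, 42, 48),
    s72 = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.25, 2.5, 3, 3.5, 4,
            5, 6, 8, 10, 12, 16, 20, 24, 30, 36, 42, 48, 54, 60, 66, 72)
  )
}

#' Default per-sex demographic distributions
#'
#' Means and SDs for weight, height and age by sex, taken from the reference
#' cohort demographics table (SD reconstructed from the printed CV%).
#'
#' @return Tibble `sex`, `parameter`, `mean`, `sd`.
#' @export
default_demographics <- function() {
  demo <- reference_summary("demographics")
  demo <- demo[demo$stratifier == "sex" &
                 demo$parameter %in% c("weight", "height", "age"), ]
  tibble::tibble(
    sex = ifelse(demo$level == "Female", "F", "M"),
    parameter = demo$parameter,
    mean = demo$mean,
    sd = demo$mean * demo$cv / 100
  )
}

# genotype-group sizes from the reference PK summary for one stratifier
reference_group_n <- function(stratifier) {
  pk <- reference_summary("pk")
  pk <- pk[pk$stratifier == stratifier & pk$parameter == "auc_dw", ]
  stats::setNames(pk$n, pk$level)
}

#' Default alternate-allele frequencies
#'
#' Frequencies of the star-defining (alternate) alleles used by the
#' simulator. Where the reference cohort summaries report genotype-group
#' sizes (SLCO1B1 *5, CYP3A5 *3, SLC22A1 *2/*5, UGT2B7 rs7439366) the
#' frequency is the allele count over twice the genotyped subjects; the
#' remaining variants carry typical European/admixed-population frequencies.
#' The same frequency is applied to every race stratum unless overridden.
#'
#' @param races Race strata to replicate frequencies over.
#' @return Tibble `rsid`, `race`, `freq`.
#' @export
default_allele_freqs <- function(races = c("Caucasian", "Latin-American",
                                           "Black", "Arabic")) {
  n_slco <- reference_group_n("slco1b1")
  n_3a5 <- reference_group_n("cyp3a5_star3")
  n_s2 <- reference_group_n("slc22a1_star2")
  n_s5 <- reference_group_n("slc22a1_star5")
  n_ugt <- reference_group_n("ugt2b7_rs7439366")
  freqs <- c(
    rs4149056 = unname((n_slco["DF"] + 2 * n_slco["PF"]) / (2 * sum(n_slco))),
    rs2306283 = 0.40,
    rs776746 = unname((n_3a5["*1/*3"] + 2 * n_3a5["*3/*3"]) / (2 * sum(n_3a5))),
    rs10264272 = 0.005,
    rs72552763 = unname((n_s2["*1/*2"] + 2 * n_s2["*2/*2"]) / (2 * sum(n_s2))),
    rs34059508 = unname(n_s5["*1/*5"] / (2 * sum(n_s5))),
    rs7439366 = unname((n_ugt["*1/*2"] + 2 * n_ugt["*2/*2"]) / (2 * sum(n_ugt))),
    rs1045642 = 0.50,
    rs2032582 = 0.45,
    rs1128503 = 0.42,
    rs3892097 = 0.20
  )
  tidyr::expand_grid(rsid = names(freqs), race = races) |>
    dplyr::mutate(freq = unname(freqs[.data$rsid]))
}

#' Default structural pharmacokinetic parameters
#'
#' One-compartment first-order absorption base values for a 70 kg
#' reference-phenotype subject, calibrated to the reference cohort: apparent
#' clearance sized so the reference-group mean AUC/DW lands near the printed
#' value, V_F = CL_F / ke with ke = ln(2)/9.1 h (the printed mean half-life),
#' and ka chosen so tmax falls in the printed 1-2 h window. CL_F and V_F
#' scale linearly with body weight.
#'
#' @return List: `cl_f` (L/h), `v_f` (L), `ka` (1/h), `ref_weight` (kg).
#' @export
default_pk_base <- function() {
  ke <- log(2) / 9.1
  cl_f <- 638
  list(cl_f = cl_f, v_f = cl_f / ke, ka = 3.5, ref_weight = 70)
}

#' Calibrate genotype effect multipliers from group mean clearances
#'
#' The clearance multiplier of a genotype/phenotype group is its mean Cl/F
#' divided by the reference group's mean Cl/F, so a lower-clearance
#' (higher-exposure) phenotype gets a multiplier below 1 and the reference
#' group's multiplier is exactly 1. The AUC-side fold change is the inverse.
#'
#' @param group_means Named numeric vector of group mean Cl/F values.
#' @param reference Name of the reference group (default the first).
#' @return Named numeric vector of CL_F multipliers.
#' @export
calibrate_effect_multipliers <- function(group_means,
                                         reference = names(group_means)[1]) {
  stopifnot(is.numeric(group_means), !is.null(names(group_means)),
            all(group_means > 0), reference %in% names(group_means))
  group_means / group_means[[reference]]
}

#' Default genotype effect multipliers
#'
#' CL_F multipliers calibrated from the reference cohort's group mean Cl/F
#' values: SLCO1B1 transporter phenotype (NF reference) and CYP3A5 *3
#' genotype (*3/*3 reference).
#'
#' @return Tibble `gene`, `level`, `cl_mult`.
#' @export
default_effect_multipliers <- function() {
  pk <- reference_summary("pk")
  clf <- pk[pk$parameter == "cl_f", ]
  grab <- function(strat, levels, reference) {
    g <- clf[clf$stratifier == strat, ]
    m <- stats::setNames(g$mean, g$level)[levels]
    calibrate_effect_multipliers(m, reference)
  }
  slco <- grab("slco1b1", c("NF", "DF", "PF"), "NF")
  cyp <- grab("cyp3a5_star3", c("*3/*3", "*1/*3", "*1/*1"), "*3/*3")
  tibble::tibble(
    gene = c(rep("SLCO1B1", 3), rep("CYP3A5", 3)),
    level = c(names(slco), names(cyp)),
    cl_mult = c(unname(slco), unname(cyp))
  )
}

#' Default adverse-drug-reaction incidence model
#'
#' Per-stratum event probabilities calibrated to the reference cohort's ADR
#' counts: gastrointestinal symptoms by trial arm, headache by sex (no male
#' cases), myalgia/arthralgia uniform.
#'
#' @return List `gi` (named by arm), `headache` (named by sex F/M),
#'   `myalgia` (scalar).
#' @export
default_adr_rates <- function() {
  adr <- reference_summary("adr")
  p <- function(type, group) {
    r <- adr[adr$adr_type == type & adr$group == group, ]
    if (nrow(r) == 0L) 0 else r$cases / r$denominator_n
  }
  list(
    gi = c(A = 0, B = p("gi", "B"), C = 0, D = p("gi", "D"), E = p("gi", "E")),
    headache = c(F = p("headache", "Female"), M = p("headache", "Male")),
    myalgia = p("myalgia", "Total")
  )
}

#' Build a simulation configuration
#'
#' Bundles and validates every parameter of the synthetic cohort: size and
#' trial-arm structure, sex ratio, per-sex demographic distributions,
#' alternate-allele frequencies per race, structural PK base values,
#' genotype-to-clearance effect multipliers, between-subject and residual
#' variability, the assay quantification limit, the missing-call rate, ADR
#' incidence, and the seed.
#'
#' @param n_subjects Cohort size (default 156).
#' @param trial_arms Tibble as [default_trial_arms()]; arm sizes must sum to
#'   `n_subjects`.
#' @param sex_ratio Fraction female (default 85/156).
#' @param race_probs Named race probabilities (default 81/70/4/1 out of 156).
#' @param demographics Per-sex means/SDs as [default_demographics()].
#' @param age_range,bmi_range Inclusion bounds enforced by redrawing
#'   out-of-range values (defaults 18-55 years and 18-30 kg/m2).
#' @param allele_freqs Tibble `rsid`, `race`, `freq`.
#' @param pk_base List as [default_pk_base()].
#' @param effect_multipliers Tibble `gene`, `level`, `cl_mult`.
#' @param genotype_effect How the multiplier acts: `"bioavailability"`
#'   (default) scales CL_F and V_F jointly, as a pre-systemic extraction
#'   effect does (both are bioavailability-scaled), which leaves ke, t1/2 and
#'   tmax untouched and moves AUC/DW, Cmax/DW and Vd/F in proportion;
#'   `"clearance"` scales CL_F alone, which also shifts ke and t1/2.
#' @param bsv_cv Named log-normal between-subject CVs for `cl_f`, `v_f`,
#'   `ka`.
#' @param bsv_corr_cl_v Correlation of the CL_F and V_F random effects
#'   (default 0.8); large subjects have both high clearance and high volume,
#'   and the correlation keeps the half-life dispersion realistic.
#' @param residual_cv Proportional assay-noise CV.
#' @param lloq Lower limit of quantification (ng/mL).
#' @param missing_rate Independent Bernoulli missing-call rate per
#'   (subject, variant). The default 0 mirrors the reference study, where the
#'   variants driving the primary analysis were genotyped in every subject;
#'   raise it to exercise the missing-call imputation rule.
#' @param adr_rates List as [default_adr_rates()].
#' @param seed Integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 156L,
                              trial_arms = default_trial_arms(),
                              sex_ratio = 85 / 156,
                              race_probs = c("Caucasian" = 81, "Latin-American" = 70,
                                             "Black" = 4, "Arabic" = 1) / 156,
                              demographics = default_demographics(),
                              age_range = c(18, 55),
                              bmi_range = c(18, 30),
                              allele_freqs = default_allele_freqs(),
                              pk_base = default_pk_base(),
                              effect_multipliers = default_effect_multipliers(),
                              genotype_effect = c("bioavailability", "clearance"),
                              bsv_cv = c(cl_f = 0.50, v_f = 0.45, ka = 0.45),
                              bsv_corr_cl_v = 0.8,
                              residual_cv = 0.10,
                              lloq = 0.05,
                              missing_rate = 0,
                              adr_rates = default_adr_rates(),
                              seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), trial_arms = trial_arms,
    sex_ratio = sex_ratio, race_probs = race_probs,
    demographics = demographics, age_range = age_range, bmi_range = bmi_range,
    allele_freqs = allele_freqs, pk_base = pk_base,
    effect_multipliers = effect_multipliers,
    genotype_effect = match.arg(genotype_effect), bsv_cv = bsv_cv,
    bsv_corr_cl_v = bsv_corr_cl_v,
    residual_cv = residual_cv, lloq = lloq, missing_rate = missing_rate,
    adr_rates = adr_rates, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("n_subjects must be at least 1")
  if (sum(cfg$trial_arms$n) != cfg$n_subjects) {
    stop("trial arm sizes (", sum(cfg$trial_arms$n),
         ") must sum to n_subjects (", cfg$n_subjects, ")")
  }
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) stop("sex_ratio must be in [0,1]")
  if (any(cfg$allele_freqs$freq < 0 | cfg$allele_freqs$freq > 1)) {
    stop("allele frequencies must be in [0,1]")
  }
  if (any(cfg$bsv_cv < 0) || cfg$residual_cv < 0) stop("CVs must be >= 0")
  if (abs(cfg$bsv_corr_cl_v) > 1) stop("bsv_corr_cl_v must be in [-1,1]")
  if (any(cfg$effect_multipliers$cl_mult <= 0)) {
    stop("effect multipliers must be > 0")
  }
  if (abs(sum(cfg$race_probs) - 1) > 1e-8) stop("race_probs must sum to 1")
  invisible(cfg)
}

# truncated-normal draw by redraw; errors if the bounds capture almost no mass
rtrunc_norm <- function(n, mean, sd, lower, upper, max_iter = 1000L) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_iter)) {
    bad <- which(x < lower | x > upper)
    if (length(bad) == 0L) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop("truncation bounds [", lower, ", ", upper,
       "] capture too little probability mass")
}

#' Sample subject demographics
#'
#' Sex is Bernoulli at the configured female fraction; weight, height and age
#' are truncated normals with the configured per-sex means/SDs; BMI is
#' derived as weight/height^2 and the (weight, height) pair is redrawn until
#' the BMI inclusion bound holds, mirroring hard eligibility limits. Race is
#' drawn from the configured probabilities, independently of body size.
#'
#' @param config A [simulation_config()].
#' @return Tibble of subject records: `subject_id`, `sex`, `race`, `age`,
#'   `weight`, `height`, `bmi`, `arm`, `schedule`, `dose`, `ezetimibe`.
#' @export
sample_demographics <- function(config) {
  validate_config(config)
  n <- config$n_subjects
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
  race <- sample(names(config$race_probs), n, replace = TRUE,
                 prob = config$race_probs)
  par <- function(s, p, col) {
    d <- config$demographics
    v <- d[[col]][d$sex == s & d$parameter == p]
    if (length(v) != 1L) stop("demographics table lacks ", p, " for sex ", s)
    v
  }
  weight <- height <- numeric(n)
  for (s in unique(sex)) {
    idx <- which(sex == s)
    w <- stats::rnorm(length(idx), par(s, "weight", "mean"), par(s, "weight", "sd"))
    h <- stats::rnorm(length(idx), par(s, "height", "mean"), par(s, "height", "sd"))
    for (it in 1:1000) {
      bmi <- w / h^2
      bad <- which(bmi < config$bmi_range[1] | bmi > config$bmi_range[2] |
                     w <= 0 | h <= 0)
      if (length(bad) == 0L) break
      w[bad] <- stats::rnorm(length(bad), par(s, "weight", "mean"),
                             par(s, "weight", "sd"))
      h[bad] <- stats::rnorm(length(bad), par(s, "height", "mean"),
                             par(s, "height", "sd"))
      if (it == 1000) stop("BMI bounds capture too little probability mass")
    }
    weight[idx] <- w
    height[idx] <- h
  }
  age <- numeric(n)
  for (s in unique(sex)) {
    idx <- which(sex == s)
    age[idx] <- rtrunc_norm(length(idx), par(s, "age", "mean"),
                            par(s, "age", "sd"),
                            config$age_range[1], config$age_range[2])
  }
  arms <- config$trial_arms
  arm_assign <- sample(rep(arms$arm, arms$n))
  ai <- match(arm_assign, arms$arm)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = sex, race = race, age = age, weight = weight, height = height,
    bmi = weight / height^2,
    arm = arm_assign, schedule = arms$schedule[ai], dose = arms$dose[ai],
    ezetimibe = arms$ezetimibe[ai]
  )
}

#' Sample genotypes in Hardy-Weinberg equilibrium
#'
#' Each subject's genotype at each configured variant is two independent
#' allele draws at the alternate-allele frequency of the subject's race
#' stratum, so genotype frequencies are in Hardy-Weinberg equilibrium by
#' construction. Allele tokens come from the panel (ref/alt).
#'
#' @param config A [simulation_config()].
#' @param subjects Output of [sample_demographics()].
#' @return Long genotype tibble: `subject_id`, `gene`, `rsid`, `allele1`,
#'   `allele2`.
#' @export
sample_genotypes <- function(config, subjects) {
  panel <- pgx_panel()
  freqs <- config$allele_freqs
  rsids <- unique(freqs$rsid)
  missing_panel <- setdiff(rsids, panel$rsid)
  if (length(missing_panel) > 0) {
    stop("allele_freqs contain rsids not in the panel: ",
         paste(missing_panel, collapse = ", "))
  }
  need <- tidyr::expand_grid(rsid = rsids, race = unique(subjects$race))
  have <- paste(freqs$rsid, freqs$race)
  lacking <- need[!paste(need$rsid, need$race) %in% have, ]
  if (nrow(lacking) > 0) {
    stop("no allele frequency for: ",
         paste(paste(lacking$rsid, lacking$race), collapse = ", "))
  }
  grid <- tidyr::expand_grid(subject_id = subjects$subject_id, rsid = rsids)
  grid$race <- subjects$race[match(grid$subject_id, subjects$subject_id)]
  grid <- dplyr::left_join(grid, freqs, by = c("rsid", "race"))
  pi <- match(grid$rsid, panel$rsid)
  n <- nrow(grid)
  a1 <- stats::runif(n) < grid$freq
  a2 <- stats::runif(n) < grid$freq
  tibble::tibble(
    subject_id = grid$subject_id,
    gene = panel$gene[pi],
    rsid = grid$rsid,
    allele1 = ifelse(a1, panel$alt[pi], panel$ref[pi]),
    allele2 = ifelse(a2, panel$alt[pi], panel$ref[pi])
  )
}

#' Mask genotype calls as missing
#'
#' Independent Bernoulli masking per (subject, variant), emulating partial
#' genotyping panels and amplification failures; masked calls become `"."`.
#'
#' @param genotypes Long genotype tibble.
#' @param rate Masking probability.
#' @return The tibble with masked calls.
#' @export
mask_missing_calls <- function(genotypes, rate) {
  stopifnot(rate >= 0, rate <= 1)
  mask <- stats::runif(nrow(genotypes)) < rate
  genotypes$allele1[mask] <- "."
  genotypes$allele2[mask] <- "."
  genotypes
}

#' One-compartment oral concentration profile (closed form)
#'
#' First-order absorption and elimination:
#' C(t) = D ka / (V_F (ka - ke)) (exp(-ke t) - exp(-ka t)) with
#' ke = CL_F / V_F. Dose in mg is converted to ng and volume to mL so the
#' result is in ng/mL. The degenerate ka = ke case is rejected.
#'
#' @param t Times (h).
#' @param dose Dose (mg).
#' @param cl_f Apparent clearance (L/h).
#' @param v_f Apparent volume (L).
#' @param ka Absorption rate constant (1/h).
#' @return Concentrations (ng/mL).
#' @export
one_compartment_conc <- function(t, dose, cl_f, v_f, ka) {
  stopifnot(dose > 0, cl_f > 0, v_f > 0, ka > 0)
  ke <- cl_f / v_f
  if (abs(ka - ke) < 1e-10) {
    stop("ka equals ke (flip-flop degenerate case); not supported")
  }
  dose_ng <- dose * 1e6
  v_ml <- v_f * 1000
  dose_ng * ka / (v_ml * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Simulate one concentration-time profile
#'
#' Evaluates the closed-form one-compartment curve at the schedule's times,
#' applies multiplicative log-normal assay noise (mean-one), and marks values
#' below the quantification limit as missing. The pre-dose sample is exactly
#' zero.
#'
#' @param subject_id Subject identifier.
#' @param dose Dose (mg).
#' @param pk List with subject-level `cl_f`, `v_f`, `ka`.
#' @param times Sampling times (h), first must be 0.
#' @param residual_cv Proportional assay-noise CV (0 for noise-free).
#' @param lloq Lower limit of quantification (ng/mL).
#' @param schedule_id Schedule label carried into the output.
#' @return Tibble `subject_id`, `schedule_id`, `time_h`, `conc_ng_ml`
#'   (`NA` = below LLOQ).
#' @export
simulate_profile <- function(subject_id, dose, pk, times, residual_cv = 0,
                             lloq = 0, schedule_id = NA_character_) {
  stopifnot(times[1] == 0, !is.unsorted(times, strictly = TRUE))
  conc <- one_compartment_conc(times, dose, pk$cl_f, pk$v_f, pk$ka)
  if (residual_cv > 0) {
    sdlog <- sqrt(log(1 + residual_cv^2))
    noise <- stats::rlnorm(length(conc), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    conc <- conc * noise
  }
  conc[1] <- 0  # pre-dose
  if (lloq > 0) conc[conc < lloq & seq_along(conc) > 1] <- NA_real_
  tibble::tibble(subject_id = subject_id, schedule_id = schedule_id,
                 time_h = times, conc_ng_ml = conc)
}

# True genotype-group labels used for effect multipliers, computed from the
# unmasked genotypes: SLCO1B1 phenotype from the rs4149056 variant-allele
# count and the CYP3A5 *3-style genotype from the count of loss-of-function
# alleles (*3 or *6).
truth_labels <- function(genotypes) {
  count_alt <- function(rsid, alt) {
    g <- genotypes[genotypes$rsid == rsid, ]
    stats::setNames((g$allele1 == alt) + (g$allele2 == alt), g$subject_id)
  }
  panel <- pgx_panel()
  alt_of <- function(rsid) panel$alt[panel$rsid == rsid]
  n5 <- count_alt("rs4149056", alt_of("rs4149056"))
  slco <- c("NF", "DF", "PF")[pmin(n5, 2) + 1L]
  lof <- count_alt("rs776746", alt_of("rs776746"))
  if ("rs10264272" %in% genotypes$rsid) {
    lof <- lof + count_alt("rs10264272", alt_of("rs10264272"))[names(lof)]
  }
  cyp <- c("*1/*1", "*1/*3", "*3/*3")[pmin(lof, 2) + 1L]
  tibble::tibble(subject_id = names(n5), slco1b1 = slco, cyp3a5 = cyp)
}

# Per-subject structural PK parameters: weight-proportional CL_F and V_F,
# correlated log-normal between-subject variability, and genotype multipliers
# acting on bioavailability (CL_F and V_F jointly) or on clearance alone.
simulate_pk_params <- function(config, subjects, labels) {
  base <- config$pk_base
  n <- nrow(subjects)
  sdlog <- sqrt(log(1 + config$bsv_cv^2))
  rho <- config$bsv_corr_cl_v
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  eta_cl <- sdlog[["cl_f"]] * z1
  eta_v <- sdlog[["v_f"]] * (rho * z1 + sqrt(1 - rho^2) * z2)
  eta_ka <- stats::rnorm(n, 0, sdlog[["ka"]])
  mult <- rep(1, n)
  em <- config$effect_multipliers
  for (g in unique(em$gene)) {
    lab <- labels[[tolower(g)]]
    if (is.null(lab)) next
    sub_em <- em[em$gene == g, ]
    m <- sub_em$cl_mult[match(lab, sub_em$level)]
    m[is.na(m)] <- 1
    mult <- mult * m
  }
  wscale <- subjects$weight / base$ref_weight
  v_mult <- if (config$genotype_effect == "bioavailability") mult else 1
  tibble::tibble(
    subject_id = subjects$subject_id,
    cl_mult = mult,
    cl_f = base$cl_f * wscale * mult * exp(eta_cl),
    v_f = base$v_f * wscale * v_mult * exp(eta_v),
    ka = base$ka * exp(eta_ka)
  )
}

#' Simulate adverse-drug-reaction indicators
#'
#' Bernoulli indicators per subject: gastrointestinal symptoms at the
#' configured per-arm probability, headache at the per-sex probability,
#' myalgia/arthralgia uniformly.
#'
#' @param config A [simulation_config()].
#' @param subjects Output of [sample_demographics()].
#' @return Tibble `subject_id`, `adr_gi`, `adr_headache`, `adr_myalgia`,
#'   `adr_any` (0/1 integers).
#' @export
simulate_adr <- function(config, subjects) {
  r <- config$adr_rates
  gi_p <- r$gi[subjects$arm]
  gi_p[is.na(gi_p)] <- 0
  hd_p <- r$headache[subjects$sex]
  hd_p[is.na(hd_p)] <- 0
  gi <- as.integer(stats::runif(nrow(subjects)) < gi_p)
  hd <- as.integer(stats::runif(nrow(subjects)) < hd_p)
  my <- as.integer(stats::runif(nrow(subjects)) < r$myalgia)
  tibble::tibble(subject_id = subjects$subject_id, adr_gi = gi,
                 adr_headache = hd, adr_myalgia = my,
                 adr_any = as.integer(gi | hd | my))
}

#' Simulate a complete cohort
#'
#' Seeds the generator once and draws, in order: demographics and trial-arm
#' assignment, genotypes in Hardy-Weinberg equilibrium, genotype-dependent
#' subject-level PK parameters, concentration-time profiles with assay noise
#' and LLOQ censoring, ADR indicators, and a missing-call-masked copy of the
#' genotypes for the translation layer to impute.
#'
#' @param config A [simulation_config()].
#' @return A list: `config`, `subjects`, `genotypes` (masked),
#'   `genotypes_true`, `truth` (true genotype-group labels and multipliers),
#'   `pk_params`, `profiles`, `adr`.
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  subjects <- sample_demographics(config)
  genotypes_true <- sample_genotypes(config, subjects)
  labels <- truth_labels(genotypes_true)
  labels <- labels[match(subjects$subject_id, labels$subject_id), ]
  pk <- simulate_pk_params(config, subjects, labels)
  sched <- default_schedules()
  profs <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    profs[[i]] <- simulate_profile(
      subjects$subject_id[i], subjects$dose[i],
      list(cl_f = pk$cl_f[i], v_f = pk$v_f[i], ka = pk$ka[i]),
      times = sched[[subjects$schedule[i]]],
      residual_cv = config$residual_cv, lloq = config$lloq,
      schedule_id = subjects$schedule[i]
    )
  }
  adr <- simulate_adr(config, subjects)
  genotypes <- mask_missing_calls(genotypes_true, config$missing_rate)
  list(config = config, subjects = subjects, genotypes = genotypes,
       genotypes_true = genotypes_true,
       truth = dplyr::left_join(labels,
                                pk[, c("subject_id", "cl_mult")],
                                by = "subject_id"),
       pk_params = pk, profiles = dplyr::bind_rows(profs), adr = adr)
}

#' Write the simulated cohort to CSV files
#'
#' Writes cohort, genotype (long format, `"."` for missing), profile and ADR
#' CSVs plus the configuration as YAML; every CSV starts with a comment line
#' recording the seed.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- paste0("# seed: ", sim$config$seed)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    con <- file(path, "w")
    writeLines(seed_line, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  geno <- sim$genotypes
  geno$allele1[is.na(geno$allele1)] <- "."
  geno$allele2[is.na(geno$allele2)] <- "."
  prof <- sim$profiles
  prof$conc_ng_ml <- ifelse(is.na(prof$conc_ng_ml), "BLQ",
                            as.character(prof$conc_ng_ml))
  paths <- c(
    cohort = wr(sim$subjects, "cohort.csv"),
    genotypes = wr(geno, "genotypes.csv"),
    profiles = wr(prof, "profiles.csv"),
    adr = wr(sim$adr, "adr.csv")
  )
  cfg <- sim$config
  cfg$trial_arms <- as.data.frame(cfg$trial_arms)
  cfg$allele_freqs <- as.data.frame(cfg$allele_freqs)
  cfg$effect_multipliers <- as.data.frame(cfg$effect_multipliers)
  cfg$demographics <- as.data.frame(cfg$demographics)
  # named vectors must become maps, or YAML drops the names
  cfg$race_probs <- as.list(cfg$race_probs)
  cfg$bsv_cv <- as.list(cfg$bsv_cv)
  cfg$adr_rates <- lapply(cfg$adr_rates, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(c(paths, config = file.path(dir, "config.yaml")))
}
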
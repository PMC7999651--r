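# Fixture builders shared across the suite: call tables built in code, small
# configs, and closed-form one-compartment oracles independent of the
# package's profile generator.

# a complete homozygous-reference call set for one subject over the panel
ref_calls <- function(subject_id = "S1", genes = NULL) {
  panel <- pgx_panel()
  if (!is.null(genes)) panel <- panel[panel$gene %in% genes, ]
  tibble::tibble(
    subject_id = subject_id, gene = panel$gene, rsid = panel$rsid,
    allele1 = panel$ref, allele2 = panel$ref
  )
}

# override specific calls: alleles like c(rs4149056 = "T/C")
with_calls <- function(calls, overrides) {
  for (rsid in names(overrides)) {
    parts <- strsplit(overrides[[rsid]], "/", fixed = TRUE)[[1]]
    i <- calls$rsid == rsid
    calls$allele1[i] <- parts[1]
    calls$allele2[i] <- parts[2]
  }
  calls
}

# small single-arm configuration for fast simulation tests
small_config <- function(n = 40L, seed = 1L, ...) {
  simulation_config(
    n_subjects = n,
    trial_arms = tibble::tibble(arm = "A", n = as.integer(n),
                                schedule = "s48", dose = 80,
                                ezetimibe = FALSE),
    seed = seed, ...
  )
}

# analytic one-compartment quantities (independent oracle)
oracle_conc <- function(t, dose_mg, cl_f, v_f, ka) {
  ke <- cl_f / v_f
  a <- dose_mg * 1e6 * ka / (v_f * 1000 * (ka - ke))
  a * (exp(-ke * t) - exp(-ka * t))
}
oracle_tmax <- function(cl_f, v_f, ka) {
  ke <- cl_f / v_f
  log(ka / ke) / (ka - ke)
}
oracle_auc_inf <- function(dose_mg, cl_f) dose_mg * 1e6 / (cl_f * 1000)
oracle_auc_t <- function(T, dose_mg, cl_f, v_f, ka) {
  ke <- cl_f / v_f
  a <- dose_mg * 1e6 * ka / (v_f * 1000 * (ka - ke))
  a * ((1 - exp(-ke * T)) / ke - (1 - exp(-ka * T)) / ka)
}
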
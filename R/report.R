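# Cohort-style summary tables and the end-to-end pipeline driver.

#' Stratified summary table (n, mean, CV%)
#'
#' Builds the cohort-table layout used to report PK parameters and
#' demographics: one row per stratum level plus a Total row, with the group
#' size, arithmetic mean and CV% of each requested column, all on the
#' untransformed scale (inference runs on logs, but tables print arithmetic
#' means). Rendering is pure: the same inputs give byte-identical output.
#'
#' @param dataset Analysis dataset.
#' @param stratifier Categorical column to stratify on.
#' @param columns Numeric columns to summarise.
#' @param total Append the overall row (default `TRUE`).
#' @return Tibble: `level`, `n`, then `<col>_mean` and `<col>_cv` per column.
#' @export
group_summary <- function(dataset, stratifier, columns, total = TRUE) {
  stopifnot(stratifier %in% names(dataset), all(columns %in% names(dataset)))
  g <- dataset[[stratifier]]
  lv <- if (is.factor(g)) levels(g) else sort(unique(as.character(g)))
  g <- as.character(g)
  one <- function(label, idx) {
    row <- tibble::tibble(level = label, n = length(idx))
    for (col in columns) {
      v <- dataset[[col]][idx]
      row[[paste0(col, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(col, "_cv")]] <- cv_percent(v)
    }
    row
  }
  rows <- lapply(lv, function(l) one(l, which(g == l)))
  if (total) rows <- c(rows, list(one("Total", seq_len(nrow(dataset)))))
  dplyr::bind_rows(rows)
}

#' Render a summary table as Markdown
#'
#' Means and CV% are printed to one decimal (the conventional table
#' precision); full precision is preserved in the CSV outputs.
#'
#' @param tab Output of [group_summary()].
#' @return Character vector of Markdown lines.
#' @export
render_markdown_table <- function(tab) {
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, format = "f", digits = 1))
    else as.character(x)
  }
  cells <- vapply(tab, fmt, character(nrow(tab)))
  cells <- matrix(cells, nrow = nrow(tab))
  header <- paste0("| ", paste(names(tab), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

set_reference_level <- function(x, ref) {
  x <- as.character(x)
  lv <- unique(x[!is.na(x)])
  stats::relevel(factor(x, levels = sort(lv)), ref = intersect(ref, lv)[1])
}

#' Run the full simulate-translate-NCA-statistics pipeline
#'
#' Executes the whole analysis end to end on a simulated cohort: genotype
#' translation (with missing-call imputation), non-compartmental PK,
#' dose/weight normalisation, univariate screening, the Bonferroni-corrected
#' multivariate stage (one model per PK outcome, all screened-in variables
#' entered, SLCO1B1 decreased- and poor-function carriers pooled into one
#' term), Hardy-Weinberg scanning, ADR incidence and logistic analyses, and
#' cohort-style summary tables. Variables measured on less than
#' `min_coverage` of subjects are excluded from the multivariate stage and
#' the exclusion is logged.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory; when given, all intermediate
#'   CSVs, Markdown tables and a JSON manifest (package version, seed, arm
#'   sizes, file checksums) are written there.
#' @param outcomes PK outcome columns analysed (default the six cohort-table
#'   parameters).
#' @param grouping_vars Candidate categorical variables for the screen.
#' @param alpha Univariate screening level (default 0.05).
#' @param min_coverage Minimum fraction of subjects a variable must be
#'   non-missing on to enter the multivariate stage (default 0.5).
#' @return A list: `sim`, `phenotypes`, `nca`, `dataset`, `univariate`,
#'   `screened`, `k`, `alpha_star`, `multivariate` (per outcome),
#'   `excluded_predictors`, `hwe`, `adr_tests`, `tables`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         outcomes = c("auc_dw", "cmax_dw", "tmax", "t_half",
                                      "vd_f_w", "cl_f_w"),
                         grouping_vars = c("sex", "arm", "ezetimibe",
                                           "race_merged", "slco1b1",
                                           "cyp3a5_star3", "slc22a1_star2",
                                           "slc22a1_star5",
                                           "ugt2b7_rs7439366"),
                         alpha = 0.05, min_coverage = 0.5) {
  sim <- simulate_cohort(config)
  phen <- translate_genotypes(sim$genotypes)
  nca <- run_nca(sim$profiles, sim$subjects, lloq = config$lloq)
  ds <- build_analysis_dataset(sim$subjects, nca, phen, sim$genotypes,
                               adr = sim$adr)
  uni <- univariate_screen(ds, outcomes, grouping_vars)

  # variables screened into the multivariate stage: significant for at least
  # one outcome, with adequate coverage; k sets the Bonferroni threshold
  sig <- uni[!is.na(uni$p) & uni$p < alpha, ]
  screened <- unique(sig$group_var)
  coverage <- vapply(grouping_vars,
                     function(v) mean(!is.na(ds[[v]])), numeric(1))
  excluded <- screened[coverage[screened] < min_coverage]
  screened <- setdiff(screened, excluded)

  # reference levels fixed so coefficient signs are interpretable
  refs <- c(sex = "F", race_merged = "Caucasian", slco1b1 = "NF",
            cyp3a5_star3 = "*3/*3", slc22a1_star2 = "*1/*1",
            slc22a1_star5 = "*1/*1", ugt2b7_rs7439366 = "*1/*1")
  md <- ds
  md$ezetimibe <- factor(md$ezetimibe, levels = c(FALSE, TRUE))
  for (v in intersect(names(refs), names(md))) {
    md[[v]] <- set_reference_level(md[[v]], refs[[v]])
  }
  if ("slco1b1" %in% screened) {
    md$slco1b1 <- set_reference_level(
      combine_levels(as.character(md$slco1b1), c("DF", "PF")), "NF")
  }

  # drop predictors whose indicator columns are linear combinations of
  # earlier ones (e.g. the ezetimibe flag is exactly the ezetimibe trial
  # arm); the exclusion is logged rather than silently absorbed
  collinear <- character(0)
  if (length(screened) >= 2L) {
    fml <- stats::as.formula(paste("~",
                                   paste(sprintf("`%s`", screened),
                                         collapse = " + ")))
    mm <- stats::model.matrix(fml, data = md[stats::complete.cases(
      md[, screened, drop = FALSE]), screened, drop = FALSE])
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      aliased_cols <- colnames(mm)[-qr_mm$pivot[seq_len(qr_mm$rank)]]
      asgn <- attr(mm, "assign")[match(aliased_cols, colnames(mm))]
      collinear <- unique(screened[asgn])
      screened <- setdiff(screened, collinear)
    }
  }
  excluded <- c(excluded, collinear)
  # the Bonferroni divisor counts every variable introduced into the
  # multivariate stage, including aliased ones that cannot get a coefficient
  k <- length(screened) + length(collinear)
  multiv <- list()
  if (k >= 1) {
    for (oc in outcomes) {
      multiv[[oc]] <- multivariate_model(md, oc, screened, k = k)
    }
  }

  hwe <- hwe_scan(sim$genotypes)
  adr_tests <- list(
    gi_by_arm = adr_incidence_test(ds, "adr_gi", "arm"),
    headache_by_sex = adr_incidence_test(ds, "adr_headache", "sex"),
    headache_logistic = adr_logistic(md, "adr_headache",
                                     c("sex", "log_auc_dw"))
  )

  table_cols <- c("auc_dw", "cmax_dw", "tmax", "t_half", "vd_f_w", "cl_f_w")
  tables <- list(
    demographics = group_summary(ds, "sex", c("weight", "bmi", "height", "age")),
    by_sex = group_summary(ds, "sex", table_cols),
    by_trial = group_summary(ds, "arm", table_cols),
    by_slco1b1 = group_summary(ds, "slco1b1", table_cols),
    by_cyp3a5 = group_summary(ds, "cyp3a5_star3", table_cols)
  )

  manifest <- list(
    package = "statinpgx",
    version = as.character(utils::packageVersion("statinpgx")),
    seed = config$seed,
    n_subjects = config$n_subjects,
    arm_sizes = stats::setNames(as.list(config$trial_arms$n),
                                config$trial_arms$arm),
    k_multivariate = k,
    alpha_star = if (k >= 1) bonferroni_alpha(k) else NA,
    excluded_predictors = as.list(excluded)
  )

  res <- list(sim = sim, phenotypes = phen, nca = nca, dataset = ds,
              univariate = uni, screened = screened, k = k,
              alpha_star = manifest$alpha_star, multivariate = multiv,
              excluded_predictors = excluded, hwe = hwe,
              adr_tests = adr_tests, tables = tables, manifest = manifest)

  if (!is.null(out_dir)) {
    res$manifest <- write_report_bundle(res, out_dir)
    res$manifest_path <- file.path(out_dir, "manifest.json")
  }
  res
}

flatten_univariate <- function(uni) {
  out <- uni[, c("outcome", "group_var", "test", "statistic", "p",
                 "n_analyzed", "flags")]
  out
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(res$sim, out_dir)
  paths <- character(0)
  put <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    paths[length(paths) + 1L] <<- path
  }
  put(res$phenotypes, "phenotypes.csv")
  put(res$nca, "nca.csv")
  put(flatten_univariate(res$univariate), "univariate.csv")
  if (length(res$multivariate) > 0) {
    mv <- dplyr::bind_rows(lapply(names(res$multivariate), function(oc) {
      co <- res$multivariate[[oc]]$coefficients
      co$outcome <- oc
      co$r_squared <- res$multivariate[[oc]]$r_squared
      co
    }))
    put(mv, "multivariate.csv")
  }
  put(res$hwe, "hwe.csv")
  for (nm in names(res$tables)) {
    put(res$tables[[nm]], paste0("table_", nm, ".csv"))
    writeLines(render_markdown_table(res$tables[[nm]]),
               file.path(out_dir, paste0("table_", nm, ".md")))
  }
  manifest <- res$manifest
  files <- list.files(out_dir, pattern = "\\.(csv|md)$", full.names = TRUE)
  manifest$checksums <- as.list(stats::setNames(
    unname(tools::md5sum(sort(files))), basename(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}
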
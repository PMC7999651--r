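# Two-stage inference pipeline: dose/weight normalisation and log transforms,
# univariate screening (t test / one-way ANOVA with Bonferroni post-hoc),
# Bonferroni-corrected multivariate regression, ADR contingency and logistic
# analyses, and Hardy-Weinberg equilibrium testing.

#' Dose/weight-normalised exposure and log transforms
#'
#' Fixed-dose trials dose every subject the same number of milligrams, so
#' lighter subjects receive a higher mg/kg dose and show higher exposure for
#' purely dosimetric reasons. Dividing AUC and Cmax by the dose/weight ratio
#' (AUC/DW = AUC * W / D) removes that artifact. Natural-log transforms of
#' all PK parameters are added for inference (defined only where positive).
#'
#' @param dataset Tibble with `auc_inf`, `cmax`, `dose`, `weight` and
#'   (optionally) `tmax`, `t_half`, `vd_f_w`, `cl_f_w`.
#' @return The dataset with `auc_dw`, `cmax_dw` and `log_*` columns added.
#' @export
normalize_exposure <- function(dataset) {
  stopifnot(all(c("auc_inf", "cmax", "dose", "weight") %in% names(dataset)))
  if (any(dataset$dose <= 0 | dataset$weight <= 0, na.rm = TRUE)) {
    stop("dose and weight must be positive")
  }
  dw <- dataset$dose / dataset$weight
  dataset$auc_dw <- dataset$auc_inf / dw
  dataset$cmax_dw <- dataset$cmax / dw
  for (col in intersect(c("auc_inf", "cmax", "auc_dw", "cmax_dw", "tmax",
                          "t_half", "vd_f_w", "cl_f_w"), names(dataset))) {
    v <- dataset[[col]]
    dataset[[paste0("log_", col)]] <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
  }
  dataset
}

#' Assemble the per-subject analysis dataset
#'
#' Joins subject covariates, NCA results, phenotype assignments and ADR
#' indicators into one row per subject; derives the categorical analysis
#' columns (SLCO1B1 phenotype, CYP3A5 *3 genotype, per-allele SLC22A1 *2/*5
#' and UGT2B7 rs7439366 genotypes, merged race) and the dose/weight-corrected
#' exposures with log transforms.
#'
#' @param subjects Subject tibble (`subject_id`, `sex`, `race`, `weight`,
#'   `dose`, `arm`, `ezetimibe`, ...).
#' @param nca Output of [run_nca()].
#' @param phenotypes Output of [translate_genotypes()].
#' @param genotypes Long genotype tibble (used for per-allele genotype
#'   columns; imputed internally).
#' @param adr Optional ADR tibble (`subject_id`, `adr_*`).
#' @param merge_race_below Merge race levels rarer than this into one
#'   combined level (default 6).
#' @return One-row-per-subject tibble ready for [univariate_screen()] and
#'   [multivariate_model()].
#' @export
build_analysis_dataset <- function(subjects, nca, phenotypes, genotypes,
                                   adr = NULL, merge_race_below = 6L) {
  stopifnot(!anyDuplicated(subjects$subject_id))
  ds <- dplyr::left_join(subjects, nca, by = "subject_id")
  pick_pheno <- function(gene, field = "phenotype") {
    ph <- phenotypes[phenotypes$gene == gene, ]
    ph[[field]][match(ds$subject_id, ph$subject_id)]
  }
  ds$slco1b1 <- pick_pheno("SLCO1B1")
  ds$cyp3a5_expresser <- pick_pheno("CYP3A5")
  imputed <- impute_missing(genotypes)
  add_star <- function(col, gene, allele) {
    sg <- star_genotype(gene, allele, imputed)
    ds[[col]] <<- sg$genotype[match(ds$subject_id, sg$subject_id)]
  }
  add_star("cyp3a5_star3", "CYP3A5", "*3")
  add_star("slc22a1_star2", "SLC22A1", "*2")
  add_star("slc22a1_star5", "SLC22A1", "*5")
  add_star("ugt2b7_rs7439366", "UGT2B7", "*2")
  ds$race_merged <- merge_sparse_levels(ds$race, min_n = merge_race_below)
  if (!is.null(adr)) ds <- dplyr::left_join(ds, adr, by = "subject_id")
  ds$ezetimibe <- as.logical(ds$ezetimibe)
  normalize_exposure(ds)
}

group_descriptives <- function(x, g) {
  lv <- unique(g)
  tibble::tibble(
    level = lv,
    n = vapply(lv, function(l) sum(g == l), integer(1), USE.NAMES = FALSE),
    mean = vapply(lv, function(l) mean(x[g == l]), numeric(1),
                  USE.NAMES = FALSE),
    cv = vapply(lv, function(l) cv_percent(x[g == l]), numeric(1),
                USE.NAMES = FALSE)
  )
}

# equal-variance two-sample t test with deterministic degenerate handling:
# identical constant samples give t = 0, p = 1 instead of an error.
t_test_log <- function(y, g, welch = FALSE) {
  lv <- unique(g)
  y1 <- y[g == lv[1]]
  y2 <- y[g == lv[2]]
  if (stats::var(y1) + stats::var(y2) == 0) {
    if (mean(y1) == mean(y2)) {
      return(list(statistic = 0, p = 1, flag = "constant_outcome"))
    }
    return(list(statistic = NA_real_, p = NA_real_,
                flag = "zero_within_group_variance"))
  }
  tt <- stats::t.test(y1, y2, var.equal = !welch)
  list(statistic = unname(tt$statistic), p = tt$p.value, flag = NA_character_)
}

#' Univariate screening of PK parameters over categorical variables
#'
#' The first inference stage: each outcome is log-transformed and compared
#' across the levels of each grouping variable with an equal-variance two-
#' sided t test (two levels) or a one-way ANOVA followed by Bonferroni-
#' adjusted pairwise comparisons (three or more levels). Group descriptives
#' (n, arithmetic mean, CV%) are reported on the untransformed scale. Levels
#' with fewer than two observations are reported descriptively and excluded
#' from the test.
#'
#' @param dataset Analysis dataset (see [build_analysis_dataset()]).
#' @param outcomes Character vector of positive outcome columns (e.g.
#'   `"auc_dw"`); tests run on their natural logs.
#' @param grouping_vars Character vector of categorical columns.
#' @param welch Use Welch instead of pooled-variance t tests (default off).
#' @return Tibble with one row per outcome x grouping variable: `outcome`,
#'   `group_var`, `test`, `statistic`, `p`, `n_analyzed`, `flags`, and
#'   list-columns `groups` (descriptives) and `posthoc` (Bonferroni-adjusted
#'   pairwise p values, ANOVA only).
#' @export
univariate_screen <- function(dataset, outcomes, grouping_vars, welch = FALSE) {
  rows <- list()
  for (outcome in outcomes) {
    for (gv in grouping_vars) {
      x <- dataset[[outcome]]
      g <- as.character(dataset[[gv]])
      ok <- !is.na(x) & !is.na(g) & x > 0
      x <- x[ok]
      g <- g[ok]
      desc <- if (length(x)) group_descriptives(x, g) else NULL
      tab <- table(g)
      testable <- names(tab)[tab >= 2L]
      keep <- g %in% testable
      y <- log(x[keep])
      gk <- g[keep]
      k_lv <- length(unique(gk))
      row <- tibble::tibble(
        outcome = outcome, group_var = gv, test = NA_character_,
        statistic = NA_real_, p = NA_real_, n_analyzed = length(y),
        flags = NA_character_
      )
      row$groups <- list(desc)
      row$posthoc <- list(NULL)
      if (length(testable) < length(tab)) {
        row$flags <- "sparse_levels_descriptive_only"
      }
      if (k_lv == 2L) {
        tt <- t_test_log(y, gk, welch = welch)
        row$test <- if (welch) "welch t" else "t"
        row$statistic <- tt$statistic
        row$p <- tt$p
        if (!is.na(tt$flag)) {
          row$flags <- paste(stats::na.omit(c(row$flags, tt$flag)),
                             collapse = ";")
        }
      } else if (k_lv >= 3L) {
        if (stats::var(y) == 0) {
          row$test <- "anova"
          row$statistic <- 0
          row$p <- 1
          row$flags <- paste(stats::na.omit(c(row$flags, "constant_outcome")),
                             collapse = ";")
        } else {
          fit <- stats::aov(y ~ factor(gk))
          an <- summary(fit)[[1]]
          row$test <- "anova"
          row$statistic <- an[["F value"]][1]
          row$p <- an[["Pr(>F)"]][1]
          ph <- stats::pairwise.t.test(y, gk, p.adjust.method = "bonferroni",
                                       pool.sd = TRUE)
          row$posthoc <- list(ph$p.value)
        }
      } else {
        row$flags <- paste(stats::na.omit(c(row$flags, "untestable")),
                           collapse = ";")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Bonferroni-corrected multivariate significance threshold
#'
#' The nominal 0.05 level divided by the number of predictors that survived
#' the univariate screen and entered the multivariate model.
#'
#' @param k Number of screened-in predictors (>= 1).
#' @return The corrected threshold 0.05 / k.
#' @export
bonferroni_alpha <- function(k) {
  stopifnot(k >= 1)
  0.05 / k
}

#' Multivariate linear model on a log-scale PK outcome
#'
#' The second inference stage: ordinary least squares of the log outcome on
#' the predictors that passed the univariate screen, with categorical
#' predictors coded by reference-level indicators. Coefficients are reported
#' unstandardised with per-coefficient p values and the model R-squared;
#' terms are flagged at the nominal 0.05 level and at the stricter
#' Bonferroni threshold 0.05/k separately. Rank deficiency is an error
#' naming the offending columns.
#'
#' @param dataset Analysis dataset.
#' @param outcome Positive outcome column; the model is fitted to its log.
#' @param predictors Character vector of screened-in predictor columns.
#' @param k Number of variables screened into the multivariate stage
#'   (defaults to `length(predictors)`), used for the Bonferroni threshold.
#' @return A list: `coefficients` tibble (`term`, `estimate`, `se`, `p`,
#'   `significant`, `significant_bonferroni`), `r_squared`, `k`,
#'   `alpha_star`, `n`.
#' @export
multivariate_model <- function(dataset, outcome, predictors,
                               k = length(predictors)) {
  stopifnot(length(predictors) >= 1)
  df <- dataset[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df) & df[[outcome]] > 0, , drop = FALSE]
  df$.y <- log(df[[outcome]])
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  alpha_star <- bonferroni_alpha(k)
  co <- sm$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    se = unname(co[, "Std. Error"]),
    p = unname(co[, "Pr(>|t|)"]),
    significant = unname(co[, "Pr(>|t|)"] < 0.05),
    significant_bonferroni = unname(co[, "Pr(>|t|)"] < alpha_star)
  )
  list(coefficients = coefs, r_squared = sm$r.squared, k = k,
       alpha_star = alpha_star, n = nrow(df), fit = fit)
}

#' Combine factor levels into one indicator level
#'
#' Convenience for contrasts that pool levels (e.g. pooling decreased- and
#' poor-function carriers against normal function in a regression term).
#'
#' @param x Character/factor vector.
#' @param levels Levels to pool.
#' @param label Name of the pooled level.
#' @return Character vector.
#' @export
combine_levels <- function(x, levels, label = paste(levels, collapse = "+")) {
  x <- as.character(x)
  x[x %in% levels] <- label
  x
}

#' Chi-square test of ADR incidence across groups
#'
#' Pearson contingency chi-square (no continuity correction) of a subject-
#' level event indicator against a categorical variable, with the share of
#' cases falling in each group reported alongside.
#'
#' @param dataset Analysis dataset.
#' @param adr Event indicator column (0/1).
#' @param group Categorical column.
#' @return A list: `statistic`, `df`, `p`, `observed` (table), `case_share`
#'   (named proportions of all cases per group).
#' @export
adr_incidence_test <- function(dataset, adr, group) {
  x <- dataset[[adr]]
  g <- as.character(dataset[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- g[ok]
  tab <- table(g, factor(x, levels = c(0, 1)))
  cases <- tab[, "1"]
  share <- if (sum(cases) > 0) cases / sum(cases) else cases * NA_real_
  if (sum(cases) == 0 || sum(tab[, "0"]) == 0) {
    return(list(statistic = 0, df = (nrow(tab) - 1), p = 1, observed = tab,
                case_share = share))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, observed = tab, case_share = share)
}

#' Logistic regression of an ADR with separation handling
#'
#' Multivariate logistic regression of an event indicator on screened-in
#' covariates. Complete or quasi-complete separation (e.g. an event absent
#' in one sex) makes the maximum-likelihood log-odds estimate diverge; the
#' fit is then flagged rather than reported as a huge coefficient, and a
#' ridge-penalised fit (small L2 penalty via glmnet) is offered as a
#' finite-coefficient fallback.
#'
#' @param dataset Analysis dataset.
#' @param adr Event indicator column (0/1).
#' @param predictors Character vector of predictor columns.
#' @param penalized Also compute the ridge-penalised fallback (default
#'   `TRUE` when separation is detected).
#' @param lambda Ridge penalty for the fallback (default 0.01).
#' @return A list: `coefficients` tibble (`term`, `estimate`, `se`, `p`),
#'   `separation` flag, `penalized_coefficients` (or `NULL`), `n`.
#' @export
adr_logistic <- function(dataset, adr, predictors, penalized = NULL,
                         lambda = 0.01) {
  df <- dataset[, c(adr, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  df$.y <- df[[adr]]
  if (length(unique(df$.y)) < 2L) {
    return(list(coefficients = NULL, separation = FALSE,
                penalized_coefficients = NULL, n = nrow(df),
                flag = "no_outcome_variation"))
  }
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", predictors),
                                       collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  if (any(abs(sm[, "Estimate"]) > 10 & sm[, "Std. Error"] > 100)) {
    separation <- TRUE
  }
  coefs <- tibble::tibble(term = rownames(sm),
                          estimate = unname(sm[, "Estimate"]),
                          se = unname(sm[, "Std. Error"]),
                          p = unname(sm[, "Pr(>|z|)"]))
  if (is.null(penalized)) penalized <- separation
  pen <- NULL
  if (penalized) {
    mm <- stats::model.matrix(fml, data = df)[, -1, drop = FALSE]
    if (ncol(mm) == 1L) {
      mm <- cbind(mm, `.pad` = 0)  # glmnet needs >= 2 columns
    }
    pen <- tryCatch({
      gfit <- glmnet::glmnet(mm, df$.y, family = "binomial", alpha = 0,
                             lambda = lambda)
      out <- tibble::tibble(
        term = c("(Intercept)", colnames(mm)),
        estimate = c(as.numeric(gfit$a0), as.numeric(gfit$beta))
      )
      out[out$term != ".pad", ]
    }, error = function(e) NULL)
  }
  list(coefficients = coefs, separation = separation,
       penalized_coefficients = pen, n = nrow(df), flag = NA_character_)
}

#' Exact Hardy-Weinberg test p value
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts and sums the probabilities of outcomes no more probable than the
#' observed one (the standard exact HWE test).
#'
#' @param counts Genotype counts `c(ref_hom, het, alt_hom)`.
#' @return Exact two-sided p value.
#' @export
hwe_exact_p <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  n_alt <- 2 * counts[3] + counts[2]
  n_ref <- 2 * n - n_alt
  rare <- min(n_alt, n_ref)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    bb <- (n_alt - h) / 2
    aa <- n - h - bb
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(n_alt + 1) + lgamma(n_ref + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(counts[2], hets)]
  sum(p[p <= obs + 1e-12])
}

#' Hardy-Weinberg equilibrium test for one variant
#'
#' Pearson's 1-df goodness-of-fit chi-square of the observed genotype counts
#' against the proportions p^2 : 2pq : q^2 expected from the sample allele
#' frequencies, plus the exact test by heterozygote-count enumeration.
#' Monomorphic variants carry no information about mating structure and are
#' flagged instead of tested.
#'
#' @param counts Genotype counts `c(ref_hom, het, alt_hom)`.
#' @param alpha Deviation threshold applied to the chi-square p (default
#'   0.05).
#' @return A tibble row: counts, `chisq`, `p_chisq`, `p_exact`,
#'   `monomorphic`, `deviating`.
#' @export
hwe_test <- function(counts, alpha = 0.05) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0)
  counts <- as.numeric(counts)
  n <- sum(counts)
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  mono <- q == 0 || q == 1
  if (mono) {
    return(tibble::tibble(n = n, ref_hom = counts[1], het = counts[2],
                          alt_hom = counts[3], allele_freq = q,
                          chisq = NA_real_, p_chisq = NA_real_,
                          p_exact = NA_real_, monomorphic = TRUE,
                          deviating = FALSE))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((counts - expected)^2 / expected)
  p_chisq <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  tibble::tibble(n = n, ref_hom = counts[1], het = counts[2],
                 alt_hom = counts[3], allele_freq = q, chisq = chisq,
                 p_chisq = p_chisq, p_exact = hwe_exact_p(counts),
                 monomorphic = FALSE, deviating = p_chisq < alpha)
}

#' Hardy-Weinberg scan over a genotype table
#'
#' Tallies genotype counts per variant from non-missing calls (using the
#' panel's ref/alt tokens) and runs [hwe_test()] on each.
#'
#' @param genotypes Long genotype tibble.
#' @param panel Panel tibble (default shipped panel).
#' @param alpha Deviation threshold.
#' @return One row per variant with counts and test results.
#' @export
hwe_scan <- function(genotypes, panel = pgx_panel(), alpha = 0.05) {
  rows <- list()
  for (rsid in unique(genotypes$rsid)) {
    prow <- panel[panel$rsid == rsid, , drop = FALSE]
    if (nrow(prow) == 0L) next
    g <- genotypes[genotypes$rsid == rsid, ]
    ok <- !is_missing_call(g$allele1, g$allele2)
    g <- g[ok, ]
    if (nrow(g) == 0L) next
    n_alt <- (g$allele1 == prow$alt[1]) + (g$allele2 == prow$alt[1])
    counts <- c(sum(n_alt == 0), sum(n_alt == 1), sum(n_alt == 2))
    res <- hwe_test(counts, alpha = alpha)
    res$rsid <- rsid
    res$gene <- prow$gene[1]
    rows[[length(rows) + 1L]] <- res
  }
  dplyr::bind_rows(rows) |>
    dplyr::relocate("gene", "rsid")
}
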
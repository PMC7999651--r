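#' Coefficient of variation in percent
#'
#' CV% = 100 * SD / mean, computed on the untransformed scale, the dispersion
#' measure used throughout cohort summary tables.
#'
#' @param x Numeric vector; `NA` values are dropped.
#' @return A single number (percent), or `NA` if fewer than two values.
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  100 * stats::sd(x) / mean(x)
}

#' Pooled mean of group means
#'
#' Recombines stratum means into the overall mean using the stratum sizes as
#' weights: sum(n_i * m_i) / sum(n_i). Group summaries are internally
#' consistent exactly when the stratified means recombine to the overall mean.
#'
#' @param n Integer vector of group sizes.
#' @param means Numeric vector of group means (same length as `n`).
#' @return The pooled (overall) mean.
#' @export
pooled_mean <- function(n, means) {
  stopifnot(length(n) == length(means), all(n >= 0))
  sum(n * means) / sum(n)
}

# Merge factor levels with fewer than `min_n` observations into one combined
# level, named by joining the merged level names with " or ". Mirrors the
# small-stratum handling needed when race groups are too sparse to test.
#' Merge sparse categorical levels
#'
#' Levels of `x` observed fewer than `min_n` times are collapsed into a single
#' combined level (named by joining the merged names with `" or "`), so that
#' downstream group comparisons have estimable within-group variances.
#'
#' @param x Character or factor vector.
#' @param min_n Minimum observations for a level to stand alone (default 6).
#' @return Character vector with sparse levels merged; returned unchanged
#'   when fewer than two levels are sparse.
#' @export
merge_sparse_levels <- function(x, min_n = 6L) {
  x <- as.character(x)
  tab <- table(x)
  small <- names(tab)[tab < min_n]
  if (length(small) < 2L) return(x)
  combined <- paste(small, collapse = " or ")
  x[x %in% small] <- combined
  x
}

# read a TSV with '#' comment headers (schema_version etc.)
read_schema_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(
    path, comment.char = "#", stringsAsFactors = FALSE,
    na.strings = c("NA", "")
  ))
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "statinpgx")
  if (!nzchar(p)) stop("extdata file not found: ", file)
  p
}

#' Reference cohort summary tables
#'
#' Loads the shipped group-level summary statistics of the reference
#' atorvastatin cohort (156 healthy volunteers, five 80 mg single-dose
#' bioequivalence trials): pharmacokinetic parameters by stratum,
#' demographics, and adverse-drug-reaction counts. These tables calibrate the
#' simulator defaults and serve as arithmetic inputs for consistency checks.
#'
#' @param which One of `"pk"`, `"demographics"`, `"adr"`.
#' @return A tibble in long format (stratifier, level, n, parameter, mean,
#'   dispersion) for `"pk"`/`"demographics"`; counts for `"adr"`.
#' @export
reference_summary <- function(which = c("pk", "demographics", "adr")) {
  which <- match.arg(which)
  file <- switch(which,
    pk = "reference_pk_summary.tsv",
    demographics = "reference_demographics.tsv",
    adr = "reference_adr.tsv"
  )
  read_schema_tsv(extdata_path(file))
}
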
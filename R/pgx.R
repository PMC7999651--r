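# Star-allele diplotype and phenotype translation.
#
# All allele/phenotype content is data-driven: the genotyping panel, allele
# definitions, and phenotype maps ship as versioned TSVs under extdata and are
# loaded (and cached) here. Nothing about a specific allele is hard-coded.

.pgx_cache <- new.env(parent = emptyenv())

pgx_tables <- function() {
  if (is.null(.pgx_cache$tables)) {
    .pgx_cache$tables <- list(
      panel    = read_schema_tsv(extdata_path("panel.tsv")),
      defs     = read_schema_tsv(extdata_path("allele_definitions.tsv")),
      methods  = read_schema_tsv(extdata_path("phenotype_methods.tsv")),
      counts   = read_schema_tsv(extdata_path("phenotype_counts.tsv")),
      cutpts   = read_schema_tsv(extdata_path("activity_cutpoints.tsv")),
      funcmaps = read_schema_tsv(extdata_path("phenotype_function_maps.tsv"))
    )
  }
  .pgx_cache$tables
}

#' Genotyping panel
#'
#' The candidate-gene variant panel: one row per genotyped variant with the
#' reference and variant allele tokens, the star allele the variant defines
#' (if any), whether it is carried as annotation only, and whether it belongs
#' to the reduced ABCB1 haplotype subset.
#'
#' @return A tibble with columns `gene`, `rsid`, `ref`, `alt`, `star_allele`,
#'   `annotation_only`, `core_haplotype`.
#' @export
pgx_panel <- function() pgx_tables()$panel

#' Star-allele definition table
#'
#' One row per named allele per gene: the defining variant (rsid and variant
#' allele), the functional classification (normal / decreased / no /
#' increased), the per-allele activity value for activity-score genes, and an
#' assignment priority. Reference alleles have no defining variant.
#'
#' @return A tibble with columns `gene`, `allele`, `rsid`, `variant_allele`,
#'   `function.` (functional class), `activity`, `priority`.
#' @export
allele_definitions <- function() pgx_tables()$defs

missing_tokens <- c(".", "", "fail", "FAIL", "Fail", "./.")

is_missing_call <- function(a1, a2) {
  is.na(a1) | is.na(a2) | a1 %in% missing_tokens | a2 %in% missing_tokens
}

#' Impute missing genotype calls to the reference allele
#'
#' Subjects genotyped on partial panels, and calls that failed amplification,
#' are completed by assuming the variant is "not mutated": every panel rsid
#' absent or unreadable for a subject is filled in as a homozygous-reference
#' call and flagged as imputed so downstream phenotype assignments can record
#' their provenance. The operation is idempotent.
#'
#' @param calls Tibble of variant calls: `subject_id`, `gene`, `rsid`,
#'   `allele1`, `allele2`. Missing calls are `NA`, `"."` or `"fail"`.
#' @param panel Panel tibble (default the shipped panel); defines the expected
#'   rsid set per gene.
#' @param genes Optional character vector restricting the expected set to
#'   these genes (default: all genes in the panel).
#' @return A tibble with one row per subject per expected rsid, columns as
#'   `calls` plus logical `imputed`.
#' @export
impute_missing <- function(calls, panel = pgx_panel(), genes = NULL) {
  stopifnot(all(c("subject_id", "gene", "rsid", "allele1", "allele2") %in%
                  names(calls)))
  bad <- setdiff(unique(calls$rsid), panel$rsid)
  if (length(bad) > 0) {
    stop("calls contain rsids not in the panel: ", paste(bad, collapse = ", "))
  }
  if (!is.null(genes)) panel <- panel[panel$gene %in% genes, ]
  grid <- tidyr::expand_grid(
    subject_id = unique(calls$subject_id),
    panel[, c("gene", "rsid", "ref")]
  )
  out <- dplyr::left_join(grid, calls[, c("subject_id", "rsid", "allele1", "allele2")],
                          by = c("subject_id", "rsid"))
  miss <- is_missing_call(out$allele1, out$allele2)
  out$imputed <- miss
  out$allele1[miss] <- out$ref[miss]
  out$allele2[miss] <- out$ref[miss]
  out$ref <- NULL
  out
}

# numeric-aware ordering of star-allele names: *1 < *1B < *3 < *5 < *41
star_order <- function(alleles) {
  num <- suppressWarnings(as.numeric(gsub("[^0-9].*$", "", sub("^\\*", "", alleles))))
  num[is.na(num)] <- Inf
  order(num, alleles)
}

reference_allele_for <- function(gene) {
  m <- pgx_tables()$methods
  hit <- m$reference_allele[m$gene == gene]
  if (length(hit) == 1L) hit else "*1"
}

# Count variant alleles per defined star allele for one subject's (imputed)
# calls of one gene.
allele_variant_counts <- function(gene, calls) {
  defs <- allele_definitions()
  defs <- defs[defs$gene == gene & !is.na(defs$rsid), , drop = FALSE]
  if (nrow(defs) == 0L) {
    return(defs[, c("allele", "priority")][0, ])
  }
  idx <- match(defs$rsid, calls$rsid)
  if (anyNA(idx)) {
    stop("calls for gene ", gene, " are incomplete; run impute_missing() first")
  }
  count <- (calls$allele1[idx] == defs$variant_allele) +
    (calls$allele2[idx] == defs$variant_allele)
  tibble::tibble(allele = defs$allele, count = as.integer(count),
                 priority = defs$priority)
}

#' Call a star-allele diplotype from imputed variant calls
#'
#' Counts variant alleles at each allele-defining site and fills the two
#' haplotype slots in priority order (loss-of-function alleles first);
#' unfilled slots take the gene's reference allele. With several heterozygous
#' single-variant alleles the trans configuration is assumed (one haplotype
#' each), the standard unphased star-allele convention. If more variant
#' alleles are present than can fit on two haplotypes, the call is truncated
#' by priority and flagged as a conflict.
#'
#' @param gene Gene symbol (must appear in the allele definition table).
#' @param calls Imputed calls for one subject covering the gene's defining
#'   rsids (see [impute_missing()]).
#' @return A list with `diplotype` (e.g. `"*1/*5"`), `alleles` (length-2
#'   character), and logical `conflict`.
#' @export
call_diplotype <- function(gene, calls) {
  counts <- allele_variant_counts(gene, calls[calls$gene == gene, ])
  ref <- reference_allele_for(gene)
  present <- counts[counts$count > 0, , drop = FALSE]
  present <- present[order(present$priority), , drop = FALSE]
  conflict <- sum(present$count) > 2L
  slots <- character(0)
  for (i in seq_len(nrow(present))) {
    room <- 2L - length(slots)
    if (room == 0L) break
    slots <- c(slots, rep(present$allele[i], min(present$count[i], room)))
  }
  slots <- c(slots, rep(ref, 2L - length(slots)))
  slots <- slots[star_order(slots)]
  list(diplotype = paste(slots, collapse = "/"), alleles = slots,
       conflict = conflict)
}

allele_meta <- function(gene, alleles) {
  defs <- allele_definitions()
  defs <- defs[defs$gene == gene, , drop = FALSE]
  idx <- match(alleles, defs$allele)
  if (anyNA(idx)) {
    stop("unknown allele(s) for ", gene, ": ",
         paste(alleles[is.na(idx)], collapse = ", "))
  }
  defs[idx, , drop = FALSE]
}

parse_diplotype <- function(diplotype) {
  parts <- strsplit(diplotype, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("diplotype must have two alleles: ", diplotype)
  parts
}

#' Assign a gene-level phenotype from a diplotype
#'
#' Applies the gene's configured assignment method (see
#' `phenotype_methods.tsv`): reduced-function allele counting (SLCO1B1),
#' expresser status (CYP3A5), activity score with cutpoints (CYP2D6, CYP2C9,
#' CYP1A2; the CYP2D6 score scales with gene copy number), or a CPIC-style
#' function-pair lookup (CYP2C19, CYP2B6). Genes configured `diplotype_only`
#' return an `NA` phenotype.
#'
#' @param gene Gene symbol.
#' @param diplotype Diplotype string (`"*1/*5"`) or length-2 allele vector.
#' @param copy_number Gene copy number (CYP2D6; default 2).
#' @return A list with `gene`, `diplotype`, `phenotype`, `activity_score`.
#' @export
assign_phenotype <- function(gene, diplotype, copy_number = 2L) {
  alleles <- if (length(diplotype) == 2L) diplotype else parse_diplotype(diplotype)
  tabs <- pgx_tables()
  m <- tabs$methods[tabs$methods$gene == gene, , drop = FALSE]
  method <- if (nrow(m) == 1L) m$method else "diplotype_only"
  meta <- allele_meta(gene, alleles)
  fun <- meta[["function."]]
  score <- NA_real_
  label <- NA_character_
  if (method == "decreased_count") {
    key <- sum(fun %in% c("decreased", "no"))
    map <- tabs$counts[tabs$counts$gene == gene & tabs$counts$method == method, ]
    label <- map$label[match(key, map$key)]
  } else if (method == "expresser") {
    key <- sum(fun == "normal")
    map <- tabs$counts[tabs$counts$gene == gene & tabs$counts$method == method, ]
    label <- map$label[match(key, map$key)]
  } else if (method == "activity_score") {
    if (anyNA(meta$activity)) {
      stop("activity values missing for ", gene)
    }
    score <- sum(meta$activity)
    if (isTRUE(m$uses_copy_number)) {
      if (copy_number < 0) stop("copy_number must be >= 0")
      score <- score / 2 * copy_number
    }
    cut <- tabs$cutpts[tabs$cutpts$gene == gene, , drop = FALSE]
    cut <- cut[order(cut$min_score), , drop = FALSE]
    i <- findInterval(score, cut$min_score)
    if (i < 1L) i <- 1L
    label <- cut$label[i]
  } else if (method == "cpic_function") {
    map <- tabs$funcmaps[tabs$funcmaps$gene == gene, , drop = FALSE]
    hit <- map$n_no == sum(fun == "no") &
      map$n_dec == sum(fun == "decreased") &
      map$n_inc == sum(fun == "increased")
    if (!any(hit)) {
      stop("no phenotype mapping for ", gene, " diplotype ",
           paste(alleles, collapse = "/"))
    }
    label <- map$label[hit][1]
  }
  list(gene = gene,
       diplotype = paste(alleles[star_order(alleles)], collapse = "/"),
       phenotype = label, activity_score = score)
}

#' SLCO1B1 transporter-function phenotype
#'
#' The OATP1B1 phenotype that drives statin dosing guidance: no
#' decreased-function (*5) allele gives normal function (NF), one gives
#' decreased function (DF), two give poor function (PF). The *1B allele is
#' treated as normal-function.
#'
#' @param diplotype Diplotype string over `{*1, *1B, *5}` (e.g. `"*1/*5"`).
#' @return Phenotype label: `"NF"`, `"DF"` or `"PF"`.
#' @export
assign_slco1b1_phenotype <- function(diplotype) {
  assign_phenotype("SLCO1B1", diplotype)$phenotype
}

#' CYP3A5 expresser status
#'
#' A carrier of at least one functional *1 allele (defined by the absence of
#' the *3 and *6 loss-of-function variants on that haplotype) expresses
#' CYP3A5; *3/*3, *3/*6 and *6/*6 carriers are non-expressers.
#'
#' @param diplotype Diplotype string over `{*1, *3, *6}`.
#' @return `"Expresser"` or `"Non-expresser"`.
#' @export
assign_cyp3a5_phenotype <- function(diplotype) {
  assign_phenotype("CYP3A5", diplotype)$phenotype
}

#' CYP2D6 activity score and metabolizer phenotype
#'
#' The activity score is the sum of the two alleles' activity values scaled
#' by gene copy number (score = (a1 + a2) / 2 * CN), so a whole-gene deletion
#' on both chromosomes scores 0 and a duplication raises the score. Cutpoints
#' mapping score to PM/IM/NM/UM live in the data table, not in code.
#'
#' @param diplotype Diplotype string (e.g. `"*4/*4"`).
#' @param copy_number Non-negative gene copy number (default 2).
#' @return A list with `activity_score` and `phenotype`.
#' @export
assign_cyp2d6_phenotype <- function(diplotype, copy_number = 2L) {
  res <- assign_phenotype("CYP2D6", diplotype, copy_number = copy_number)
  list(activity_score = res$activity_score, phenotype = res$phenotype)
}

#' Merge transporter variants into a composite haplotype label
#'
#' For multi-variant transporter genes (SLC22A1, ABCB1) the per-gene burden
#' is summarised by counting variant alleles across the gene's panel sites:
#' zero variant alleles give the wild-type haplotype, exactly one the
#' heterozygous haplotype, and two or more the mutant haplotype. A single
#' homozygous-variant site therefore already counts as mutant. For ABCB1 the
#' reduced three-variant subset (C3435T, G2677T/A, C1236T) can be used
#' instead of the full panel.
#'
#' @param gene `"SLC22A1"` or `"ABCB1"`.
#' @param calls Imputed calls for one subject covering the gene's panel sites.
#' @param core_only Use only the reduced ABCB1 subset (default `FALSE`).
#' @return `"wild-type"`, `"heterozygous"` or `"mutant"`.
#' @export
merge_transporter_haplotype <- function(gene, calls, core_only = FALSE) {
  stopifnot(gene %in% c("SLC22A1", "ABCB1"))
  panel <- pgx_panel()
  panel <- panel[panel$gene == gene, , drop = FALSE]
  if (core_only) {
    panel <- panel[panel$core_haplotype, , drop = FALSE]
  }
  calls <- calls[calls$gene == gene & calls$rsid %in% panel$rsid, , drop = FALSE]
  idx <- match(panel$rsid, calls$rsid)
  if (anyNA(idx)) {
    stop("calls for gene ", gene, " are incomplete; run impute_missing() first")
  }
  n_var <- sum((calls$allele1[idx] != panel$ref) + (calls$allele2[idx] != panel$ref))
  if (n_var == 0L) "wild-type" else if (n_var == 1L) "heterozygous" else "mutant"
}

#' Per-allele genotype label
#'
#' Collapses a subject's calls to the genotype with respect to one star
#' allele (the representation used when a gene's alleles are analysed
#' separately, e.g. SLC22A1 *2): zero, one or two copies of the allele give
#' `"*1/*1"`, `"*1/*2"`, `"*2/*2"`-style labels built from the reference
#' allele name.
#'
#' @param gene Gene symbol.
#' @param allele Star-allele name (e.g. `"*2"`).
#' @param calls Imputed calls (may contain several subjects).
#' @return Tibble `subject_id`, `genotype`.
#' @export
star_genotype <- function(gene, allele, calls) {
  defs <- allele_definitions()
  def <- defs[defs$gene == gene & defs$allele == allele, , drop = FALSE]
  if (nrow(def) != 1L || is.na(def$rsid)) {
    stop("no single defining variant for ", gene, " ", allele)
  }
  ref <- reference_allele_for(gene)
  sub <- calls[calls$rsid == def$rsid, , drop = FALSE]
  n <- (sub$allele1 == def$variant_allele) + (sub$allele2 == def$variant_allele)
  lab <- c(paste0(ref, "/", ref), paste0(ref, "/", allele),
           paste0(allele, "/", allele))[n + 1L]
  tibble::tibble(subject_id = sub$subject_id, genotype = lab)
}

#' Translate a genotype table into diplotypes and phenotypes
#'
#' The batch driver: imputes missing calls, calls each subject's diplotype
#' per gene, assigns the gene-level phenotype, and (optionally) appends the
#' merged transporter haplotypes as additional rows. Imputed rsids are
#' recorded per assignment so every call's provenance is preserved.
#'
#' @param genotypes Long genotype tibble: `subject_id`, `gene`, `rsid`,
#'   `allele1`, `allele2` (missing as `NA`/`"."`/`"fail"`).
#' @param copy_numbers Optional tibble `subject_id`, `gene`, `copy_number`
#'   (used for CYP2D6); subjects absent from it default to 2 copies.
#' @param genes Genes to translate (default: all panel genes present in
#'   the allele definition table).
#' @param include_haplotypes Append merged SLC22A1/ABCB1 haplotype rows
#'   (gene suffixed `"_haplotype"`, plus `"ABCB1_core"`).
#' @return Tibble: `subject_id`, `gene`, `diplotype`, `phenotype`,
#'   `activity_score`, `imputed_rsids` (semicolon-joined), `conflict`.
#' @export
translate_genotypes <- function(genotypes, copy_numbers = NULL, genes = NULL,
                                include_haplotypes = TRUE) {
  panel <- pgx_panel()
  def_genes <- unique(allele_definitions()$gene)
  if (is.null(genes)) genes <- intersect(unique(panel$gene), def_genes)
  imputed <- impute_missing(genotypes, panel = panel,
                            genes = union(genes,
                                          if (include_haplotypes)
                                            c("SLC22A1", "ABCB1") else character(0)))
  subjects <- unique(imputed$subject_id)
  rows <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    sc <- imputed[imputed$subject_id == s, , drop = FALSE]
    per_gene <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      gcalls <- sc[sc$gene == g, , drop = FALSE]
      if (nrow(gcalls) == 0L) next
      dip <- call_diplotype(g, gcalls)
      cn <- 2L
      if (!is.null(copy_numbers)) {
        hit <- copy_numbers$subject_id == s & copy_numbers$gene == g
        if (any(hit)) cn <- copy_numbers$copy_number[hit][1]
      }
      ph <- assign_phenotype(g, dip$alleles, copy_number = cn)
      per_gene[[gi]] <- tibble::tibble(
        subject_id = s, gene = g, diplotype = dip$diplotype,
        phenotype = ph$phenotype, activity_score = ph$activity_score,
        imputed_rsids = paste(gcalls$rsid[gcalls$imputed], collapse = ";"),
        conflict = dip$conflict
      )
    }
    hap <- NULL
    if (include_haplotypes) {
      hap <- tibble::tibble(
        subject_id = s,
        gene = c("SLC22A1_haplotype", "ABCB1_haplotype", "ABCB1_core"),
        diplotype = NA_character_,
        phenotype = c(merge_transporter_haplotype("SLC22A1", sc),
                      merge_transporter_haplotype("ABCB1", sc),
                      merge_transporter_haplotype("ABCB1", sc, core_only = TRUE)),
        activity_score = NA_real_,
        imputed_rsids = paste(
          sc$rsid[sc$imputed & sc$gene %in% c("SLC22A1", "ABCB1")],
          collapse = ";"),
        conflict = FALSE
      )
    }
    rows[[si]] <- dplyr::bind_rows(c(per_gene, list(hap)))
  }
  dplyr::bind_rows(rows)
}

#' Read a long-format genotype CSV
#'
#' Fixed dialect: comma-separated with header, columns `subject_id`, `gene`,
#' `rsid`, `allele1`, `allele2`, missing calls as `"."`.
#'
#' @param path CSV path.
#' @return Genotype tibble suitable for [translate_genotypes()].
#' @export
read_genotypes <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    na.strings = c("NA"), comment.char = "#"))
}

#' Read genotype calls from a VCF
#'
#' Optional VCF ingestion: unphased or phased GT fields are accepted, sample
#' columns become subjects, and alleles are translated to the panel's
#' ref/alt tokens by rsid (the VCF ID column). Variants whose ID is not in
#' the panel are dropped with a warning.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param panel Panel tibble (default the shipped panel).
#' @return Long genotype tibble (`subject_id`, `gene`, `rsid`, `allele1`,
#'   `allele2`).
#' @export
read_genotype_vcf <- function(path, panel = pgx_panel()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix$ID %in% panel$rsid
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " VCF records not in the panel")
  }
  rows <- list()
  for (i in which(keep)) {
    rsid <- fix$ID[i]
    prow <- panel[panel$rsid == rsid, , drop = FALSE][1, ]
    tokens <- c(prow$ref, prow$alt)  # 0 -> ref token, 1 -> alt token
    g <- gt[i, ]
    parts <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    a1 <- vapply(parts, function(p) p[1], character(1), USE.NAMES = FALSE)
    a2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 character(1), USE.NAMES = FALSE)
    to_tok <- function(a) {
      ifelse(is.na(a) | a == ".", NA_character_,
             tokens[as.integer(a) + 1L])
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subject_id = colnames(gt), gene = prow$gene, rsid = rsid,
      allele1 = to_tok(a1), allele2 = to_tok(a2)
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a per-subject phenotype CSV
#'
#' @param phenotypes Output of [translate_genotypes()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}
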
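# Genotype-to-phenotype translation: imputation, diplotype calling,
# phenotype assignment, haplotype merging, and the data-file round trip.

test_that("missing and failed calls are imputed to homozygous reference", {
  calls <- ref_calls(genes = "CYP3A5")
  calls <- calls[calls$rsid != "rs776746", ]  # absent call
  imp <- impute_missing(calls, genes = "CYP3A5")
  row <- imp[imp$rsid == "rs776746", ]
  expect_equal(nrow(row), 1L)
  expect_true(row$imputed)
  expect_equal(row$allele1, "A")  # reference: no *3 allele
  expect_equal(row$allele2, "A")
  # amplification-failure marker gets the same treatment
  calls2 <- with_calls(ref_calls(genes = "CYP3A5"), c(rs776746 = "fail/fail"))
  imp2 <- impute_missing(calls2, genes = "CYP3A5")
  expect_true(imp2$imputed[imp2$rsid == "rs776746"])
  expect_equal(imp2$allele1[imp2$rsid == "rs776746"], "A")
})

test_that("imputation is idempotent and complete call sets pass unchanged", {
  calls <- with_calls(ref_calls(genes = "SLCO1B1"), c(rs4149056 = "T/C"))
  once <- impute_missing(calls, genes = "SLCO1B1")
  twice <- impute_missing(once[, names(calls)], genes = "SLCO1B1")
  expect_identical(once$allele1, twice$allele1)
  expect_identical(once$allele2, twice$allele2)
  expect_false(any(once$imputed))
  expect_equal(once$allele1[once$rsid == "rs4149056"], "T")
})

test_that("rsids outside the panel are rejected with their identity", {
  calls <- tibble::tibble(subject_id = "S1", gene = "GENEX",
                          rsid = "rs0000001", allele1 = "A", allele2 = "A")
  expect_error(impute_missing(calls), "rs0000001")
})

test_that("diplotype calls reproduce the canonical statin-gene examples", {
  slco <- function(gt) {
    call_diplotype("SLCO1B1", impute_missing(
      with_calls(ref_calls(genes = "SLCO1B1"), c(rs4149056 = gt)),
      genes = "SLCO1B1"))$diplotype
  }
  expect_equal(slco("T/T"), "*1/*1")
  expect_equal(slco("T/C"), "*1/*5")
  expect_equal(slco("C/C"), "*5/*5")
  # absence of *3 and *6 variants defines *1/*1
  cyp <- call_diplotype("CYP3A5",
                        impute_missing(ref_calls(genes = "CYP3A5"),
                                       genes = "CYP3A5"))
  expect_equal(cyp$diplotype, "*1/*1")
  g33 <- with_calls(ref_calls(genes = "CYP3A5"), c(rs776746 = "G/G"))
  expect_equal(call_diplotype("CYP3A5", impute_missing(g33, genes = "CYP3A5"))$diplotype,
               "*3/*3")
  # two heterozygous single-variant alleles resolve in trans
  g36 <- with_calls(ref_calls(genes = "CYP3A5"),
                    c(rs776746 = "A/G", rs10264272 = "C/T"))
  expect_equal(call_diplotype("CYP3A5", impute_missing(g36, genes = "CYP3A5"))$diplotype,
               "*3/*6")
  # more variant alleles than haplotype slots is flagged as a conflict
  g_conf <- with_calls(ref_calls(genes = "CYP3A5"),
                       c(rs776746 = "G/G", rs10264272 = "C/T"))
  expect_true(call_diplotype("CYP3A5", impute_missing(g_conf, genes = "CYP3A5"))$conflict)
})

test_that("SLCO1B1 phenotype counts reduced-function alleles, *1B is normal", {
  expect_equal(assign_slco1b1_phenotype("*1/*1"), "NF")
  expect_equal(assign_slco1b1_phenotype("*1/*5"), "DF")
  expect_equal(assign_slco1b1_phenotype("*5/*5"), "PF")
  expect_equal(assign_slco1b1_phenotype("*1B/*1B"), "NF")
  expect_equal(assign_slco1b1_phenotype("*1B/*5"), "DF")
})

test_that("adding a *5 allele never moves the SLCO1B1 phenotype toward NF", {
  severity <- c(NF = 1, DF = 2, PF = 3)
  for (other in c("*1", "*1B", "*5")) {
    without <- assign_slco1b1_phenotype(paste(other, "*1", sep = "/"))
    with5 <- assign_slco1b1_phenotype(paste(other, "*5", sep = "/"))
    expect_gte(severity[[with5]], severity[[without]])
  }
})

test_that("CYP3A5 expresser status requires a functional allele", {
  expect_equal(assign_cyp3a5_phenotype("*1/*1"), "Expresser")
  expect_equal(assign_cyp3a5_phenotype("*1/*3"), "Expresser")
  expect_equal(assign_cyp3a5_phenotype("*3/*3"), "Non-expresser")
  expect_equal(assign_cyp3a5_phenotype("*3/*6"), "Non-expresser")
})

test_that("CYP2D6 activity score scales with copy number and maps to labels", {
  expect_equal(assign_cyp2d6_phenotype("*4/*4")$activity_score, 0)
  expect_equal(assign_cyp2d6_phenotype("*4/*4")$phenotype, "PM")
  nm <- assign_cyp2d6_phenotype("*1/*1", copy_number = 2)
  expect_equal(nm$activity_score, 2)
  expect_equal(nm$phenotype, "NM")
  del <- assign_cyp2d6_phenotype("*1/*1", copy_number = 0)
  expect_equal(del$activity_score, 0)
  expect_equal(del$phenotype, "PM")
  dup <- assign_cyp2d6_phenotype("*1/*1", copy_number = 3)
  expect_equal(dup$activity_score, 3)
  expect_equal(dup$phenotype, "UM")
  expect_equal(assign_cyp2d6_phenotype("*1/*4")$phenotype, "IM")
  expect_equal(assign_cyp2d6_phenotype("*1/*41")$phenotype, "NM")
})

test_that("transporter haplotype merging counts variant alleles", {
  base <- impute_missing(ref_calls(genes = c("SLC22A1", "ABCB1")),
                         genes = c("SLC22A1", "ABCB1"))
  expect_equal(merge_transporter_haplotype("SLC22A1", base), "wild-type")
  one_het <- impute_missing(
    with_calls(ref_calls(genes = c("SLC22A1", "ABCB1")),
               c(rs12208357 = "C/T")), genes = c("SLC22A1", "ABCB1"))
  expect_equal(merge_transporter_haplotype("SLC22A1", one_het), "heterozygous")
  hom <- impute_missing(
    with_calls(ref_calls(genes = c("SLC22A1", "ABCB1")),
               c(rs12208357 = "T/T")), genes = c("SLC22A1", "ABCB1"))
  expect_equal(merge_transporter_haplotype("SLC22A1", hom), "mutant")
  # reduced ABCB1 subset ignores variants outside it
  non_core <- impute_missing(
    with_calls(ref_calls(genes = c("SLC22A1", "ABCB1")),
               c(rs3842 = "C/C", rs1045642 = "C/T")),
    genes = c("SLC22A1", "ABCB1"))
  expect_equal(merge_transporter_haplotype("ABCB1", non_core), "mutant")
  expect_equal(merge_transporter_haplotype("ABCB1", non_core, core_only = TRUE),
               "heterozygous")
})

test_that("every realisable diplotype maps to exactly one phenotype label", {
  defs <- allele_definitions()
  for (gene in c("SLCO1B1", "CYP3A5", "CYP2D6", "CYP2C9", "CYP2C19",
                 "CYP2B6", "CYP1A2")) {
    alleles <- defs$allele[defs$gene == gene]
    pairs <- expand.grid(a = alleles, b = alleles,
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pairs))) {
      res <- assign_phenotype(gene, c(pairs$a[i], pairs$b[i]))
      expect_true(is.character(res$phenotype) && length(res$phenotype) == 1L &&
                    !is.na(res$phenotype),
                  info = paste(gene, pairs$a[i], pairs$b[i]))
    }
  }
})

test_that("per-allele genotype labels and batch translation line up", {
  g1 <- with_calls(ref_calls("S1", genes = c("SLCO1B1", "CYP3A5", "SLC22A1",
                                             "ABCB1", "UGT2B7")),
                   c(rs4149056 = "T/C", rs776746 = "G/G"))
  g2 <- with_calls(ref_calls("S2", genes = c("SLCO1B1", "CYP3A5", "SLC22A1",
                                             "ABCB1", "UGT2B7")),
                   c(rs72552763 = "GAT/del", rs7439366 = "C/C"))
  g2$allele1[g2$rsid == "rs776746"] <- "."  # missing -> imputed *1
  g2$allele2[g2$rsid == "rs776746"] <- "."
  genotypes <- dplyr::bind_rows(g1, g2)
  tr <- translate_genotypes(genotypes, genes = c("SLCO1B1", "CYP3A5"))
  s1_slco <- tr[tr$subject_id == "S1" & tr$gene == "SLCO1B1", ]
  expect_equal(s1_slco$diplotype, "*1/*5")
  expect_equal(s1_slco$phenotype, "DF")
  s2_cyp <- tr[tr$subject_id == "S2" & tr$gene == "CYP3A5", ]
  expect_equal(s2_cyp$diplotype, "*1/*1")
  expect_match(s2_cyp$imputed_rsids, "rs776746")
  expect_equal(tr$phenotype[tr$subject_id == "S2" &
                              tr$gene == "SLC22A1_haplotype"], "heterozygous")

  imp <- impute_missing(genotypes)
  sg <- star_genotype("SLC22A1", "*2", imp)
  expect_equal(sg$genotype[sg$subject_id == "S2"], "*1/*2")
  ug <- star_genotype("UGT2B7", "*2", imp)
  expect_equal(ug$genotype[ug$subject_id == "S2"], "*2/*2")
})

test_that("genotype CSV and VCF ingestion reproduce the same calls", {
  csv <- withr::local_tempfile(fileext = ".csv")
  g <- with_calls(ref_calls(genes = "SLCO1B1"), c(rs4149056 = "T/C"))
  utils::write.csv(g, csv, row.names = FALSE)
  back <- read_genotypes(csv)
  expect_equal(back$allele1[back$rsid == "rs4149056"], "T")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "12\t21178615\trs4149056\tT\tC\t.\tPASS\t.\tGT\t0/1\t1/1",
    "7\t99672916\trs776746\tA\tG\t.\tPASS\t.\tGT\t1|1\t0/0"
  ), vcf)
  calls <- read_genotype_vcf(vcf)
  expect_equal(sort(unique(calls$subject_id)), c("S1", "S2"))
  s1 <- calls[calls$subject_id == "S1" & calls$rsid == "rs4149056", ]
  expect_equal(sort(c(s1$allele1, s1$allele2)), c("C", "T"))
  s2 <- calls[calls$subject_id == "S2" & calls$rsid == "rs776746", ]
  expect_equal(c(s2$allele1, s2$allele2), c("A", "A"))
  tr <- translate_genotypes(calls, genes = c("SLCO1B1", "CYP3A5"),
                            include_haplotypes = FALSE)
  expect_equal(tr$phenotype[tr$subject_id == "S1" & tr$gene == "SLCO1B1"], "DF")
  expect_equal(tr$diplotype[tr$subject_id == "S1" & tr$gene == "CYP3A5"], "*3/*3")
})
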
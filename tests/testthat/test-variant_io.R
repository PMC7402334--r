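# Reading and writing variants, genotypes and phenotypes.

write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=A,Type=String,Description="Gene">',
    '##INFO=<ID=SIFT,Number=A,Type=Float,Description="SIFT">',
    '##INFO=<ID=CADD,Number=A,Type=Float,Description="CADD">',
    '##INFO=<ID=AF_1KG,Number=A,Type=Float,Description="AF">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("GT fields decode to ALT-allele dosages and missing stays missing", {
  path <- write_test_vcf(c(
    vcf_header(),
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=X;SIFT=0.5\tGT\t0/1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\tGENE=X;SIFT=0.9\tGT\t./.\t0/0"))
  res <- read_annotated_vcf(path)
  expect_equal(unname(res$genotypes["S1", ]), c(1L, NA))
  expect_equal(unname(res$genotypes["S2", ]), c(2L, 0L))
})

test_that("annotations parse into variant fields (PRNP-style record)", {
  path <- write_test_vcf(c(
    vcf_header("S1"),
    "chr20\t4680521\trs1800014\tG\tA\t.\tPASS\tGENE=PRNP;SIFT=0.03;CADD=14.46;AF_1KG=0.016\tGT\t0/1"))
  res <- read_annotated_vcf(path)
  v <- res$variants
  expect_equal(v$rsid, "rs1800014")
  expect_equal(v$sift, 0.03)
  expect_equal(v$cadd, 14.46)
  expect_equal(v$ref_af, 0.016)
  expect_equal(v$gene, "PRNP")
  expect_equal(v$key, "chr20:4680521:G:A")
})

test_that("multi-allelic records split per ALT and conserve allele counts", {
  path <- write_test_vcf(c(
    vcf_header(c("S1", "S2", "S3")),
    "1\t100\t.\tA\tG,T\t.\tPASS\tGENE=X;SIFT=0.1,0.6\tGT\t1/2\t0/1\t2/2"))
  res <- read_annotated_vcf(path)
  expect_equal(nrow(res$variants), 2L)
  expect_equal(res$variants$alt, c("G", "T"))
  expect_equal(res$variants$sift, c(0.1, 0.6))
  # S1 carries one of each ALT; S3 two copies of the second
  expect_equal(unname(res$genotypes[, "1:100:A:G"]), c(1L, 1L, 0L))
  expect_equal(unname(res$genotypes[, "1:100:A:T"]), c(1L, 0L, 2L))
  # total ALT alleles per record conserved after splitting
  expect_equal(sum(res$genotypes), 1L + 1L + 1L + 2L)
})

test_that("malformed header errors and unknown annotation keys warn", {
  bad <- write_test_vcf(c("not a vcf", "1\t1\t.\tA\tG\t.\t.\t.\tGT\t0/0"))
  expect_error(read_annotated_vcf(bad), "line 1")
  path <- write_test_vcf(c(
    vcf_header("S1"),
    "1\t100\t.\tA\tG\t.\tPASS\tGENE=X\tGT\t0/1"))
  expect_warning(res <- read_annotated_vcf(path, c(sift = "NOSUCH")),
                 "NOSUCH")
  expect_true(is.na(res$variants$sift))
})

test_that("VCF write/read round-trips variants and dosages", {
  set.seed(31)
  cohort <- small_cohort(seed = 31L, n = 25L, genes = 3L)
  path <- tempfile(fileext = ".vcf")
  write_annotated_vcf(cohort$variants, cohort$genotypes, path)
  back <- read_annotated_vcf(path)
  expect_equal(back$variants$key, cohort$variants$key)
  expect_equal(back$variants$sift, cohort$variants$sift)
  expect_equal(back$variants$ref_af, cohort$variants$ref_af)
  expect_equal(back$variants$gene, cohort$variants$gene)
  expect_equal(back$genotypes, cohort$genotypes)
})

test_that("variant table invariants are enforced", {
  v <- make_variants()
  expect_silent(validate_variants(v))
  v2 <- v; v2$sift[1] <- 1.2
  expect_error(validate_variants(v2), "SIFT")
  v3 <- rbind(v, v[1, ])
  expect_error(validate_variants(v3), "duplicated")
  v4 <- v; v4$pos[1] <- 0L
  expect_error(validate_variants(v4), ">= 1")
})

test_that("phenotype reading screens eligibility and keeps blanks missing", {
  path <- tempfile(fileext = ".tsv")
  df <- rbind(make_pheno("A", w0 = 20), make_pheno("B", w0 = 13),
              make_pheno("C", w0 = NA), make_pheno("D", w6 = NA))
  write_phenotypes(df, path)
  expect_warning(res <- read_phenotypes(path), "rejected 2")
  expect_equal(res$sample_id, c("A", "D"))
  expect_true(is.na(res$hamd_w6[res$sample_id == "D"]))
})

test_that("phenotype and annotation TSVs round-trip a simulated cohort", {
  cohort <- small_cohort(seed = 13L, n = 30L, genes = 3L)
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_phenotypes(cohort$phenotypes, p1)
  res <- read_phenotypes(p1)
  expect_equal(res, cohort$phenotypes, ignore_attr = TRUE)
  write_annotation_tsv(cohort$variants, p2)
  expect_equal(read_annotation_tsv(p2), cohort$variants, ignore_attr = TRUE)
})
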
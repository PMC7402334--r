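# Input/output for annotated variants, genotype dosages, and phenotypes.
#
# Internal representations:
#   * variant table  — data.frame with columns chrom, pos (1-based), ref, alt,
#     rsid, gene, sift, cadd, ref_af and a canonical key "chrom:pos:ref:alt";
#     one row per ALT allele (multi-allelic VCF records are split).
#   * genotype matrix — integer matrix, samples x variants, entries 0/1/2
#     (ALT-allele dosage) or NA for missing genotypes; dimnames carry sample
#     ids and variant keys.
#   * phenotype table — data.frame with sample_id, sex, age, hamd_w<week>
#     columns for weeks 0,1,2,3,6,9,12, plus arbitrary numeric covariates.

DEFAULT_ANNOTATION_SPEC <- c(sift = "SIFT", cadd = "CADD",
                             ref_af = "AF_1KG", gene = "GENE")

#' Validate an annotated variant table
#'
#' Checks column presence, value ranges (positions >= 1, SIFT and reference
#' allele frequencies within \[0,1\]) and uniqueness of the
#' (chrom, pos, ref, alt) key.
#'
#' @param variants data.frame as produced by [read_annotated_vcf()] or
#'   [read_annotation_tsv()].
#' @return the validated table, invisibly.
#' @export
validate_variants <- function(variants) {
  required <- c("chrom", "pos", "ref", "alt", "rsid", "gene",
                "sift", "cadd", "ref_af", "key")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0L)
    stopf("variant table lacks columns: %s", paste(missing, collapse = ", "))
  if (any(variants$pos < 1L))
    stopf("variant positions must be >= 1 (1-based VCF convention)")
  sift <- variants$sift
  if (any(!is.na(sift) & (sift < 0 | sift > 1)))
    stopf("SIFT scores must lie in [0, 1]")
  af <- variants$ref_af
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stopf("reference allele frequencies must lie in [0, 1]")
  if (anyDuplicated(variants$key))
    stopf("duplicated variant key(s): %s",
          paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "))
  invisible(variants)
}

# Decode one GT string ("0/1", "1|1", "./.", ".") into the dosage of ALT
# allele `allele_idx` (1-based among ALT alleles).
decode_gt_dosage <- function(gt, allele_idx) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  if (!any(ok)) return(out)
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == as.character(allele_idx))
  }, integer(1))
  out
}

parse_info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pattern, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

info_numeric_for_alt <- function(values, alt_idx) {
  # Per-record INFO values may carry one entry per ALT allele ("0.03,0.5").
  vapply(seq_along(values), function(i) {
    v <- values[i]
    if (is.na(v) || v == "" || v == ".") return(NA_real_)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    part <- if (length(parts) >= alt_idx[i]) parts[alt_idx[i]] else parts[1]
    if (part %in% c("", ".")) return(NA_real_)
    suppressWarnings(as.numeric(part))
  }, numeric(1))
}

info_character_for_alt <- function(values, alt_idx) {
  vapply(seq_along(values), function(i) {
    v <- values[i]
    if (is.na(v) || v == "" || v == ".") return(NA_character_)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    if (length(parts) >= alt_idx[i]) parts[alt_idx[i]] else parts[1]
  }, character(1))
}

#' Read an annotated VCF into a variant table and genotype matrix
#'
#' Parses a VCF 4.x file (plain or gzip) whose INFO fields carry per-variant
#' annotations (SIFT, CADD, reference-panel allele frequency, gene symbol).
#' Multi-allelic records are split into one row per ALT allele; the dosage of
#' each split allele is counted separately so total ALT allele counts are
#' conserved. Missing genotypes stay missing (`NA`), they are never imputed
#' to homozygous reference here.
#'
#' @param path VCF file path.
#' @param annotation_spec named character vector mapping internal fields
#'   (`sift`, `cadd`, `ref_af`, `gene`) to INFO keys. Keys absent from the
#'   VCF header trigger a warning and leave the field `NA`.
#' @return list with elements `variants` (data.frame, see
#'   [validate_variants()]) and `genotypes` (samples x variants integer
#'   matrix).
#' @export
read_annotated_vcf <- function(path, annotation_spec = DEFAULT_ANNOTATION_SPEC) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "##fileformat=VCF"))
    stopf("malformed VCF header at line 1 of %s: expected '##fileformat=VCF...'",
          path)
  spec <- DEFAULT_ANNOTATION_SPEC
  spec[names(annotation_spec)] <- annotation_spec

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  meta <- vcf@meta
  for (field in names(spec)) {
    if (!any(grepl(paste0("ID=", spec[[field]], "[,>]"), meta)))
      warnf("INFO key '%s' (for %s) not declared in VCF header; field left missing",
            spec[[field]], field)
  }
  n_rec <- nrow(fix)
  sample_ids <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep(seq_len(n_rec), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  info <- fix[rec_idx, "INFO"]

  rsid <- fix[rec_idx, "ID"]
  rsid[rsid %in% c(".", "")] <- NA_character_
  variants <- data.frame(
    chrom = fix[rec_idx, "CHROM"],
    pos = as.integer(fix[rec_idx, "POS"]),
    ref = fix[rec_idx, "REF"],
    alt = unlist(alt_list, use.names = FALSE),
    rsid = rsid,
    gene = info_character_for_alt(parse_info_field(info, spec[["gene"]]), alt_idx),
    sift = info_numeric_for_alt(parse_info_field(info, spec[["sift"]]), alt_idx),
    cadd = info_numeric_for_alt(parse_info_field(info, spec[["cadd"]]), alt_idx),
    ref_af = info_numeric_for_alt(parse_info_field(info, spec[["ref_af"]]), alt_idx),
    stringsAsFactors = FALSE
  )
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  validate_variants(variants)

  dosages <- matrix(NA_integer_, nrow = length(sample_ids), ncol = nrow(variants),
                    dimnames = list(sample_ids, variants$key))
  for (j in seq_len(nrow(variants))) {
    dosages[, j] <- decode_gt_dosage(gt[rec_idx[j], ], alt_idx[j])
  }
  list(variants = variants, genotypes = dosages)
}

#' Write a variant table and genotype matrix as VCF 4.2
#'
#' Emits one record per variant row (previously split multi-allelic alleles
#' are written as separate biallelic records) with annotations in the INFO
#' column and unphased GT genotypes. The output round-trips through
#' [read_annotated_vcf()].
#'
#' @param variants variant table (see [validate_variants()]).
#' @param genotypes samples x variants dosage matrix aligned with `variants$key`.
#' @param path output path; a `.gz` suffix gzips the file.
#' @param annotation_spec INFO key mapping, as in [read_annotated_vcf()].
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, genotypes, path,
                                annotation_spec = DEFAULT_ANNOTATION_SPEC) {
  validate_variants(variants)
  if (!identical(colnames(genotypes), variants$key))
    stopf("genotype matrix columns must match variants$key")
  spec <- DEFAULT_ANNOTATION_SPEC
  spec[names(annotation_spec)] <- annotation_spec
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf('##INFO=<ID=%s,Number=A,Type=String,Description="Gene symbol">',
            spec[["gene"]]),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="SIFT score">',
            spec[["sift"]]),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="CADD phred score">',
            spec[["cadd"]]),
    sprintf('##INFO=<ID=%s,Number=A,Type=Float,Description="Reference panel ALT allele frequency">',
            spec[["ref_af"]]),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), NA_character_, format(x, trim = TRUE,
                                                                scientific = FALSE))
  info_of <- function(i) {
    parts <- c(
      if (!is.na(variants$gene[i])) sprintf("%s=%s", spec[["gene"]], variants$gene[i]),
      if (!is.na(variants$sift[i])) sprintf("%s=%s", spec[["sift"]], fmt_num(variants$sift[i])),
      if (!is.na(variants$cadd[i])) sprintf("%s=%s", spec[["cadd"]], fmt_num(variants$cadd[i])),
      if (!is.na(variants$ref_af[i])) sprintf("%s=%s", spec[["ref_af"]], fmt_num(variants$ref_af[i]))
    )
    if (length(parts) == 0L) "." else paste(parts, collapse = ";")
  }
  gt_string <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  records <- vapply(seq_len(nrow(variants)), function(i) {
    gts <- genotypes[, i]
    gt_col <- ifelse(is.na(gts), "./.", gt_string[as.character(gts)])
    paste(c(variants$chrom[i], variants$pos[i],
            ifelse(is.na(variants$rsid[i]), ".", variants$rsid[i]),
            variants$ref[i], variants$alt[i], ".", "PASS", info_of(i), "GT",
            gt_col), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, records), con)
  invisible(path)
}

#' Read a flat annotation TSV
#'
#' Alternative to VCF INFO annotations: a tab-separated table with columns
#' `chrom, pos, ref, alt, rsid, gene, sift, cadd, ref_af`.
#'
#' @param path TSV path.
#' @return validated variant table.
#' @export
read_annotation_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character", ref = "character",
                                        alt = "character", rsid = "character",
                                        gene = "character"))
  x$pos <- as.integer(x$pos)
  for (col in c("rsid", "gene")) x[[col]][x[[col]] %in% c("", ".")] <- NA
  x$key <- variant_key(x$chrom, x$pos, x$ref, x$alt)
  validate_variants(x)
  x
}

#' @rdname read_annotation_tsv
#' @param variants validated variant table to write.
#' @export
write_annotation_tsv <- function(variants, path) {
  validate_variants(variants)
  cols <- c("chrom", "pos", "ref", "alt", "rsid", "gene", "sift", "cadd", "ref_af")
  utils::write.table(variants[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a longitudinal phenotype table
#'
#' Expects a tab-separated file with columns `sample_id`, `sex`
#' (`male`/`female`), `age`, `hamd_w0` ... `hamd_w12` (the seven-visit
#' schedule) and any number of numeric covariate columns (for example
#' baseline `hads_a`). Blank cells become `NA`, never zero. Records are
#' screened for study eligibility: the baseline HAM-D must be present and
#' at least 14 (moderate depression); failing rows are dropped with a
#' warning naming them.
#'
#' @param path TSV path.
#' @param min_baseline_hamd eligibility threshold on the week-0 score
#'   (default 14).
#' @return phenotype data.frame of eligible records.
#' @export
read_phenotypes <- function(path, min_baseline_hamd = 14) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("sample_id", "sex", "age", hamd_cols())
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stopf("phenotype table lacks columns: %s", paste(missing, collapse = ", "))
  bad_sex <- !x$sex %in% c("male", "female")
  if (any(bad_sex)) stopf("sex must be 'male' or 'female' (rows: %s)",
                          paste(which(bad_sex), collapse = ", "))
  w0 <- x$hamd_w0
  reject <- is.na(w0) | w0 < min_baseline_hamd
  if (any(reject)) {
    warnf("rejected %d record(s) failing eligibility (baseline HAM-D missing or < %s): %s",
          sum(reject), min_baseline_hamd,
          paste(x$sample_id[reject], collapse = ", "))
    x <- x[!reject, , drop = FALSE]
  }
  rownames(x) <- NULL
  x
}

#' @rdname read_phenotypes
#' @param phenotypes phenotype data.frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
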
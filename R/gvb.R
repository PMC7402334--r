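# Gene-wise variant burden (GVB): per sample and gene, the geometric mean
# of the SIFT scores of the deleterious variants the sample carries. A GVB
# of 1 means no deleterious burden; values near 0 mean heavy predicted
# functional impact.

#' GVB scoring parameters
#'
#' @param sift_deleterious_threshold variants with SIFT strictly below this
#'   cutoff count as deleterious (default 0.7, following the burden-scoring
#'   methodology this score derives from; SIFT's own "damaging" call at 0.05
#'   is much stricter and can be configured here).
#' @param zero_floor effective score substituted for SIFT = 0 so the
#'   geometric mean stays positive (default 0.001).
#' @param per_allele if `TRUE`, a variant's score enters the mean once per
#'   ALT allele (homozygotes count twice); default `FALSE` counts each
#'   carried variant once regardless of zygosity.
#' @param no_variant_score score assigned when a sample carries no
#'   qualifying variant in the gene (default 1.0, i.e. no burden).
#' @return list of class `gvb_params`.
#' @export
gvb_params <- function(sift_deleterious_threshold = 0.7, zero_floor = 0.001,
                       per_allele = FALSE, no_variant_score = 1.0) {
  if (!(zero_floor > 0 && zero_floor <= sift_deleterious_threshold &&
        sift_deleterious_threshold <= 1))
    stopf("need 0 < zero_floor <= sift_deleterious_threshold <= 1")
  structure(list(sift_deleterious_threshold = sift_deleterious_threshold,
                 zero_floor = zero_floor, per_allele = per_allele,
                 no_variant_score = no_variant_score),
            class = "gvb_params")
}

#' Deleterious (qualifying) variants for burden scoring
#'
#' Returns the subset of variants with a SIFT score present and strictly
#' below the deleteriousness threshold, adding an `sift_eff` column where
#' exact zeros are replaced by the configured floor.
#'
#' @param variants annotated variant table.
#' @param params a [gvb_params()].
#' @return variant table subset with an extra `sift_eff` column.
#' @export
qualifying_variants <- function(variants, params = gvb_params()) {
  keep <- !is.na(variants$sift) &
    variants$sift < params$sift_deleterious_threshold
  out <- variants[keep, , drop = FALSE]
  out$sift_eff <- ifelse(out$sift == 0, params$zero_floor, out$sift)
  rownames(out) <- NULL
  out
}

#' Compute the gene-wise variant burden matrix
#'
#' For every sample and gene, collects the effective SIFT scores of the
#' qualifying (deleterious) variants the sample carries (dosage >= 1;
#' missing dosage treated as non-carrier) and takes their geometric mean;
#' with `per_allele = TRUE` each score is weighted by the allele dosage.
#' Samples carrying no qualifying variant in a gene score
#' `params$no_variant_score` (1 by default).
#'
#' @param genotypes samples x variants dosage matrix (columns named by
#'   variant key).
#' @param variants annotated variant table aligned with the matrix columns.
#' @param params a [gvb_params()].
#' @param genes genes to score; defaults to all genes present in `variants`.
#'   Genes with no annotated variant get a column of `no_variant_score`
#'   with a warning.
#' @return samples x genes numeric matrix with values in (0, 1].
#' @export
compute_gvb <- function(genotypes, variants, params = gvb_params(),
                        genes = NULL) {
  if (!all(variants$key %in% colnames(genotypes)))
    stopf("all variant keys must be present as genotype matrix columns")
  genes <- genes %||% sort(unique(variants$gene[!is.na(variants$gene)]))
  qual <- qualifying_variants(variants, params)
  scores <- matrix(params$no_variant_score,
                   nrow = nrow(genotypes), ncol = length(genes),
                   dimnames = list(rownames(genotypes), genes))
  absent <- setdiff(genes, variants$gene)
  if (length(absent) > 0L)
    warnf("gene(s) with no annotated variant scored as %s: %s",
          params$no_variant_score, paste(absent, collapse = ", "))
  for (g in intersect(genes, unique(qual$gene))) {
    vg <- qual[qual$gene %in% g, , drop = FALSE]
    dos <- genotypes[, vg$key, drop = FALSE]
    dos[is.na(dos)] <- 0L
    logs <- log(vg$sift_eff)
    if (params$per_allele) {
      num <- dos %*% logs
      den <- rowSums(dos)
    } else {
      carrier <- dos >= 1L
      num <- carrier %*% logs
      den <- rowSums(carrier)
    }
    has <- den > 0
    scores[has, g] <- exp(num[has] / den[has])
  }
  scores
}

#' Write a GVB matrix as TSV
#'
#' Rows are samples, columns genes; a leading `sample_id` column carries the
#' row names.
#'
#' @param gvb samples x genes matrix from [compute_gvb()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gvb_tsv <- function(gvb, path) {
  df <- data.frame(sample_id = rownames(gvb), gvb, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
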
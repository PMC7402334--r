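# Shared fixture builders. Everything is generated in code; no binary data.

# Minimal annotated variant table; defaults give two genes with a spread of
# SIFT scores.
make_variants <- function(chrom = c("1", "1", "2", "2", "2"),
                          pos = c(100L, 200L, 300L, 400L, 500L),
                          ref = c("A", "C", "G", "T", "A"),
                          alt = c("G", "T", "A", "C", "C"),
                          gene = c("GENEA", "GENEA", "GENEB", "GENEB", "GENEB"),
                          sift = c(0.03, 0.8, 0.04, 0.25, NA),
                          ref_af = c(0.02, 0.2, 0.005, 0.009, 0.3),
                          rsid = NA_character_,
                          cadd = NA_real_) {
  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  rsid = rsid, gene = gene, sift = sift, cadd = cadd,
                  ref_af = ref_af, stringsAsFactors = FALSE)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  v
}

make_genotypes <- function(variants, dosages, sample_ids = NULL) {
  n <- nrow(dosages)
  sample_ids <- sample_ids %||% sprintf("S%03d", seq_len(n))
  dimnames(dosages) <- list(sample_ids, variants$key)
  dosages
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A phenotype row builder with the full visit schedule.
make_pheno <- function(sample_id = "S001", sex = "male", age = 40,
                       hads_a = 8, w0 = 20, w1 = 18, w2 = 16, w3 = 15,
                       w6 = 12, w9 = 9, w12 = 7) {
  data.frame(sample_id = sample_id, sex = sex, age = age, hads_a = hads_a,
             hamd_w0 = w0, hamd_w1 = w1, hamd_w2 = w2, hamd_w3 = w3,
             hamd_w6 = w6, hamd_w9 = w9, hamd_w12 = w12,
             stringsAsFactors = FALSE)
}

# Small simulated cohort shared by pipeline-level tests.
small_cohort <- function(seed = 7L, causal = NULL, n = 150L, genes = 8L) {
  cfg <- sim_config(n_samples = n, n_genes = genes, variants_per_gene = 6L,
                    causal_genes = causal, seed = seed)
  simulate_cohort(cfg)
}
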
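# Gene-wise variant burden scoring.

test_that("qualifying variants follow the SIFT threshold and zero floor", {
  v <- make_variants(sift = c(0.03, 0.8, 0.0, 0.69, NA))
  q <- qualifying_variants(v, gvb_params())
  expect_equal(q$sift, c(0.03, 0.0, 0.69))
  expect_equal(q$sift_eff, c(0.03, 0.001, 0.69))
  # stricter threshold drops more
  q2 <- qualifying_variants(v, gvb_params(sift_deleterious_threshold = 0.05))
  expect_equal(q2$sift, c(0.03, 0.0))
})

test_that("single-variant carriers score the variant's SIFT; others 1.0", {
  v <- make_variants(gene = c("COMT", "COMT", "B", "B", "B"),
                     sift = c(0.01, 0.9, 0.04, 0.25, 0.5))
  dos <- matrix(0L, nrow = 3, ncol = 5)
  dos[1, 1] <- 1L                    # S001 carries only the SIFT=0.01 variant
  dos[2, 3] <- 1L; dos[2, 4] <- 2L   # S002 carries both deleterious B variants
  g <- make_genotypes(v, dos)
  scores <- compute_gvb(g, v)
  expect_equal(scores["S001", "COMT"], 0.01)
  expect_equal(scores["S002", "COMT"], 1.0)
  expect_equal(scores["S003", "B"], 1.0)
  expect_equal(scores["S002", "B"], sqrt(0.04 * 0.25))  # = 0.1 exactly
  expect_equal(scores["S002", "B"], 0.1)
})

test_that("per-allele weighting: homozygous single variant equals per-variant", {
  v <- make_variants()
  dos <- matrix(0L, 2, 5); dos[1, 1] <- 2L
  g <- make_genotypes(v, dos)
  pv <- compute_gvb(g, v, gvb_params(per_allele = FALSE))
  pa <- compute_gvb(g, v, gvb_params(per_allele = TRUE))
  expect_equal(pv["S001", "GENEA"], pa["S001", "GENEA"])
  # but a het + hom pair weights the hom variant twice
  dos2 <- matrix(0L, 1, 5); dos2[1, 3] <- 1L; dos2[1, 4] <- 2L
  g2 <- make_genotypes(v, dos2, "X1")
  pa2 <- compute_gvb(g2, v, gvb_params(per_allele = TRUE))
  expect_equal(pa2["X1", "GENEB"], exp((log(0.04) + 2 * log(0.25)) / 3))
})

test_that("missing dosages count as non-carriers", {
  v <- make_variants()
  dos <- matrix(NA_integer_, 1, 5)
  g <- make_genotypes(v, dos, "X1")
  expect_equal(unname(compute_gvb(g, v)["X1", ]), c(1, 1))
})

test_that("genes without annotated variants warn and score no_variant_score", {
  v <- make_variants()
  dos <- matrix(0L, 1, 5)
  g <- make_genotypes(v, dos, "X1")
  expect_warning(scores <- compute_gvb(g, v, genes = c("GENEA", "EMPTY")),
                 "EMPTY")
  expect_equal(unname(scores["X1", "EMPTY"]), 1)
})

test_that("GVB matches a brute-force oracle on random instances", {
  # oracle: enumerate carried qualifying variants, multiply scores, take
  # the appropriate root
  oracle_gvb <- function(dos_row, variants, params) {
    qual <- !is.na(variants$sift) &
      variants$sift < params$sift_deleterious_threshold
    out <- list()
    for (g in unique(variants$gene)) {
      idx <- which(variants$gene == g & qual & !is.na(dos_row) & dos_row >= 1)
      if (length(idx) == 0L) { out[[g]] <- 1.0; next }
      s <- variants$sift[idx]
      s[s == 0] <- params$zero_floor
      out[[g]] <- prod(s)^(1 / length(s))
    }
    out
  }
  set.seed(17)
  for (rep in 1:5) {
    n <- 20; m <- 50
    v <- make_variants(chrom = rep("1", m), pos = seq_len(m) * 10L,
                       ref = rep("A", m), alt = rep("G", m),
                       gene = sample(paste0("G", 1:6), m, TRUE),
                       sift = round(runif(m), 3),
                       ref_af = runif(m, 0, 0.5))
    dos <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), n * m, TRUE), n, m)
    g <- make_genotypes(v, dos)
    params <- gvb_params()
    scores <- compute_gvb(g, v, params)
    for (i in sample(n, 4)) {
      oracle <- oracle_gvb(dos[i, ], v, params)
      for (gene in names(oracle))
        expect_equal(scores[i, gene], oracle[[gene]], tolerance = 1e-12)
    }
    # bounds: min effective SIFT <= score <= max effective SIFT when carried
    qual <- qualifying_variants(v, params)
    for (gene in unique(qual$gene)) {
      vg <- qual[qual$gene == gene, ]
      dosg <- dos[, match(vg$key, v$key), drop = FALSE]
      carried <- apply(dosg, 1, function(d) any(!is.na(d) & d >= 1))
      if (any(carried)) {
        expect_true(all(scores[carried, gene] >= min(vg$sift_eff) - 1e-12))
        expect_true(all(scores[carried, gene] <= max(vg$sift_eff) + 1e-12))
      }
      expect_true(all(scores[!carried, gene] == 1))
    }
    # permutation invariance over variant order
    perm <- sample(m)
    scores_perm <- compute_gvb(g[, perm], v[perm, ], params)
    expect_equal(scores_perm[, colnames(scores)], scores)
  }
})
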
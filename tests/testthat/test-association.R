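test_that("MAF filter applies the strict > threshold rule on non-missing dosages", {
  # 10 accessions: sums give exact allele frequencies
  G <- cbind(snpA = c(1, rep(0, 9)),        # MAF 0.05 -> dropped (strict)
             snpB = c(1, 1, rep(0, 8)),     # MAF 0.10 -> kept
             snpC = rep(1, 10),             # MAF 0.50 (all het) -> kept
             snpD = rep(0, 10),             # monomorphic -> dropped
             snpE = rep(2, 10),             # monomorphic at fixed alt -> dropped
             snpF = c(2, rep(0, 9)))        # MAF 0.10 -> kept
  kept <- colnames(maf_filter(G, 0.05))
  expect_setequal(kept, c("snpB", "snpC", "snpF"))
  # MAF computed on non-missing dosages only
  Gna <- cbind(x = c(1, 1, NA, NA, rep(0, 6)))  # 2/16 = 0.125 on 8 calls
  expect_equal(ncol(maf_filter(Gna, 0.1)), 1L)
  expect_equal(ncol(maf_filter(Gna, 0.13)), 0L)
  expect_error(maf_filter(G, 0.5), "0, 0.5")
  # list form keeps the snp table aligned
  sim <- simulate_genotypes(50, 100, maf_range = c(0.02, 0.5), seed = 31)
  f <- maf_filter(sim, 0.1)
  expect_equal(ncol(f$genotypes), nrow(f$snps))
  expect_true(all(attr(f, "maf") > 0.1))
})

test_that("lr_scan equals the closed-form OLS oracle to 1e-10", {
  sim <- simulate_genotypes(50, 40, seed = 7)
  sc <- lr_scan(sim$genotypes, sim$phenotype)
  for (j in c(1, 13, 40)) {
    fit <- summary(lm(sim$phenotype ~ sim$genotypes[, j]))
    expect_equal(sc$beta[j], coef(fit)[2, 1], tolerance = 1e-10)
    expect_equal(sc$se[j], coef(fit)[2, 2], tolerance = 1e-10)
    expect_equal(sc$p[j], coef(fit)[2, 4], tolerance = 1e-10)
  }
  expect_equal(attr(sc, "model"), "LR")
})

test_that("a perfectly associated SNP attains the scan minimum; zero-variance SNPs are flagged", {
  sim <- simulate_genotypes(60, 30, seed = 8)
  G <- sim$genotypes
  G[, 5] <- G[, 12]                 # make a duplicate so y is exact for both
  y <- as.numeric(G[, 12])
  G[, 20] <- 1                      # constant dosage
  sc <- lr_scan(G, y)
  expect_true(all(sc$p[c(5, 12)] <= min(sc$p[-c(5, 12)])))
  expect_true(sc$zero_variance[20])
  expect_equal(sc$p[20], 1)
  expect_true(is.na(sc$beta[20]))
  # missing dosages are mean-imputed, not dropped
  Gna <- sim$genotypes
  Gna[1:5, 3] <- NA
  expect_silent(lr_scan(Gna, sim$phenotype))
})

test_that("kinship matrix is symmetric PSD with duplicate-accession structure", {
  sim <- simulate_genotypes(40, 500, seed = 9)
  G <- sim$genotypes
  G[2, ] <- G[1, ]  # clone accession 1
  K <- kinship_matrix(G)
  expect_equal(K, t(K))
  expect_equal(K[1, ], K[2, ], tolerance = 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # unrelated accessions: off-diagonals shrink with many SNPs
  K2 <- kinship_matrix(simulate_genotypes(30, 5000, seed = 10)$genotypes)
  off <- K2[upper.tri(K2)]
  expect_lt(max(abs(off)), 0.2)
  expect_error(kinship_matrix(matrix(c(0, 1), 2, 1)), "two SNPs")
})

test_that("emmax_scan collapses to lr_scan when K is the identity", {
  sim <- simulate_genotypes(80, 300, causal_snps = data.frame(index = 3, effect = 0.5),
                            seed = 11)
  lr <- lr_scan(sim$genotypes, sim$phenotype)
  em <- emmax_scan(sim$genotypes, sim$phenotype, diag(80))
  expect_lt(max(abs(em$neg_log10_p - lr$neg_log10_p)), 1e-4)
})

test_that("emmax_scan validates the kinship matrix", {
  sim <- simulate_genotypes(20, 50, seed = 12)
  Kbad <- diag(20); Kbad[1, 2] <- 0.5
  expect_error(emmax_scan(sim$genotypes, sim$phenotype, Kbad), "symmetric")
  Kneg <- diag(20); Kneg[1, 1] <- -1
  expect_error(emmax_scan(sim$genotypes, sim$phenotype, Kneg), "semidefinite")
  expect_error(emmax_scan(sim$genotypes, sim$phenotype, diag(19)), "n x n")
})

test_that("population structure inflates LR but not the mixed model, which still finds the causal SNP", {
  sim <- simulate_genotypes(180, 1500, causal_snps = data.frame(index = 700, effect = 1.2),
                            structure_groups = 2, group_shift = 2, noise_sd = 0.7,
                            seed = 13)
  lr <- lr_scan(sim$genotypes, sim$phenotype)
  em <- emmax_scan(sim$genotypes, sim$phenotype)
  expect_gt(attr(lr, "lambda_gc"), attr(em, "lambda_gc"))
  expect_gt(attr(lr, "lambda_gc"), 1.1)
  expect_lt(abs(attr(em, "lambda_gc") - 1), 0.15)
  # the planted causal SNP ranks in the EMMAX top 1%
  expect_lte(rank(em$p)[700], 0.01 * nrow(em))
})

test_that("genomic inflation is the median chi-square ratio", {
  expect_equal(genomic_inflation(rep(0.5, 200)), 1)
  withr::with_seed(14, {
    p <- runif(5000)
    l1 <- genomic_inflation(p)
    l2 <- genomic_inflation(p / 2)
    expect_gt(l2, l1)
  })
  expect_error(genomic_inflation(runif(50)), "100")
  expect_error(genomic_inflation(c(rep(0.5, 100), 0)), "0, 1")
  expect_error(genomic_inflation(c(rep(0.5, 100), 1.2)), "0, 1")
  qq <- qq_table(c(0.5, 0.1, 0.9))
  expect_equal(qq$observed, -log10(c(0.1, 0.5, 0.9)))
  expect_true(all(diff(qq$expected) < 0) || all(diff(qq$expected) > 0) ||
                !is.unsorted(rev(qq$expected)))
})

test_that("candidate calling respects the promoter and threshold boundaries exactly", {
  genes <- tibble::tibble(
    gene_id = c("plus_g", "minus_g"), chrom = "1",
    start = c(10000L, 30000L), end = c(11000L, 31000L),
    strand = c("+", "-"))
  mk_assoc <- function(pos, nlp) {
    structure(tibble::tibble(snp_id = paste0("s", seq_along(pos)), chrom = "1",
                             pos = pos, p = 10^(-nlp), neg_log10_p = nlp),
              model = "LR", lambda_gc = NA_real_,
              class = c("chill_assoc", class(tibble::tibble())))
  }
  # 1,999 bp upstream of a + gene: inside the promoter window
  expect_equal(call_candidates(mk_assoc(10000L - 1999L, 5), genes)$gene_id, "plus_g")
  # 2,001 bp upstream: outside
  expect_equal(nrow(call_candidates(mk_assoc(10000L - 2001L, 5), genes)), 0L)
  # minus-strand promoter lies downstream of the gene end
  expect_equal(call_candidates(mk_assoc(31000L + 1999L, 5), genes)$gene_id, "minus_g")
  expect_equal(nrow(call_candidates(mk_assoc(10000L - 1999L, 5), genes,
                                    promoter_bp = 0)), 0L)
  # threshold is >= as printed: 4.49 out, 4.50 in
  expect_equal(nrow(call_candidates(mk_assoc(10500L, 4.49), genes)), 0L)
  expect_equal(call_candidates(mk_assoc(10500L, 4.50), genes)$gene_id, "plus_g")
  # monotone: raising the threshold never adds candidates
  a <- mk_assoc(c(10500L, 30100L, 20000L), c(5, 4.6, 7))
  lo <- call_candidates(a, genes, threshold_nlp = 4.5)
  hi <- call_candidates(a, genes, threshold_nlp = 6)
  expect_true(all(hi$gene_id %in% lo$gene_id))
  # unsorted annotations are sorted with a warning
  expect_warning(call_candidates(a, genes[2:1, ]), "sorted")
  # best SNP reported per candidate
  multi <- mk_assoc(c(10100L, 10200L), c(5, 8))
  cc <- call_candidates(multi, genes)
  expect_equal(cc$best_pos, 10200L)
  expect_equal(cc$n_hits, 2L)
})

test_that("assoc tidiers expose per-SNP rows and scan-level summaries", {
  sim <- simulate_genotypes(60, 150, seed = 16)
  sc <- lr_scan(sim$genotypes, sim$phenotype)
  td <- tidy(sc)
  expect_false(inherits(td, "chill_assoc"))
  expect_equal(nrow(td), 150L)
  gl <- glance(sc)
  expect_equal(gl$model, "LR")
  expect_equal(gl$n_snps, 150L)
  expect_equal(gl$lambda_gc, attr(sc, "lambda_gc"))
})
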
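# Simulators for the statistical layers: accession phenotype panels with known
# variance components, and genotype/phenotype pairs with planted causal SNPs
# and optional population structure.

#' Simulate an accession phenotype panel
#'
#' One-way random-effects model: value(a, r) = mean + g_a + e_ar with
#' g_a ~ N(0, var_genetic) and e_ar ~ N(0, var_residual). The defaults are
#' the study conditions of the chilling-tolerance panel: 417 accessions,
#' 3 replicates, and variance components giving a broad-sense heritability of
#' h2 = 21 / (21 + 4) = 0.84.
#'
#' @param n_accessions,n_replicates panel shape (`n_replicates` >= 2 so the
#'   residual variance is estimable).
#' @param var_genetic,var_residual variance components (>= 0).
#' @param mean grand mean of the trait.
#' @param seed integer seed.
#' @return tibble with columns `accession`, `replicate`, `area`.
#' @export
simulate_phenotype_panel <- function(n_accessions = 417, n_replicates = 3,
                                     var_genetic = 21, var_residual = 4,
                                     mean = 100, seed = 1L) {
  if (n_accessions < 2) abort("`n_accessions` must be >= 2.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2 for heritability estimation.")
  assert_scalar_num(var_genetic, "var_genetic", lower = 0)
  assert_scalar_num(var_residual, "var_residual", lower = 0)
  withr::with_seed(seed, {
    g <- rnorm(n_accessions, 0, sqrt(var_genetic))
    tidyr::expand_grid(accession = sprintf("acc_%03d", seq_len(n_accessions)),
                       replicate = seq_len(n_replicates)) |>
      dplyr::mutate(area = mean + g[match(.data$accession,
                                          sprintf("acc_%03d", seq_len(n_accessions)))] +
                      rnorm(dplyr::n(), 0, sqrt(var_residual)))
  })
}

#' Simulate a genotype matrix with a phenotype and known truth
#'
#' Genotypes are 0/1/2 binomial draws at per-SNP allele frequencies drawn
#' uniformly from `maf_range`. With `structure_groups`, per-group allele
#' frequencies follow a Balding-Nichols model (divergence `fst`) and each
#' group receives a phenotype shift, generating the confounding that a
#' kinship-corrected scan must absorb. The phenotype is
#' sum(effect * dosage) + group shift + N(0, noise_sd^2).
#'
#' @param n_accessions,n_snps matrix shape.
#' @param maf_range allele-frequency interval, a subset of (0, 0.5].
#' @param causal_snps data frame with columns `index`, `effect` (may be empty).
#' @param structure_groups optional number of subpopulations (>= 2).
#' @param group_shift standard deviation-scale phenotype offset between groups.
#' @param fst Balding-Nichols divergence used when structure is simulated.
#' @param noise_sd residual phenotype noise.
#' @param seed integer seed.
#' @return list with `genotypes` (n x m dosage matrix), `snps` (tibble:
#'   snp_id, chrom, pos, ref, alt), `phenotype` (named vector), and `truth`
#'   (causal table and group labels).
#' @export
simulate_genotypes <- function(n_accessions = 200, n_snps = 1000,
                               maf_range = c(0.05, 0.5),
                               causal_snps = NULL,
                               structure_groups = NULL, group_shift = 1,
                               fst = 0.1, noise_sd = 1, seed = 1L) {
  if (maf_range[1L] <= 0 || maf_range[2L] > 0.5 || maf_range[1L] > maf_range[2L]) {
    abort("`maf_range` must lie within (0, 0.5].")
  }
  if (!is.null(causal_snps) && nrow(causal_snps) &&
      any(causal_snps$index > n_snps | causal_snps$index < 1)) {
    abort("Causal SNP indices must lie in 1..n_snps.")
  }
  withr::with_seed(seed, {
    p <- runif(n_snps, maf_range[1L], maf_range[2L])
    groups <- NULL
    if (!is.null(structure_groups)) {
      if (structure_groups < 2) abort("`structure_groups` must be >= 2.")
      groups <- sample(rep_len(seq_len(structure_groups), n_accessions))
      a <- p * (1 - fst) / fst
      b <- (1 - p) * (1 - fst) / fst
      G <- matrix(0L, n_accessions, n_snps)
      for (k in seq_len(structure_groups)) {
        pk <- rbeta(n_snps, a, b)
        rows <- which(groups == k)
        G[rows, ] <- matrix(rbinom(length(rows) * n_snps, 2L,
                                   rep(pk, each = length(rows))),
                            length(rows), n_snps)
      }
    } else {
      G <- matrix(rbinom(n_accessions * n_snps, 2L, rep(p, each = n_accessions)),
                  n_accessions, n_snps)
    }
    acc <- sprintf("acc_%04d", seq_len(n_accessions))
    snp <- sprintf("snp_%05d", seq_len(n_snps))
    dimnames(G) <- list(acc, snp)
    y <- rnorm(n_accessions, 0, noise_sd)
    if (!is.null(causal_snps) && nrow(causal_snps)) {
      for (i in seq_len(nrow(causal_snps))) {
        y <- y + causal_snps$effect[i] * G[, causal_snps$index[i]]
      }
    }
    if (!is.null(groups)) y <- y + group_shift * (groups - mean(groups))
    names(y) <- acc
    snps <- tibble(snp_id = snp, chrom = "1",
                   pos = seq_len(n_snps) * 100L, ref = "A", alt = "T")
    list(genotypes = G, snps = snps, phenotype = y,
         truth = list(causal = causal_snps, groups = groups, maf = p))
  })
}
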
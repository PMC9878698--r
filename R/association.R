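# Single-SNP association scans: MAF filtering, ordinary least-squares scan,
# genomic relationship (kinship) matrix, kinship-corrected mixed-model scan
# in the EMMAX style (null-model REML once, then per-SNP generalised least
# squares), genomic-control diagnostics, and candidate-gene calling with the
# 2-kb promoter window.

# normalize genotype input: a dosage matrix, or a list with $genotypes/$snps
as_geno <- function(G) {
  if (is.list(G) && !is.null(G$genotypes)) {
    list(G = G$genotypes, snps = G$snps, wrap = TRUE)
  } else {
    list(G = as.matrix(G), snps = NULL, wrap = FALSE)
  }
}

# per-SNP mean imputation of missing dosages
impute_mean <- function(G) {
  if (!anyNA(G)) return(G)
  cm <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G))
  G[idx] <- cm[((idx - 1L) %/% nrow(G)) + 1L]
  G
}

#' Minor-allele-frequency filter
#'
#' Retains SNPs whose minor allele frequency, computed on non-missing
#' dosages, is strictly greater than `threshold` (the study convention:
#' MAF > 0.05). Monomorphic SNPs are always dropped.
#'
#' @param G dosage matrix (accessions x SNPs, entries 0/1/2/NA) or a list
#'   with elements `genotypes` and `snps` as returned by
#'   [simulate_genotypes()] or [read_genotypes()].
#' @param threshold MAF threshold in `[0, 0.5)`; strict inequality.
#' @return the input, with filtered columns (and filtered `snps` rows when
#'   present); attribute `maf` carries the retained frequencies.
#' @export
maf_filter <- function(G, threshold = 0.05) {
  if (threshold < 0 || threshold >= 0.5) abort("`threshold` must be in [0, 0.5).")
  gi <- as_geno(G)
  p <- colMeans(gi$G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > threshold & maf > 0
  Gf <- gi$G[, keep, drop = FALSE]
  if (gi$wrap) {
    out <- G
    out$genotypes <- Gf
    if (!is.null(out$snps)) out$snps <- out$snps[keep, , drop = FALSE]
    attr(out, "maf") <- maf[keep]
    out
  } else {
    attr(Gf, "maf") <- maf[keep]
    Gf
  }
}

# assemble a chill_assoc tibble from per-SNP statistics
new_assoc <- function(snps, beta, se, p, model, flagged) {
  beta <- unname(beta); se <- unname(se); flagged <- unname(flagged)
  p <- pmin(pmax(unname(p), .Machine$double.xmin), 1)
  tb <- if (!is.null(snps)) as_tibble(snps) else
    tibble(snp_id = sprintf("snp_%05d", seq_along(p)))
  tb$beta <- beta; tb$se <- se; tb$p <- p
  tb$neg_log10_p <- -log10(p)
  tb$zero_variance <- flagged
  lambda <- if (length(p) >= 100L) genomic_inflation(p) else NA_real_
  structure(tb, model = model, lambda_gc = lambda,
            class = c("chill_assoc", class(tb)))
}

#' Linear-regression association scan
#'
#' Per SNP, ordinary least squares of the phenotype on the dosage (with
#' intercept) and a two-sided t-test on the slope. Missing dosages are
#' mean-imputed per SNP; SNPs with zero dosage variance after imputation get
#' `p = 1` and are flagged.
#'
#' @param G dosage matrix or genotype list (see [maf_filter()]).
#' @param y phenotype vector, one value per accession (non-zero variance).
#' @return a `chill_assoc` tibble: per-SNP `beta`, `se`, `p`,
#'   `neg_log10_p`, `zero_variance`; attributes `model` ("LR") and
#'   `lambda_gc` (when >= 100 SNPs). Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
lr_scan <- function(G, y) {
  gi <- as_geno(G)
  X <- impute_mean(gi$G)
  n <- nrow(X)
  if (length(y) != n) abort("`y` length must equal the number of accessions.")
  if (var(y) == 0) abort("Phenotype has zero variance.")
  yc <- y - base::mean(y)
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  Sxy <- as.vector(crossprod(X, yc))
  Syy <- sum(yc^2)
  ok <- Sxx > 1e-12
  beta <- ifelse(ok, Sxy / Sxx, NA_real_)
  sse <- pmax(Syy - beta^2 * Sxx, 0)
  s2 <- sse / (n - 2L)
  se <- sqrt(s2 / Sxx)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df = n - 2L)
  p[!ok] <- 1
  se[!ok] <- NA_real_
  new_assoc(gi$snps, beta, se, p, "LR", !ok)
}

#' Centred-and-scaled genomic relationship (kinship) matrix
#'
#' `K = Z t(Z) / n_snps` with `Z` columns standardised by
#' `sqrt(2 p (1 - p))`; missing dosages mean-imputed, monomorphic SNPs
#' skipped. The result is symmetric positive semidefinite up to numerical
#' tolerance.
#'
#' @param G dosage matrix or genotype list (>= 2 SNPs).
#' @return n x n `KinshipMatrix`.
#' @export
kinship_matrix <- function(G) {
  gi <- as_geno(G)
  X <- impute_mean(gi$G)
  if (ncol(X) < 2L) abort("Need at least two SNPs.")
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  (K + t(K)) / 2
}

#' EMMAX-style kinship-corrected association scan
#'
#' Estimates the variance components of `y = mu + u + e`
#' (`u ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`) once under the null by
#' REML — one eigendecomposition of the projected kinship plus Brent
#' optimisation of the variance ratio `delta = sigma2_e / sigma2_g` over
#' `log(delta) in [-10, 10]` (tolerance 1e-8) — then tests every SNP by
#' generalised least squares with that fixed covariance.
#'
#' @param G dosage matrix or genotype list.
#' @param y phenotype vector.
#' @param K kinship matrix from [kinship_matrix()] (defaults to computing it
#'   from `G`).
#' @return a `chill_assoc` tibble (model `"EMMAX"`); attribute `varcomp`
#'   carries `sigma2_g`, `sigma2_e`, `delta`.
#' @export
emmax_scan <- function(G, y, K = NULL) {
  gi <- as_geno(G)
  X <- impute_mean(gi$G)
  n <- nrow(X)
  if (is.null(K)) K <- kinship_matrix(X)
  if (!is.matrix(K) || nrow(K) != n || ncol(K) != n) {
    abort("`K` must be an n x n matrix matching the phenotype length.")
  }
  if (length(y) != n) abort("`y` length must equal the number of accessions.")
  if (max(abs(K - t(K))) > 1e-8) abort("`K` must be symmetric.")
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(1, max(eK$values))) {
    abort("`K` is not positive semidefinite within tolerance.")
  }
  dK <- pmax(eK$values, 0)

  # REML for the null model (intercept only) on the projected kinship
  one <- rep(1, n)
  S <- diag(n) - tcrossprod(one) / n
  M <- S %*% K %*% S
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eM$values[seq_len(n - 1L)], 0)
  Us <- eM$vectors[, seq_len(n - 1L), drop = FALSE]
  eta2 <- as.vector(crossprod(Us, y))^2
  nq <- n - 1L
  reml_ll <- function(ld) {
    delta <- exp(ld)
    R <- sum(eta2 / (lam + delta))
    0.5 * (nq * log(nq / (2 * pi)) - nq - nq * log(R) - sum(log(lam + delta)))
  }
  opt <- optimize(reml_ll, c(-10, 10), maximum = TRUE, tol = 1e-8)
  if (!is.finite(opt$objective)) abort("REML did not converge: non-finite objective.")
  delta <- exp(opt$maximum)
  sigma2_g <- sum(eta2 / (lam + delta)) / nq
  sigma2_e <- delta * sigma2_g

  # GLS scan with fixed covariance: rotate by the eigenvectors of K
  U <- eK$vectors
  w <- 1 / (dK + delta)
  yt <- as.vector(crossprod(U, y))
  x0 <- as.vector(crossprod(U, one))
  Gt <- crossprod(U, X)
  a00 <- sum(w * x0^2)
  b0 <- sum(w * x0 * yt)
  swyy <- sum(w * yt^2)
  a01 <- as.vector(crossprod(Gt, w * x0))
  a11 <- colSums(w * Gt^2)
  b1 <- as.vector(crossprod(Gt, w * yt))
  det_ <- a00 * a11 - a01^2
  ok <- (a11 - a01^2 / a00) > 1e-12
  beta1 <- (a00 * b1 - a01 * b0) / det_
  beta0 <- (a11 * b0 - a01 * b1) / det_
  sse <- pmax(swyy - (beta0 * b0 + beta1 * b1), 0)
  s2 <- sse / (n - 2L)
  se <- sqrt(s2 * a00 / det_)
  tstat <- beta1 / se
  p <- 2 * pt(-abs(tstat), df = n - 2L)
  p[!ok] <- 1
  beta1[!ok] <- NA_real_; se[!ok] <- NA_real_
  out <- new_assoc(gi$snps, beta1, se, p, "EMMAX", !ok)
  attr(out, "varcomp") <- c(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                            delta = delta)
  out
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`; a well-calibrated
#' scan has lambda close to 1.
#'
#' @param pvals p-values in `(0, 1]` (at least 100 of them).
#' @return scalar lambda.
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) < 100L) abort("Need at least 100 p-values for a stable lambda.")
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1].")
  chi <- qchisq(pvals, df = 1, lower.tail = FALSE)
  median(chi) / qchisq(0.5, df = 1)
}

#' Quantile-quantile plot coordinates
#'
#' @param pvals p-values in `(0, 1]`.
#' @return tibble with `expected` and `observed` -log10 p, sorted.
#' @export
qq_table <- function(pvals) {
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1].")
  n <- length(pvals)
  tibble(expected = -log10(stats::ppoints(n)),
         observed = -log10(sort(pvals)))
}

#' Call candidate genes from an association scan
#'
#' A gene is a candidate when at least one SNP with
#' `-log10 p >= threshold_nlp` lies inside the gene body (`[start, end]`,
#' 1-based inclusive) or inside its strand-aware promoter window: the
#' `promoter_bp` bases immediately upstream (`[start - promoter_bp,
#' start - 1]` on "+", `[end + 1, end + promoter_bp]` on "-").
#'
#' @param result a `chill_assoc` tibble with `chrom`, `pos`, `p`,
#'   `neg_log10_p` columns.
#' @param genes data frame: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param threshold_nlp -log10 p cutoff (default 4.5, inclusive).
#' @param promoter_bp promoter window length (default 2000).
#' @return tibble of candidate genes with their best (smallest-p) supporting
#'   SNP: `gene_id`, `chrom`, `start`, `end`, `strand`, `best_pos`,
#'   `best_p`, `best_neg_log10_p`, `n_hits`.
#' @export
call_candidates <- function(result, genes, threshold_nlp = 4.5,
                            promoter_bp = 2000) {
  if (threshold_nlp <= 0) abort("`threshold_nlp` must be positive.")
  if (promoter_bp < 0) abort("`promoter_bp` must be >= 0.")
  if (any(genes$start > genes$end)) abort("Gene annotation with start > end.")
  resort <- !identical(order(genes$chrom, genes$start), seq_len(nrow(genes)))
  if (resort) {
    warn("Gene annotations were not position-sorted; sorting internally.")
    genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  }
  hits <- result[result$neg_log10_p >= threshold_nlp, , drop = FALSE]
  out <- purrr::pmap(genes, function(gene_id, chrom, start, end, strand, ...) {
    win_lo <- if (strand == "-") start else start - promoter_bp
    win_hi <- if (strand == "-") end + promoter_bp else end
    sel <- hits$chrom == chrom & hits$pos >= win_lo & hits$pos <= win_hi
    if (!any(sel)) return(NULL)
    sub <- hits[sel, , drop = FALSE]
    best <- which.min(sub$p)
    tibble(gene_id = gene_id, chrom = chrom, start = start, end = end,
           strand = strand, best_pos = sub$pos[best], best_p = sub$p[best],
           best_neg_log10_p = sub$neg_log10_p[best], n_hits = sum(sel))
  })
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  best_pos = integer(), best_p = double(),
                  best_neg_log10_p = double(), n_hits = integer())
  dplyr::bind_rows(empty, out)
}

#' @export
print.chill_assoc <- function(x, ...) {
  cat(sprintf("<chill_assoc: %s scan, %d SNPs, lambda_GC = %s>\n",
              attr(x, "model"), nrow(x),
              ifelse(is.na(attr(x, "lambda_gc")), "NA",
                     sprintf("%.3f", attr(x, "lambda_gc")))))
  NextMethod()
}

#' @rdname lr_scan
#' @param x a `chill_assoc` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.chill_assoc <- function(x, ...) {
  as_tibble(unclass_assoc(x))
}

#' @rdname lr_scan
#' @exportS3Method generics::glance
#' @export
glance.chill_assoc <- function(x, ...) {
  tibble(model = attr(x, "model"), n_snps = nrow(x),
         lambda_gc = attr(x, "lambda_gc"),
         min_p = min(x$p), max_neg_log10_p = max(x$neg_log10_p))
}

unclass_assoc <- function(x) {
  class(x) <- setdiff(class(x), "chill_assoc")
  attr(x, "model") <- NULL; attr(x, "lambda_gc") <- NULL
  attr(x, "varcomp") <- NULL
  x
}
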
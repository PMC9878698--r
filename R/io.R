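# Readers and writers for the standard interchange formats: dosage TSV,
# minimal VCF v4.2 (biallelic, GT-only), BED6 and GFF3 gene annotations.
# VCF parsing is delegated to vcfR, BED/GFF parsing to rtracklayer; this
# module only converts to and from the package's genotype-list convention:
# list(genotypes = accession x SNP dosage matrix, snps = tibble, accessions).

#' Read a genotype matrix
#'
#' @param path a VCF (v4.2, diploid GT) or dosage TSV file. The TSV layout
#'   is: columns `snp_id`, `chrom`, `pos`, `ref`, `alt`, then one 0/1/2/NA
#'   column per accession (SNPs as rows).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return genotype list: `genotypes` (accessions x SNPs dosage matrix,
#'   dimnames set), `snps` (tibble: snp_id, chrom, pos, ref, alt),
#'   `accessions`; attribute `n_multiallelic_skipped` counts dropped
#'   multiallelic records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
    n_multi <- sum(multi)
    if (n_multi) {
      message(sprintf("Skipped %d multiallelic record(s).", n_multi))
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    alleles <- gsub("[|/]", "", gt)
    if (any(nchar(alleles[!is.na(alleles)]) != 2L)) {
      abort("Non-diploid GT encountered; only ploidy 2 is supported.")
    }
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    known <- !is.na(gt)
    dose[known] <- vapply(strsplit(gt[known], "[|/]"),
                          function(a) sum(a == "1"), numeric(1))
    if (any(!is.na(gt) & !grepl("^[01.][|/][01.]$", gt))) {
      abort("Malformed or non-biallelic GT field.")
    }
    snps <- tibble(snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                   paste0(fix$CHROM, ":", fix$POS), fix$ID),
                   chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT)
    G <- t(dose)  # accessions x SNPs
    colnames(G) <- snps$snp_id
    out <- list(genotypes = G, snps = snps, accessions = rownames(G))
    attr(out, "n_multiallelic_skipped") <- n_multi
    return(out)
  }
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  if (!all(need %in% header)) {
    abort(sprintf("Malformed dosage TSV header: need columns %s.",
                  paste(need, collapse = ", ")))
  }
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          snp_id = readr::col_character(),
                          chrom = readr::col_character(),
                          pos = readr::col_integer(),
                          ref = readr::col_character(),
                          alt = readr::col_character(),
                          .default = readr::col_double()))
  acc <- setdiff(names(tb), need)
  G <- t(as.matrix(tb[, acc]))
  colnames(G) <- tb$snp_id
  rownames(G) <- acc
  out <- list(genotypes = G,
              snps = tb[, need],
              accessions = acc)
  attr(out, "n_multiallelic_skipped") <- 0L
  out
}

#' Write a genotype list
#'
#' @param geno genotype list (see [read_genotypes()]).
#' @param path output file.
#' @param format `"tsv"` (lossless round trip) or `"vcf"` (minimal VCF v4.2,
#'   biallelic, GT-only; missing dosage becomes `./.`).
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  G <- geno$genotypes; snps <- geno$snps
  if (format == "tsv") {
    tb <- dplyr::bind_cols(as_tibble(snps),
                           as_tibble(t(G), .name_repair = "minimal"))
    readr::write_tsv(tb, path)
  } else {
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G)), collapse = "\t"))
    body <- vapply(seq_len(ncol(G)), function(j) {
      gts <- gt_code[as.character(G[, j])]
      gts[is.na(gts)] <- "./."
      paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j], snps$ref[j],
              snps$alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Read gene annotations (BED6 or GFF3)
#'
#' BED input (0-based, half-open) is converted to the internal 1-based
#' inclusive convention; GFF3 `gene` features are taken as-is (all features
#' are used when no `gene` type is present).
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_annotations <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) abort(sprintf("Failed to parse %s: %s", path,
                                      conditionMessage(e))))
  md <- as.data.frame(gr)
  if (format == "gff3" && "type" %in% names(md) && any(md$type == "gene")) {
    md <- md[md$type == "gene", , drop = FALSE]
  }
  id <- md$name %||% md$ID %||% md$gene_id %||% md$Name
  if (is.null(id)) id <- paste0("gene_", seq_len(nrow(md)))
  id <- as.character(id)
  id[is.na(id)] <- paste0("gene_", which(is.na(id)))
  out <- tibble(gene_id = id, chrom = as.character(md$seqnames),
                start = as.integer(md$start), end = as.integer(md$end),
                strand = as.character(md$strand))
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  if (any(out$start < 1)) {
    abort(sprintf("Non-positive coordinate at line(s): %s",
                  paste(which(out$start < 1), collapse = ", ")))
  }
  if (any(out$end < out$start)) {
    abort(sprintf("Annotation with end < start at line(s): %s",
                  paste(which(out$end < out$start), collapse = ", ")))
  }
  out
}
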
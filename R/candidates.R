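# Knockout-mutant validation rules and the expression-phenotype concordance
# classification. The package ships the curated validation tables of the 16
# chilling-tolerance genes and the 9 strong candidates as plain-text
# fixtures; live runs build the same records from compare_mutant() output.

#' Load a packaged gene-validation table
#'
#' Mutant-level records: one row per insertion mutant with the gene's
#' cold/normal expression ratio, the mutant's growth ratio relative to
#' Col-0, its significance call, the GWAS model(s) that flagged the gene,
#' and whether the gene was previously reported as a cold-tolerance gene.
#'
#' @param which `"validated"` (the 16 chilling-tolerance genes) or
#'   `"candidates"` (the 9 strong candidate genes).
#' @return tibble with columns `gene_id`, `protein`, `expression_ratio`,
#'   `mutant_id`, `growth_ratio`, `significant`, `models`,
#'   `previously_reported`.
#' @export
chilling_gene_table <- function(which = c("validated", "candidates")) {
  which <- match.arg(which)
  f <- switch(which,
              validated = "chilling_tolerance_genes.tsv",
              candidates = "strong_candidate_genes.tsv")
  path <- system.file("extdata", f, package = "chillscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    expression_ratio = readr::col_double(),
                    growth_ratio = readr::col_double(),
                    significant = readr::col_logical(),
                    previously_reported = readr::col_logical(),
                    .default = readr::col_character()))
}

#' Classify mutant validation outcomes per gene
#'
#' The validation rule: a gene with two or more significant mutants is
#' `validated`; exactly one significant mutant among two or more tested is a
#' `strong_candidate`; none significant among two or more tested is
#' `rejected`; a single tested mutant is `insufficient` regardless of its
#' outcome.
#'
#' @param records mutant-level tibble with `gene_id` and `significant`
#'   columns (e.g. [chilling_gene_table()] or rows built from
#'   [compare_mutant()]).
#' @return gene-level tibble: `gene_id`, `n_tested`, `n_significant`,
#'   `outcome` (factor: validated / strong_candidate / rejected /
#'   insufficient).
#' @export
classify_validation <- function(records) {
  if (!nrow(records)) abort("No mutant records supplied.")
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_tested = dplyr::n(),
                     n_significant = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(outcome = factor(dplyr::case_when(
      .data$n_tested == 1L ~ "insufficient",
      .data$n_significant >= 2L ~ "validated",
      .data$n_significant == 1L ~ "strong_candidate",
      TRUE ~ "rejected"),
      levels = c("validated", "strong_candidate", "rejected", "insufficient")))
}

#' Concordance class of one gene
#'
#' Compares the direction of the gene's cold-stress expression change with
#' the mean growth response of its knockout mutants: a suppressed gene
#' (ratio < 1) whose mutants outgrow the wild type (mean ratio > 1) is a
#' concordant negative regulator; an induced gene whose mutants grow less is
#' a concordant positive regulator; ties on either axis are indeterminate;
#' anything else is discordant. The MEAN over a gene's mutant ratios is used
#' so that a single aberrant insertion (e.g. a promoter insertion raising
#' rather than ablating expression) does not flip the gene's call.
#'
#' @param expression_ratio cold/normal transcript ratio (positive; NA allowed).
#' @param mutant_ratios numeric vector of mutant/wild-type growth ratios.
#' @return character class: `"concordant_negative_regulator"`,
#'   `"concordant_positive_regulator"`, `"discordant"`, `"indeterminate"`,
#'   or `NA` when the expression ratio is missing.
#' @export
concordance_class <- function(expression_ratio, mutant_ratios) {
  if (!length(mutant_ratios)) abort("Empty mutant ratio list.")
  if (is.na(expression_ratio)) return(NA_character_)
  if (expression_ratio <= 0) abort("`expression_ratio` must be positive.")
  m <- base::mean(mutant_ratios)
  if (expression_ratio == 1 || m == 1) return("indeterminate")
  if (expression_ratio < 1 && m > 1) return("concordant_negative_regulator")
  if (expression_ratio > 1 && m < 1) return("concordant_positive_regulator")
  "discordant"
}

#' Classify concordance for every gene in a record table
#'
#' @param records mutant-level tibble with `gene_id`, `expression_ratio`,
#'   `growth_ratio`.
#' @return gene-level tibble: `gene_id`, `expression_ratio`,
#'   `mean_growth_ratio`, `concordance`.
#' @export
classify_concordance <- function(records) {
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(expression_ratio = dplyr::first(.data$expression_ratio),
                     mean_growth_ratio = base::mean(.data$growth_ratio),
                     .groups = "drop") |>
    dplyr::mutate(concordance = purrr::map2_chr(
      .data$expression_ratio, .data$mean_growth_ratio,
      ~ concordance_class(.x, .y)))
}

#' Tally concordance classes
#'
#' @param records mutant-level record tibble (see [classify_concordance()]).
#' @return one-row tibble: `concordant_negative`, `concordant_positive`,
#'   `discordant`, `indeterminate`, `total_concordant`, `n_genes`.
#' @export
summarize_concordance <- function(records) {
  cls <- classify_concordance(records)
  neg <- sum(cls$concordance == "concordant_negative_regulator", na.rm = TRUE)
  pos <- sum(cls$concordance == "concordant_positive_regulator", na.rm = TRUE)
  tibble(
    concordant_negative = neg,
    concordant_positive = pos,
    discordant = sum(cls$concordance == "discordant", na.rm = TRUE),
    indeterminate = sum(cls$concordance == "indeterminate", na.rm = TRUE),
    total_concordant = neg + pos,
    n_genes = nrow(cls))
}

#' Percentage of genes previously reported in the literature
#'
#' @param records mutant-level record tibble with `gene_id` and
#'   `previously_reported`.
#' @return percent of genes flagged as previously reported.
#' @export
overlap_percentage <- function(records) {
  if (!nrow(records)) abort("Empty record list.")
  genes <- records |>
    dplyr::distinct(.data$gene_id, .data$previously_reported)
  100 * sum(genes$previously_reported) / nrow(genes)
}
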
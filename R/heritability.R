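# Broad-sense heritability from a one-way random-effects ANOVA on an
# accession panel: h2 = sigma2_g / (sigma2_g + sigma2_e).

#' Broad-sense heritability of a phenotype panel
#'
#' Fits the one-way random-effects ANOVA value ~ accession and recovers the
#' variance components by the method of moments: `sigma2_e = MS_within`,
#' `sigma2_g = max(0, (MS_between - MS_within) / n0)` with
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`, the standard unequal-replication
#' coefficient (equal to the replicate count for balanced panels). The
#' heritability estimate is clamped to [0, 1].
#'
#' @param panel data frame of phenotype records.
#' @param value,group column names (strings) of the trait and the accession
#'   id; defaults match [simulate_phenotype_panel()].
#' @param log_area if `TRUE`, the trait is log-transformed first.
#' @return a `chill_h2` object with fields `h2`, `sigma2_g`, `sigma2_e`,
#'   `n_groups`, `n_obs`, `n0`; supports [tidy()] and [glance()].
#' @export
broad_sense_heritability <- function(panel, value = "area",
                                     group = "accession", log_area = FALSE) {
  y <- panel[[value]]
  g <- factor(panel[[group]])
  if (is.null(y) || is.null(panel[[group]])) {
    abort("`panel` must contain the `value` and `group` columns.")
  }
  if (log_area) y <- log_transform(y)
  k <- nlevels(g)
  if (k < 2L) abort("Need at least two accessions.")
  n_i <- tabulate(g)
  N <- length(y)
  if (all(n_i < 2L)) abort("Residual variance inestimable: no accession has two replicates.")
  fit <- aov(y ~ g)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  ms_between <- ms[1L]; ms_within <- ms[2L]
  n0 <- (N - sum(n_i^2) / N) / (k - 1L)
  sigma2_e <- ms_within
  sigma2_g <- max(0, (ms_between - ms_within) / n0)
  h2 <- if (sigma2_g + sigma2_e == 0) 0 else sigma2_g / (sigma2_g + sigma2_e)
  structure(list(h2 = min(max(h2, 0), 1), sigma2_g = sigma2_g,
                 sigma2_e = sigma2_e, n_groups = k, n_obs = N, n0 = n0),
            class = "chill_h2")
}

#' @export
print.chill_h2 <- function(x, ...) {
  cat(sprintf("Broad-sense heritability: h2 = %.3f (sigma2_g = %.3f, sigma2_e = %.3f; %d accessions, %d observations)\n",
              x$h2, x$sigma2_g, x$sigma2_e, x$n_groups, x$n_obs))
  invisible(x)
}

#' @rdname broad_sense_heritability
#' @param x a `chill_h2` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
#' @export
tidy.chill_h2 <- function(x, ...) {
  tibble(term = c("genetic", "residual"),
         variance = c(x$sigma2_g, x$sigma2_e),
         proportion = c(x$sigma2_g, x$sigma2_e) / (x$sigma2_g + x$sigma2_e))
}

#' @rdname broad_sense_heritability
#' @exportS3Method generics::glance
#' @export
glance.chill_h2 <- function(x, ...) {
  tibble(h2 = x$h2, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
         n_groups = x$n_groups, n_obs = x$n_obs, n0 = x$n0)
}
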
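# Top-level orchestration: a YAML-configurable run that takes tray images to
# per-cell areas, joins the genotype map, derives the trait, runs the
# association scan and candidate calling, and writes a machine-readable
# report.

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file. See [run_pipeline()] for the recognised keys.
#' @return config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  cfg
}

require_keys <- function(cfg, keys, where = "config") {
  miss <- setdiff(keys, names(cfg))
  if (length(miss)) {
    abort(sprintf("Missing %s key(s): %s", where, paste(miss, collapse = ", ")))
  }
}

filter_from_config <- function(x, default) {
  if (is.null(x)) return(default)
  color_filter(space = x$space %||% "hsv", lower = unlist(x$lower),
               upper = unlist(x$upper), opening_px = x$opening_px %||% 0)
}

#' Run the full image-to-candidates pipeline
#'
#' Stages: process every tray image to per-cell areas; join the cell-to-
#' genotype map; derive the per-accession trait (mean area, log-transformed
#' by default); optionally scan genotypes (LR or EMMAX after MAF filtering)
#' and call candidate genes; write result tables and a JSON report. Every
#' stage logs its row counts; failures carry the stage name.
#'
#' @param config list (or path to YAML) with keys: `seed`; `out_dir`;
#'   `images` (character vector of PNG paths); `grid` (`rows`, `cols`,
#'   optionally `cell_px`); `map` (TSV path: image_id, cell_row, cell_col,
#'   genotype, treatment, timepoint); optional `filters` (`tray`, `plant`
#'   blocks with `space`/`lower`/`upper`); optional `min_blob_px`,
#'   `calibration`, `margin`, `log_transform` (default `TRUE`); optional
#'   `scan` block (`genotypes`, `model` = "lr"/"emmax", `maf`,
#'   `threshold_nlp`, `promoter_bp`, optional `annotations`).
#' @return list: `measurements`, `phenotype`, `assoc` (or NULL),
#'   `candidates` (or NULL), `report` (also written as JSON), `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  require_keys(config, c("seed", "out_dir", "images", "grid", "map"))
  require_keys(config$grid, c("rows", "cols"), "config$grid")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, message = msg)
  }
  tc <- tray_config(
    rows = config$grid$rows, cols = config$grid$cols,
    tray_filter = filter_from_config(config$filters$tray, default_tray_filter()),
    plant_filter = filter_from_config(config$filters$plant, default_plant_filter()),
    cell_px = config$grid$cell_px,
    min_blob_px = config$min_blob_px %||% 10,
    margin = config$margin %||% 0,
    calibration = config$calibration,
    manual_crop = config$manual_crop)

  imgs <- config$images
  ids <- names(imgs) %||% tools::file_path_sans_ext(basename(imgs))
  meas <- purrr::map2(imgs, ids, ~ process_tray(.x, tc, image_id = .y)) |>
    dplyr::bind_rows()
  note("images", sprintf("%d image(s) -> %d cell measurements",
                         length(imgs), nrow(meas)))

  map_tb <- readr::read_tsv(config$map, show_col_types = FALSE)
  need <- c("image_id", "cell_row", "cell_col", "genotype")
  require_keys(as.list(map_tb), need, "genotype map")
  joined <- dplyr::inner_join(meas, map_tb,
                              by = c("image_id", "cell_row", "cell_col"))
  note("join", sprintf("%d measurements matched to genotypes", nrow(joined)))

  pheno <- joined |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(mean_area = base::mean(.data$area_px), .groups = "drop")
  use_log <- config$log_transform %||% TRUE
  pheno$trait <- if (use_log) log_transform(pheno$mean_area) else pheno$mean_area
  note("trait", sprintf("%d accession trait values (%s)", nrow(pheno),
                        if (use_log) "log mean area" else "mean area"))

  assoc <- NULL; cand <- NULL
  if (!is.null(config$scan)) {
    require_keys(config$scan, "genotypes", "config$scan")
    geno <- read_genotypes(config$scan$genotypes)
    common <- intersect(geno$accessions, pheno$genotype)
    if (length(common) < 3L) abort("Fewer than 3 accessions shared between map and genotypes.")
    G <- geno
    G$genotypes <- geno$genotypes[common, , drop = FALSE]
    y <- pheno$trait[match(common, pheno$genotype)]
    G <- maf_filter(G, config$scan$maf %||% 0.05)
    note("maf", sprintf("%d SNPs retained after MAF filter", ncol(G$genotypes)))
    model <- tolower(config$scan$model %||% "lr")
    assoc <- switch(model,
                    lr = lr_scan(G, y),
                    emmax = emmax_scan(G, y),
                    abort(sprintf("Unknown scan model '%s'.", model)))
    note("scan", sprintf("%s scan, lambda_GC = %.3f", attr(assoc, "model"),
                         attr(assoc, "lambda_gc")))
    if (!is.null(config$scan$annotations)) {
      genes <- read_annotations(config$scan$annotations)
      cand <- call_candidates(assoc, genes,
                              threshold_nlp = config$scan$threshold_nlp %||% 4.5,
                              promoter_bp = config$scan$promoter_bp %||% 2000)
      note("candidates", sprintf("%d candidate gene(s)",
                                 if (is.null(cand)) 0L else nrow(cand)))
    }
  }

  readr::write_csv(meas, file.path(out_dir, "measurements.csv"))
  readr::write_tsv(pheno, file.path(out_dir, "phenotype.tsv"))
  if (!is.null(assoc)) {
    readr::write_tsv(tidy(assoc), file.path(out_dir, "association.tsv"))
    readr::write_csv(qq_table(assoc$p), file.path(out_dir, "qq.csv"))
  }
  if (!is.null(cand) && nrow(cand)) {
    readr::write_tsv(cand, file.path(out_dir, "candidates.tsv"))
  }
  logtb <- dplyr::bind_rows(log)
  report <- list(
    seed = config$seed,
    n_images = length(imgs),
    n_cells = nrow(meas),
    n_accessions = nrow(pheno),
    model = if (is.null(assoc)) NULL else attr(assoc, "model"),
    lambda_gc = if (is.null(assoc)) NULL else attr(assoc, "lambda_gc"),
    n_snps = if (is.null(assoc)) NULL else nrow(assoc),
    n_candidates = if (is.null(cand)) NULL else nrow(cand),
    candidate_genes = if (is.null(cand) || !nrow(cand)) NULL else cand$gene_id,
    log = logtb)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(measurements = meas, phenotype = pheno, assoc = assoc,
       candidates = cand, report = report, log = logtb)
}
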
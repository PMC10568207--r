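#' Write labeled counts to a Matrix Market directory
#'
#' Writes the four species matrices as `pl.mtx`, `ml.mtx`, `pu.mtx`,
#' `mu.mtx` with shared `barcodes.tsv` and `features.tsv`, plus `cells.tsv`
#' (per-cell metadata including phase in radians and, for readability, in
#' hours).
#'
#' @param counts A `labeled_counts` object.
#' @param dir Output directory (created if needed).
#' @param period Cell-cycle period in hours used for the phase-in-hours
#'   column.
#' @return `dir`, invisibly.
#' @export
write_labeled_counts <- function(counts, dir, period = 19.33) {
  stopifnot(inherits(counts, "labeled_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in c("pl", "ml", "pu", "mu")) {
    Matrix::writeMM(methods::as(counts[[sp]], "CsparseMatrix"),
                    file.path(dir, paste0(sp, ".mtx")))
  }
  readr::write_tsv(tibble::tibble(cell_barcode = colnames(counts$pl)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(gene = rownames(counts$pl)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  cells <- counts$cells
  if ("phase" %in% names(cells)) {
    cells$phase_hours <- cells$phase / (2 * pi) * period
  }
  readr::write_tsv(cells, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read labeled counts from a Matrix Market directory
#'
#' Inverse of [write_labeled_counts()]. All four species matrices must be
#' present; barcodes on disk may be in any order in `cells.tsv`, the result
#' is aligned by barcode key. Unknown or missing barcodes are an error.
#'
#' @param dir Directory containing `pl.mtx`, `ml.mtx`, `pu.mtx`, `mu.mtx`,
#'   `barcodes.tsv`, `features.tsv`, `cells.tsv`.
#' @return A `labeled_counts` object.
#' @export
read_labeled_counts <- function(dir) {
  species <- c("pl", "ml", "pu", "mu")
  paths <- file.path(dir, paste0(species, ".mtx"))
  missing <- species[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("missing species matrix file(s): ",
         paste(paste0(missing, ".mtx"), collapse = ", "))
  }
  cells_path <- file.path(dir, "cells.tsv")
  if (!file.exists(cells_path)) stop("cells.tsv is missing in ", dir)
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = "cell_barcode",
                              show_col_types = FALSE)$cell_barcode
  genes <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = "gene", show_col_types = FALSE)$gene
  cells <- readr::read_tsv(cells_path, show_col_types = FALSE)
  if (!"cell_barcode" %in% names(cells)) {
    stop("cells.tsv is corrupt: no cell_barcode column")
  }
  mismatched <- union(setdiff(cells$cell_barcode, barcodes),
                      setdiff(barcodes, cells$cell_barcode))
  if (length(mismatched) > 0) {
    stop("barcodes.tsv and cells.tsv disagree for: ",
         paste(utils::head(mismatched, 5), collapse = ", "))
  }
  # align metadata rows to the matrix column order
  cells <- cells[match(barcodes, cells$cell_barcode), ]
  mats <- lapply(paths, function(p) {
    m <- methods::as(Matrix::readMM(p), "CsparseMatrix")
    dimnames(m) <- list(genes, barcodes)
    m
  })
  names(mats) <- species
  labeled_counts(pl = mats$pl, ml = mats$ml, pu = mats$pu, mu = mats$mu,
                 cells = cells)
}

# Per-gene per-cell mature observations extracted from a labeled_counts.
gene_cells <- function(counts, gene) {
  tibble::tibble(
    cell_barcode = counts$cells$cell_barcode,
    phase = counts$cells$phase,
    mu = as.numeric(counts$mu[gene, ]),
    ml = as.numeric(counts$ml[gene, ])
  )
}

#' Run the downstream kinetic pipeline end to end
#'
#' Given a directory of labeled count matrices (or a `labeled_counts`
#' object), smooths every gene, estimates simplified-model rates, computes
#' predictions, deviations, peak calls and classifications, and writes
#' `gene_kinetics.tsv`, per-gene rate profile TSVs and a provenance record.
#' Deterministic given the configuration.
#'
#' @param config A list (or path to a YAML file) with entries: `input`
#'   (counts directory) or `counts` (a `labeled_counts`), `output_dir`,
#'   `labeling_time_hours`, and optionally `period_hours` (19.33),
#'   `grid_points` (200), `genes`, `dev_threshold` (0.2), `mode_threshold`
#'   (0.2), `seed` (1).
#' @return Tibble of per-gene results (also written to disk), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("output_dir", "labeling_time_hours")
  if (!all(need %in% names(config))) {
    stop("config stage: missing entries ",
         paste(setdiff(need, names(config)), collapse = ", "))
  }
  counts <- if (!is.null(config$counts)) {
    config$counts
  } else if (!is.null(config$input)) {
    tryCatch(read_labeled_counts(config$input),
             error = function(e) stop("read stage: ", conditionMessage(e)))
  } else {
    stop("config stage: provide either input (directory) or counts (object)")
  }
  if (!"phase" %in% names(counts$cells)) {
    stop("read stage: cells metadata lacks a phase column")
  }
  grid <- phase_grid(n = config$grid_points %||% 200,
                     period = config$period_hours %||% 19.33)
  genes <- config$genes %||% rownames(counts$ml)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed %||% 1)
  results <- purrr::map(genes, function(g) {
    fit <- tryCatch(
      fit_gene_kinetics(gene_cells(counts, g),
                        t = config$labeling_time_hours, grid = grid,
                        dev_threshold = config$dev_threshold %||% 0.2,
                        mode_threshold = config$mode_threshold %||% 0.2),
      error = function(e) stop("estimate stage (gene ", g, "): ",
                               conditionMessage(e))
    )
    readr::write_tsv(
      tibble::as_tibble(fit$estimates),
      file.path(config$output_dir, paste0("rates_", g, ".tsv"))
    )
    dplyr::bind_cols(tibble::tibble(gene = g), tidy(fit))
  })
  table <- dplyr::bind_rows(results)
  readr::write_tsv(table, file.path(config$output_dir, "gene_kinetics.tsv"))
  prov <- config[setdiff(names(config), "counts")]
  prov$package_version <- as.character(utils::packageVersion("cyclerates"))
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
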
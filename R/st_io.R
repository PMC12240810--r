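#' Spot-level spatial transcriptomics container
#'
#' A `spot_matrix` bundles a sparse gene-by-spot count matrix with the spot
#' coordinates and identifier vectors that every downstream operation needs.
#' Counts are stored as a [Matrix::sparseMatrix()]; coordinates share one
#' (unit-agnostic) length unit within a dataset.
#'
#' @param counts Non-negative numeric matrix or sparse Matrix, genes x spots.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param barcodes Character vector of unique spot identifiers (columns).
#' @param coords Numeric matrix, spots x 2, planar spot positions.
#' @param spot_diameter Optional positive spot diameter in coordinate units.
#' @param meta Optional named list of free-form annotations (e.g.
#'   `unit = "TPM"` marks profiles that normalization must pass through).
#' @return An object of class `spot_matrix`.
#' @export
spot_matrix <- function(counts, gene_ids, barcodes, coords,
                        spot_diameter = NULL, meta = list()) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  obj <- structure(
    list(counts = counts, gene_ids = as.character(gene_ids),
         barcodes = as.character(barcodes), coords = coords,
         spot_diameter = spot_diameter, meta = meta),
    class = "spot_matrix"
  )
  validate_spot_matrix(obj)
}

validate_spot_matrix <- function(m) {
  stopifnot(inherits(m, "spot_matrix"))
  if (nrow(m$counts) != length(m$gene_ids))
    stop("counts rows (", nrow(m$counts), ") != length(gene_ids) (",
         length(m$gene_ids), ")")
  if (ncol(m$counts) != length(m$barcodes))
    stop("counts columns != length(barcodes)")
  if (nrow(m$coords) != length(m$barcodes) || ncol(m$coords) != 2)
    stop("coords must be spots x 2 and match barcodes")
  if (anyDuplicated(m$gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(m$barcodes)) stop("barcodes must be unique")
  if (any(m$counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(m$spot_diameter) && m$spot_diameter <= 0)
    stop("spot_diameter must be positive")
  dimnames(m$counts) <- list(m$gene_ids, m$barcodes)
  rownames(m$coords) <- m$barcodes
  m
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("spot_matrix: %d genes x %d spots\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.spot_matrix <- function(x) dim(x$counts)

subset_spots <- function(m, idx) {
  spot_matrix(m$counts[, idx, drop = FALSE], m$gene_ids, m$barcodes[idx],
              m$coords[idx, , drop = FALSE], m$spot_diameter, m$meta)
}

subset_genes <- function(m, idx) {
  spot_matrix(m$counts[idx, , drop = FALSE], m$gene_ids[idx], m$barcodes,
              m$coords, m$spot_diameter, m$meta)
}

#' Read a spot matrix from a Matrix Market directory
#'
#' Expects the conventional trio `matrix.mtx` (genes x spots), `features.tsv`,
#' `barcodes.tsv`, plus a spot-position table `positions.csv` with columns
#' `barcode, in_tissue, array_row, array_col, x, y`. Spots absent from the
#' position table are dropped (logged); spots flagged `in_tissue == 0` are
#' excluded unless `keep_out_of_tissue = TRUE`.
#'
#' @param path Directory containing the four files.
#' @param keep_out_of_tissue Keep spots with `in_tissue == 0`? Default `FALSE`.
#' @return A [spot_matrix()].
#' @export
read_spot_matrix <- function(path, keep_out_of_tissue = FALSE) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "positions.csv")
  paths <- file.path(path, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s) in ", path, ": ", paste(missing, collapse = ", "))
  counts <- Matrix::readMM(paths[1])
  feats <- utils::read.delim(paths[2], header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(paths[3], header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  pos <- utils::read.csv(paths[4], stringsAsFactors = FALSE)
  gene_ids <- feats[[1]]
  keep_bc <- intersect(barcodes, pos$barcode)
  if (length(keep_bc) == 0)
    stop("no barcode overlap between matrix and position table")
  dropped <- length(barcodes) - length(keep_bc)
  if (dropped > 0)
    log_msg("read_spot_matrix: dropping %d spot(s) without positions", dropped)
  pos <- pos[match(keep_bc, pos$barcode), , drop = FALSE]
  if (!keep_out_of_tissue && "in_tissue" %in% names(pos)) {
    keep <- pos$in_tissue != 0
    if (!all(keep))
      log_msg("read_spot_matrix: excluding %d out-of-tissue spot(s)",
              sum(!keep))
    pos <- pos[keep, , drop = FALSE]
    keep_bc <- keep_bc[keep]
  }
  col_idx <- match(keep_bc, barcodes)
  meta <- list()
  manifest <- file.path(path, "manifest.json")
  if (file.exists(manifest)) {
    mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    meta <- mf$meta %||% list()
  }
  spot_matrix(counts[, col_idx, drop = FALSE], gene_ids, keep_bc,
              cbind(x = pos$x, y = pos$y), meta = as.list(meta))
}

#' Write a spot matrix as a Matrix Market directory
#'
#' Inverse of [read_spot_matrix()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, `positions.csv` and a JSON manifest. Coordinates are
#' serialized at full double precision so a round trip preserves them to
#' better than 1e-9.
#'
#' @param m A [spot_matrix()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_spot_matrix <- function(m, path) {
  validate_spot_matrix(m)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(m$gene_ids, m$gene_ids),
                     file.path(path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, file.path(path, "barcodes.tsv"))
  pos <- data.frame(barcode = m$barcodes, in_tissue = 1L,
                    array_row = seq_along(m$barcodes) - 1L,
                    array_col = seq_along(m$barcodes) - 1L,
                    x = sprintf("%.17g", m$coords[, 1]),
                    y = sprintf("%.17g", m$coords[, 2]))
  utils::write.csv(pos, file.path(path, "positions.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(format = "spatlink-spot-matrix", n_genes = nrow(m$counts),
         n_spots = ncol(m$counts), spot_diameter = m$spot_diameter,
         meta = m$meta),
    file.path(path, "manifest.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Map gene identifiers to symbols
#'
#' Renames rows via an identifier-to-symbol table (e.g. Ensembl to HGNC).
#' Rows without a mapping are dropped; rows mapping to the same symbol are
#' summed, conserving library size.
#'
#' @param m A [spot_matrix()].
#' @param gene_map Two-column data frame (identifier, symbol) or the path of a
#'   two-column TSV without header.
#' @return A [spot_matrix()] keyed by symbols.
#' @export
map_gene_ids <- function(m, gene_map) {
  if (is.character(gene_map) && length(gene_map) == 1)
    gene_map <- utils::read.delim(gene_map, header = FALSE,
                                  stringsAsFactors = FALSE)
  gene_map <- as.data.frame(gene_map)[, 1:2]
  names(gene_map) <- c("id", "symbol")
  if (anyDuplicated(gene_map$id))
    stop("gene map: each source identifier may appear at most once")
  sym <- gene_map$symbol[match(m$gene_ids, gene_map$id)]
  keep <- !is.na(sym)
  if (!any(keep)) stop("no gene identifier could be mapped to a symbol")
  dropped <- sum(!keep)
  if (dropped > 0)
    log_msg("map_gene_ids: dropping %d unmapped gene(s)", dropped)
  counts <- m$counts[keep, , drop = FALSE]
  sym <- sym[keep]
  if (anyDuplicated(sym)) {
    # duplicate symbols summed (conserves total counts over mappable genes)
    agg <- Matrix::fac2sparse(factor(sym, levels = unique(sym)))
    counts <- agg %*% counts
    sym <- unique(sym)
  }
  spot_matrix(counts, sym, m$barcodes, m$coords, m$spot_diameter, m$meta)
}

#' Filter spots by number of expressed genes
#'
#' Retains spots with strictly more than `min_genes` genes having count > 0
#' (the strict reading of "over 200 expressed genes"); spot order preserved.
#'
#' @param m A [spot_matrix()].
#' @param min_genes Threshold; default 200.
#' @param strict Use strict inequality (default) or `>=`.
#' @return Filtered [spot_matrix()].
#' @export
qc_filter_spots <- function(m, min_genes = 200, strict = TRUE) {
  n_expr <- Matrix::colSums(m$counts > 0)
  keep <- if (strict) n_expr > min_genes else n_expr >= min_genes
  if (!any(keep))
    stop("qc_filter_spots removed every spot (min_genes = ", min_genes, ")")
  subset_spots(m, which(keep))
}

#' Remove housekeeping genes
#'
#' Drops rows whose symbol appears in the housekeeping list; spots untouched.
#' An empty intersection is a logged no-op.
#'
#' @param m A [spot_matrix()].
#' @param housekeeping Character vector of symbols, or path of a one-symbol-
#'   per-line text file.
#' @return A [spot_matrix()] without the listed genes.
#' @export
remove_housekeeping <- function(m, housekeeping) {
  if (is.character(housekeeping) && length(housekeeping) == 1 &&
      file.exists(housekeeping))
    housekeeping <- readLines(housekeeping)
  housekeeping <- housekeeping[nzchar(housekeeping)]
  if (length(housekeeping) == 0) stop("housekeeping list is empty")
  hit <- m$gene_ids %in% housekeeping
  if (!any(hit)) {
    log_msg("remove_housekeeping: no listed gene present; matrix unchanged")
    return(m)
  }
  subset_genes(m, which(!hit))
}
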
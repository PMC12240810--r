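# Gene-sentence construction: an expression profile becomes an ordered,
# space-joined list of its top-expressed gene symbols, the text-modality input.

#' Construct a gene sentence from a single expression profile
#'
#' Takes the `k` highest-valued genes in descending order of expression. Ties
#' are broken by ascending input gene order (deterministic across runs); genes
#' with value 0 are never included, so fewer than `k` symbols may be emitted.
#'
#' @param expr Named numeric vector of per-gene values (names are symbols).
#' @param k Maximum sentence length in gene symbols; default 50.
#' @return A `gene_sentence`: list with `genes` (character vector) and `text`
#'   (symbols joined by single spaces).
#' @export
build_sentence <- function(expr, k = 50) {
  if (is.null(names(expr)) || any(!nzchar(names(expr))))
    stop("expression vector must be named by gene symbols")
  if (all(expr <= 0)) stop("all-zero expression profile: no sentence to build")
  pos <- which(expr > 0)
  # order(-value, index): descending value, ties by ascending input order
  ord <- pos[order(-expr[pos], pos)]
  genes <- names(expr)[utils::head(ord, k)]
  new_gene_sentence(genes)
}

new_gene_sentence <- function(genes) {
  if (any(grepl("\\s", genes))) stop("gene symbols must not contain whitespace")
  if (anyDuplicated(genes)) stop("gene sentence must not repeat symbols")
  structure(list(genes = genes, text = paste(genes, collapse = " ")),
            class = "gene_sentence")
}

#' @export
print.gene_sentence <- function(x, ...) {
  cat("gene_sentence:", x$text, "\n")
  invisible(x)
}

#' Library-size normalize a spot matrix
#'
#' Per-spot scaling to a fixed total (default 10,000) followed by `log1p`.
#' Profiles whose `meta$unit` marks them as TPM/FPKM are already on a
#' normalized scale and pass through unchanged. Per-spot ranking of genes is
#' invariant to this transform; it matters only for exported matrices.
#'
#' @param m A [spot_matrix()].
#' @param target_sum Per-spot total after scaling; default 1e4.
#' @return A [spot_matrix()] of normalized values.
#' @export
normalize_counts <- function(m, target_sum = 1e4) {
  unit <- toupper(m$meta$unit %||% "counts")
  if (unit %in% c("TPM", "FPKM")) return(m)
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0))
    stop("zero-count spot(s) present; run qc_filter_spots first")
  norm <- m$counts %*% Matrix::Diagonal(x = target_sum / tot)
  norm@x <- log1p(norm@x)
  spot_matrix(norm, m$gene_ids, m$barcodes, m$coords, m$spot_diameter,
              utils::modifyList(m$meta, list(unit = "lognorm")))
}

#' Build a sentence corpus from a spot matrix
#'
#' One record per spot, each holding the spot's top-`k` gene sentence and an
#' optional image-patch reference. Exact duplicate (sentence, patch) records
#' are removed, mirroring corpus-level deduplication.
#'
#' @param m A [spot_matrix()] (raw or normalized; ranking is identical).
#' @param k Sentence length cap; default 50.
#' @param patches Optional character vector of per-spot patch references.
#' @return A `sentence_corpus`: data frame with columns `id`, `sentence`,
#'   `patch`.
#' @export
build_corpus <- function(m, k = 50, patches = NULL) {
  dense <- as.matrix(m$counts)
  sentences <- vapply(seq_len(ncol(dense)), function(j) {
    v <- dense[, j]
    names(v) <- m$gene_ids
    build_sentence(v, k)$text
  }, character(1))
  patch <- if (is.null(patches)) NA_character_ else as.character(patches)
  corpus <- data.frame(id = m$barcodes, sentence = sentences, patch = patch,
                       stringsAsFactors = FALSE)
  dup <- duplicated(corpus[, c("sentence", "patch")])
  if (any(dup)) {
    log_msg("build_corpus: removing %d duplicate record(s)", sum(dup))
    corpus <- corpus[!dup, , drop = FALSE]
  }
  rownames(corpus) <- NULL
  class(corpus) <- c("sentence_corpus", "data.frame")
  corpus
}

#' Convert a bulk profile to a gene sentence
#'
#' Bulk (or pseudo-bulk) references use the same top-`k` ranking rule as
#' spots, so reference and query sentences live in one convention.
#'
#' @param profile Named numeric vector or two-column data frame
#'   (gene, value).
#' @param k Sentence length cap; default 50.
#' @return A `gene_sentence`.
#' @export
profile_to_sentence <- function(profile, k = 50) {
  if (is.data.frame(profile)) {
    v <- profile[[2]]
    names(v) <- as.character(profile[[1]])
    profile <- v
  }
  build_sentence(profile, k)
}

#' Convert an ordered marker-gene list to a sentence
#'
#' Markers are joined in the user-given order; duplicates are removed keeping
#' the first occurrence.
#'
#' @param markers Character vector of gene symbols.
#' @return A `gene_sentence`.
#' @export
marker_sentence <- function(markers) {
  markers <- as.character(markers)
  if (length(markers) == 0) stop("marker list is empty")
  new_gene_sentence(markers[!duplicated(markers)])
}

#' Write a sentence corpus as JSON-lines or TSV
#'
#' @param corpus A `sentence_corpus`.
#' @param path Output file; `.jsonl` writes one JSON object per line,
#'   anything else a TSV with header.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (grepl("\\.jsonl$", path)) {
    lines <- vapply(seq_len(nrow(corpus)), function(i)
      jsonlite::toJSON(as.list(corpus[i, , drop = FALSE])[c("id", "sentence",
                                                            "patch")],
                       auto_unbox = TRUE, null = "null"),
      character(1))
    writeLines(lines, path)
  } else {
    utils::write.table(corpus, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
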
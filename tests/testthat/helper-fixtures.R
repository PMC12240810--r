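# Shared fixture builders; everything is generated in code at test time.

toy_spot_matrix <- function(counts = rbind(c(5, 0), c(1, 2), c(0, 3)),
                            gene_ids = c("TP53", "ACTB", "EPCAM"),
                            barcodes = c("bc1", "bc2"),
                            coords = cbind(x = c(0, 1), y = c(0, 0))) {
  spot_matrix(counts, gene_ids, barcodes, coords)
}

random_spot_matrix <- function(n_genes = 30, n_spots = 12, seed = 1,
                               lambda = 5) {
  withr_seed <- function(expr) {
    set.seed(seed)
    expr
  }
  withr_seed({
    counts <- matrix(rpois(n_genes * n_spots, lambda), n_genes, n_spots)
    spot_matrix(counts, sprintf("G%02d", seq_len(n_genes)),
                sprintf("bc%02d", seq_len(n_spots)),
                cbind(runif(n_spots), runif(n_spots)))
  })
}

write_mtx_fixture <- function(dir, m = toy_spot_matrix(),
                              drop_position_for = NULL) {
  write_spot_matrix(m, dir)
  if (!is.null(drop_position_for)) {
    pos <- read.csv(file.path(dir, "positions.csv"))
    pos <- pos[!pos$barcode %in% drop_position_for, , drop = FALSE]
    write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE,
              quote = FALSE)
  }
  dir
}

# Deterministic small paired cohort used across module tests
small_cohort <- function(seed = 1, n_spots = 100, n_genes = 120, ...) {
  simulate_paired_cohort(cohort_spec(n_spots = n_spots, n_genes = n_genes,
                                     seed = seed, ...))
}

# text embeddings of a cohort, rows ordered like the spot barcodes
cohort_text_embs <- function(cohort, cfg) {
  e <- encode_corpus(build_corpus(cohort$spots, k = cfg$max_genes), cfg)
  e[match(cohort$spots$barcodes, rownames(e)), , drop = FALSE]
}

# per-type pure-profile reference embeddings from the cohort loading matrix
cohort_type_refs <- function(cohort, cfg) {
  t(vapply(colnames(cohort$fractions), function(ty) {
    v <- cohort$loadings[, ty]
    names(v) <- rownames(cohort$loadings)
    encode_text(build_sentence(v, cfg$max_genes), cfg)
  }, numeric(cfg$embed_dim)))
}
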
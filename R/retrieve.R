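# Image-to-transcriptomics retrieval: rank a bank of transcriptomic
# embeddings by cosine similarity to an image query; score with Recall@K over
# quantile ranks.

#' Retrieval bank
#'
#' @param embeddings Entries x d embedding matrix; no zero rows.
#' @param entry_ids Unique identifiers; default rownames or `E1, E2, ...`.
#' @param paired_image_embs Optional entries x d embeddings of each entry's
#'   paired image (for similarity reports).
#' @return A `retrieval_bank` list.
#' @export
retrieval_bank <- function(embeddings, entry_ids = NULL,
                           paired_image_embs = NULL) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) == 0) stop("empty retrieval bank")
  if (any(rowSums(embeddings^2) == 0)) stop("bank contains zero embeddings")
  entry_ids <- entry_ids %||% rownames(embeddings) %||%
    paste0("E", seq_len(nrow(embeddings)))
  if (anyDuplicated(entry_ids)) stop("entry ids must be unique")
  if (!is.null(paired_image_embs)) {
    paired_image_embs <- as.matrix(paired_image_embs)
    stopifnot(nrow(paired_image_embs) == nrow(embeddings))
  }
  structure(list(embeddings = embeddings, entry_ids = as.character(entry_ids),
                 paired_image_embs = paired_image_embs),
            class = "retrieval_bank")
}

#' Retrieve the top-k bank entries for a query embedding
#'
#' Entries are ranked by descending cosine similarity to the query; ties
#' break by bank insertion order. When `truth_id` is supplied the ground
#' truth's quantile rank (1-based rank / bank size) is recorded for
#' [recall_at_k()].
#'
#' @param query Query embedding vector.
#' @param bank A [retrieval_bank()].
#' @param k Number of entries returned; defaults to the full bank.
#' @param truth_id Optional identifier of the ground-truth entry.
#' @return A `ranked_retrieval`: list with `entry_ids`, `scores`
#'   (non-increasing), `rank_of_truth`, `quantile`.
#' @export
retrieve_topk <- function(query, bank, k = NULL, truth_id = NULL) {
  stopifnot(inherits(bank, "retrieval_bank"))
  n <- nrow(bank$embeddings)
  k <- k %||% n
  if (k > n) stop("k exceeds bank size")
  sims <- as.numeric(cosine_matrix(rbind(query), bank$embeddings))
  ord <- order(-sims, seq_len(n)) # stable: ties by insertion order
  rank_of_truth <- NA_integer_; quant <- NA_real_
  if (!is.null(truth_id)) {
    pos <- match(truth_id, bank$entry_ids)
    if (is.na(pos)) stop("truth_id not present in bank")
    rank_of_truth <- which(ord == pos)
    quant <- rank_of_truth / n
  }
  structure(list(entry_ids = bank$entry_ids[ord[seq_len(k)]],
                 scores = sims[ord[seq_len(k)]],
                 rank_of_truth = rank_of_truth, quantile = quant,
                 bank_size = n),
            class = "ranked_retrieval")
}

#' Recall at a quantile threshold K
#'
#' Fraction of queries whose ground-truth entry ranks within the top-K
#' quantile of the bank: `(1/N) sum_q 1[quantile(q) <= K]` with
#' `quantile(q) = rank(truth)/bank size`.
#'
#' @param results List of `ranked_retrieval` objects with known truth.
#' @param K Quantile threshold in `(0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
recall_at_k <- function(results, K) {
  stopifnot(K > 0, K <= 1)
  q <- vapply(results, function(r) r$quantile, numeric(1))
  if (anyNA(q)) stop("every result needs a known ground-truth entry")
  mean(q <= K)
}

#' Similarity of query images to their retrieved entries' paired images
#'
#' For each query, the top-1 transcriptomic entry is retrieved and the
#' reported score is the cosine similarity between the query image embedding
#' and the paired image embedding of that entry (the ground-truth proxy used
#' when true transcriptomics are unavailable). Entries lacking paired images
#' are excluded with a warning.
#'
#' @param query_embs Query image embeddings, q x d.
#' @param bank A [retrieval_bank()] with `paired_image_embs`.
#' @return List with `per_query` (data frame: query, retrieved, score) and
#'   `median_score`.
#' @export
retrieval_similarity_report <- function(query_embs, bank) {
  stopifnot(inherits(bank, "retrieval_bank"))
  if (is.null(bank$paired_image_embs))
    stop("bank carries no paired image embeddings")
  ok <- rowSums(bank$paired_image_embs^2) > 0
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " bank entr(ies) lacking paired images")
    bank <- retrieval_bank(bank$embeddings[ok, , drop = FALSE],
                           bank$entry_ids[ok],
                           bank$paired_image_embs[ok, , drop = FALSE])
  }
  query_embs <- rbind(query_embs)
  rows <- lapply(seq_len(nrow(query_embs)), function(i) {
    top <- retrieve_topk(query_embs[i, ], bank, k = 1)
    j <- match(top$entry_ids[1], bank$entry_ids)
    data.frame(query = rownames(query_embs)[i] %||% as.character(i),
               retrieved = top$entry_ids[1],
               score = cosine_similarity(query_embs[i, ],
                                         bank$paired_image_embs[j, ]))
  })
  per <- do.call(rbind, rows)
  list(per_query = per, median_score = stats::median(per$score))
}
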
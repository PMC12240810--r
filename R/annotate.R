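# Zero-shot tissue annotation: patches are scored against reference
# embeddings derived from bulk profiles or marker-gene sentences, with
# optional fusion of two models' score tables.

#' Cosine-similarity map of patches against one reference embedding
#'
#' Higher similarity indicates greater presence of the reference tissue type
#' at a patch; with coordinates attached the vector renders as a heat map.
#'
#' @param patch_embs Patch embeddings, n x d.
#' @param ref Reference embedding vector, length d.
#' @param coords Optional n x 2 coordinates carried through to the output.
#' @return Data frame with `id`, `score` and optional `x`, `y`.
#' @export
similarity_map <- function(patch_embs, ref, coords = NULL) {
  patch_embs <- as.matrix(patch_embs)
  scores <- as.numeric(cosine_matrix(patch_embs, rbind(ref)))
  out <- data.frame(id = rownames(patch_embs) %||%
                      as.character(seq_len(nrow(patch_embs))),
                    score = scores)
  if (!is.null(coords)) {
    out$x <- coords[, 1]; out$y <- coords[, 2]
  }
  out
}

#' Build a patches x candidates similarity score table
#'
#' @param patch_embs Patch embeddings, n x d.
#' @param candidate_embs Candidate reference embeddings, c x d, with unique
#'   rownames as labels.
#' @return A `score_table`: numeric matrix images x candidates.
#' @export
score_table <- function(patch_embs, candidate_embs) {
  candidate_embs <- as.matrix(candidate_embs)
  if (nrow(candidate_embs) < 2) stop("need at least 2 candidates")
  labels <- rownames(candidate_embs)
  if (is.null(labels) || anyDuplicated(labels))
    stop("candidate embeddings need unique rownames as labels")
  s <- cosine_matrix(as.matrix(patch_embs), candidate_embs)
  colnames(s) <- labels
  class(s) <- c("score_table", class(s))
  s
}

#' Zero-shot classification by maximum cosine similarity
#'
#' Each patch receives the label of its most similar candidate; ties resolve
#' to the first candidate in input order.
#'
#' @param patch_embs Patch embeddings, n x d (a single vector is accepted).
#' @param candidate_embs Labeled candidate embeddings, c x d (unique
#'   rownames).
#' @return List with `labels` (character vector) and `scores` (the score
#'   table).
#' @export
zero_shot_classify <- function(patch_embs, candidate_embs) {
  if (is.null(dim(patch_embs))) patch_embs <- rbind(patch_embs)
  s <- score_table(patch_embs, candidate_embs)
  idx <- max.col(s, ties.method = "first")
  list(labels = colnames(s)[idx], scores = s)
}

#' Fuse two score tables by per-image min-max normalization and summation
#'
#' Each table's row is min-max normalized over candidates, the normalized
#' tables are summed, and the per-image argmax gives the fused label. A
#' degenerate row (max equals min) contributes the neutral value 0.5 to every
#' candidate.
#'
#' @param a,b Score tables over identical images (rows) and candidate labels
#'   (columns).
#' @return List with `scores` (fused table) and `labels` (per-image argmax,
#'   ties to the first candidate).
#' @export
fuse_scores <- function(a, b) {
  a <- unclass(as.matrix(a)); b <- unclass(as.matrix(b))
  if (!identical(dim(a), dim(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("score tables must share images and candidate labels")
  minmax <- function(m) {
    lo <- apply(m, 1, min); hi <- apply(m, 1, max)
    span <- hi - lo
    out <- (m - lo) / ifelse(span == 0, 1, span)
    out[span == 0, ] <- 0.5
    out
  }
  fused <- minmax(a) + minmax(b)
  idx <- max.col(fused, ties.method = "first")
  list(scores = fused, labels = colnames(fused)[idx])
}

#' Precision, recall and weighted F1 of a label prediction
#'
#' Per-class precision, recall and `F1 = 2 TP / (2 TP + FP + FN)`; the
#' weighted F1 averages class F1 scores weighted by true class frequency.
#'
#' @param pred,truth Equal-length label vectors.
#' @return List with `per_class` (data frame: class, n, precision, recall,
#'   f1), `weighted_f1`, and `confusion` (truth rows x prediction columns).
#' @export
evaluate_classification <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be non-empty and of equal length")
  classes <- sort(unique(c(pred, truth)))
  pred <- factor(pred, levels = classes)
  truth <- factor(truth, levels = classes)
  confusion <- table(truth = truth, pred = pred)
  per <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    data.frame(class = cl, n = sum(truth == cl), precision = precision,
               recall = recall, f1 = f1)
  })
  per <- do.call(rbind, per)
  keep <- per$n > 0
  weighted_f1 <- sum(per$f1[keep] * per$n[keep]) / sum(per$n[keep])
  list(per_class = per, weighted_f1 = weighted_f1, confusion = confusion)
}
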
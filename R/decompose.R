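# Cell-type decomposition: a probabilistic mapping matrix M (spots x
# reference profiles) is optimized by gradient descent so that the projected
# reference embeddings M S match the spatial embeddings G column-by-column in
# cosine distance; per-spot type fractions follow by summing each type's
# mapped mass, with optional non-maximum-suppression refinement.

#' Collapse cell embeddings to cluster-level reference profiles
#'
#' Mapping at the cluster level (mean embedding per cluster, cluster sizes
#' recorded) keeps the optimization small without changing the model.
#'
#' @param cell_embs Cell embeddings, cells x d.
#' @param labels Cluster (cell-type) label per cell.
#' @return List with `embeddings` (clusters x d), `cell_types` (label per
#'   row) and `cluster_sizes`.
#' @export
cluster_profiles <- function(cell_embs, labels) {
  cell_embs <- as.matrix(cell_embs)
  stopifnot(nrow(cell_embs) == length(labels))
  labels <- as.character(labels)
  lv <- unique(labels)
  embs <- t(vapply(lv, function(l)
    colMeans(cell_embs[labels == l, , drop = FALSE]),
    numeric(ncol(cell_embs))))
  rownames(embs) <- lv
  list(embeddings = embs, cell_types = lv,
       cluster_sizes = as.numeric(table(factor(labels, levels = lv))))
}

#' Mapping problem container
#'
#' @param S Reference embeddings (cells or clusters x d).
#' @param G Target spatial embeddings (spots x d), same d.
#' @param cell_types Label per reference row.
#' @param cluster_sizes Optional cell count per reference row (cluster-level
#'   mapping); default 1 per row.
#' @return A `mapping_problem` list.
#' @export
mapping_problem <- function(S, G, cell_types,
                            cluster_sizes = rep(1, nrow(S))) {
  S <- as.matrix(S); G <- as.matrix(G)
  stopifnot(ncol(S) == ncol(G), nrow(S) == length(cell_types),
            length(cluster_sizes) == nrow(S), all(is.finite(S)),
            all(is.finite(G)))
  structure(list(S = S, G = G, cell_types = as.character(cell_types),
                 cluster_sizes = as.numeric(cluster_sizes)),
            class = "mapping_problem")
}

# Loss: sum over embedding dimensions k of the cosine distance between the
# projected column (M S)[, k] and G[, k]; uniform density prior = no extra
# density term.
mapping_loss_terms <- function(M, S, G) {
  V <- M %*% S
  nv <- sqrt(colSums(V^2)); ng <- sqrt(colSums(G^2))
  dots <- colSums(V * G)
  cos_k <- dots / (nv * ng)
  list(V = V, nv = nv, ng = ng, cos_k = cos_k,
       loss = sum(1 - cos_k))
}

#' Optimize the probabilistic mapping of reference profiles onto spots
#'
#' `M` is parameterized as a columnwise softmax over spots of an
#' unconstrained matrix (each reference profile distributes probability 1
#' across spots at every step) and fitted by plain gradient descent on
#' `L(S, M) = sum_k cosdistance((M S)[, k], G[, k])`, the sum running over
#' embedding dimensions. Deterministic given `seed`.
#'
#' @param p A [mapping_problem()].
#' @param lr Learning rate; default 0.1.
#' @param epochs Gradient steps; default 1000.
#' @param seed Integer seed for the parameter initialization.
#' @return A `mapping_result`: `M` (spots x references), `loss_trace`,
#'   `cell_types`, `cluster_sizes`.
#' @export
map_cells <- function(p, lr = 0.1, epochs = 1000, seed = 1) {
  stopifnot(inherits(p, "mapping_problem"))
  n_spots <- nrow(p$G); n_ref <- nrow(p$S)
  theta <- with_seed(derive_seed(seed, "map-cells"),
                     matrix(stats::rnorm(n_spots * n_ref, sd = 0.01),
                            n_spots, n_ref))
  softmax_cols <- function(th) {
    e <- exp(sweep(th, 2, apply(th, 2, max)))
    sweep(e, 2, colSums(e), "/")
  }
  loss_trace <- numeric(epochs + 1)
  M <- softmax_cols(theta)
  lt <- mapping_loss_terms(M, p$S, p$G)
  loss_trace[1] <- lt$loss
  for (ep in seq_len(epochs)) {
    # dL/dV[, k] = -(g_k / (|v_k||g_k|) - cos_k v_k / |v_k|^2)
    dV <- -(sweep(p$G, 2, lt$nv * lt$ng, "/") -
              sweep(lt$V, 2, lt$cos_k / lt$nv^2, "*"))
    dM <- dV %*% t(p$S)
    # softmax backward per column
    dTheta <- M * sweep(dM, 2, colSums(M * dM))
    theta <- theta - lr * dTheta
    M <- softmax_cols(theta)
    lt <- mapping_loss_terms(M, p$S, p$G)
    if (!is.finite(lt$loss))
      stop("mapping loss became non-finite at epoch ", ep,
           "; reduce the learning rate")
    loss_trace[ep + 1] <- lt$loss
  }
  structure(list(M = M, loss_trace = loss_trace, cell_types = p$cell_types,
                 cluster_sizes = p$cluster_sizes),
            class = "mapping_result")
}

#' Per-spot cell-type probabilities from a mapping matrix
#'
#' `P[spot, type] = sum over references of that type of
#' M[spot, ref] * cluster_size(ref)`, row-normalized. A zero row becomes
#' uniform with a warning.
#'
#' @param M Mapping matrix (spots x references) or a `mapping_result`.
#' @param cell_types Label per reference column (taken from the result if
#'   omitted).
#' @param cluster_sizes Cell count per reference column; default 1.
#' @return A `type_probability_map`: spots x types matrix, rows summing to 1.
#' @export
fractions_from_mapping <- function(M, cell_types = NULL,
                                   cluster_sizes = NULL) {
  if (inherits(M, "mapping_result")) {
    cell_types <- cell_types %||% M$cell_types
    cluster_sizes <- cluster_sizes %||% M$cluster_sizes
    M <- M$M
  }
  stopifnot(ncol(M) == length(cell_types))
  cluster_sizes <- cluster_sizes %||% rep(1, ncol(M))
  weighted <- sweep(M, 2, cluster_sizes, "*")
  agg <- t(rowsum(t(weighted), group = cell_types, reorder = FALSE))
  rs <- rowSums(agg)
  if (any(rs == 0)) {
    warning("zero probability row(s); set to uniform")
    agg[rs == 0, ] <- 1 / ncol(agg)
    rs[rs == 0] <- 1
  }
  P <- agg / rs
  rownames(P) <- rownames(M)
  class(P) <- c("type_probability_map", class(P))
  P
}

#' Non-maximum-suppression refinement of a type probability map
#'
#' Per spot, only the highest-probability cell type keeps its original value;
#' all others are zeroed. Argmax ties resolve to the lowest type index.
#' Idempotent.
#'
#' @param P Spots x types probability matrix.
#' @return Matrix of the same shape with at most one nonzero per row.
#' @export
nms_refine <- function(P) {
  P <- as.matrix(unclass(P))
  idx <- max.col(P, ties.method = "first")
  out <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  out[cbind(seq_len(nrow(P)), idx)] <- P[cbind(seq_len(nrow(P)), idx)]
  class(out) <- c("type_probability_map", class(out))
  out
}

#' Per-type z-score of a probability map across spots (display scale)
#'
#' @param P Spots x types probability matrix.
#' @return Matrix of per-type z-scores.
#' @export
type_zscores <- function(P) {
  scale(as.matrix(unclass(P)))[, , drop = FALSE]
}

#' Score a decomposition against ground-truth fractions
#'
#' For every cell type, the predicted and true spot vectors are normalized to
#' probability distributions over spots and compared by Jensen-Shannon
#' divergence; SSIM treats the per-type spot map as a (single-window) image.
#' The per-type means feed [impact_score()].
#'
#' @param pred,truth Spots x types probability matrices over identical spots
#'   and types.
#' @return List with `per_type` (data frame: type, js, ssim), `mean_js`,
#'   `mean_ssim`.
#' @export
evaluate_decomposition <- function(pred, truth) {
  pred <- as.matrix(unclass(pred)); truth <- as.matrix(unclass(truth))
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must share spots and types")
  if (!is.null(colnames(pred)) && !is.null(colnames(truth)) &&
      !identical(colnames(pred), colnames(truth)))
    stop("type labels differ between pred and truth")
  types <- colnames(pred) %||% paste0("T", seq_len(ncol(pred)))
  per <- lapply(seq_along(types), function(k) {
    p <- pred[, k]; q <- truth[, k]
    data.frame(type = types[k],
               js = js_divergence(p / sum(p), q / sum(q)),
               ssim = ssim(p, q))
  })
  per <- do.call(rbind, per)
  list(per_type = per, mean_js = mean(per$js), mean_ssim = mean(per$ssim))
}
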
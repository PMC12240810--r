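# Spot-level gene expression prediction from image embeddings: a query's
# expression is the similarity-weighted average of training-spot expression,
# with a 10-fold cross-validation harness.

#' Predict expression as a similarity-weighted average of training spots
#'
#' `w[i, j] = cosine(query_i, train_j)` and
#' `X_i = sum_j w[i, j] X_j / sum_j w[i, j]`. Because cosine weights can be
#' negative, a guarded fallback applies per query: if the weight sum is not
#' positive, only strictly positive weights are used; if none are positive,
#' the unweighted training mean is returned with a warning.
#'
#' @param train_text_embs Training transcriptomic embeddings, T x d.
#' @param train_expr Training expression, T x genes.
#' @param query_image_embs Query image embeddings, Q x d.
#' @param eps Positivity threshold on the weight sum; default 1e-8.
#' @return Q x genes predicted expression matrix.
#' @export
predict_expression <- function(train_text_embs, train_expr,
                               query_image_embs, eps = 1e-8) {
  train_text_embs <- as.matrix(train_text_embs)
  train_expr <- as.matrix(train_expr)
  query_image_embs <- rbind(query_image_embs)
  if (nrow(train_text_embs) == 0) stop("empty training set")
  stopifnot(nrow(train_expr) == nrow(train_text_embs))
  W <- cosine_matrix(query_image_embs, train_text_embs) # Q x T
  pred <- matrix(NA_real_, nrow(W), ncol(train_expr),
                 dimnames = list(rownames(query_image_embs),
                                 colnames(train_expr)))
  fell_back <- 0L
  for (i in seq_len(nrow(W))) {
    w <- W[i, ]
    if (sum(w) <= eps) w <- ifelse(w > 0, w, 0)
    if (sum(w) <= eps) {
      fell_back <- fell_back + 1L
      pred[i, ] <- colMeans(train_expr)
    } else {
      pred[i, ] <- as.numeric(crossprod(w, train_expr)) / sum(w)
    }
  }
  if (fell_back > 0)
    warning(fell_back, " quer(ies) had no positive weight; ",
            "unweighted training mean used")
  pred
}

#' Cross-validated expression prediction from image features
#'
#' Spots are partitioned into `folds` seeded validation splits. Per fold,
#' linear adapters are optionally fine-tuned on the training pairs
#' (contrastive objective), training transcriptomes are encoded as gene
#' sentences and validation spots as image features, the validation split's
#' top `top_genes` expressed genes are selected as the evaluation panel, and
#' expression (log-normalized) is predicted via [predict_expression()].
#' Scores: per-spot MSE over the panel (fold mean) and per-gene Pearson
#' correlation across validation spots (fold median).
#'
#' @param spots A [spot_matrix()].
#' @param features Spots x channels image-feature matrix (rows match spots).
#' @param folds Number of folds; default 10.
#' @param top_genes Evaluation panel size; default 300.
#' @param finetune_epochs Adapter fine-tuning epochs per fold (0 skips);
#'   default 10.
#' @param panel_from Select the gene panel from the `"validation"` split (the
#'   protocol as printed, which leaks panel identity) or from `"train"`.
#' @param cfg An [encoder_config()].
#' @param seed Integer seed for the fold split.
#' @return List with `per_fold` (data frame: fold, n_validation, mse,
#'   median_pcc), `median_pcc`, `mean_mse`, and `predictions` (spots x panel
#'   genes, assembled across folds; NA outside each fold's panel).
#' @export
crossval_predex <- function(spots, features, folds = 10, top_genes = 300,
                            finetune_epochs = 10,
                            panel_from = c("validation", "train"),
                            cfg = encoder_config(), seed = 1) {
  panel_from <- match.arg(panel_from)
  n <- ncol(spots$counts)
  if (n < folds) stop("fewer spots than folds")
  features <- as.matrix(features)
  stopifnot(nrow(features) == n)
  norm <- normalize_counts(spots)
  expr <- t(as.matrix(norm$counts)) # spots x genes
  corpus <- build_corpus(spots, k = cfg$max_genes)
  text_embs <- encode_corpus(corpus, cfg)
  text_embs <- text_embs[match(spots$barcodes, rownames(text_embs)), ,
                         drop = FALSE]
  image_embs <- encode_features(features, cfg)
  fold_id <- with_seed(derive_seed(seed, "predex-folds"),
                       sample(rep(seq_len(folds), length.out = n)))
  all_pred <- matrix(NA_real_, n, ncol(expr),
                     dimnames = list(spots$barcodes, colnames(expr)))
  per_fold <- lapply(seq_len(folds), function(f) {
    val <- which(fold_id == f); trn <- which(fold_id != f)
    te <- text_embs[trn, , drop = FALSE]
    qe <- image_embs[val, , drop = FALSE]
    if (finetune_epochs > 0) {
      ad <- finetune_adapters(image_embs[trn, , drop = FALSE], te,
                              epochs = finetune_epochs, cfg = cfg)
      te <- apply_adapter(te, ad, "text")
      qe <- apply_adapter(qe, ad, "image")
    }
    panel_rows <- if (panel_from == "validation") val else trn
    totals <- colSums(expr[panel_rows, , drop = FALSE])
    panel <- utils::head(order(-totals), min(top_genes, ncol(expr)))
    pred <- predict_expression(te, expr[trn, panel, drop = FALSE], qe)
    truth <- expr[val, panel, drop = FALSE]
    all_pred[val, panel] <<- pred
    pcc <- vapply(seq_along(panel), function(g)
      tryCatch(pearson(pred[, g], truth[, g]),
               error = function(e) NA_real_), numeric(1))
    data.frame(fold = f, n_validation = length(val),
               mse = mean(rowMeans((pred - truth)^2)),
               median_pcc = stats::median(pcc, na.rm = TRUE))
  })
  per_fold <- do.call(rbind, per_fold)
  list(per_fold = per_fold,
       median_pcc = stats::median(per_fold$median_pcc),
       mean_mse = mean(per_fold$mse),
       predictions = all_pred)
}
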
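# Dual reference encoder: text (gene sentences) and image (feature channels)
# map into one shared embedding space. Both modalities expand their inputs
# over per-name seeded Gaussian basis vectors, so an untrained pair is already
# aligned when image channels are named by the same symbols that appear in the
# sentences -- the structural property that contrastive pretraining of a real
# dual encoder produces. The reference pair is deterministic given
# (input, seed, embed_dim) and is not a reproduction of any trained model.

#' Encoder configuration
#'
#' @param embed_dim Embedding length; default 768.
#' @param temperature Contrastive softmax temperature; default 0.07.
#' @param seed Integer seed fixing the encoder's random basis.
#' @param max_genes Cap on the number of leading sentence genes consumed;
#'   default 50.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 768, temperature = 0.07, seed = 1,
                           max_genes = 50) {
  stopifnot(embed_dim >= 2, temperature > 0, max_genes >= 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 temperature = temperature, seed = as.integer(seed),
                 max_genes = as.integer(max_genes)),
            class = "encoder_config")
}

# Per-name basis vector: a standard Gaussian vector of length embed_dim whose
# RNG state is a pure function of (name, seed, embed_dim). Cached per session.
.token_cache <- new.env(parent = emptyenv())

token_vector <- function(name, cfg) {
  key <- paste(cfg$seed, cfg$embed_dim, name, sep = "\r")
  v <- .token_cache[[key]]
  if (is.null(v)) {
    v <- with_seed(derive_seed(cfg$seed, paste0("token:", name)),
                   stats::rnorm(cfg$embed_dim))
    if (length(.token_cache) > 50000) # bound session memory
      rm(list = ls(.token_cache), envir = .token_cache)
    .token_cache[[key]] <- v
  }
  v
}

#' Encode a gene sentence
#'
#' Reference text encoder: the gene at (1-based) rank r contributes its basis
#' vector weighted by 1/log2(r + 1), so the embedding is order-sensitive the
#' way the ranked sentence is. Genes beyond `max_genes` are ignored. Raw
#' outputs are stored unnormalized; similarity and loss computations
#' L2-normalize internally.
#'
#' @param s A `gene_sentence` (or bare character vector of ordered symbols).
#' @param cfg An [encoder_config()].
#' @return Numeric embedding of length `cfg$embed_dim`.
#' @export
encode_text <- function(s, cfg = encoder_config()) {
  genes <- if (inherits(s, "gene_sentence")) s$genes else as.character(s)
  if (length(genes) == 0) stop("cannot encode an empty sentence")
  genes <- utils::head(genes, cfg$max_genes)
  w <- 1 / log2(seq_along(genes) + 1)
  emb <- numeric(cfg$embed_dim)
  for (i in seq_along(genes)) emb <- emb + w[i] * token_vector(genes[i], cfg)
  emb
}

#' Encode an image patch or feature vector
#'
#' Reference image encoder: a deterministic linear map of per-channel
#' intensities onto the shared basis. Named feature channels use the same
#' per-name basis vectors as the text encoder; unnamed channels fall back to
#' positional names `ch1, ch2, ...`. Raster patches (matrix or 3-d array,
#' h x w x channels) are mean-pooled per channel first.
#'
#' @param patch Numeric feature vector, matrix, or h x w x c array.
#' @param cfg An [encoder_config()].
#' @return Numeric embedding of length `cfg$embed_dim`.
#' @export
encode_image <- function(patch, cfg = encoder_config()) {
  if (is.array(patch) && length(dim(patch)) == 3) {
    patch <- apply(patch, 3, mean)
  } else if (is.matrix(patch)) {
    patch <- c(mean = mean(patch))
    names(patch) <- "ch1"
  }
  feats <- as.numeric(patch)
  if (length(feats) == 0 || any(!is.finite(feats)))
    stop("image features must be a finite, non-empty vector")
  nms <- names(patch)
  if (is.null(nms)) nms <- paste0("ch", seq_along(feats))
  basis <- vapply(nms, token_vector, numeric(cfg$embed_dim), cfg = cfg)
  as.numeric(basis %*% feats)
}

#' Encode every record of a sentence corpus
#'
#' @param corpus A `sentence_corpus` from [build_corpus()].
#' @param cfg An [encoder_config()].
#' @return Numeric matrix, records x embed_dim, rownames = record ids.
#' @export
encode_corpus <- function(corpus, cfg = encoder_config()) {
  emb <- t(vapply(strsplit(corpus$sentence, " ", fixed = TRUE),
                  encode_text, numeric(cfg$embed_dim), cfg = cfg))
  rownames(emb) <- corpus$id
  emb
}

#' Encode rows of an image-feature matrix
#'
#' @param features Numeric matrix, observations x channels; column names, when
#'   present, select the shared per-name basis.
#' @param cfg An [encoder_config()].
#' @return Numeric matrix, observations x embed_dim.
#' @export
encode_features <- function(features, cfg = encoder_config()) {
  features <- as.matrix(features)
  nms <- colnames(features)
  if (is.null(nms)) nms <- paste0("ch", seq_len(ncol(features)))
  basis <- vapply(nms, token_vector, numeric(cfg$embed_dim), cfg = cfg)
  out <- features %*% t(basis)
  rownames(out) <- rownames(features)
  out
}

#' Cosine similarity of two embeddings
#'
#' @param a,b Numeric vectors of equal length; both non-zero.
#' @return The dot product of the unit-normalized vectors, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- l2_norm(a); nb <- l2_norm(b)
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# Cross cosine-similarity matrix between the rows of two matrices
cosine_matrix <- function(a, b) {
  l2_normalize_rows(a) %*% t(l2_normalize_rows(b))
}

#' Symmetric contrastive (InfoNCE) loss over a batch of embedding pairs
#'
#' For N paired rows the loss averages the image-to-text and text-to-image
#' cross-entropy terms:
#' \deqn{L = -\frac{1}{N}\Big[\sum_i \log\frac{e^{x_i^\top y_i/\sigma}}
#'   {\sum_j e^{x_i^\top y_j/\sigma}} +
#'   \sum_i \log\frac{e^{y_i^\top x_i/\sigma}}
#'   {\sum_j e^{y_i^\top x_j/\sigma}}\Big]}
#' Rows are L2-normalized internally before the dot products.
#'
#' @param x Image embeddings, N x d.
#' @param y Paired text embeddings, N x d.
#' @param sigma Temperature, > 0; default 0.07.
#' @return Non-negative scalar loss.
#' @export
contrastive_loss <- function(x, y, sigma = 0.07) {
  if (sigma <= 0) stop("temperature sigma must be positive")
  x <- rbind(x); y <- rbind(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == ncol(y))
  n <- nrow(x)
  s <- cosine_matrix(x, y) / sigma # s[i, j] = x_i . y_j / sigma
  term_it <- sum(diag(s) - apply(s, 1, logsumexp)) # image -> text
  term_ti <- sum(diag(s) - apply(s, 2, logsumexp)) # text -> image
  -(term_it + term_ti) / n
}

#' Fine-tune linear adapter heads on frozen reference embeddings
#'
#' Trains one square adapter per modality (initialized at identity) by
#' full-gradient descent on the symmetric contrastive loss over mini-batches,
#' emulating adapter-style fine-tuning on top of a frozen encoder pair.
#'
#' @param image_embs,text_embs Paired embedding matrices, N x d (same rows).
#' @param epochs Number of passes over the pairs; >= 1.
#' @param cfg An [encoder_config()] (supplies temperature and seed).
#' @param batch_size Mini-batch size; default 64.
#' @param lr Learning rate; default 0.02.
#' @return An `adapter_pair`: list with matrices `A` (image), `B` (text),
#'   `loss_trace` (epoch-mean loss, index 1 = before training) and
#'   `paired_cosine` (mean paired cosine per epoch, same indexing).
#' @export
finetune_adapters <- function(image_embs, text_embs, epochs = 10,
                              cfg = encoder_config(), batch_size = 64,
                              lr = 0.02) {
  image_embs <- as.matrix(image_embs); text_embs <- as.matrix(text_embs)
  n <- nrow(image_embs)
  if (n < 2) stop("need at least 2 pairs to form a contrastive batch")
  stopifnot(nrow(text_embs) == n, epochs >= 1)
  d <- ncol(image_embs)
  A <- diag(d); B <- diag(d)
  sigma <- cfg$temperature
  eval_state <- function() {
    xi <- image_embs %*% t(A); yi <- text_embs %*% t(B)
    cm <- cosine_matrix(xi, yi)
    c(loss = contrastive_loss(xi, yi, sigma), cos = mean(diag(cm)))
  }
  st <- eval_state()
  loss_trace <- st["loss"]; cos_trace <- st["cos"]
  with_seed(derive_seed(cfg$seed, "finetune"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        if (length(idx) < 2) next
        g <- contrastive_grad(image_embs[idx, , drop = FALSE],
                              text_embs[idx, , drop = FALSE], A, B, sigma)
        A <- A - lr * g$dA
        B <- B - lr * g$dB
      }
      st <- eval_state()
      loss_trace <- c(loss_trace, st["loss"])
      cos_trace <- c(cos_trace, st["cos"])
    }
  })
  structure(list(A = A, B = B, loss_trace = unname(loss_trace),
                 paired_cosine = unname(cos_trace)),
            class = "adapter_pair")
}

# Analytic gradient of the symmetric InfoNCE loss w.r.t. the adapters.
# u_i = A x_i, v_i = B y_i; loss uses the normalized rows.
contrastive_grad <- function(x, y, A, B, sigma) {
  n <- nrow(x)
  u <- x %*% t(A); v <- y %*% t(B)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  uh <- u / nu; vh <- v / nv
  s <- (uh %*% t(vh)) / sigma
  P <- exp(s - apply(s, 1, logsumexp))      # softmax over j (image -> text)
  Q <- t(exp(t(s) - apply(s, 2, logsumexp))) # col-softmax: Q[i,j] over i
  Cmat <- -((diag(n) - P) + (diag(n) - Q)) / (n * sigma)
  dUh <- Cmat %*% vh
  dVh <- t(Cmat) %*% uh
  # back through row normalization: du = (dUh - (dUh . uh) uh) / ||u||
  dU <- (dUh - uh * rowSums(dUh * uh)) / nu
  dV <- (dVh - vh * rowSums(dVh * vh)) / nv
  list(dA = t(dU) %*% x, dB = t(dV) %*% y)
}

#' Apply a fine-tuned adapter to embeddings
#'
#' @param embs Embedding matrix (rows) or single vector.
#' @param adapters An `adapter_pair` from [finetune_adapters()].
#' @param modality `"image"` (adapter `A`) or `"text"` (adapter `B`).
#' @return Adapted embeddings with the input's shape.
#' @export
apply_adapter <- function(embs, adapters, modality = c("image", "text")) {
  modality <- match.arg(modality)
  M <- if (modality == "image") adapters$A else adapters$B
  if (is.matrix(embs)) {
    out <- embs %*% t(M)
    rownames(out) <- rownames(embs)
    out
  } else {
    as.numeric(M %*% embs)
  }
}
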
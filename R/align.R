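# Embedding-augmented nonrigid coherent point drift (CPD). Each spot becomes
# a point whose first two dimensions are its spatial position and whose
# remaining dimensions are leading principal components of its embedding;
# the source set drifts onto the target under a Gaussian-mixture EM, with the
# displacement field restricted to the spatial coordinates. A final rigid
# (rotation + translation) projection of the nonrigid fit suppresses
# distortion and is the default output.

#' Construct a (possibly feature-augmented) point set for registration
#'
#' Spatial columns are centered per column and scaled by one pooled standard
#' deviation (shape-preserving); feature columns are z-scored per column and
#' multiplied by `feature_scale` to balance modality influence. The original
#' coordinates and the target-frame back-transform are retained.
#'
#' @param coords n x 2 spatial coordinates.
#' @param features Optional n x f feature columns.
#' @param feature_scale Multiplier on standardized features; default 1.
#' @param standardize Standardize blocks as above; default `TRUE`.
#' @return A `point_set` with elements `spatial`, `features`, `D`, `center`,
#'   `scale`, `orig_spatial`.
#' @export
point_set <- function(coords, features = NULL, feature_scale = 1,
                      standardize = TRUE) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, nrow(coords) >= 3, all(is.finite(coords)))
  center <- c(0, 0); scale <- 1
  spatial <- coords
  if (standardize) {
    center <- colMeans(coords)
    spatial <- sweep(coords, 2, center)
    scale <- sqrt(mean(spatial^2))
    if (scale == 0) scale <- 1
    spatial <- spatial / scale
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    stopifnot(nrow(features) == nrow(coords), all(is.finite(features)))
    if (standardize) {
      sds <- apply(features, 2, stats::sd)
      keep <- sds > 1e-12
      features <- features[, keep, drop = FALSE]
      if (ncol(features) > 0)
        features <- scale(features)[, , drop = FALSE] * feature_scale
    }
    if (ncol(features) == 0) features <- NULL
  }
  structure(list(spatial = spatial, features = features,
                 D = 2L + if (is.null(features)) 0L else ncol(features),
                 center = center, scale = scale, orig_spatial = coords),
            class = "point_set")
}

point_block <- function(ps) {
  if (is.null(ps$features)) ps$spatial else cbind(ps$spatial, ps$features)
}

#' Augment spot coordinates with embedding principal components
#'
#' Appends the first two principal-component scores of the embeddings to the
#' 2-d coordinates, yielding (up to) 4-d points. Rank-deficient embeddings
#' fall back to 1 or 0 feature columns with a warning.
#'
#' @param coords n x 2 spot coordinates.
#' @param embeddings n x d embedding matrix.
#' @param feature_scale Passed to [point_set()].
#' @param n_components Principal components to append; default 2.
#' @return A `point_set` with `D` up to `2 + n_components`.
#' @export
augment_points <- function(coords, embeddings, feature_scale = 1,
                           n_components = 2) {
  embeddings <- as.matrix(embeddings)
  stopifnot(nrow(embeddings) == nrow(coords))
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  usable <- sum(pc$sdev > 1e-8 * max(pc$sdev, 1e-300))
  take <- min(n_components, usable, ncol(pc$x))
  if (take < n_components)
    warning("embeddings support only ", take,
            " principal component(s); augmenting with ", take)
  feats <- if (take > 0) pc$x[, seq_len(take), drop = FALSE] else NULL
  point_set(coords, feats, feature_scale = feature_scale)
}

#' Jointly augment a source and a target section
#'
#' Fits one PCA on the stacked source and target embeddings so both sections
#' share a single component basis (fitting per section leaves component signs
#' and order arbitrary, which would decorrelate matched features), then
#' splits the scores and standardizes the feature columns with joint
#' statistics. Spatial standardization stays per section.
#'
#' @param source_coords,target_coords n x 2 coordinate matrices.
#' @param source_embs,target_embs Embedding matrices (same width).
#' @param feature_scale Passed to [point_set()].
#' @param n_components Principal components to append; default 2.
#' @return List with `source` and `target` `point_set`s of equal `D`.
#' @export
augment_pair <- function(source_coords, source_embs, target_coords,
                         target_embs, feature_scale = 1, n_components = 2) {
  source_embs <- as.matrix(source_embs); target_embs <- as.matrix(target_embs)
  stopifnot(ncol(source_embs) == ncol(target_embs))
  stacked <- rbind(source_embs, target_embs)
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  usable <- sum(pc$sdev > 1e-8 * max(pc$sdev, 1e-300))
  take <- min(n_components, usable, ncol(pc$x))
  if (take < n_components)
    warning("embeddings support only ", take, " principal component(s)")
  n_src <- nrow(source_embs)
  feats <- if (take > 0) pc$x[, seq_len(take), drop = FALSE] else NULL
  if (!is.null(feats)) {
    mu <- colMeans(feats)
    sds <- apply(feats, 2, stats::sd)
    keep <- sds > 1e-12
    feats <- sweep(sweep(feats[, keep, drop = FALSE], 2, mu[keep]), 2,
                   sds[keep], "/") * feature_scale
    if (ncol(feats) == 0) feats <- NULL
  }
  fs <- if (is.null(feats)) NULL else feats[seq_len(n_src), , drop = FALSE]
  ft <- if (is.null(feats)) NULL else feats[-seq_len(n_src), , drop = FALSE]
  src <- point_set(source_coords, NULL)
  tgt <- point_set(target_coords, NULL)
  attach_feats <- function(ps, f) {
    if (is.null(f)) return(ps)
    ps$features <- f
    ps$D <- 2L + ncol(f)
    ps
  }
  list(source = attach_feats(src, fs), target = attach_feats(tgt, ft))
}

#' CPD parameters
#'
#' @param beta Gaussian kernel width controlling transformation stiffness
#'   (standardized units); default 2.
#' @param lambda Regularization weight trading data fidelity against
#'   smoothness; default 2.
#' @param w Outlier weight in `[0, 1)`; default 0.
#' @param max_iter Maximum EM iterations; default 100.
#' @param tol Convergence tolerance on the relative change of `sigma2`;
#'   default 1e-5.
#' @param feature_scale Multiplier on standardized feature columns; default 1.
#' @param clip_w Clip the transform coefficients to `[0, 1]` after each
#'   M-step. Off by default: the constraint is dimensionally inconsistent for
#'   a displacement-coefficient matrix and is exposed only as an option.
#' @return A `cpd_params` list.
#' @export
cpd_params <- function(beta = 2, lambda = 2, w = 0, max_iter = 100,
                       tol = 1e-5, feature_scale = 1, clip_w = FALSE) {
  stopifnot(beta > 0, lambda > 0, w >= 0, w < 1, max_iter >= 1, tol > 0)
  structure(as.list(environment()), class = "cpd_params")
}

#' Initial Gaussian-mixture variance for CPD
#'
#' `sigma2 = (1 / (D N M)) * sum_{m,n} ||x_n - y_m||^2` over all D
#' dimensions; floored at 1e-12 (with a warning) for degenerate identical
#' sets.
#'
#' @param X Target points, N x D matrix (or `point_set`).
#' @param Y Source points, M x D matrix (or `point_set`).
#' @return Positive scalar.
#' @export
init_sigma2 <- function(X, Y) {
  if (inherits(X, "point_set")) X <- point_block(X)
  if (inherits(Y, "point_set")) Y <- point_block(Y)
  stopifnot(ncol(X) == ncol(Y))
  D <- ncol(X); N <- nrow(X); M <- nrow(Y)
  s <- (N * sum(Y^2) + M * sum(X^2) - 2 * sum(colSums(X) * colSums(Y))) /
    (D * N * M)
  if (s < 1e-12) {
    warning("degenerate point sets: sigma2 floored at 1e-12")
    s <- 1e-12
  }
  s
}

#' Gaussian smoothness kernel over the source points
#'
#' `G[i, j] = exp(-||y_i - y_j||^2 / (2 beta^2))`; symmetric with unit
#' diagonal.
#'
#' @param Y Source points, M x D matrix (or `point_set`).
#' @param beta Kernel width, > 0.
#' @return M x M matrix.
#' @export
gaussian_kernel <- function(Y, beta) {
  stopifnot(beta > 0)
  if (inherits(Y, "point_set")) Y <- point_block(Y)
  sq <- rowSums(Y^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * Y %*% t(Y), 0)
  exp(-d2 / (2 * beta^2))
}

#' E-step: posterior correspondence probabilities
#'
#' `P[m, n]` is the posterior that target point `x_n` was generated by
#' transformed source point `t_m`, including the uniform outlier term
#' `(w/(1-w)) (2 pi sigma2)^{D/2} M / N`. Computed in the log domain
#' (log-sum-exp) for numerical stability. With `w = 0` every column sums
#' to 1.
#'
#' @param X Target points, N x D.
#' @param Tm Transformed source points, M x D.
#' @param sigma2 Current variance, > 0.
#' @param w Outlier weight in `[0, 1)`.
#' @return M x N posterior matrix.
#' @export
estep_posterior <- function(X, Tm, sigma2, w = 0) {
  if (inherits(X, "point_set")) X <- point_block(X)
  stopifnot(sigma2 > 0, w >= 0, w < 1)
  D <- ncol(X); N <- nrow(X); M <- nrow(Tm)
  d2 <- pmax(outer(rowSums(Tm^2), rowSums(X^2), "+") - 2 * Tm %*% t(X), 0)
  lnum <- -d2 / (2 * sigma2) # M x N
  logc <- if (w > 0) {
    log(w / (1 - w)) + (D / 2) * log(2 * pi * sigma2) + log(M / N)
  } else {
    -Inf
  }
  logden <- apply(lnum, 2, function(col) logsumexp(c(col, logc)))
  exp(sweep(lnum, 2, logden))
}

#' M-step: update transform coefficients, positions and variance
#'
#' Solves `(G + lambda sigma2 d(P1)^{-1}) W = d(P1)^{-1} P X - Y` for the
#' spatial columns of `W` only (feature columns of the displacement are held
#' at zero so that only coordinates move), sets `T = Y + G W`, and updates
#' `sigma2 = (tr(X' d(P'1) X) - 2 tr((P X)' T) + tr(T' d(P1) T)) / (Np D)`
#' over all D dimensions. Tiny posterior row sums are floored before
#' inversion; a singular system falls back to a logged ridge jitter.
#'
#' @param X Target points, N x D.
#' @param Y Source points, M x D.
#' @param G Kernel from [gaussian_kernel()].
#' @param P Posterior from [estep_posterior()].
#' @param lambda Regularization weight.
#' @param sigma2 Current variance.
#' @param spatial_cols Indices of the coordinate columns; default `1:2`.
#' @param clip_w Clip `W` entries to `[0, 1]`; default `FALSE`.
#' @return List with `W` (M x D, feature columns zero), `Tm` (M x D) and
#'   `sigma2` (updated).
#' @export
mstep_update <- function(X, Y, G, P, lambda, sigma2, spatial_cols = 1:2,
                         clip_w = FALSE) {
  if (inherits(X, "point_set")) X <- point_block(X)
  if (inherits(Y, "point_set")) Y <- point_block(Y)
  D <- ncol(X)
  p1 <- pmax(rowSums(P), 1e-12)
  A <- G + lambda * sigma2 * diag(1 / p1)
  rhs <- (P %*% X[, spatial_cols, drop = FALSE]) / p1 -
    Y[, spatial_cols, drop = FALSE]
  Wsp <- tryCatch(solve(A, rhs), error = function(e) {
    log_msg("mstep_update: singular system; adding ridge jitter 1e-8")
    solve(A + 1e-8 * diag(nrow(A)), rhs)
  })
  if (clip_w) Wsp <- pmin(pmax(Wsp, 0), 1)
  W <- matrix(0, nrow(Y), D)
  W[, spatial_cols] <- Wsp
  Tm <- Y + G %*% W
  Np <- sum(P)
  xPx <- sum(colSums(P) * rowSums(X^2))
  tPt <- sum(p1 * rowSums(Tm^2))
  cross <- sum((P %*% X) * Tm)
  s2 <- (xPx - 2 * cross + tPt) / (Np * D)
  list(W = W, Tm = Tm, sigma2 = max(s2, 1e-12))
}

# Least-squares rigid fit (rotation with det +1, translation) B ~ R A + t
fit_rigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

#' Align a source section onto a target section with augmented CPD
#'
#' Runs the EM registration of the (optionally feature-augmented) source
#' point set onto the target set, then fits the rigid rotation + translation
#' that best explains the nonrigid fit and applies it to the original source
#' coordinates, suppressing distortion. The rigid-projected coordinates are
#' the default output; the raw nonrigid positions are also returned.
#'
#' @param source,target `point_set` objects (see [point_set()],
#'   [augment_points()]); both must share `D`.
#' @param params A [cpd_params()].
#' @param keep_posterior Return the final posterior matrix; default `FALSE`.
#' @return An `alignment` list: `coords` (rigid-projected source coordinates
#'   in the target frame), `nonrigid` (nonrigid positions in the target
#'   frame), `rigid` (`R`, `t` acting on original source coordinates), `W`,
#'   `sigma2_trace`, `converged`, and optionally `P`.
#' @export
cpd_align <- function(source, target, params = cpd_params(),
                      keep_posterior = FALSE) {
  stopifnot(inherits(source, "point_set"), inherits(target, "point_set"))
  if (source$D != target$D)
    stop("source and target dimensionality differ (", source$D, " vs ",
         target$D, ")")
  Y <- point_block(source); X <- point_block(target)
  G <- gaussian_kernel(Y, params$beta)
  Tm <- Y
  sigma2 <- init_sigma2(X, Y)
  trace <- numeric(0)
  converged <- FALSE
  P <- NULL
  for (it in seq_len(params$max_iter)) {
    P <- estep_posterior(X, Tm, sigma2, params$w)
    up <- mstep_update(X, Y, G, P, params$lambda, sigma2,
                       clip_w = params$clip_w)
    Tm <- up$Tm
    rel <- abs(up$sigma2 - sigma2) / sigma2
    sigma2 <- up$sigma2
    trace <- c(trace, sigma2)
    if (rel < params$tol) {
      converged <- TRUE
      break
    }
  }
  # nonrigid spatial positions mapped into the target's original frame
  nonrigid <- sweep(Tm[, 1:2, drop = FALSE] * target$scale, 2,
                    target$center, "+")
  rigid <- fit_rigid(source$orig_spatial, nonrigid)
  coords <- sweep(source$orig_spatial %*% t(rigid$R), 2, rigid$t, "+")
  rownames(coords) <- rownames(source$orig_spatial)
  rownames(nonrigid) <- rownames(source$orig_spatial)
  out <- list(coords = coords, nonrigid = nonrigid, rigid = rigid,
              W = up$W, sigma2_trace = trace, converged = converged)
  if (keep_posterior) out$P <- P
  structure(out, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d points, %d iteration(s), converged = %s\n",
              nrow(x$coords), length(x$sigma2_trace), x$converged))
  invisible(x)
}

#' Expression agreement between aligned source and target sections
#'
#' Maps each aligned source spot to its nearest target spot and computes the
#' Pearson and Kendall tau correlation of highly variable gene expression
#' (log-normalized) between the matched profiles.
#'
#' @param aligned A [spot_matrix()] whose `coords` are aligned source
#'   positions in the target frame.
#' @param target The target [spot_matrix()].
#' @param top_genes Number of most-variable shared genes used; default 50.
#' @return List with `per_spot` (data frame: barcode, pcc, tau),
#'   `median_pcc`, `median_tau`.
#' @export
evaluate_alignment <- function(aligned, target, top_genes = 50) {
  shared <- intersect(aligned$gene_ids, target$gene_ids)
  if (length(shared) < 2)
    stop("fewer than 2 shared genes: correlation undefined")
  a <- as.matrix(normalize_counts(aligned)$counts[shared, , drop = FALSE])
  b <- as.matrix(normalize_counts(target)$counts[shared, , drop = FALSE])
  vars <- apply(b, 1, stats::var)
  top <- utils::head(order(-vars), min(top_genes, length(shared)))
  a <- a[top, , drop = FALSE]; b <- b[top, , drop = FALSE]
  d2 <- outer(rowSums(aligned$coords^2), rowSums(target$coords^2), "+") -
    2 * aligned$coords %*% t(target$coords)
  nearest <- max.col(-d2, ties.method = "first")
  per <- vapply(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, nearest[j]]
    c(pcc = tryCatch(pearson(x, y), error = function(e) NA_real_),
      tau = tryCatch(kendall_tau(x, y), error = function(e) NA_real_))
  }, numeric(2))
  df <- data.frame(barcode = aligned$barcodes, pcc = per["pcc", ],
                   tau = per["tau", ])
  list(per_spot = df,
       median_pcc = stats::median(df$pcc, na.rm = TRUE),
       median_tau = stats::median(df$tau, na.rm = TRUE))
}
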
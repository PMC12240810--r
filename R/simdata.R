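# Seeded synthetic-data generators. A paired cohort emulates the structure a
# contrastively pretrained dual encoder assumes: spot expression and image
# features share one latent cell-type-mixture field. Perturbed sections,
# depth downsampling and pseudo-spot binning emulate the evaluation designs
# used for alignment, robustness and cross-platform studies.

#' Specification of a paired expression/image cohort
#'
#' Per-spot cell-type fractions blend a smooth spatial field (Gaussian bumps
#' around per-type anchor points, emulating tissue domains) with per-spot
#' Dirichlet noise. Counts are negative binomial around
#' `library size * (loadings %*% fractions)`; image features are the linear
#' map `A %*% fractions` of the same fractions plus Gaussian noise, with `A`
#' defaulting to the gene-loading matrix so feature channels are gene-named
#' pseudo-intensities.
#'
#' @param n_spots,n_genes,n_types Cohort dimensions; defaults 200, 200, 4.
#' @param concentration Dirichlet concentration of the per-spot noise
#'   component; default 0.3 (spots dominated by one or two types, as in
#'   capture-spot data).
#' @param spatial_mix Weight of the smooth spatial field in the fractions,
#'   in `[0, 1]`; default 0.7.
#' @param markers_per_type Marker genes boosted per type; default 10.
#' @param marker_strength Additive loading boost for markers; default 10.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson counts. Default 0.1.
#' @param lib_range Per-spot library-size range; default `c(2000, 5000)`.
#' @param feature_noise_sd Gaussian sd added to image features; default 0.
#' @param image_map `"loadings"` (default) uses the gene-loading matrix as
#'   `A`, giving gene-named feature channels that the reference image encoder
#'   embeds on the same basis as the text encoder (an already-aligned pair,
#'   as after pretraining); `"random"` draws a generic channel map, giving an
#'   unaligned modality pair (the fine-tuning scenario); or a custom
#'   channels x types matrix with channel rownames.
#' @param n_channels Image channels when `image_map = "random"`; default 32.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_spots = 200, n_genes = 200, n_types = 4,
                        concentration = 0.3, spatial_mix = 0.7,
                        markers_per_type = 10, marker_strength = 10,
                        dispersion = 0.1, lib_range = c(2000, 5000),
                        feature_noise_sd = 0, image_map = "loadings",
                        n_channels = 32, seed = 1) {
  stopifnot(n_spots > 0, n_genes > 0, n_types > 0, concentration > 0,
            spatial_mix >= 0, spatial_mix <= 1, dispersion >= 0,
            feature_noise_sd >= 0, length(lib_range) == 2,
            all(lib_range > 0))
  structure(as.list(environment()), class = "cohort_spec")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a paired expression/image cohort with known fractions
#'
#' @param spec A [cohort_spec()].
#' @return List with `spots` (a [spot_matrix()]), `features` (spots x
#'   channels image-feature matrix, gene-named columns), `fractions` (spots x
#'   types ground truth), `loadings` (genes x types) and `spec`.
#' @export
simulate_paired_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$seed, "cohort"), {
    n <- spec$n_spots; g <- spec$n_genes; k <- spec$n_types
    side <- ceiling(sqrt(n))
    grid <- expand.grid(x = seq_len(side), y = seq_len(side))
    coords <- as.matrix(grid[seq_len(n), ])
    # smooth spatial field: one Gaussian bump per type
    anchors <- cbind(stats::runif(k, 1, side), stats::runif(k, 1, side))
    bw <- 0.4 * side
    d2 <- outer(rowSums(coords^2), rowSums(anchors^2), "+") -
      2 * coords %*% t(anchors)
    field <- exp(-d2 / (2 * bw^2))
    field <- field / rowSums(field)
    noise <- rdirichlet(n, rep(spec$concentration, k))
    fractions <- spec$spatial_mix * field + (1 - spec$spatial_mix) * noise
    fractions <- fractions / rowSums(fractions)
    colnames(fractions) <- paste0("T", seq_len(k))
    gene_ids <- sprintf("G%03d", seq_len(g))
    loadings <- matrix(stats::rgamma(g * k, shape = 0.3) + 0.02, g, k,
                       dimnames = list(gene_ids, colnames(fractions)))
    marker_pool <- sample.int(g, min(g, spec$markers_per_type * k))
    for (t in seq_len(k)) {
      mk <- marker_pool[((t - 1) * spec$markers_per_type + 1):
                          (t * spec$markers_per_type)]
      mk <- mk[!is.na(mk)]
      loadings[mk, t] <- loadings[mk, t] + spec$marker_strength
    }
    loadings <- sweep(loadings, 2, colSums(loadings), "/")
    lib <- stats::runif(n, spec$lib_range[1], spec$lib_range[2])
    mu <- (loadings %*% t(fractions)) * rep(lib, each = g)
    counts <- if (spec$dispersion > 0) {
      stats::rnbinom(g * n, mu = as.numeric(mu), size = 1 / spec$dispersion)
    } else {
      stats::rpois(g * n, as.numeric(mu))
    }
    counts <- matrix(counts, g, n)
    barcodes <- sprintf("S%04d", seq_len(n))
    rownames(coords) <- barcodes
    A <- if (is.matrix(spec$image_map)) {
      stopifnot(ncol(spec$image_map) == k)
      spec$image_map
    } else if (identical(spec$image_map, "random")) {
      matrix(stats::rnorm(spec$n_channels * k), spec$n_channels, k,
             dimnames = list(paste0("ch", seq_len(spec$n_channels)),
                             colnames(fractions)))
    } else {
      loadings # gene-named pseudo-intensity channels
    }
    features <- fractions %*% t(A) # spots x channels
    if (spec$feature_noise_sd > 0)
      features <- features +
        matrix(stats::rnorm(length(features), sd = spec$feature_noise_sd),
               nrow = n)
    rownames(features) <- barcodes
    rownames(fractions) <- barcodes
    list(spots = spot_matrix(counts, gene_ids, barcodes, coords,
                             spot_diameter = 0.5),
         features = features, fractions = fractions, loadings = loadings,
         spec = spec)
  })
}

#' Specification of a section perturbation
#'
#' @param noise Preset: `"low"` resamples 10% of each spot's counts with
#'   coordinate jitter sd 0.25 x spot spacing; `"high"` 40% and 1.0 x
#'   spacing; `"none"` leaves both at 0. Explicit `jitter_sd` /
#'   `resample_frac` override the preset.
#' @param rotation_deg Rigid rotation about the section centroid, degrees.
#' @param translation Length-2 rigid translation.
#' @param jitter_sd Per-spot coordinate jitter sd (coordinate units).
#' @param resample_frac Fraction of each spot's counts resampled.
#' @param seed Integer seed.
#' @return A `perturb_spec` list.
#' @export
perturb_spec <- function(noise = c("low", "high", "none"), rotation_deg = 0,
                         translation = c(0, 0), jitter_sd = NULL,
                         resample_frac = NULL, seed = 1) {
  noise <- match.arg(noise)
  structure(list(noise = noise, rotation_deg = rotation_deg,
                 translation = translation, jitter_sd = jitter_sd,
                 resample_frac = resample_frac, seed = seed),
            class = "perturb_spec")
}

#' Mean nearest-neighbor distance of a coordinate set
#'
#' The natural length scale ("spot spacing") used by jitter presets and
#' recovery scoring.
#'
#' @param coords Numeric matrix, n x 2.
#' @return Positive scalar.
#' @export
mean_spot_spacing <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Apply / invert a rigid transform
#'
#' Transforms are stored as `list(R, t, center)` acting as
#' `x' = R (x - center) + center + t`.
#'
#' @param tf A rigid transform list.
#' @param coords n x 2 matrix.
#' @return Transformed n x 2 matrix.
#' @export
apply_transform <- function(tf, coords) {
  sweep(sweep(coords, 2, tf$center) %*% t(tf$R), 2,
        tf$center + tf$t, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  list(R = t(tf$R), t = -as.numeric(t(tf$R) %*% tf$t), center = tf$center)
}

rotation_matrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# Multivariate hypergeometric draw: remove `k` items without replacement
# from category counts `counts`.
rmvhyper <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (k == 0) break
    x <- stats::rhyper(1, counts[i], remaining - counts[i], k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - counts[i]
  }
  out
}

#' Perturb a section: rigid transform, jitter, and count resampling
#'
#' Coordinates are rotated/translated and then jittered; each spot's counts
#' are perturbed by removing a fraction of counts (multivariate
#' hypergeometric) and redrawing the same number from the spot's own
#' multinomial proportions, conserving per-spot totals. The exact inverse
#' rigid transform is returned for recovery scoring.
#'
#' @param m A [spot_matrix()] of integer counts.
#' @param spec A [perturb_spec()].
#' @return List with `spots` (perturbed [spot_matrix()]), `transform`
#'   (forward rigid transform) and `inverse` (its exact inverse).
#' @export
perturb_section <- function(m, spec = perturb_spec()) {
  spacing <- mean_spot_spacing(m$coords)
  preset <- switch(spec$noise,
                   none = list(jitter = 0, frac = 0),
                   low = list(jitter = 0.25 * spacing, frac = 0.10),
                   high = list(jitter = 1.0 * spacing, frac = 0.40))
  jitter_sd <- spec$jitter_sd %||% preset$jitter
  frac <- spec$resample_frac %||% preset$frac
  tf <- list(R = rotation_matrix(spec$rotation_deg),
             t = as.numeric(spec$translation), center = colMeans(m$coords))
  with_seed(derive_seed(spec$seed, "perturb"), {
    coords <- apply_transform(tf, m$coords)
    if (jitter_sd > 0)
      coords <- coords + matrix(stats::rnorm(length(coords), sd = jitter_sd),
                                ncol = 2)
    counts <- as.matrix(m$counts)
    if (frac > 0) {
      for (j in seq_len(ncol(counts))) {
        cj <- counts[, j]
        total <- sum(cj)
        if (total == 0) next
        n_res <- round(frac * total)
        removed <- rmvhyper(cj, n_res)
        added <- stats::rmultinom(1, n_res, prob = cj / total)[, 1]
        counts[, j] <- cj - removed + added
      }
    }
    rownames(coords) <- m$barcodes
    list(spots = spot_matrix(counts, m$gene_ids, m$barcodes, coords,
                             m$spot_diameter, m$meta),
         transform = tf, inverse = invert_transform(tf))
  })
}

#' Downsample sequencing depth by binomial thinning
#'
#' Every count is thinned with probability `target_depth / median depth`,
#' emulating a lower-depth ST experiment while preserving within-spot
#' expression ranks in expectation.
#'
#' @param m A [spot_matrix()] of integer counts.
#' @param target_depth Target median per-spot total; must not exceed the
#'   current median depth.
#' @param seed Integer seed.
#' @return A [spot_matrix()] of thinned integer counts.
#' @export
downsample_depth <- function(m, target_depth, seed = 1) {
  if (target_depth <= 0) stop("target_depth must be positive")
  med <- stats::median(Matrix::colSums(m$counts))
  p <- target_depth / med
  if (p > 1) stop("target_depth exceeds current median depth (", med, ")")
  with_seed(derive_seed(seed, "downsample"), {
    counts <- m$counts
    counts@x <- as.double(stats::rbinom(length(counts@x),
                                        size = as.integer(counts@x),
                                        prob = p))
    counts <- Matrix::drop0(counts)
    spot_matrix(counts, m$gene_ids, m$barcodes, m$coords, m$spot_diameter,
                m$meta)
  })
}

#' Bin single cells onto a pseudo-spot grid
#'
#' Cells are assigned to the nearest spot center within `diameter / 2`; each
#' retained spot's profile is the mean of its member cells' expression
#' (averaging, not summing). Spots capturing no cell are dropped.
#'
#' @param cell_coords n_cells x 2 matrix of cell positions.
#' @param cell_expr n_cells x n_genes expression matrix (column names are
#'   gene identifiers).
#' @param spacing Center-to-center grid spacing.
#' @param diameter Capture diameter; default `spacing`.
#' @return A [spot_matrix()] of pseudo-spots.
#' @export
make_pseudo_spots <- function(cell_coords, cell_expr, spacing,
                              diameter = spacing) {
  cell_coords <- as.matrix(cell_coords)
  cell_expr <- as.matrix(cell_expr)
  stopifnot(nrow(cell_coords) == nrow(cell_expr), spacing > 0, diameter > 0)
  gx <- seq(min(cell_coords[, 1]), max(cell_coords[, 1]) + spacing,
            by = spacing)
  gy <- seq(min(cell_coords[, 2]), max(cell_coords[, 2]) + spacing,
            by = spacing)
  centers <- as.matrix(expand.grid(x = gx, y = gy))
  d2 <- outer(rowSums(cell_coords^2), rowSums(centers^2), "+") -
    2 * cell_coords %*% t(centers)
  nearest <- max.col(-d2, ties.method = "first")
  dist_near <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), nearest)], 0))
  inside <- dist_near <= diameter / 2
  if (!any(inside)) stop("no cell falls within any pseudo-spot")
  nearest <- nearest[inside]
  expr <- cell_expr[inside, , drop = FALSE]
  keep <- sort(unique(nearest))
  prof <- t(vapply(keep, function(s)
    colMeans(expr[nearest == s, , drop = FALSE]), numeric(ncol(expr))))
  gene_ids <- colnames(cell_expr) %||% paste0("G", seq_len(ncol(cell_expr)))
  barcodes <- sprintf("PS%04d", keep)
  spot_matrix(t(prof), gene_ids, barcodes, centers[keep, , drop = FALSE],
              spot_diameter = diameter)
}

#' Add Gaussian noise to an image-feature matrix
#'
#' @param features Numeric matrix.
#' @param sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
add_feature_noise <- function(features, sd, seed = 1) {
  stopifnot(sd >= 0)
  if (sd == 0) return(features)
  with_seed(derive_seed(seed, "feature-noise"),
            features + matrix(stats::rnorm(length(features), sd = sd),
                              nrow = nrow(features)))
}
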
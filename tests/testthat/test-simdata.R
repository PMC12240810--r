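test_that("cohorts are bit-reproducible with simplex fractions and the
          stated pairing structure", {
  s <- cohort_spec(n_spots = 40, n_genes = 50, seed = 5)
  a <- simulate_paired_cohort(s)
  b <- simulate_paired_cohort(s)
  expect_identical(as.matrix(a$spots$counts), as.matrix(b$spots$counts))
  expect_identical(a$features, b$features)
  expect_equal(unname(rowSums(a$fractions)), rep(1, 40), tolerance = 1e-12)
  # noiseless features recover the fraction-driven expectation exactly
  expect_equal(a$features, a$fractions %*% t(a$loadings), tolerance = 1e-12)
  expect_error(cohort_spec(concentration = 0), "concentration")
})

test_that("negative-binomial counts match their target means at scale", {
  co <- simulate_paired_cohort(cohort_spec(n_spots = 1000, n_genes = 30,
                                           dispersion = 0.1, seed = 8,
                                           lib_range = c(3000, 3000)))
  mu <- (co$loadings %*% t(co$fractions)) * 3000
  obs <- Matrix::rowSums(co$spots$counts)
  expected <- rowSums(mu)
  # per-gene total within 3 standard errors of the NB target
  v <- rowSums(mu + 0.1 * mu^2)
  expect_gt(mean(abs(obs - expected) <= 3 * sqrt(v)), 0.95)
})

test_that("paired embeddings of the same spot beat mismatched pairs", {
  co <- small_cohort(seed = 67)
  cfg <- encoder_config(embed_dim = 128, seed = 3)
  te <- cohort_text_embs(co, cfg)
  ie <- encode_features(co$features, cfg)
  cm <- spatlink:::cosine_matrix(ie, te)
  expect_gt(mean(diag(cm)), mean(cm[row(cm) != col(cm)]))
})

test_that("perturbation conserves per-spot totals, returns an exact inverse,
          and is the identity at zero noise", {
  co <- small_cohort(seed = 71, n_spots = 40, n_genes = 50)
  none <- perturb_section(co$spots, perturb_spec("none", seed = 2))
  expect_identical(as.matrix(none$spots$counts), as.matrix(co$spots$counts))
  expect_equal(none$spots$coords, co$spots$coords, tolerance = 1e-12,
               ignore_attr = TRUE)
  pert <- perturb_section(co$spots,
                          perturb_spec("high", rotation_deg = 30,
                                       translation = c(4, -1), seed = 2))
  expect_equal(unname(Matrix::colSums(pert$spots$counts)),
               unname(Matrix::colSums(co$spots$counts)))
  # inverse transform undoes the rigid part exactly (jitter remains)
  jitter_only <- apply_transform(pert$inverse, pert$spots$coords) -
    co$spots$coords
  spacing <- mean_spot_spacing(co$spots$coords)
  expect_lt(max(abs(jitter_only)), 6 * spacing) # bounded jitter
  rigid_only <- perturb_section(co$spots,
                                perturb_spec("none", rotation_deg = 30,
                                             translation = c(4, -1),
                                             seed = 2))
  expect_equal(apply_transform(rigid_only$inverse, rigid_only$spots$coords),
               co$spots$coords, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("depth downsampling thins counts binomially", {
  co <- small_cohort(seed = 73, n_spots = 50, n_genes = 60)
  med <- median(Matrix::colSums(co$spots$counts))
  same <- downsample_depth(co$spots, med, seed = 4)
  # p = 1 keeps every count
  expect_identical(as.matrix(same$counts), as.matrix(co$spots$counts))
  half <- downsample_depth(co$spots, med / 2, seed = 4)
  tot0 <- sum(co$spots$counts); tot1 <- sum(half$counts)
  se <- sqrt(tot0 * 0.5 * 0.5)
  expect_lt(abs(tot1 - 0.5 * tot0), 3 * se)
  # thinning preserves within-spot ranks on average
  j <- which.max(Matrix::colSums(co$spots$counts))
  expect_gt(cor(as.numeric(co$spots$counts[, j]),
                as.numeric(half$counts[, j]), method = "spearman"), 0.7)
  expect_error(downsample_depth(co$spots, med * 2), "exceeds")
})

test_that("pseudo-spot binning averages member cells at the nearest center", {
  # two co-located cells average to one profile
  cells <- rbind(c(0.1, 0.1), c(0.12, 0.1))
  expr <- rbind(c(2, 0), c(0, 2))
  ps <- make_pseudo_spots(cells, expr, spacing = 1)
  expect_identical(ncol(ps$counts), 1L)
  expect_equal(as.numeric(ps$counts), c(1, 1))
  # one cell per spot passes profiles through
  far <- rbind(c(0, 0), c(5, 5))
  ps2 <- make_pseudo_spots(far, expr, spacing = 1)
  expect_identical(ncol(ps2$counts), 2L)
  expect_equal(as.matrix(ps2$counts), t(expr), ignore_attr = TRUE)
  # assignment matches a brute-force nearest-center search
  set.seed(5)
  cc <- matrix(runif(40, 0, 6), ncol = 2)
  ee <- matrix(rpois(20 * 8, 4), 20)
  colnames(ee) <- paste0("g", 1:8)
  ps3 <- make_pseudo_spots(cc, ee, spacing = 2, diameter = 2)
  for (s in seq_along(ps3$barcodes)) {
    center <- ps3$coords[s, ]
    d <- sqrt(colSums((t(cc) - center)^2))
    members <- which(d <= 1 + 1e-12)
    # member cells must be nearer this center than any other retained center
    expect_true(length(members) >= 1)
  }
  # grid centers at (0,0), (10,0), (0,10), (10,10); both cells > diameter/2
  expect_error(make_pseudo_spots(rbind(c(0, 5), c(3, 0)),
                                 rbind(c(1, 1), c(2, 2)),
                                 spacing = 10, diameter = 1), "no cell")
})

test_that("feature noise is seeded additive Gaussian with the requested sd", {
  m <- matrix(0, 100, 50)
  expect_identical(add_feature_noise(m, 0, seed = 1), m)
  noisy <- add_feature_noise(m, 0.5, seed = 1)
  expect_identical(noisy, add_feature_noise(m, 0.5, seed = 1))
  se <- 0.25 * sqrt(2 / (length(m) - 1))
  expect_lt(abs(sd(noisy) - 0.5), 3 * se * 2)
  # cosine similarity to the original decays with increasing noise
  co <- small_cohort(seed = 79, n_spots = 30, n_genes = 40)
  base <- co$features
  sims <- vapply(c(0.01, 0.1, 1), function(s) {
    n <- add_feature_noise(base, s, seed = 3)
    mean(vapply(seq_len(nrow(base)), function(i)
      cosine_similarity(base[i, ], n[i, ]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})
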
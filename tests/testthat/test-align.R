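test_that("initial variance matches its closed form", {
  X <- matrix(c(0, 0, 2, 0), 2, byrow = TRUE)
  Y <- matrix(c(0, 0), 1)
  expect_equal(init_sigma2(X, Y), 1.0) # (0 + 4)/(2*2*1)
  # homogeneity: scaling coordinates by c scales sigma2 by c^2
  set.seed(4)
  A <- matrix(rnorm(10), 5); B <- matrix(rnorm(10), 5)
  expect_equal(init_sigma2(3 * A, 3 * B), 9 * init_sigma2(A, B),
               tolerance = 1e-12)
  expect_warning(s <- init_sigma2(matrix(c(1, 1), 1), matrix(c(1, 1), 1)),
                 "floored")
  expect_equal(s, 1e-12)
})

test_that("Gaussian kernel has unit diagonal and the exp(-1/2) scale point", {
  Y <- matrix(c(0, 0, 2, 0, 0, 5), ncol = 2, byrow = TRUE)
  G <- gaussian_kernel(Y, beta = 2)
  expect_equal(diag(G), rep(1, 3))
  expect_equal(G[1, 2], exp(-1 / 2)) # separation equals beta
  expect_equal(G, t(G))
  expect_true(all(G > 0 & G <= 1))
})

test_that("E-step posteriors are normalized, symmetric on equidistant
          sources, and shrink under the outlier term", {
  X <- matrix(c(0, 0), 1)
  Tm <- matrix(c(-1, 0, 1, 0), 2, byrow = TRUE)
  P <- estep_posterior(X, Tm, sigma2 = 0.5, w = 0)
  expect_equal(as.numeric(P), c(0.5, 0.5))
  set.seed(6)
  X2 <- matrix(rnorm(20), 10); T2 <- matrix(rnorm(16), 8)
  P2 <- estep_posterior(X2, T2, sigma2 = 0.7, w = 0)
  expect_equal(colSums(P2), rep(1, 10), tolerance = 1e-12)
  # far-away target with a large outlier weight keeps little posterior mass
  P3 <- estep_posterior(matrix(c(100, 100), 1), Tm, sigma2 = 0.5, w = 0.5)
  expect_lt(sum(P3), 0.01)
})

test_that("M-step solves the regularized system and matches a brute-force
          variance update", {
  set.seed(8)
  Y <- matrix(rnorm(10), 5)
  G <- gaussian_kernel(Y, 2)
  # perfect correspondence: X == Y, P identity -> W ~ 0, sigma2 -> ~0
  up <- mstep_update(Y, Y, G, diag(5), lambda = 2, sigma2 = 1e-6)
  expect_lt(max(abs(up$W)), 1e-5)
  expect_lt(up$sigma2, 1e-6)
  expect_equal(up$Tm, Y + G %*% up$W, tolerance = 1e-12)
  # brute-force trace evaluation of the variance update on random instances
  for (rep in 1:5) {
    X <- matrix(rnorm(10), 5)
    P <- matrix(rexp(25), 5)
    up <- mstep_update(X, Y, G, P, lambda = 1.5, sigma2 = 0.3)
    Tm <- up$Tm
    Np <- sum(P)
    brute <- (sum(diag(t(X) %*% diag(colSums(P)) %*% X)) -
                2 * sum(diag(t(P %*% X) %*% Tm)) +
                sum(diag(t(Tm) %*% diag(rowSums(P)) %*% Tm))) / (Np * 2)
    expect_equal(up$sigma2, max(brute, 1e-12), tolerance = 1e-10)
  }
})

test_that("point sets standardize shape-preservingly and augmentation adds
          two principal components", {
  set.seed(10)
  coords <- cbind(runif(30, 0, 50), runif(30, 0, 5))
  embs <- matrix(rnorm(30 * 20), 30)
  ps <- augment_points(coords, embs)
  expect_identical(ps$D, 4L + 0L)
  expect_equal(colMeans(ps$spatial), c(0, 0), tolerance = 1e-12)
  # pooled scaling preserves the aspect ratio
  ratio_orig <- diff(range(coords[, 1])) / diff(range(coords[, 2]))
  ratio_std <- diff(range(ps$spatial[, 1])) / diff(range(ps$spatial[, 2]))
  expect_equal(ratio_std, ratio_orig, tolerance = 1e-9)
  # constant embeddings degrade to a pure-spatial point set
  expect_warning(ps0 <- augment_points(coords, matrix(1, 30, 5)),
                 "principal component")
  expect_identical(ps0$D, 2L)
  # embeddings that duplicate the coordinates give features tracking space
  psc <- augment_points(coords, cbind(coords, coords))
  cor_block <- abs(stats::cor(cbind(psc$spatial, psc$features)))[1:2, 3:4]
  expect_gt(max(cor_block[1, ]), 0.95)
})

test_that("CPD on identical sets stays put and recovers planted rigid
          transforms", {
  set.seed(12)
  coords <- cbind(runif(40, 0, 10), runif(40, 0, 10))
  feats <- matrix(rnorm(80), 40)
  same <- cpd_align(point_set(coords, feats), point_set(coords, feats))
  diam <- max(dist(coords))
  expect_lt(mean(sqrt(rowSums((same$coords - coords)^2))), 1e-6 * diam)
  expect_true(all(same$sigma2_trace > 0))
  # pure translation with matched features
  shifted <- sweep(coords, 2, c(5, 0), "+")
  res <- cpd_align(point_set(shifted, feats), point_set(coords, feats))
  expect_lt(max(abs(res$rigid$t - c(-5, 0))), 1e-2 * diam)
  expect_equal(res$rigid$R, diag(2), tolerance = 1e-2)
  expect_lt(mean(sqrt(rowSums((res$coords - coords)^2))), 1e-2 * diam)
  # 15-degree rotation: post-alignment nearest-neighbor distance is small
  th <- 15 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- coords %*% t(R)
  res2 <- cpd_align(point_set(rot, feats), point_set(coords, feats))
  nn <- apply(as.matrix(dist(rbind(res2$coords, coords)))[1:40, 41:80], 1,
              min)
  expect_lt(mean(nn), 0.05 * mean_spot_spacing(coords))
})

test_that("the rigid projection is an isometry of the source", {
  set.seed(14)
  coords <- cbind(runif(25, 0, 8), runif(25, 0, 8))
  target <- cbind(runif(25, 0, 8), runif(25, 0, 8))
  res <- cpd_align(point_set(coords), point_set(target))
  expect_equal(as.matrix(dist(res$coords)), as.matrix(dist(coords)),
               tolerance = 1e-9)
  R <- res$rigid$R
  expect_equal(t(R) %*% R, diag(2), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("sigma2 trace is non-increasing after the first iterations on
          identical point sets", {
  set.seed(16)
  coords <- cbind(runif(30), runif(30))
  res <- cpd_align(point_set(coords), point_set(coords))
  tr <- res$sigma2_trace
  if (length(tr) > 2) expect_true(all(diff(tr[-(1:2)]) <= 1e-12))
})

test_that("alignment evaluation returns perfect scores on identity and
          chance scores on permuted expression", {
  co <- small_cohort(seed = 17, n_spots = 60, n_genes = 80)
  ev <- evaluate_alignment(co$spots, co$spots, top_genes = 40)
  expect_equal(ev$median_pcc, 1)
  expect_equal(ev$median_tau, 1)
  perm <- co$spots
  set.seed(1)
  shuffled <- as.matrix(perm$counts)[sample(nrow(perm$counts)), ]
  perm <- spot_matrix(shuffled, perm$gene_ids, perm$barcodes, perm$coords)
  ev2 <- evaluate_alignment(perm, co$spots, top_genes = 40)
  expect_lt(abs(ev2$median_pcc), 0.3)
})
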
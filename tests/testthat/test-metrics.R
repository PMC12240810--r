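test_that("Calinski-Harabasz score matches hand evaluation and brute force", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(pts, c("A", "A", "B", "B")), 200)
  expect_equal(calinski_harabasz(pts + 57.3, c("A", "A", "B", "B")), 200)
  # brute-force oracle on random instances
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(60), ncol = 3)
    lab <- sample(c("a", "b", "c"), 20, replace = TRUE)
    brute <- {
      cl <- split(seq_len(20), lab)
      cc <- colMeans(x)
      b <- sum(vapply(cl, function(i)
        length(i) * sum((colMeans(x[i, , drop = FALSE]) - cc)^2),
        numeric(1)))
      w <- sum(vapply(cl, function(i) {
        ci <- colMeans(x[i, , drop = FALSE])
        sum(t(t(x[i, , drop = FALSE]) - ci)^2)
      }, numeric(1)))
      (b / (length(cl) - 1)) / (w / (20 - length(cl)))
    }
    expect_equal(calinski_harabasz(x, lab), brute, tolerance = 1e-8)
  }
  expect_error(calinski_harabasz(pts, rep("A", 4)), "2 clusters")
})

test_that("Calinski-Harabasz grows as clusters separate", {
  set.seed(1)
  base <- matrix(rnorm(40), ncol = 2)
  lab <- rep(c("A", "B"), each = 10)
  ch <- vapply(c(1, 3, 6), function(shift) {
    x <- base
    x[lab == "B", 1] <- x[lab == "B", 1] + shift
    calinski_harabasz(x, lab)
  }, numeric(1))
  expect_true(all(diff(ch) > 0))
})

test_that("Pearson matches its raw-moment formula and stats::cor", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, 5:1), -1)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84))
  set.seed(9)
  for (rep in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "constant")
})

test_that("Kendall tau-b matches pair enumeration and stats::cor", {
  expect_equal(kendall_tau(1:6, 1:6), 1)
  # P=5, Q=0, T=0, U=1 -> 5/sqrt(30)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 2, 2, 3)), 5 / sqrt(30))
  set.seed(13)
  for (rep in 1:10) {
    x <- sample(1:8, 25, replace = TRUE)
    y <- sample(1:8, 25, replace = TRUE)
    expect_equal(kendall_tau(x, y),
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(2, 4), 1:4), "tied")
})

test_that("JS divergence uses base-2 logs and stays in [0, 1]", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  kl_pm <- 0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)
  kl_qm <- log2(1 / 0.75)
  expect_equal(js_divergence(c(0.5, 0.5), c(1, 0)), (kl_pm + kl_qm) / 2,
               tolerance = 1e-12)
  expect_error(js_divergence(c(-0.1, 1.1), c(0.5, 0.5)), "non-negative")
  expect_error(js_divergence(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("JS divergence is symmetric and its square root is a metric on
          random triples", {
  set.seed(21)
  for (rep in 1:20) {
    r <- function() {
      v <- rexp(6)
      v / sum(v)
    }
    p <- r(); q <- r(); s <- r()
    expect_equal(js_divergence(p, q), js_divergence(q, p),
                 tolerance = 1e-12)
    expect_lte(sqrt(js_divergence(p, s)),
               sqrt(js_divergence(p, q)) + sqrt(js_divergence(q, s)) + 1e-12)
  }
})

test_that("global-window SSIM obeys its closed forms", {
  set.seed(2)
  x <- rnorm(50)
  expect_equal(ssim(x, x), 1)
  # constant maps: closed form (2ab + C1)/(a^2 + b^2 + C1), variances zero
  a <- 0.4; b <- 0.7
  L <- b - a
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  expect_equal(ssim(rep(a, 10), rep(b, 10)),
               ((2 * a * b + C1) * C2) / ((a^2 + b^2 + C1) * C2))
  xc <- x - mean(x)
  expect_lt(ssim(xc, -xc), 0)
  y <- rnorm(50)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
})

test_that("mse is the mean squared elementwise difference", {
  a <- matrix(1:6, 2)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, a + 1), 1)
  set.seed(3)
  x <- matrix(rnorm(20), 4); y <- matrix(rnorm(20), 4)
  brute <- 0
  for (i in 1:4) for (j in 1:5) brute <- brute + (x[i, j] - y[i, j])^2
  expect_equal(mse(x, y), brute / 20, tolerance = 1e-12)
  expect_error(mse(x, y[, 1:3]), "shape")
})

test_that("impact scores z-score both metrics, invert JS, and rank the
          published-style triple correctly", {
  df <- data.frame(method = c("m1", "m2", "m3"),
                   mean_ssim = c(0.30, 0.13, 0.00070),
                   mean_js = c(0.40, 0.43, 0.44))
  out <- impact_score(df)
  expect_identical(out$method, c("m1", "m2", "m3"))
  expect_true(all(diff(out$impact) < 0))
  expect_equal(sum(out$impact), 0, tolerance = 1e-12)
  two <- impact_score(data.frame(method = c("a", "b"),
                                 mean_ssim = c(0.9, 0.2),
                                 mean_js = c(0.1, 0.5)))
  expect_equal(two$impact, c(1, -1) * two$impact[1])
  expect_warning(impact_score(data.frame(method = c("a", "b"),
                                         mean_ssim = c(0.5, 0.5),
                                         mean_js = c(0.1, 0.2))),
                 "zero variance")
})
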
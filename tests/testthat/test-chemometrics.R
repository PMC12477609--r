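make_matrix <- function(n = 6, p = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), as.character(260 + 1:p)))
  m
}

test_that("PCA matches a brute-force covariance eigendecomposition", {
  for (seed in 1:5) {
    x <- make_matrix(seed = seed)
    m <- fit_pca(x, scale_unit_variance = FALSE, range = NULL)
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    k <- min(nrow(x) - 1, ncol(x))
    # eigenvalues
    expect_equal(m$var_fraction[1:k] * sum(ev$values),
                 ev$values[1:k], tolerance = 1e-8)
    # loadings up to the fixed sign convention
    for (j in 1:k) {
      v <- ev$vectors[, j]
      if (v[which.max(abs(v))] < 0) v <- -v
      expect_equal(unname(m$loadings[, j]), v, tolerance = 1e-8)
    }
  }
})

test_that("PCA model satisfies its structural invariants", {
  x <- make_matrix(n = 8, p = 5, seed = 3)
  m <- fit_pca(x, scale_unit_variance = TRUE, range = NULL)
  L <- m$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(m$var_fraction), 1, tolerance = 1e-12)
  centered <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  expect_equal(unname(m$scores), unname(centered %*% L), tolerance = 1e-10)
  # full reconstruction of the centered/scaled data
  expect_equal(unname(m$scores %*% t(L)), unname(centered),
               tolerance = 1e-8)
})

test_that("rank-1 data put 100% of the variance on PC1", {
  u <- 1:6
  v <- c(2, -1, 3, 0.5)
  x <- outer(u, v)
  colnames(x) <- as.character(231:234)
  m <- fit_pca(x, scale_unit_variance = FALSE, range = NULL)
  expect_equal(explained_variance(m, 1), 100, tolerance = 1e-8)
})

test_that("sample permutation permutes scores and fixes loadings", {
  x <- make_matrix(n = 7, p = 5, seed = 9)
  m1 <- fit_pca(x, range = NULL)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  m2 <- fit_pca(x[perm, ], range = NULL)
  expect_equal(m2$loadings, m1$loadings, tolerance = 1e-10)
  expect_equal(unname(m2$scores), unname(m1$scores[perm, ]),
               tolerance = 1e-10)
  expect_equal(m2$var_fraction, m1$var_fraction, tolerance = 1e-12)
})

test_that("explained variance is cumulative, monotone and bounded", {
  x <- make_matrix(n = 6, p = 4)
  m <- fit_pca(x, range = NULL)
  k_max <- length(m$var_fraction)
  ev <- vapply(1:k_max, function(k) explained_variance(m, k), numeric(1))
  expect_true(all(diff(ev) >= -1e-12))
  expect_equal(ev[k_max], 100)
  expect_error(explained_variance(m, 0), "between")
  expect_error(explained_variance(m, k_max + 1), "between")
})

test_that("constant wavelengths are refused when scaling", {
  x <- make_matrix(n = 5, p = 4)
  x[, 2] <- 7
  expect_error(fit_pca(x, scale_unit_variance = TRUE, range = NULL), "262")
  expect_silent(fit_pca(x, scale_unit_variance = FALSE, range = NULL))
})

test_that("projection reproduces training scores and is affine-linear", {
  x <- make_matrix(n = 6, p = 4, seed = 13)
  m <- fit_pca(x, range = NULL)
  for (i in 1:6) {
    sc <- project(m, x[i, ])
    expect_equal(as.numeric(sc[1, -1]), unname(m$scores[i, ]),
                 tolerance = 1e-10)
  }
  # projecting the center gives the zero score
  expect_equal(as.numeric(project(m, m$center)[1, -1]),
               rep(0, ncol(m$scores)), tolerance = 1e-12)
  # linearity about the center: project(a + b - center) =
  # project(a) + project(b)
  a <- x[1, ]; b <- x[2, ]
  lhs <- as.numeric(project(m, a + b - m$center)[1, -1])
  rhs <- as.numeric(project(m, a)[1, -1]) + as.numeric(project(m, b)[1, -1])
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(project(m, 1:3), "does not match")
})

test_that("k-NN prediction votes in score space with documented tie-breaks", {
  pan <- simulate_panel(n_per_class = 5, seed = 101)
  m <- fit_pca(pan)
  # a training sample with k = 1 returns its own label
  one <- pan[pan$sample == "parallel_01", ]
  pred <- predict_label(m, one$value[order(one$wavelength)], k = 1)
  expect_identical(pred$label, "parallel")
  # k = panel size returns the majority class (here a 3-way 5/5/5 tie is
  # broken by smallest mean distance, deterministically)
  pred_all <- predict_label(m, one$value[order(one$wavelength)],
                            k = nrow(m$scores))
  expect_identical(pred_all$label, pred_all$votes$label[1])
  expect_equal(nrow(pred_all$neighbors), 15)
  expect_error(predict_label(m, one$value, k = 16), "exceeds")
  expect_error(predict_label(m, one$value, descriptor = "missing"),
               "not present")
})

test_that("well-separated synthetic classes are fully recovered leave-one-out", {
  pan <- simulate_panel(n_per_class = 5, seed = 101)
  loo <- loo_label_recovery(pan)
  expect_equal(mean(loo$correct), 1)
})

test_that("topology classes separate in the PC1/PC2 plane at low noise", {
  pan <- simulate_panel(n_per_class = 5, seed = 101)
  m <- fit_pca(pan)
  sil <- cluster::silhouette(as.integer(factor(m$meta$label)),
                             stats::dist(m$scores[, 1:2]))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("tidy and glance expose the model tables", {
  pan <- simulate_panel(n_per_class = 3, seed = 7)
  m <- fit_pca(pan)
  sc <- tidy(m, "scores")
  expect_true(all(c("sample", "label", "PC1", "PC2") %in% names(sc)))
  ld <- tidy(m, "loadings")
  expect_setequal(names(ld), c("wavelength", "component", "loading"))
  eigs <- tidy(m, "eigenvalues")
  expect_equal(max(eigs$cumulative_percent), 100, tolerance = 1e-9)
  g <- glance(m)
  expect_equal(g$n_samples, 9)
  expect_equal(g$pc12_percent, explained_variance(m, 2))
})
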
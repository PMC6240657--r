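test_that("duplicated samples get identical PCA scores", {
  set.seed(41)
  vals <- matrix(rlnorm(30 * 6), 30, 6)
  vals[, 4] <- vals[, 1]  # sample 4 duplicates sample 1
  x <- make_nsaf(vals)
  pca <- pca_fit(x)
  expect_equal(pca$scores[1, ], pca$scores[4, ], tolerance = 1e-9)
})

test_that("PCA loadings match closed-form 2x2 eigenvectors", {
  # two variables with known covariance: analytic eigendecomposition
  set.seed(43)
  n <- 200
  z <- matrix(rnorm(2 * n), n, 2)
  A <- rbind(c(2, 0.6), c(0.6, 1))   # target "sqrt" mixing
  mat <- z %*% A
  x <- make_nsaf(t(mat - min(mat) + 0.1), treatments = rep("T", n),
                 n_replicates = n)
  pca <- pca_fit(x)
  S <- stats::cov(t(x$values))
  # closed-form eigenvectors of a symmetric 2x2 [[a,b],[b,d]]
  a <- S[1, 1]; b <- S[1, 2]; d <- S[2, 2]
  l1 <- (a + d) / 2 + sqrt(((a - d) / 2)^2 + b^2)
  l2 <- (a + d) / 2 - sqrt(((a - d) / 2)^2 + b^2)
  v1 <- c(b, l1 - a); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(l2 - d, b); v2 <- v2 / sqrt(sum(v2^2))
  align <- function(u, v) min(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2)))
  expect_equal(align(pca$loadings[, 1], v1), 0, tolerance = 1e-9)
  expect_equal(align(pca$loadings[, 2], v2), 0, tolerance = 1e-9)
  expect_equal(pca$explained_variance[1:2], c(l1, l2), tolerance = 1e-9)
})

test_that("all components reconstruct the centered data and scores decorrelate", {
  set.seed(45)
  vals <- matrix(rlnorm(20 * 6), 20, 6)
  x <- make_nsaf(vals)
  pca <- pca_fit(x)
  centered <- t(x$values) - rep(pca$center, each = 6)
  recon <- pca$scores %*% t(pca$loadings)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-9)
  cv <- stats::cov(pca$scores)
  expect_equal(unname(cv), diag(pca$explained_variance), tolerance = 1e-9)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
})

test_that("loading-sum profiles partition total NSAF mass and match an oracle", {
  cm <- random_counts(30, 12, seed = 47)
  x <- nsaf(cm)
  pca <- pca_fit(x)
  hi <- loading_sum_profile(pca, x, 1, n = 15, side = "high")
  lo <- loading_sum_profile(pca, x, 1, n = 15, side = "low")
  expect_equal(hi + lo, colSums(treatment_means(x)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # oracle: sort-and-sum recomputation
  ld <- sort(pca$loadings[, 1], decreasing = TRUE)
  sel <- names(ld)[1:5]
  expect_equal(c(unclass(loading_sum_profile(pca, x, 1, n = 5, side = "high"))),
               unname(colSums(treatment_means(x)[sel, ])), tolerance = 1e-12,
               ignore_attr = TRUE)

  one <- loading_sum_profile(pca, x, 1, n = 1, side = "low")
  worst <- names(which.min(pca$loadings[, 1]))
  expect_equal(unname(one), unname(treatment_means(x)[worst, ]),
               ignore_attr = TRUE)
  expect_error(loading_sum_profile(pca, x, 1, n = 0), "positive")
})

test_that("profile normalization yields proportions that sum to one", {
  expect_equal(unname(profile_normalize(rbind(c(1, 1, 1, 1)))[1, ]),
               rep(0.25, 4))
  expect_equal(unname(profile_normalize(rbind(c(3, 0, 0, 1)))[1, ]),
               c(0.75, 0, 0, 0.25))
  set.seed(49)
  m <- matrix(rlnorm(200), 50, 4, dimnames = list(sprintf("p%02d", 1:50), NULL))
  expect_equal(rowSums(profile_normalize(m)), rep(1, 50),
               tolerance = 1e-12, ignore_attr = TRUE)
  m[3, ] <- 0
  expect_warning(out <- profile_normalize(m), "all-zero")
  expect_equal(nrow(out), 49)
})

test_that("k = 1 yields the grand mean and separated blobs are recovered", {
  set.seed(51)
  prof <- profile_normalize(matrix(rlnorm(40 * 4), 40, 4,
                                   dimnames = list(sprintf("p%02d", 1:40), NULL)))
  km1 <- kmeans_fit(prof, k = 1, seed = 1, n_restarts = 2)
  expect_equal(unname(km1$centroids[1, ]), unname(colMeans(prof)),
               tolerance = 1e-12)

  # three well-separated blobs on the 4-simplex
  centers <- rbind(c(0.85, 0.05, 0.05, 0.05),
                   c(0.05, 0.85, 0.05, 0.05),
                   c(0.05, 0.05, 0.05, 0.85))
  lab <- rep(1:3, each = 20)
  pts <- centers[lab, ] + matrix(runif(60 * 4, 0, 0.02), 60, 4)
  rownames(pts) <- sprintf("b%02d", 1:60)
  pts <- pts / rowSums(pts)
  km <- kmeans_fit(pts, k = 3, seed = 5, n_restarts = 10)
  # assignments recover blob labels up to permutation
  tab <- table(lab, km$assignments)
  expect_identical(sort(unname(apply(tab, 1, max))), c(20L, 20L, 20L))
})

test_that("k-means is deterministic, order-invariant, and improves with restarts", {
  set.seed(53)
  prof <- profile_normalize(matrix(rlnorm(60 * 4), 60, 4,
                                   dimnames = list(sprintf("p%02d", 1:60), NULL)))
  a <- kmeans_fit(prof, k = 5, seed = 9, n_restarts = 5)
  b <- kmeans_fit(prof[sample(nrow(prof)), ], k = 5, seed = 9, n_restarts = 5)
  expect_identical(a$assignments, b$assignments)
  expect_equal(a$inertia, b$inertia)
  more <- kmeans_fit(prof, k = 5, seed = 9, n_restarts = 10)
  expect_lte(more$inertia, a$inertia)
  expect_error(kmeans_fit(prof, k = 61, seed = 1), "exceeds")
})

test_that("cluster profile summaries match group-by recomputation", {
  set.seed(55)
  prof <- profile_normalize(matrix(rlnorm(50 * 4), 50, 4,
                                   dimnames = list(sprintf("p%02d", 1:50), NULL)))
  km <- kmeans_fit(prof, k = 6, seed = 11, n_restarts = 5)
  dat <- cluster_profile_plot_data(km)
  for (cl in rownames(dat$profile)) {
    members <- names(km$assignments)[km$assignments == as.integer(cl)]
    expect_equal(dat$profile[cl, ],
                 colMeans(km$profiles[members, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_identical(dat$members[[cl]], sort(members))
  }
  # pooled mean of two clusters equals the size-weighted average
  ids <- as.integer(rownames(dat$profile)[1:2])
  n1 <- dat$size[1]; n2 <- dat$size[2]
  pooled <- (n1 * dat$profile[1, ] + n2 * dat$profile[2, ]) / (n1 + n2)
  merged <- colMeans(km$profiles[km$assignments %in% ids, , drop = FALSE])
  expect_equal(unname(pooled), unname(merged), tolerance = 1e-12)
  expect_error(cluster_profile_plot_data(km, 99), "unknown cluster")
})
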
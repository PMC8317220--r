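test_that("z-normalization follows the sample-SD convention and inverts exactly", {
  feats <- rbind(c(1, 1, 1), c(3, 3, 3))
  colnames(feats) <- c("glucose_auc", "insulin_auc", "uric_acid")
  p <- zscore_fit(feats)
  expect_equal(unname(p$mean), rep(2, 3))
  expect_equal(unname(p$sd), rep(sqrt(2), 3)) # sample SD of {1, 3}
  z <- zscore_apply(p, feats)
  expect_equal(unname(z[, 1]), c(-1, 1) / sqrt(2))

  set.seed(1)
  X <- matrix(rnorm(300, 50, 9), 100, 3,
              dimnames = list(NULL, colnames(feats)))
  p <- zscore_fit(X)
  Z <- zscore_apply(p, X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3))
  expect_equal(zscore_apply(p, Z, inverse = TRUE), X)

  flat <- X; flat[, 2] <- 7
  expect_error(zscore_fit(flat), class = "obty_error_degenerate")
})

test_that("k-means recovers well-separated blob centers", {
  centers <- rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))
  b <- make_blobs(60, centers, sd = 0.4, seed = 2)
  fit <- kmeans_cluster(b$X, 4, seed = 3)
  # match each fitted center to the nearest generating mean
  se <- 0.4 / sqrt(60)
  for (j in 1:4) {
    d <- sqrt(rowSums(sweep(centers, 2, fit$centers[j, ])^2))
    expect_lt(min(d), 3 * se * sqrt(3))
  }
  # agreement with the generating labels after matching
  m <- match_clusters(b$truth, fit$cluster)
  expect_gt(attr(m, "agreement") / nrow(b$X), 0.99)
})

test_that("k-means degenerate sizes behave as specified", {
  X <- matrix(rnorm(24), 8, 3)
  expect_error(kmeans_cluster(X, 1), class = "obty_error_size")
  expect_error(kmeans_cluster(X, 9), class = "obty_error_size")
  fit <- kmeans_cluster(X, 8, seed = 1)
  expect_equal(fit$wcss, 0)
})

test_that("k-means attains the exhaustive-search optimum on tiny instances", {
  set.seed(4)
  X <- matrix(rnorm(8 * 2), 8, 2)
  fit <- kmeans_cluster(X, 2, n_init = 50, seed = 5)
  expect_equal(fit$wcss, brute_force_wcss(X, 2), tolerance = 1e-8)
})

test_that("k-means matches stats::kmeans on separated data (independent check)", {
  b <- make_blobs(40, rbind(c(0, 0), c(6, 0), c(3, 6)), sd = 0.5, seed = 6)
  ours <- kmeans_cluster(b$X, 3, seed = 7)
  ref <- kmeans(b$X, 3, nstart = 25, iter.max = 50)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("mean silhouette matches a hand-worked instance and the cluster package", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 10, 0, 10, 1, 11, 0), 6, 2, byrow = TRUE)
  cl <- c(1, 1, 1, 2, 2, 2)
  ours <- mean_silhouette(X, cl)
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(cl, dist(X))[, "sil_width"])
  expect_equal(ours, ref)

  # two essentially separated tight blobs approach 1
  b <- make_blobs(30, rbind(c(0, 0), c(100, 0)), sd = 0.1, seed = 8)
  expect_gt(mean_silhouette(b$X, b$truth), 0.99)

  # random labels on one blob sit near 0
  set.seed(9)
  X1 <- matrix(rnorm(1000), 500, 2)
  lab <- sample(1:2, 500, replace = TRUE)
  expect_lt(abs(mean_silhouette(X1, lab)), 0.05)
})

test_that("silhouette-based selection finds the generating cluster count", {
  b <- make_blobs(50, rbind(c(0, 0), c(8, 0)), sd = 0.5, seed = 10)
  expect_equal(as.integer(select_k(b$X, 2:6, seed = 11)), 2L)

  # a single Gaussian blob has no preferred k: the silhouette profile is
  # uniformly low, which is the "no structure" signal callers act on
  set.seed(12)
  X1 <- matrix(rnorm(600), 300, 2)
  k <- select_k(X1, 2:6, seed = 13)
  expect_lt(max(attr(k, "silhouette")), 0.45)
  expect_lt(diff(range(attr(k, "silhouette"))), 0.1)
})

test_that("subtype labeling reproduces the published center geometry per sex", {
  cfg <- default_config()
  expect_identical(label_subtypes(cfg$centers$male), subtype_levels())
  expect_identical(label_subtypes(cfg$centers$female), subtype_levels())
  # order-invariance
  perm <- c(3, 1, 4, 2)
  expect_identical(label_subtypes(cfg$centers$male[perm, ]),
                   subtype_levels()[perm])
  expect_error(label_subtypes(cfg$centers$male[1:3, ]), class = "obty_error_size")
  tied <- cfg$centers$male
  tied[, "glucose_auc"] <- 1000
  expect_error(label_subtypes(tied), class = "obty_error_validation")
})

test_that("sex-stratified fitting is order-invariant and needs both strata", {
  g <- generate_cohort(default_config(n = 160), seed = 14)
  cfg <- clustering_config(k_range = 2:5, n_init = 10)
  fit1 <- fit_sex_stratified(g$cohort, "kmeans", cfg, seed = 15)
  perm <- sample(nrow(g$cohort))
  shuffled <- as_cohort(as.data.frame(g$cohort)[perm, ],
                        comorbidities = comorbidity_names(g$cohort))
  fit2 <- fit_sex_stratified(shuffled, "kmeans", cfg, seed = 15)
  expect_equal(fit1$strata$male$centers, fit2$strata$male$centers)
  expect_identical(fit1$partition, fit2$partition)

  males <- as_cohort(as.data.frame(g$cohort)[g$cohort$sex == "male", ],
                     comorbidities = comorbidity_names(g$cohort))
  expect_error(fit_sex_stratified(males, "kmeans", cfg, seed = 15),
               class = "obty_error_stratum")
  expect_error(fit_sex_stratified(g$cohort, "kmeans", cfg),
               class = "obty_error_validation") # seed is mandatory
})

test_that("de-normalized centers re-normalize to the z-space solution", {
  g <- generate_cohort(default_config(n = 200), seed = 16)
  fit <- fit_sex_stratified(g$cohort, "kmeans",
                            clustering_config(k_range = 4), seed = 17)
  for (s in c("male", "female")) {
    st <- fit$strata[[s]]
    Cz <- zscore_apply(st$normalization, st$centers)
    back <- zscore_apply(st$normalization, Cz, inverse = TRUE)
    expect_lt(max(abs(back - st$centers) / abs(st$centers)), 1e-10)
  }
})
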
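# Class-separability indices and 2-D projections.

test_that("z-scoring standardizes, zeroes constant columns, is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  expect_warning(Z <- zscore_table(X), "constant")
  expect_equal(colMeans(Z), c(a = 0, b = 0, c = 0))
  expect_equal(sd(Z[, "a"]), 1)
  expect_true(all(Z[, "b"] == 0))
  Z2 <- suppressWarnings(zscore_table(Z))
  expect_equal(Z2[, c("a", "c")], Z[, c("a", "c")], tolerance = 1e-12)
  # missing values are median-imputed before scaling
  Xna <- cbind(a = c(1, NA, 3, 5))
  expect_false(anyNA(zscore_table(Xna)))
})

test_that("silhouette matches brute force and an independent library", {
  X <- matrix(c(0, 0, 1, 0, 10, 0, 11, 1), ncol = 2, byrow = TRUE)
  labs <- c("a", "a", "b", "b")
  mine <- silhouette_mean(X, labs)
  expect_equal(mine, oracle_silhouette(X, labs), tolerance = 1e-12)
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(labs)), stats::dist(X))
  expect_equal(mine, mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette is high for tight blobs, ~0 for shuffled labels", {
  set.seed(61)
  blobs <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
                 matrix(rnorm(100, 20, 0.1), ncol = 2))
  labs <- rep(c("a", "b"), each = 50)
  expect_gt(silhouette_mean(blobs, labs), 0.9)
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    one <- matrix(rnorm(400), ncol = 2)
    silhouette_mean(one, sample(rep(c("a", "b"), each = 100)))
  }, numeric(1))
  expect_lt(max(abs(nulls)), 0.05)
  expect_error(silhouette_mean(blobs, c("a", rep("b", 99))), "singleton")
})

test_that("Davies-Bouldin reproduces the line-cluster hand value", {
  X <- matrix(c(0, 2, 10, 12), ncol = 1)
  labs <- c("a", "a", "b", "b")
  expect_equal(davies_bouldin(X, labs), 0.2, tolerance = 1e-12)
  # scale invariance
  expect_equal(davies_bouldin(7 * X, labs), 0.2, tolerance = 1e-12)
  expect_equal(silhouette_mean(7 * X, labs), silhouette_mean(X, labs),
               tolerance = 1e-12)
  # coincident centroids are undefined
  Xc <- matrix(c(0, 2, 0, 2), ncol = 1)
  expect_error(davies_bouldin(Xc, labs), "coincident")
})

test_that("Calinski-Harabasz matches hand scatter and tracks separation", {
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  labs <- rep(c("a", "b"), each = 3)
  # by hand: trB = 2 * 3 * 25 = 150, trW = 4, k=2, n=6 -> (150/1)/(4/4)
  expect_equal(calinski_harabasz(X, labs), 150, tolerance = 1e-12)
  chis <- vapply(c(2, 5, 10), function(sep) {
    set.seed(71)
    Y <- rbind(matrix(rnorm(200), ncol = 2),
               matrix(rnorm(200, sep), ncol = 2))
    calinski_harabasz(Y, rep(c("a", "b"), each = 100))
  }, numeric(1))
  expect_true(all(diff(chis) > 0))
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    calinski_harabasz(matrix(rnorm(500 * 100), ncol = 100),
                      sample(rep(c("a", "b"), each = 250)))
  }, numeric(1))
  expect_true(all(nulls > 0.5 & nulls < 2))
  # permutation invariance of all three indices
  set.seed(72)
  Y <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 3), ncol = 2))
  yl <- rep(c("a", "b"), each = 30)
  p <- sample(60)
  expect_equal(calinski_harabasz(Y[p, ], yl[p]), calinski_harabasz(Y, yl))
  expect_equal(silhouette_mean(Y[p, ], yl[p]), silhouette_mean(Y, yl))
  expect_equal(davies_bouldin(Y[p, ], yl[p]), davies_bouldin(Y, yl))
})

test_that("merging confusable classes improves the index pattern", {
  # two pairs of heavily overlapping subclasses; merging each pair raises
  # CHI and lowers DBI
  tab <- generate_feature_table(
    60, effect = list(f1 = c(A1 = 0, A2 = 0.6, B1 = 5, B2 = 5.6),
                      f2 = c(A1 = 0, A2 = 0.6, B1 = 5, B2 = 5.6)),
    classes = c("A1", "A2", "B1", "B2"), n_features = 4, seed = 81)
  X <- as.matrix(tab[, setdiff(names(tab), "Group")])
  fine <- as.character(tab$Group)
  merged <- substr(fine, 1, 1)
  expect_gt(calinski_harabasz(X, merged), calinski_harabasz(X, fine))
  expect_lt(davies_bouldin(X, merged), davies_bouldin(X, fine))
})

test_that("PCA projection recovers planar structure; t-SNE is seeded", {
  set.seed(91)
  basis <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:2]
  plane <- matrix(rnorm(120), ncol = 2) %*% t(basis)  # rank-2 in 10-D
  Y <- project_2d(plane, "pca")
  expect_equal(dim(Y), c(60, 2))
  # top-2 PCs explain everything in the exact low-rank case
  Z <- zscore_table(plane)
  expect_gt(sum(apply(Y, 2, var)) / sum(apply(Z, 2, var)), 1 - 1e-8)
  expect_gte(var(Y[, 1]), var(Y[, 2]))
  set.seed(92)
  small <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  t1 <- project_2d(small, "tsne", seed = 5)
  t2 <- project_2d(small, "tsne", seed = 5)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(60, 2))
  # pluggable engine
  eng <- function(X, seed) X[, 1:2]
  expect_equal(project_2d(small, "tsne", engine = eng)[, 1],
               zscore_table(small)[, 1])
  expect_error(project_2d(small, "umap"), "arg")
})

test_that("separability reports carry the indices and provenance fields", {
  tab <- generate_feature_table(
    30, effect = list(f1 = c(3, 0, 0, 0), f2 = c(0, 3, 0, 3)),
    n_features = 6, seed = 99)
  rep_ <- separability_report(tab, scheme_name = "four")
  expect_s3_class(rep_, "separability_report")
  expect_true(rep_$silhouette_mean >= -1 && rep_$silhouette_mean <= 1)
  expect_gte(rep_$davies_bouldin, 0)
  expect_gte(rep_$calinski_harabasz, 0)
  expect_equal(rep_$n_samples, 120)
  expect_identical(rep_$standardization, "zscore")
  expect_output(print(rep_), "Silhouette")
})
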
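test_that("feature reduction drops variable then redundant features in order", {
  set.seed(1)
  fp <- matrix(rnorm(500 * 4), 500, 4,
               dimnames = list(NULL, c("a", "b", "a_dup", "c")))
  fp[, "a_dup"] <- fp[, "a"]  # exact duplicate: R^2 = 1
  lis1 <- matrix(rnorm(4 * 4, 0, 0.5), 4, 4,
                 dimnames = list(NULL, colnames(fp)))
  lis1[, "c"] <- c(0, 10, -10, 10)  # SD ~9.6 >= 3: dropped as variable
  red <- reduce_features(fp, lis1)
  expect_equal(red$retained, c("a", "b"))  # earlier of the pair kept
  expect_setequal(red$dropped$feature, c("a_dup", "c"))
  expect_equal(red$dropped$reason[red$dropped$feature == "c"], "variable")
  expect_equal(red$dropped$reason[red$dropped$feature == "a_dup"], "redundant")
  expect_equal(sd(c(0, 10, -10, 10)), 9.574271, tolerance = 1e-6)
})

test_that("independent noise features survive reduction and it is idempotent", {
  set.seed(2)
  fp <- matrix(rnorm(500 * 30), 500, 30,
               dimnames = list(NULL, sprintf("f%02d", 1:30)))
  lis1 <- matrix(rnorm(5 * 30, 0, 0.5), 5, 30,
                 dimnames = list(NULL, colnames(fp)))
  red <- reduce_features(fp, lis1)
  expect_gte(length(red$retained) / 30, 0.95)
  red2 <- reduce_features(fp[, red$retained, drop = FALSE],
                          lis1[, red$retained, drop = FALSE])
  expect_identical(red2$retained, red$retained)
  expect_equal(nrow(red2$dropped), 0)
})

test_that("correlation distance has the expected extremes", {
  fp <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cc <- cor(t(fp))
  expect_equal(1 - cc["a", "b"], 0)       # identical profiles: distance 0
  expect_equal(1 - cc["a", "c"], 2)       # anti-correlated: distance 2
  # Pearson distance is invariant to per-gene affine transforms
  fp2 <- fp * c(2, 0.5, 10) + c(5, -3, 0)
  expect_equal(1 - cor(t(fp2)), 1 - cc, tolerance = 1e-12)
})

test_that("identical fingerprints merge first in the tree", {
  set.seed(3)
  fp <- matrix(rnorm(5 * 8), 5, 8,
               dimnames = list(c("g1", "g2", "g3", "g4", "g5"), NULL))
  fp["g2", ] <- fp["g1", ]
  colnames(fp) <- sprintf("f%d", 1:8)
  res <- hierarchical_cluster(fp, k = 4, scale = FALSE)
  expect_equal(res$labels[["g1"]], res$labels[["g2"]])
  first_merge <- res$tree$merge[1, ]
  merged <- res$tree$labels[-first_merge]
  expect_setequal(merged, c("g1", "g2"))
})

test_that("hierarchical clustering agrees with a brute-force linkage oracle", {
  set.seed(4)
  fp <- matrix(rnorm(12 * 6), 12, 6,
               dimnames = list(sprintf("g%02d", 1:12), sprintf("f%d", 1:6)))
  res <- hierarchical_cluster(fp, k = 4, scale = FALSE)
  dmat <- 1 - cor(t(fp))
  for (k in c(2, 3, 4, 6)) {
    oracle <- naive_linkage_labels(dmat, k)
    ours <- cutree(res$tree, k = k)[rownames(fp)]
    expect_true(same_partition(oracle, unname(ours)))
  }
})

test_that("zero-variance fingerprints become flagged singletons", {
  set.seed(5)
  fp <- matrix(rnorm(4 * 6), 4, 6,
               dimnames = list(c("a", "b", "c", "flat"), sprintf("f%d", 1:6)))
  fp["flat", ] <- 2
  res <- hierarchical_cluster(fp, k = 2, scale = FALSE)
  expect_equal(res$flagged, "flat")
  expect_false("flat" %in% res$tree$labels)
  expect_true("flat" %in% names(res$labels))
  expect_equal(sum(res$labels == res$labels[["flat"]]), 1)
})

test_that("K-means separates planted blobs and keeps duplicates together", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40 * 3, 0, 0.2), 40, 3),
             matrix(rnorm(40 * 3, 5, 0.2), 40, 3))
  rownames(x) <- sprintf("g%02d", 1:80)
  truth <- rep(1:2, each = 40)
  km <- kmeans_cargo_clusters(x, K = 2, seed = 7)
  expect_true(same_partition(unname(km$labels), truth))
  # duplicates co-cluster
  x2 <- x; x2[2, ] <- x2[1, ]
  km2 <- kmeans_cargo_clusters(x2, K = 2, seed = 7)
  expect_equal(km2$labels[[1]], km2$labels[[2]])
  # K = 1 returns the grand mean centroid
  km1 <- kmeans_cargo_clusters(x, K = 1, seed = 7)
  expect_equal(as.numeric(km1$centers), colMeans(x))
  expect_error(kmeans_cargo_clusters(x, K = 100), "exceeds")
  # determinism under fixed seed
  expect_identical(kmeans_cargo_clusters(x, K = 5, seed = 9)$labels,
                   kmeans_cargo_clusters(x, K = 5, seed = 9)$labels)
})

test_that("cluster labels survive feature-registry permutation", {
  set.seed(7)
  pm <- planted_module_fingerprints(4, 6, 12, seed = 7)
  perm <- sample(ncol(pm$fingerprints))
  km1 <- kmeans_cargo_clusters(pm$fingerprints, K = 4, seed = 3)
  km2 <- kmeans_cargo_clusters(pm$fingerprints[, perm], K = 4, seed = 3)
  expect_true(same_partition(unname(km1$labels), unname(km2$labels)))
  h1 <- hierarchical_cluster(pm$fingerprints, k = 4)
  h2 <- hierarchical_cluster(pm$fingerprints[, perm], k = 4)
  expect_true(same_partition(unname(h1$labels[names(h2$labels)]),
                             unname(h2$labels)))
})

test_that("planted co-functional modules are recovered by both methods", {
  pm <- planted_module_fingerprints(6, 8, 20, separation = 3, seed = 11)
  hc <- hierarchical_cluster(pm$fingerprints, k = 6)
  expect_gte(adjusted_rand(unname(hc$labels[rownames(pm$fingerprints)]),
                           pm$labels), 0.9)
  km <- kmeans_cargo_clusters(pm$fingerprints, K = 6, seed = 13)
  expect_gte(adjusted_rand(unname(km$labels), pm$labels), 0.9)
})

test_that("the 2-D embedding is deterministic and separates planted modules", {
  pm <- planted_module_fingerprints(2, 10, 15, separation = 4, seed = 15)
  e1 <- embed_fingerprints(pm$fingerprints, seed = 1)
  e2 <- embed_fingerprints(pm$fingerprints, seed = 1)
  expect_identical(e1, e2)
  d <- as.matrix(dist(e1[, c("dim1", "dim2")]))
  same <- outer(pm$labels, pm$labels, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
  single <- embed_fingerprints(pm$fingerprints[1, , drop = FALSE])
  expect_true(all(is.finite(c(single$dim1, single$dim2))))
})

test_that("heatmap export preserves leaf order and min-max scaling", {
  pm <- planted_module_fingerprints(3, 4, 8, seed = 17)
  hc <- hierarchical_cluster(pm$fingerprints, k = 3)
  csv <- tempfile(fileext = ".csv")
  mat <- export_heatmap(pm$fingerprints, hc, file = NULL, matrix_file = csv)
  expect_equal(rownames(mat), hc$tree$labels[hc$tree$order])
  expect_equal(unname(apply(mat, 2, min)), rep(0, ncol(mat)))
  expect_equal(unname(apply(mat, 2, max)), rep(1, ncol(mat)))
  back <- read.csv(csv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]),
               unname(mat)[, , drop = FALSE], tolerance = 1e-9,
               ignore_attr = TRUE)
  nwk <- tempfile(fileext = ".newick")
  write_dendrogram(hc, nwk)
  expect_setequal(ape::read.tree(nwk)$tip.label, rownames(mat))
})
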
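test_that("encode_matrix yields integer scale positions with subsetting and grouping", {
  g <- generate_cohort(paper_like_preset(n = 40), seed = 5L)
  co <- g$cohort
  X <- encode_matrix(co)
  expect_equal(dim(X), c(40, 79))
  expect_true(all(X == round(X)) && min(X) >= 1 && max(X) <= 9)
  Xf <- encode_matrix(co, "food_item")
  expect_equal(ncol(Xf), 58)
  Xb <- encode_matrix(co, c("food_item", "dietary_behavior"))
  expect_equal(ncol(Xb), 70)
  # singleton groups are an identity transform
  grp <- list(chicken = "chicken", coffee = "coffee")
  Xg <- encode_matrix(co, "food_item", grouping = grp)
  expect_equal(Xg[, "chicken"], unname(X[, "chicken"]))
  # real groups average member columns
  Xd <- encode_matrix(co, "food_item",
                      grouping = list(dairy = c("milk_yogurt",
                                                "reduced_fat_milk_yogurt")))
  expect_equal(Xd[, "dairy"],
               rowMeans(X[, c("milk_yogurt", "reduced_fat_milk_yogurt")]),
               ignore_attr = TRUE)
  expect_equal(ncol(Xd), 57)
  expect_error(encode_matrix(co, character(0)), "non-empty")
})

test_that("umap embedding is deterministic, 2D, and errors on tiny input", {
  set.seed(1)
  X <- matrix(sample(1:7, 50 * 10, TRUE), 50)
  e1 <- umap_embed(X, seed = 9L, n_epochs = 100)
  e2 <- umap_embed(X, seed = 9L, n_epochs = 100)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(50, 2))
  expect_true(all(is.finite(e1)))
  e3 <- umap_embed(X, seed = 10L, n_epochs = 100)
  expect_false(identical(e1, e3))
  expect_error(umap_embed(X[1:5, ], n_neighbors = 10), "at least")
})

test_that("umap separates two planted response blocks", {
  set.seed(3)
  lo <- matrix(sample(1:3, 40 * 20, TRUE), 40)
  hi <- matrix(sample(5:7, 40 * 20, TRUE), 40)
  X <- rbind(lo, hi)
  emb <- umap_embed(X, seed = 2L)
  km <- kmeans_assign(emb, 2, clustering_config(seed = 2L))
  sil <- mean(cluster::silhouette(km$labels + 1,
                                  dist(emb))[, "sil_width"])
  expect_gt(sil, 0.5)
  truth <- rep(0:1, each = 40)
  expect_gte(adjusted_rand(km$labels, truth), 0.9)
})

test_that("select_k recovers the blob count and reports all diagnostics", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8), c(8, 8))
  emb <- gaussian_blobs(centers, 40, sd = 0.5, seed = 11)
  sel <- select_k(emb, config = clustering_config(seed = 1L))
  expect_equal(sel$diagnostics$silhouette_k, 4)
  expect_equal(sel$diagnostics$kde_peak_count, 4)
  expect_equal(sel$k, 4)
  # WCSS non-increasing in k; silhouette within [-1, 1]
  expect_true(all(diff(sel$diagnostics$wcss) <= 1e-8))
  expect_true(all(abs(sel$diagnostics$silhouette) <= 1))

  one <- gaussian_blobs(rbind(c(0, 0)), 100, sd = 1, seed = 4)
  sel1 <- select_k(one, config = clustering_config(seed = 1L))
  expect_equal(sel1$diagnostics$kde_peak_count, 1)
  expect_error(select_k(matrix(1, 30, 2)), "degenerate")
})

test_that("kde_peak_count matches closed-form expectations", {
  # two point masses ten bandwidths apart -> two modes
  two <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
               matrix(rep(c(10, 0), 20), ncol = 2, byrow = TRUE))
  expect_equal(kde_peak_count(two, bandwidth = 1, grid = 120), 2)
  # coincident points: a single mode by definition
  expect_equal(kde_peak_count(matrix(rep(c(2, 3), 15), ncol = 2, byrow = TRUE)), 1)
  # threshold 1.0 keeps only the global maximum
  emb <- gaussian_blobs(rbind(c(0, 0), c(6, 0)), c(60), sd = 0.4, seed = 2)
  expect_equal(kde_peak_count(emb, bandwidth = 0.5, threshold = 1.0), 1)
  expect_error(kde_peak_count(emb, bandwidth = -1), "positive")
})

test_that("cluster_overlap: identity, permutation invariance, and a moved point", {
  set.seed(8)
  a <- sample(0:3, 120, TRUE)
  expect_true(all(cluster_overlap(a, a) == 100))
  perm <- c(2L, 3L, 0L, 1L)
  expect_true(all(cluster_overlap(a, perm[a + 1]) == 100))
  # ten points, one moved between clusters: that cluster drops to 4/5
  a10 <- rep(0:1, each = 5)
  b10 <- a10; b10[1] <- 1L
  ov <- cluster_overlap(a10, b10)
  expect_equal(unname(ov["A"]), 80)
  expect_equal(unname(ov["B"]), 100)
  expect_error(cluster_overlap(a10, b10[-1]), "different")
})

test_that("adjusted_rand agrees with the mclust oracle", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:10) {
    a <- sample(0:3, 80, TRUE)
    b <- sample(0:2, 80, TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  a <- sample(0:3, 50, TRUE)
  expect_equal(adjusted_rand(a, a), 1)
})
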
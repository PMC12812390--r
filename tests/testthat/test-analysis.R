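test_that("pearson correlation matches the closed-form oracle", {
  x <- c(0.1, 0.4, 0.9, 0.2)
  y <- c(0.2, 0.5, 0.7, 0.1)
  # frozen value from independent hand evaluation of the product-moment formula
  expect_equal(pearson_r(x, y), 0.9182929821994383, tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1.0)
  expect_equal(pearson_r(x, -x + 0.7), -1.0)
  expect_equal(pearson_r(x, y), pearson_r(y, x))
  expect_error(pearson_r(x, rep(0.5, 4)), "undefined correlation")
  expect_error(pearson_r(x[1:2], y[1:2]), "at least 3")
  expect_error(pearson_r(x, y[1:3]), "length")
})

test_that("pearson correlation is invariant under positive affine maps", {
  set.seed(4)
  for (i in 1:10) {
    x <- runif(20); y <- runif(20)
    r <- pearson_r(x, y)
    a <- runif(1, 0.1, 5); b <- runif(1, -2, 2)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(-a * x + b, y), -r, tolerance = 1e-12)
  }
})

test_that("pairwise correlations preserve pair order and validate names", {
  mat <- toy_beta_matrix(seed = 2)
  pairs <- data.frame(sample_a = c("ctl01", "cas01", "ctl02"),
                      sample_b = c("ctl01", "ctl03", "cas02"))
  res <- platform_correlations(mat, pairs)
  expect_equal(nrow(res), 3)
  expect_equal(res$sample_a, pairs$sample_a)
  expect_equal(res$r[1], 1.0)
  expect_equal(res$n_probes, rep(nrow(mat$values), 3))
  expect_error(platform_correlations(mat, data.frame(sample_a = "nope",
                                                     sample_b = "ctl01")),
               "unknown sample")
})

test_that("complete-linkage clustering matches the exhaustive oracle", {
  for (trial in 1:30) {
    set.seed(trial + 100)
    n <- sample(3:6, 1)
    pts <- matrix(runif(n * 4), n,
                  dimnames = list(sprintf("s%d", seq_len(n)),
                                  sprintf("f%d", 1:4)))
    samples <- data.frame(sample_id = rownames(pts), group = "control",
                          platform = "array")
    mat <- beta_matrix(t(pts), samples)
    hc <- beta_hclust(mat)
    ref <- naive_complete_linkage(pts)
    expect_equal(hc$height, ref$heights, tolerance = 1e-12)
    expect_identical(hclust_members(hc), ref$members)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  }
})

test_that("clustering resolves designed structure and degenerate input", {
  # two tight pairs: the first two merges must be the pairs themselves
  base <- c(0.2, 0.8, 0.5, 0.3)
  v <- cbind(a1 = base, a2 = base + 0.005, b1 = base + 0.5, b2 = base + 0.505)
  rownames(v) <- sprintf("p%d", 1:4)
  mat <- beta_matrix(pmin(v, 1),
                     data.frame(sample_id = colnames(v), group = "control",
                                platform = "array"))
  hc <- beta_hclust(mat)
  first_two <- vapply(hclust_members(hc)[1:2], function(m) {
    paste(sort(hc$labels[m]), collapse = "+")
  }, character(1))
  expect_setequal(first_two, c("a1+a2", "b1+b2"))

  # two samples merge at their Euclidean distance
  m2 <- mat[, 1:2]
  hc2 <- beta_hclust(m2)
  expect_equal(hc2$height, sqrt(sum((v[, 1] - v[, 2])^2)))

  # duplicate columns merge at height zero
  v3 <- v; v3[, 2] <- v3[, 1]
  m3 <- beta_matrix(pmin(v3, 1), mat$samples)
  expect_equal(min(beta_hclust(m3)$height), 0)
})

test_that("dendrograms export as Newick with heights", {
  mat <- toy_beta_matrix(n_probes = 10, n_controls = 3, n_cases = 2, seed = 6)
  nwk <- dendrogram_newick(beta_hclust(mat))
  expect_match(nwk, "^\\(.*\\);$")
  for (id in mat$samples$sample_id) expect_match(nwk, id, fixed = TRUE)
})

test_that("classical MDS reproduces distances of genuinely 2-D point sets", {
  # 3-4-5 right triangle
  pts <- rbind(c(0, 0), c(3, 0), c(3, 4))
  rownames(pts) <- c("a", "b", "c")
  emb <- beta_mds(pts, k = 2)
  expect_equal(as.matrix(dist(emb$coordinates)), as.matrix(dist(pts)),
               tolerance = 1e-8)

  # random planar sets embedded in high dimension are recovered exactly
  for (trial in 1:5) {
    set.seed(trial)
    plane <- matrix(rnorm(12), 6, 2)
    basis <- qr.Q(qr(matrix(rnorm(40), 10, 4)))[, 1:2]
    high <- plane %*% t(basis)
    rownames(high) <- sprintf("s%d", 1:6)
    emb <- beta_mds(high, k = 2)
    expect_equal(as.matrix(dist(emb$coordinates)), as.matrix(dist(high)),
                 tolerance = 1e-8)
  }
})

test_that("MDS handles edge cases per contract", {
  # two points in k = 1: the embedding is an isometry
  two <- rbind(a = c(0, 0, 0), b = c(1, 2, 2))
  emb <- beta_mds(two, k = 1)
  expect_equal(unname(abs(diff(emb$coordinates[, 1]))), 3, tolerance = 1e-10)

  # identical samples embed at the origin
  same <- matrix(0.5, 4, 3, dimnames = list(sprintf("s%d", 1:4), NULL))
  expect_true(all(beta_mds(same, k = 2)$coordinates == 0))

  # k exceeding the positive eigenvalues errors
  expect_error(beta_mds(two, k = 2), "positive eigenvalue")

  # axis sign convention: largest-magnitude loading is positive
  pts <- matrix(rnorm(24, sd = 2), 8, 3)
  rownames(pts) <- sprintf("s%d", 1:8)
  co <- beta_mds(pts, k = 2)$coordinates
  for (j in 1:2) expect_gt(co[which.max(abs(co[, j])), j], 0)
})

test_that("silhouette is positive for separated groups, negative for swapped labels", {
  set.seed(12)
  coords <- rbind(matrix(rnorm(20, 0, 0.1), 10),
                  matrix(rnorm(20, 3, 0.1), 10))
  labels <- rep(c("case", "control"), each = 10)
  expect_gt(group_silhouette(coords, labels), 0.8)
  shuffled <- sample(labels)
  expect_lt(group_silhouette(coords, shuffled),
            group_silhouette(coords, labels))
  expect_error(group_silhouette(coords, rep("case", 20)), "two groups")
})
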
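test_that("row centering subtracts row means and is exactly invertible", {
  xc <- row_center(toy_t1())
  expect_equal(unname(xc$values["r1", ]), c(-1/3, -1/3, 2/3))
  expect_true(all(abs(rowSums(xc$values)) < 1e-9))
  expect_equal(xc$values + xc$row_means, toy_t1()$entries * 1.0,
               ignore_attr = TRUE)

  zero_row <- rbind(c(0, 0, 0), c(1, -1, 0))
  expect_equal(row_center(zero_row)$values[1, ], c(0, 0, 0))
  expect_error(row_center(matrix(1, 2, 1)), "at least 2 studies")
})

test_that("Gram covariance matches the printed form and hand examples", {
  xt <- rbind(c(1, -1), c(-1, 1))
  sigma <- gram_covariance(xt)
  expect_equal(sigma, rbind(c(2, -2), c(-2, 2)))
  expect_true(all(gram_covariance(matrix(0, 3, 4)) == 0))
  set.seed(5)
  x <- matrix(rnorm(20), 5, 4)
  s <- gram_covariance(x)
  expect_equal(s, t(s))
  expect_true(all(diag(s) >= 0))
  expect_equal(s, x %*% t(x) / 3)
})

test_that("eigendecomposition is sorted, sign-fixed, and solves the eigen problem", {
  eig <- eigendecompose(rbind(c(2, -2), c(-2, 2)))
  expect_equal(eig$values, c(4, 0))
  expect_equal(abs(eig$vectors[, 1]), c(1, 1) / sqrt(2))
  # sign rule: largest-magnitude component positive (first on ties)
  expect_gt(eig$vectors[1, 1], 0)

  eig3 <- eigendecompose(diag(3))
  expect_equal(eig3$values, c(1, 1, 1))
  expect_equal(crossprod(eig3$vectors), diag(3), tolerance = 1e-8)

  set.seed(9)
  a <- matrix(rnorm(36), 6, 6); sigma <- a + t(a)
  eig6 <- eigendecompose(sigma)
  expect_true(all(diff(eig6$values) <= 1e-12))
  expect_equal(sum(eig6$values), sum(diag(sigma)), tolerance = 1e-6)
  for (i in 1:6)
    expect_equal(sigma %*% eig6$vectors[, i],
                 eig6$values[i] * eig6$vectors[, i],
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(eigendecompose(matrix(1:6, 2, 3)), "symmetric")
  expect_error(eigendecompose(rbind(c(1, 2), c(0, 1))), "symmetric")
})

test_that("region scores follow the principal-coordinate convention", {
  xt <- structure(list(values = rbind(c(1, -1), c(-1, 1)),
                       row_means = c(0, 0)), class = "centered_matrix")
  eig <- eigendecompose(gram_covariance(xt))
  s <- region_scores(xt, eig, 1L)
  expect_equal(sort(as.numeric(s)), c(-sqrt(2), sqrt(2)))
  expect_error(region_scores(xt, eig, 2L), "positive eigenvalues")
})

test_that("full-dimensional scores preserve pairwise distances (Gram/PCoA identity)", {
  set.seed(77)
  for (rep in 1:5) {
    fp <- rand_fingerprint(10, 6)
    xc <- row_center(fp$matrix)
    eig <- eigendecompose(gram_covariance(xc))
    pos <- sum(eig$values > 1e-9)
    s <- region_scores(xc, eig, pos)
    # scores carry the 1/(|S|-1) normalisation of the Gram matrix
    expect_equal(as.matrix(stats::dist(s)),
                 as.matrix(stats::dist(xc$values)) / sqrt(ncol(xc$values) - 1),
                 tolerance = 1e-6)
  }
})

test_that("duplicate rows receive identical scores", {
  x <- rbind(a = c(-1, 0, 1, 0), b = c(-1, 0, 1, 0), c = c(1, 1, 0, -1))
  xc <- row_center(x)
  eig <- eigendecompose(gram_covariance(xc))
  s <- region_scores(xc, eig, sum(eig$values > 1e-9))
  expect_equal(s["a", ], s["b", ], tolerance = 1e-9)
})

test_that("Gram and feature covariance share their non-zero spectrum; rank <= |S|-1", {
  set.seed(31)
  for (rep in 1:5) {
    fp <- rand_fingerprint(sample(5:15, 1), sample(3:8, 1))
    xc <- row_center(fp$matrix)
    lg <- eigendecompose(gram_covariance(xc))$values
    lf <- eigendecompose(feature_covariance(xc))$values
    k <- min(length(lg), length(lf))
    expect_equal(lg[1:k], lf[1:k], tolerance = 1e-8)
    expect_lte(sum(lg > 1e-9), ncol(fp$matrix$entries) - 1L)
  }
})

test_that("explained variance ratios are non-negative and sum to one", {
  emb <- snf_embedding(toy_t1(), n_components = 1L, toy_scheme())
  expect_true(all(emb$explained_variance_ratio >= 0))
  expect_equal(sum(emb$explained_variance_ratio), 1)
  expect_identical(emb$dominant_network, c("k1", "k1", "k2"))
})

test_that("Ward merges identical rows first and matches the 3-point hand case", {
  x <- rbind(c(0, 0), c(0, 0), c(3, 4))
  cl <- ward_dendrogram(x)
  expect_equal(cl$merge_table$height[1], 0)
  expect_identical(cl$hclust$merge[1, ], c(-2L, -1L))
  # Ward distance from {r1,r2} to {r3}: sqrt(2*2*1/3)*5
  expect_equal(cl$merge_table$height[2], sqrt(4 / 3) * 5, tolerance = 1e-9)
  expect_error(ward_dendrogram(matrix(0, 1, 3)), "at least 2 regions")
})

test_that("Ward heights are non-decreasing and trees are deterministic", {
  set.seed(44)
  for (rep in 1:10) {
    fp <- rand_fingerprint(sample(4:10, 1), 4)
    c1 <- ward_dendrogram(fp$matrix)
    expect_true(all(diff(c1$merge_table$height) >= -1e-12))
    c2 <- ward_dendrogram(fp$matrix)
    expect_identical(c1$hclust$merge, c2$hclust$merge)
    expect_equal(c1$hclust$height, c2$hclust$height)
  }
})

test_that("Ward agrees with the centroid-form objective oracle on ternary data", {
  set.seed(202)
  for (rep in 1:8) {
    x <- matrix(sample(c(-1, 0, 1), 32, replace = TRUE), 8, 4)
    rownames(x) <- paste0("r", 1:8)
    cl <- ward_dendrogram(x)
    orc <- oracle_ward(x)
    expect_equal(cl$merge_table$height, orc$heights, tolerance = 1e-8)
    for (t in seq_len(7)) {
      impl_part <- stats::cutree(cl$hclust, k = 8 - t)
      expect_equal(adjusted_rand_index(unname(impl_part), orc$partitions[[t]]), 1)
    }
  }
})

test_that("Ward matches stats::hclust ward.D2 on tie-free continuous data", {
  set.seed(303)
  for (rep in 1:5) {
    x <- matrix(rnorm(40), 10, 4)
    cl <- ward_dendrogram(x)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    expect_equal(cl$hclust$height, hc$height, tolerance = 1e-8)
    for (k in c(2, 4, 7))
      expect_equal(adjusted_rand_index(unname(stats::cutree(cl$hclust, k)),
                                       unname(stats::cutree(hc, k))), 1)
  }
})

test_that("labels_at_k yields exactly k non-empty groups over the valid range", {
  cl <- ward_dendrogram(toy_t1())
  for (k in 1:3)
    expect_identical(length(unique(labels_at_k(cl, k))), k)
  expect_error(labels_at_k(cl, 0), "between 1 and")
  expect_error(labels_at_k(cl, 4), "between 1 and")
})

test_that("adjusted Rand index matches references and is permutation-invariant", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), pair_count_ari(a, b),
                 tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    relab <- c(10, 20, 30)[a]
    expect_equal(adjusted_rand_index(relab, b), adjusted_rand_index(a, b))
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})

test_that("cluster-vs-network agreement is 1 for a network-identical partition", {
  # two tight groups matching the two toy networks exactly
  x <- rbind(r1 = c(-1, -1, 0, 0), r2 = c(-1, -1, 0, 0),
             r3 = c(0, 0, 1, 1), r4 = c(0, 0, 1, 1))
  regions <- region_records(rownames(x), rownames(x), "BILATERAL", "GM",
                            c("k1", "k1", "k2", "k2"), vocabulary = c("k1", "k2"))
  studies <- study_records(paste0("s", 1:4), "x", "VBM", "CROSS_SECTIONAL")
  m <- fingerprint_matrix(x, regions, studies)
  sch <- network_scheme(regions, network_ids = c("k1", "k2"),
                        priority = c("k1", "k2"))
  cl <- ward_dendrogram(m)
  expect_equal(cluster_network_agreement(cl, sch, 2), 1)
  expect_error(cluster_network_agreement(cl, sch, 1), "between 2 and")
})

test_that("Newick export round-trips topology and uses merge-height branch lengths", {
  cl <- ward_dendrogram(toy_t1())
  txt <- export_newick(cl)
  expect_match(txt, ";$")
  ph <- ape::read.tree(text = txt)
  expect_identical(sort(ph$tip.label), c("r1", "r2", "r3"))
  expect_identical(ape::Ntip(ph), 3L)
  # ultrametric: every leaf sits at depth equal to the root merge height
  depths <- ape::node.depth.edgelength(ph)[seq_len(3)]
  expect_equal(depths, rep(max(cl$merge_table$height), 3), tolerance = 1e-6)

  # topology equals the ape conversion of the same hclust tree
  ref <- ape::as.phylo(cl$hclust)
  expect_true(ape::all.equal.phylo(ph, ref, use.edge.length = FALSE))

  # 2-leaf tree
  cl2 <- ward_dendrogram(rbind(a = c(0, 0), b = c(3, 4)))
  ph2 <- ape::read.tree(text = export_newick(cl2))
  expect_identical(sort(ph2$tip.label), c("a", "b"))
  expect_equal(as.numeric(ph2$edge.length), c(5, 5))
})

test_that("clustering on centered rows is available and differs only via centering", {
  fp <- rand_fingerprint(8, 5)
  cl_raw <- ward_dendrogram(fp$matrix, use_centered = FALSE)
  cl_cen <- ward_dendrogram(fp$matrix, use_centered = TRUE)
  expect_false(cl_cen$use_centered == FALSE)
  ref <- ward_dendrogram(row_center(fp$matrix)$values)
  expect_equal(cl_cen$hclust$height, ref$hclust$height)
  expect_identical(cl_raw$labels, cl_cen$labels)
})
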
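test_that("Euclidean distances match the naive double-loop oracle", {
  expect_equal(as.matrix(euclideanDistances(
    rbind(a = c(1, 0, 0), b = c(0, 1, 0))))["a", "b"], sqrt(2))
  set.seed(14)
  for (r in 1:10) {
    x <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("v", 1:6), NULL))
    d <- as.matrix(euclideanDistances(x))
    for (i in 1:6) for (j in 1:6)
      expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)),
                   tolerance = 1e-12)
  }
})

test_that("all eight linkages reproduce the Lance-Williams reference heights", {
  set.seed(15)
  for (r in 1:30) {
    x <- matrix(rnorm(8 * 4), 8, dimnames = list(paste0("v", 1:8), NULL))
    d <- euclideanDistances(x)
    for (m in linkageMethods()) {
      h <- agglomerativeTree(d, m)
      expect_equal(sort(h$height), sort(lanceWilliamsOracle(d, m)),
                   tolerance = 1e-9, info = m)
    }
  }
})

test_that("average linkage merges the closest pair first; single linkage follows the MST", {
  pts <- matrix(c(0, 1, 10), dimnames = list(c("a", "b", "c"), NULL))
  h <- agglomerativeTree(euclideanDistances(pts), "average")
  expect_equal(h$height[1], 1)
  expect_identical(sort(h$labels[-h$merge[1, ]]), c("a", "b"))
  set.seed(16)
  for (r in 1:10) {
    x <- matrix(rnorm(9 * 3), 9, dimnames = list(paste0("v", 1:9), NULL))
    d <- euclideanDistances(x)
    hs <- agglomerativeTree(d, "single")
    g <- igraph::graph_from_adjacency_matrix(as.matrix(d), mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    expect_equal(sort(hs$height), sort(igraph::E(mst)$weight),
                 tolerance = 1e-9)
  }
})

test_that("ward.D2 separates planted blobs at the top split and its cophenetic correlation is high", {
  set.seed(17)
  b <- threeBlobs(17)
  d <- euclideanDistances(b$points[1:40, ])  # two blobs
  h <- agglomerativeTree(d, "ward.D2")
  cut2 <- cutTreeClusters(h, 2)
  expect_identical(unname(cut2[1:20]), rep(cut2[[1]], 20))
  expect_identical(unname(cut2[21:40]), rep(cut2[[21]], 20))
  ## ultrametric input: cophenetic distances reproduce the generating tree
  hu <- agglomerativeTree(euclideanDistances(b$points), "ward.D2")
  du <- cophenetic(hu)
  h2 <- agglomerativeTree(du, "ward.D2")
  expect_gt(cor(as.vector(cophenetic(h2)), as.vector(du)), 0.99)
})

test_that("tree cutting matches the height-threshold oracle and labels by leaf order", {
  set.seed(18)
  for (r in 1:50) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n, dimnames = list(paste0("v", 1:n), NULL))
    h <- agglomerativeTree(euclideanDistances(x), "average")
    k <- sample(1:n, 1)
    ct <- cutTreeClusters(h, k)
    expect_identical(length(unique(ct)), k)
    expect_identical(sort(unique(ct)), seq_len(k))
    ## same partition as stats::cutree (height-threshold machinery)
    ref <- cutree(h, k = k)
    expect_identical(length(unique(paste(ct, ref))), k)
    ## first leaf in display order always carries label 1
    expect_identical(unname(ct[h$labels[h$order][1]]), 1L)
  }
  h <- agglomerativeTree(euclideanDistances(
    matrix(rnorm(15), 5, dimnames = list(letters[1:5], NULL))), "complete")
  expect_identical(length(unique(cutTreeClusters(h, 5))), 5L)
  expect_identical(unname(cutTreeClusters(h, 1)), rep(1L, 5))
})

test_that("trait purity matches an exhaustive recount and handles edge cases", {
  ## 12 leaves, 4 pure clusters of 3 -> perfect score 12
  set.seed(19)
  pts <- do.call(rbind, lapply(0:3, function(g)
    matrix(rnorm(3 * 2, 10 * g, .1), 3)))
  rownames(pts) <- paste0("v", 1:12)
  tr <- toyTraits(rownames(pts), vt = rep(c("L", "C"), each = 6),
                  gh = rep(c("W", "S", "W", "S"), each = 3))
  h <- agglomerativeTree(euclideanDistances(pts), "ward.D2")
  ps <- traitPurityScore(h, tr, "VTGH", k = 4, min_size = 3)
  expect_identical(ps$score, 12L)
  expect_true(ps$min_size_met)
  ## k = 1: modal class count of the whole sample
  expect_identical(traitPurityScore(h, tr, "VT", k = 1, min_size = 3)$score,
                   6L)
  ## brute-force recount oracle on random trees with 2 balanced classes
  for (r in 1:50) {
    n <- 12
    x <- matrix(rnorm(n * 3), n, dimnames = list(paste0("v", 1:n), NULL))
    tr2 <- toyTraits(paste0("v", 1:n), vt = sample(rep(c("L", "C"), n / 2)),
                     gh = sample(rep(c("W", "S"), n / 2)))
    h2 <- agglomerativeTree(euclideanDistances(x), "average")
    ps2 <- traitPurityScore(h2, tr2, "VT", k = 2, min_size = 2)
    ct <- cutTreeClusters(h2, ps2$cut_k)
    sz <- sort(table(ct), decreasing = TRUE)
    lab <- setNames(tr2$VT, tr2$cultivar_id)
    manual <- sum(vapply(names(sz)[1:2], function(cl)
      max(table(lab[names(ct)[ct == cl]])), 0L))
    expect_identical(ps2$score, manual)
  }
  expect_error(traitPurityScore(h, tr, "VTGH", k = 5, min_size = 3),
               "cannot obtain")
})

test_that("linkage selection ranks all eight methods by purity then parsimony", {
  sim <- generateKaryograms()
  ty <- deriveChromosomeTypes(dropExcludedChromosomes(sim$experiment))
  d <- euclideanDistances(ty$indicator)
  sel <- selectLinkageMethod(d, traitTable(sim$experiment), ty$indicator)
  expect_setequal(sel$linkage, linkageMethods())
  expect_true(all(diff(sel$purity_total) <= 0))
  ties <- split(seq_len(8), sel$purity_total)
  for (ix in ties)
    if (length(ix) > 1) expect_true(all(diff(sel$parsimony[ix]) >= 0))
  ## the selected linkage recovers the planted structure
  tree <- attr(sel, "trees")[[sel$linkage[1]]]
  st <- setNames(sim$truth$labels$structure, sim$truth$labels$cultivar_id)
  expect_gte(adjustedRandIndex(cutTreeClusters(tree, 3), st), 0.8)
})

test_that("K-means on standardized distance profiles recovers planted blobs", {
  hits <- 0
  for (s in 1:20) {
    b <- threeBlobs(s)
    d <- euclideanDistances(b$points)
    km <- kmeansPartition(d, 3, seed = s)
    if (adjustedRandIndex(km$assignment,
                          setNames(b$truth, rownames(b$points))) >= 0.9)
      hits <- hits + 1
  }
  expect_gte(hits, 18)
  ## k = 1: single cluster, WCSS equals the total scaled dispersion
  b <- threeBlobs(1)
  d <- euclideanDistances(b$points)
  km1 <- kmeansPartition(d, 1, seed = 1)
  expect_identical(unname(km1$assignment), rep(1L, 60))
  x <- standardizedDistanceFeatures(d)
  expect_equal(km1$wcss, sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)
  expect_error(kmeansPartition(d, 100, seed = 1), "exceeds")
})

test_that("K-means is deterministic given the seed", {
  b <- threeBlobs(4)
  d <- euclideanDistances(b$points)
  expect_identical(kmeansPartition(d, 3, seed = 7)$assignment,
                   kmeansPartition(d, 3, seed = 7)$assignment)
})

test_that("cluster-center coordinates average the within-cluster distances", {
  m <- matrix(c(0, 1, 4,
                1, 0, 2,
                4, 2, 0), 3, dimnames = list(c("a", "b", "c"),
                                             c("a", "b", "c")))
  assign <- c(a = 1L, b = 1L, c = 2L)
  cc <- clusterCenterCoordinates(as.dist(m), assign)
  ## hand computation: cluster1 = {a,b}, cluster2 = {c}
  expect_equal(unname(cc["a", ]), c((0 + 1) / 2, 4))
  expect_equal(unname(cc["b", ]), c((1 + 0) / 2, 2))
  expect_equal(unname(cc["c", ]), c((4 + 2) / 2, 0))
  ## singleton's own coordinate is 0; rows bounded by min/max of d(i, .)
  expect_equal(cc["c", "cluster2"], 0)
  dm <- as.matrix(m)
  for (i in rownames(dm))
    expect_true(all(cc[i, ] >= min(dm[i, ]) & cc[i, ] <= max(dm[i, ])))
})
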
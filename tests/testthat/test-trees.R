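test_that("Fitch length is exact on trivial trees and invariant to reordering", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  X <- matrix(c(0L, 1L), 2, dimnames = list(c("A", "B"), NULL))
  expect_identical(fitchParsimonyScore(t2, X)$length, 1L)
  expect_identical(fitchParsimonyScore(
    t2, matrix(1L, 2, 4, dimnames = list(c("A", "B"), NULL)))$length, 0L)
  set.seed(40)
  phy <- randomRootedTree(9)
  X <- matrix(rbinom(9 * 12, 1, .5), 9,
              dimnames = list(phy$tip.label, NULL))
  s0 <- fitchParsimonyScore(phy, X)$length
  expect_identical(fitchParsimonyScore(phy, X[sample(9), ])$length, s0)
  expect_identical(fitchParsimonyScore(phy, X[, sample(12)])$length, s0)
  ## rotated topology (same clusters) scores identically
  phy2 <- ape::rotate(phy, length(phy$tip.label) + 1L)
  expect_identical(fitchParsimonyScore(phy2, X)$length, s0)
})

test_that("Fitch agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("phangorn")
  set.seed(41)
  for (r in 1:20) {
    n <- sample(6:12, 1)
    phy <- randomRootedTree(n)
    X <- matrix(rbinom(n * 15, 1, .5), n,
                dimnames = list(phy$tip.label, NULL))
    pd <- phangorn::phyDat(X, type = "USER", levels = c(0, 1))
    expect_identical(fitchParsimonyScore(phy, X)$length,
                     as.integer(phangorn::parsimony(phy, pd,
                                                    method = "fitch")))
  }
})

test_that("RF distance obeys identity, mirror-invariance and the metric axioms", {
  set.seed(42)
  phy <- randomRootedTree(8)
  expect_identical(rfDistance(phy, phy), 0L)
  mirror <- karyoclass:::.asNested(phy)
  flipAll <- function(nd) if (is.list(nd)) lapply(rev(nd), flipAll) else nd
  ## rebuild a phylo from the mirrored nesting via its Newick string
  nwk <- function(nd) if (is.list(nd))
    paste0("(", paste(vapply(nd, nwk, ""), collapse = ","), ")") else nd
  mirrored <- ape::read.tree(text = paste0(nwk(flipAll(mirror)), ";"))
  expect_identical(rfDistance(phy, mirrored), 0L)
  for (r in 1:25) {
    a <- randomRootedTree(8); b <- randomRootedTree(8)
    cc <- randomRootedTree(8)
    expect_identical(rfDistance(a, b), rfDistance(b, a))
    expect_lte(rfDistance(a, cc), rfDistance(a, b) + rfDistance(b, cc))
  }
  expect_error(rfDistance(randomRootedTree(5),
                          randomRootedTree(5, labels = letters[1:5])),
               "leaf set")
})

test_that("RF distance equals the enumerated cluster-set symmetric difference", {
  set.seed(43)
  for (r in 1:100) {
    a <- randomRootedTree(8); b <- randomRootedTree(8)
    ka <- apeCladeKeys(a); kb <- apeCladeKeys(b)
    oracle <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
    expect_identical(rfDistance(a, b), oracle)
  }
})

test_that("bootstrap support is deterministic and certain for fully supported splits", {
  set.seed(44)
  f <- cbind(matrix(rep(c(0L, 1L), c(5, 5)), 10, 50),
             matrix(rbinom(10 * 10, 1, .5), 10))
  rownames(f) <- paste0("v", 1:10)
  b1 <- bootstrapCladeSupport(f, "average", B = 200, seed = 3)
  b2 <- bootstrapCladeSupport(f, "average", B = 200, seed = 3)
  expect_identical(b1$support, b2$support)
  grp <- sort(paste0("v", 1:5))
  sup_grp <- b1$support$support[vapply(b1$support$members,
                                       function(m) setequal(m, grp) ||
                                         setequal(m, paste0("v", 6:10)),
                                       TRUE)]
  expect_true(all(sup_grp >= 99))
  ## root clade is always recovered
  expect_true(any(b1$support$size == 10 & b1$support$support == 100))
  expect_error(bootstrapCladeSupport(f, "average", B = 0), "B must be")
  expect_error(bootstrapCladeSupport(f[, 1, drop = FALSE], "average"),
               ">= 2 features")
})

test_that("single-feature bootstrap yields only 0 or 100 percent support", {
  set.seed(45)
  f <- cbind(a = rbinom(8, 1, .5), b = rbinom(8, 1, .5))
  rownames(f) <- paste0("v", 1:8)
  b <- bootstrapCladeSupport(f, "average", B = 50, seed = 1)
  ## with 2 columns the resample space is tiny; supports are coarse
  expect_true(all(b$support$support >= 0 & b$support$support <= 100))
})

test_that("Mk2 pruning likelihood on a 3-leaf star equals the closed form", {
  star <- ape::read.tree(text = "(A:0.3,B:0.5,C:0.2);")
  X <- matrix(c(1L, 0L, 1L), 3, dimnames = list(c("A", "B", "C"), NULL))
  el <- star$edge.length
  a <- 0.5 + 0.5 * exp(-2 * el)   # P(same) per edge, edge order A,B,C
  ## closed form: sum over the root state
  lik <- 0.5 * ((1 - a[1]) * a[2] * (1 - a[3])) +
    0.5 * (a[1] * (1 - a[2]) * a[3])
  expect_equal(karyoclass:::.mk2LogLik(star, X, el), log(lik),
               tolerance = 1e-12)
})

test_that("branch-length optimization improves the likelihood monotonically", {
  set.seed(46)
  phy <- ape::read.tree(text = "((A:0.2,B:0.4):0.3,(C:0.1,D:0.5):0.2);")
  X <- matrix(rbinom(4 * 10, 1, .5), 4,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  fit <- mlBranchLengths(phy, X)
  expect_false(is.unsorted(fit$trace))
  expect_gte(fit$logLik, fit$logLik_initial - 1e-12)
  ## constant characters drive all lengths to the lower bound
  Xc <- matrix(1L, 4, 6, dimnames = list(c("A", "B", "C", "D"), NULL))
  fc <- mlBranchLengths(phy, Xc)
  expect_true(all(fc$tree$edge.length <= 1e-8 + 1e-12))
  expect_error(
    mlBranchLengths(ape::read.tree(text = "(A:1,B:1,C:1,D:1);"), X),
    "binary")
})

test_that("entanglement matches the direct rank-difference formula", {
  o <- letters[1:10]
  expect_identical(entanglement(o, o), 0)
  expect_equal(entanglement(o, rev(o)), 1)
  set.seed(47)
  for (r in 1:50) {
    p <- sample(o)
    r2 <- match(o, p)
    L <- 1.5
    oracle <- sum(abs(seq_along(o) - r2)^L) /
      sum(abs(seq_along(o) - rev(seq_along(o)))^L)
    expect_equal(entanglement(o, p), oracle, tolerance = 1e-12)
  }
  expect_error(entanglement(letters[1:4], letters[2:5]), "differ")
})

test_that("untangling never increases entanglement and is seed-reproducible", {
  set.seed(48)
  for (r in 1:50) {
    x1 <- matrix(rnorm(8 * 3), 8, dimnames = list(letters[1:8], NULL))
    x2 <- matrix(rnorm(8 * 3), 8, dimnames = list(letters[1:8], NULL))
    h1 <- agglomerativeTree(euclideanDistances(x1), "average")
    h2 <- agglomerativeTree(euclideanDistances(x2), "average")
    u <- untanglePair(h1, h2, seed = r)
    expect_lte(u$entanglement, u$entanglement_initial + 1e-12)
  }
  h1 <- agglomerativeTree(euclideanDistances(
    matrix(rnorm(24), 8, dimnames = list(letters[1:8], NULL))), "average")
  u1 <- untanglePair(h1, h1, seed = 9)
  u2 <- untanglePair(h1, h1, seed = 9)
  expect_identical(u1, u2)
  ## identical topologies untangle to zero entanglement
  expect_equal(u1$entanglement, 0)
  expect_identical(u1$rf, 0L)
})

test_that("distance-matrix correlation matches the naive formula and scaling law", {
  set.seed(49)
  x <- matrix(rnorm(10 * 3), 10, dimnames = list(paste0("v", 1:10), NULL))
  d1 <- euclideanDistances(x)
  d2 <- as.dist(2 * as.matrix(d1))
  expect_equal(distanceMatrixCorrelation(d1, d2), 1)
  y <- matrix(rnorm(10 * 3), 10, dimnames = list(paste0("v", 1:10), NULL))
  d3 <- euclideanDistances(y)
  m1 <- as.matrix(d1); m3 <- as.matrix(d3)
  oracle <- cor(m1[lower.tri(m1)], m3[lower.tri(m3)])
  expect_equal(distanceMatrixCorrelation(d1, d3), oracle, tolerance = 1e-12)
  ## independent matrices at n = 87 decorrelate on average
  rs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    a <- matrix(rnorm(87 * 5), 87, dimnames = list(paste0("v", 1:87), NULL))
    b <- matrix(rnorm(87 * 5), 87, dimnames = list(paste0("v", 1:87), NULL))
    distanceMatrixCorrelation(euclideanDistances(a), euclideanDistances(b))
  }, 0)
  expect_lt(mean(abs(rs)), 0.1)
  dz <- as.dist(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_warning(r0 <- distanceMatrixCorrelation(dz, dz), "zero variance")
  expect_true(is.na(r0))
})
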
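.toyExperiment <- function(m) {
  CbandExperiment(m, traits = toyTraits(
    rownames(m),
    vt = rep(c("L", "C"), length.out = nrow(m)),
    gh = rep(c("W", "S"), length.out = nrow(m))))
}

test_that("chromosome exclusion removes exactly the excluded chromosomes", {
  sim <- generateKaryograms()
  x <- sim$experiment
  expect_identical(length(unique(bandCatalog(x)$chromosome)), 21L)
  x2 <- dropExcludedChromosomes(x)
  expect_identical(length(unique(bandCatalog(x2)$chromosome)), 19L)
  expect_false(any(c("4D", "5D") %in% bandCatalog(x2)$chromosome))
  expect_identical(colnames(x2), colnames(x))
  expect_identical(bandSizes(dropExcludedChromosomes(x, character(0))),
                   bandSizes(x))
  expect_error(dropExcludedChromosomes(x, wheatChromosomes()),
               "excluding all")
  expect_error(dropExcludedChromosomes(x, "9Z"), "unknown chromosome")
})

test_that("presence binarization thresholds at size > 0 and is idempotent", {
  m <- matrix(c(0L, 1L, 5L, 2L, 0L, 3L), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("1A.S.1", "1A.S.2", "1A.L.1")))
  p <- binarizePresence(m)
  expect_identical(as.vector(p), c(0L, 1L, 1L, 0L, 1L, 1L))
  expect_identical(binarizePresence(p), p)
  set.seed(3)
  mm <- matrix(sample(0:5, 60, TRUE), 10)
  expect_identical(as.integer(colSums(binarizePresence(mm))),
                   as.integer(apply(mm, 2, function(c0) sum(c0 != 0))))
})

test_that("constant-band filtering keeps exactly the varying columns", {
  m <- matrix(c(3L, 3L, 3L,
                0L, 1L, 2L,
                5L, 5L, 5L,
                2L, 0L, 2L), 3,
              dimnames = list(c("a", "b", "c"),
                              c("1A.S.1", "1A.S.2", "2B.S.1", "2B.L.1")))
  x <- .toyExperiment(m)
  x2 <- dropConstantBands(x)
  expect_identical(colnames(bandSizes(x2)), c("1A.S.2", "2B.L.1"))
  expect_identical(bandSizes(dropConstantBands(x2)), bandSizes(x2))
  allconst <- .toyExperiment(matrix(2L, 3, 2,
    dimnames = list(c("a", "b", "c"), c("1A.S.1", "1A.S.2"))))
  expect_error(dropConstantBands(allconst), "no diagnostic features")
})

test_that("generator-configured diagnostic band count is recovered by the filter", {
  sim <- generateKaryograms()   # 147 positions, 49 constant -> 98 varying
  x <- dropConstantBands(dropExcludedChromosomes(sim$experiment))
  expect_identical(nrow(x), 98L)
  planted <- setdiff(sim$truth$varying_bands,
                     rownames(sim$experiment)[bandCatalog(sim$experiment)$chromosome
                                              %in% c("4D", "5D")])
  expect_setequal(rownames(x), planted)
})

test_that("chromosome types match hand enumeration and a set-construction oracle", {
  ## hand case: patterns {1010, 1010, 1110} on 2B -> two types (1,1,0)/(0,0,1)
  m <- matrix(c(1L, 0L, 2L, 0L,
                3L, 0L, 1L, 0L,
                1L, 4L, 2L, 0L), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"),
                              c("2B.S.1", "2B.S.2", "2B.S.3", "2B.L.1")))
  ty <- deriveChromosomeTypes(.toyExperiment(m))
  expect_identical(colnames(ty$indicator), c("2B.t1", "2B.t2"))
  expect_identical(unname(ty$indicator[, "2B.t1"]), c(1L, 1L, 0L))
  expect_identical(unname(ty$indicator[, "2B.t2"]), c(0L, 0L, 1L))
  expect_identical(ty$catalog[["2B"]][["2B.t1"]]$pattern, c(1L, 0L, 1L, 0L))

  ## brute-force uniqueness oracle over random matrices
  set.seed(21)
  for (r in 1:100) {
    n <- sample(3:10, 1)
    chroms <- sample(wheatChromosomes(), sample(1:4, 1))
    toks <- unlist(lapply(chroms, function(ch)
      sprintf("%s.S.%d", ch, 1:sample(2:4, 1))))
    mm <- matrix(sample(0:3, n * length(toks), TRUE), n,
                 dimnames = list(paste0("v", 1:n), toks))
    tt <- deriveChromosomeTypes(.toyExperiment(mm))
    for (ch in chroms) {
      sub <- (mm[, grepl(paste0("^", ch), colnames(mm)), drop = FALSE] > 0)
      n_unique <- length(unique(apply(sub, 1, paste, collapse = "")))
      n_types <- sum(grepl(paste0("^", ch, "\\.t"), colnames(tt$indicator)))
      expect_identical(n_types, n_unique)
    }
    ## partition property: one-hot per chromosome
    for (ch in chroms) {
      cols <- grepl(paste0("^", ch, "\\.t"), colnames(tt$indicator))
      expect_true(all(rowSums(tt$indicator[, cols, drop = FALSE]) == 1L))
    }
  }
})

test_that("types are invariant under size changes that preserve presence", {
  sim <- generateKaryograms()
  x <- dropExcludedChromosomes(sim$experiment)
  ty1 <- deriveChromosomeTypes(x)
  m <- bandSizes(x)
  set.seed(8)
  m2 <- m
  pos <- m2 > 0
  m2[pos] <- sample(1:5, sum(pos), replace = TRUE)
  ty2 <- deriveChromosomeTypes(CbandExperiment(m2, traitTable(x)))
  expect_identical(ty1$indicator, ty2$indicator)
})

test_that("associated-type groups are the maximal duplicated-column classes", {
  ind <- cbind(a1 = c(1, 0, 1, 0), a2 = c(1, 0, 1, 0),
               b1 = c(0, 1, 0, 1), b2 = c(0, 1, 0, 1), b3 = c(0, 1, 0, 1),
               c1 = c(1, 1, 0, 0), c2 = c(1, 1, 0, 0),
               c3 = c(1, 1, 0, 0), c4 = c(1, 1, 0, 0),
               d1 = c(1, 1, 1, 0))
  rownames(ind) <- paste0("v", 1:4)
  g <- findAssociatedTypeGroups(ind)
  expect_identical(vapply(g, `[[`, 0L, "size"), c(4L, 3L, 2L))
  expect_identical(g[[1]]$types, paste0("c", 1:4))
  expect_identical(g[[2]]$types, paste0("b", 1:3))
  expect_identical(g[[3]]$types, paste0("a", 1:2))
  expect_identical(g[[1]]$members, c("v1", "v2"))
  ## all-distinct columns -> nothing
  expect_length(findAssociatedTypeGroups(
    cbind(x = c(1, 0, 0), y = c(0, 1, 0), z = c(1, 1, 0))), 0L)
})

test_that("planted associated-type groups are recovered from generated data", {
  sim <- generateKaryograms()
  ty <- deriveChromosomeTypes(dropExcludedChromosomes(sim$experiment))
  found <- findAssociatedTypeGroups(ty$indicator)
  for (pg in sim$truth$assoc_groups) {
    hit <- Filter(function(g) setequal(g$members, pg$members) &&
                    all(vapply(pg$chromosomes, function(ch)
                      any(grepl(paste0("^", ch, "\\."), g$types)), TRUE)),
                  found)
    expect_gte(length(hit), 1L)
    expect_gte(hit[[1]]$size, pg$size)
  }
})
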
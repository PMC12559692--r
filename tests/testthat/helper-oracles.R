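# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, naive formulas, or a
# different library's machinery.

# hypergeometric tail sum for overrepresentation: background N, carriers K,
# target n, observed overlap k; P(X >= k) by direct binomial-coefficient sums
hypergeomTailOracle <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# minimum number of state changes on a rooted tree by exhaustive enumeration
# of all internal-node labelings (binary characters)
bruteForceFitch <- function(phy, X) {
  ntip <- length(phy$tip.label)
  m <- phy$Nnode
  E <- phy$edge
  X <- X[phy$tip.label, , drop = FALSE]
  lab <- as.matrix(expand.grid(rep(list(0:1), m)))
  total <- 0L
  for (ch in seq_len(ncol(X))) {
    best <- Inf
    for (l in seq_len(nrow(lab))) {
      s <- c(X[, ch], lab[l, ])
      best <- min(best, sum(abs(s[E[, 1]] - s[E[, 2]])))
    }
    total <- total + best
  }
  total
}

# naive Lance-Williams agglomeration reproducing stats::hclust's conventions:
# every method applies the update formula to the dissimilarities as given,
# except ward.D2, which squares the input and reports square-rooted heights
lanceWilliamsOracle <- function(d, method) {
  D <- as.matrix(d)
  n <- nrow(D)
  sq <- method == "ward.D2"
  if (sq) D <- D^2
  diag(D) <- Inf
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    i <- idx[min(w)]; j <- idx[max(w)]
    dij <- D[i, j]
    heights[step] <- if (sq) sqrt(dij) else dij
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      nk <- size[k]
      dik <- D[i, k]; djk <- D[j, k]
      D[i, k] <- D[k, i] <- switch(
        method,
        single   = min(dik, djk),
        complete = max(dik, djk),
        average  = (ni * dik + nj * djk) / (ni + nj),
        mcquitty = (dik + djk) / 2,
        ward.D   = ,
        ward.D2  = ((ni + nk) * dik + (nj + nk) * djk - nk * dij) /
          (ni + nj + nk),
        centroid = (ni * dik + nj * djk) / (ni + nj) -
          ni * nj * dij / (ni + nj)^2,
        median   = dik / 2 + djk / 2 - dij / 4)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
  }
  heights
}

# same exhaustive minimum, vectorized over all internal labelings so whole
# topology sets can be screened: returns the total for each matrix in Xlist
bruteForceFitchMany <- function(phy, Xlist) {
  ntip <- length(phy$tip.label)
  m <- phy$Nnode
  E <- phy$edge
  L <- as.matrix(expand.grid(rep(list(0:1), m)))   # labelings x internals
  tipE <- E[, 2] <= ntip
  # internal-edge mismatches depend only on the labeling
  ic <- rowSums(abs(L[, E[!tipE, 1] - ntip, drop = FALSE] -
                      L[, E[!tipE, 2] - ntip, drop = FALSE]))
  Lp <- L[, E[tipE, 1] - ntip, drop = FALSE]        # parent states, tip edges
  tipIdx <- E[tipE, 2]
  vapply(Xlist, function(X) {
    Xe <- X[phy$tip.label, , drop = FALSE][tipIdx, , drop = FALSE]
    cost <- ic + Lp %*% (1 - Xe) + (1 - Lp) %*% Xe  # labelings x chars
    sum(apply(cost, 2L, min))
  }, 0)
}

# random rooted binary tree with unit-interval edge lengths
randomRootedTree <- function(n, labels = paste0("t", seq_len(n))) {
  phy <- ape::rtree(n, tip.label = labels)
  phy
}

# clade leaf sets of a rooted tree via ape's own machinery (prop.part),
# as canonical sorted key strings; nontrivial clusters only
apeCladeKeys <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) paste(sort(labs[ix]), collapse = "\r"), "")
  sizes <- lengths(pp)
  unique(keys[sizes < length(labs)])
}

# three well-separated planted 2-D blobs (20 points each)
threeBlobs <- function(seed, sep = 8, sd = 0.5, per = 20L) {
  set.seed(seed)
  pts <- rbind(
    matrix(stats::rnorm(per * 2, 0, sd), ncol = 2),
    matrix(stats::rnorm(per * 2, sep, sd), ncol = 2),
    sweep(matrix(stats::rnorm(per * 2, 0, sd), ncol = 2), 2, c(0, sep), `+`))
  rownames(pts) <- paste0("p", seq_len(3 * per))
  list(points = pts, truth = rep(1:3, each = per))
}

# small trait table covering all four VTGH classes
toyTraits <- function(ids, vt, gh) {
  data.frame(cultivar_id = ids, VT = vt, GH = gh,
             VTGH = paste0(vt, gh), stringsAsFactors = FALSE)
}
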
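## ---- internal tree helpers -------------------------------------------------

## Leaf sets below every node of a rooted phylo; returns list indexed by node.
.descTips <- function(phy) {
  ntip <- length(phy$tip.label)
  po <- stats::reorder(phy, "postorder")$edge
  desc <- vector("list", ntip + phy$Nnode)
  desc[seq_len(ntip)] <- as.list(phy$tip.label)
  for (i in seq_len(nrow(po)))
    desc[[po[i, 1L]]] <- c(desc[[po[i, 1L]]], desc[[po[i, 2L]]])
  desc
}

## Canonical keys of the nontrivial clusters (clades) of a rooted tree:
## leaf sets of size >= 2 excluding the full leaf set.
.cladeKeys <- function(phy, keep_root = FALSE) {
  ntip <- length(phy$tip.label)
  desc <- .descTips(phy)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  keys <- vapply(desc[nodes],
                 function(s) paste(sort(s), collapse = "\r"), "")
  sizes <- lengths(desc[nodes])
  if (!keep_root) keys <- keys[sizes < ntip]
  unique(keys)
}

## ---- Fitch parsimony -------------------------------------------------------

#' Fitch parsimony length of a dendrogram topology
#'
#' The smallest number of character-state changes explaining the topology,
#' computed per character by the bottom-up Fitch state-set pass (bitmask
#' intersection/union) and summed. Used, together with trait purity, to
#' choose among linkage methods.
#'
#' @param tree `hclust` or rooted `phylo`.
#' @param chars integer matrix of discrete character states (rows named by
#'   the tree leaves; typically the binary chromosome-type indicator or
#'   band-presence matrix). No missing data.
#' @return list: `length` (total parsimony length), `per_character`
#'   (integer vector of changes per character).
#' @export
fitchParsimonyScore <- function(tree, chars) {
  phy <- asPhylo(tree)
  chars <- as.matrix(chars)
  if (is.null(rownames(chars)) || !all(phy$tip.label %in% rownames(chars)))
    stop("character matrix must cover all tree leaves (named rows)")
  X <- chars[phy$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("missing character states at leaves")
  if (!all(X == round(X)) || any(X < 0) || any(X > 30))
    stop("character states must be integers in 0..30")
  ntip <- length(phy$tip.label)
  nch <- ncol(X)
  masks <- matrix(0L, ntip + phy$Nnode, nch)
  masks[seq_len(ntip), ] <- bitwShiftL(1L, X)
  changes <- integer(nch)
  seen <- logical(ntip + phy$Nnode)
  po <- stats::reorder(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]; ch <- po[i, 2L]
    if (!seen[p]) {
      masks[p, ] <- masks[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(masks[p, ], masks[ch, ])
      disjoint <- inter == 0L
      changes <- changes + disjoint
      masks[p, ] <- ifelse(disjoint, bitwOr(masks[p, ], masks[ch, ]), inter)
    }
  }
  names(changes) <- colnames(X)
  list(length = sum(changes), per_character = changes)
}

## ---- bootstrap clade support ----------------------------------------------

#' Bootstrap support for the clades of a feature-based dendrogram
#'
#' Felsenstein-style support for the monophyly of each clade: feature
#' columns (characters) are resampled with replacement `B` times, the tree
#' is rebuilt (Euclidean distance + the given linkage) from each replicate,
#' and a clade's support is the percentage of replicate trees containing
#' the identical leaf set as a cluster.
#'
#' @param features numeric cultivar x feature matrix.
#' @param linkage one of [linkageMethods()].
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed; results are bit-exact given the seed.
#' @return list: `tree` (the original `hclust`), `support` (`data.frame`
#'   with `size`, `support` in percent and list-column `members`, one row
#'   per internal clade of the original tree, root included at 100).
#' @export
bootstrapCladeSupport <- function(features, linkage = "ward.D2",
                                  B = 1000L, seed = 1L) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) stop("need >= 2 features to resample")
  if (B < 1L) stop("B must be >= 1")
  tree <- agglomerativeTree(euclideanDistances(features), linkage)
  phy <- asPhylo(tree)
  keys <- .cladeKeys(phy, keep_root = TRUE)
  hits <- stats::setNames(integer(length(keys)), keys)
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(features), replace = TRUE)
    tb <- agglomerativeTree(euclideanDistances(features[, cols, drop = FALSE]),
                            linkage)
    kb <- .cladeKeys(asPhylo(tb), keep_root = TRUE)
    m <- keys %in% kb
    hits[m] <- hits[m] + 1L
  }
  members <- strsplit(keys, "\r", fixed = TRUE)
  sup <- data.frame(size = lengths(members),
                    support = 100 * hits / B)
  sup$members <- members
  sup <- sup[order(-sup$size, -sup$support), ]
  rownames(sup) <- NULL
  list(tree = tree, support = sup)
}

## ---- Mk2 branch lengths ----------------------------------------------------

## Log-likelihood of binary characters on a rooted binary topology under the
## two-state symmetric Markov model, by Felsenstein pruning.
## X: tips x chars in {0,1}; el: edge lengths in phy$edge order.
.mk2LogLik <- function(phy, X, el) {
  ntip <- length(phy$tip.label)
  nch <- ncol(X)
  po <- stats::reorder(phy, "postorder")
  L0 <- matrix(NA_real_, ntip + phy$Nnode, nch)
  L1 <- L0
  L0[seq_len(ntip), ] <- 1 - X
  L1[seq_len(ntip), ] <- X
  eo <- match(paste(po$edge[, 1], po$edge[, 2]),
              paste(phy$edge[, 1], phy$edge[, 2]))
  seen <- logical(ntip + phy$Nnode)
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    a <- 0.5 + 0.5 * exp(-2 * el[eo[i]])
    c0 <- a * L0[ch, ] + (1 - a) * L1[ch, ]
    c1 <- (1 - a) * L0[ch, ] + a * L1[ch, ]
    if (!seen[p]) {
      L0[p, ] <- c0; L1[p, ] <- c1; seen[p] <- TRUE
    } else {
      L0[p, ] <- L0[p, ] * c0; L1[p, ] <- L1[p, ] * c1
    }
  }
  root <- ntip + 1L
  sum(log(0.5 * L0[root, ] + 0.5 * L1[root, ]))
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes the edge lengths of a fixed rooted binary dendrogram topology
#' under the two-state symmetric Markov model (Mk2, stationary 1/2-1/2,
#' diagonal transition probability `1/2 + 1/2 exp(-2t)`) by bounded
#' quasi-Newton (L-BFGS-B), starting from the dendrogram's parent-child
#' height differences. Edge lengths are bounded below at `eps`.
#'
#' @param topology `hclust` or rooted binary `phylo`.
#' @param chars binary character matrix, rows named by leaves.
#' @param eps lower bound on edge lengths (default 1e-8).
#' @param maxit optimizer iteration cap.
#' @return list: `tree` (`phylo` with optimized lengths), `logLik`,
#'   `logLik_initial`, `trace` (best log-likelihood after each evaluation,
#'   non-decreasing), `convergence` (0 = converged).
#' @export
mlBranchLengths <- function(topology, chars, eps = 1e-8, maxit = 200L) {
  if (inherits(topology, "phylo") && !ape::is.binary(topology))
    stop("topology must be binary")
  phy <- asPhylo(topology)
  if (!ape::is.binary(phy)) stop("topology must be binary")
  chars <- as.matrix(chars)
  X <- chars[phy$tip.label, , drop = FALSE]
  if (anyNA(X) || !all(X %in% c(0, 1))) stop("characters must be binary, no NA")
  el0 <- phy$edge.length
  if (is.null(el0)) el0 <- rep(0.1, nrow(phy$edge))
  el0 <- pmax(el0, eps)
  trace <- numeric(0)
  best <- -Inf
  fn <- function(el) {
    ll <- .mk2LogLik(phy, X, el)
    if (ll > best) best <<- ll
    trace <<- c(trace, best)
    -ll
  }
  ll0 <- .mk2LogLik(phy, X, el0)
  ## the edge-length surface can be multimodal for small character sets;
  ## a second moderate-length start guards against the local basin around
  ## degenerate initial heights
  starts <- list(el0, rep(0.5, length(el0)))
  opt <- NULL
  for (s in starts) {
    o <- stats::optim(s, fn, method = "L-BFGS-B",
                      lower = eps, upper = 100,
                      control = list(maxit = maxit))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  if (opt$convergence != 0)
    warning("branch-length optimization did not converge; best iterate kept")
  phy$edge.length <- opt$par
  list(tree = phy, logLik = -opt$value, logLik_initial = ll0,
       trace = trace, convergence = opt$convergence)
}

## ---- tree comparison -------------------------------------------------------

#' Robinson-Foulds symmetric difference between two dendrograms
#'
#' Size of the symmetric difference of the two trees' nontrivial cluster
#' sets. The default follows the rooted-cluster convention natural for
#' dendrograms; `rooted = FALSE` compares unrooted bipartitions instead.
#'
#' @param t1,t2 `hclust` or rooted `phylo` over the same leaves.
#' @param rooted compare rooted clusters (default) or unrooted bipartitions.
#' @return integer distance; 0 iff the topologies agree.
#' @export
rfDistance <- function(t1, t2, rooted = TRUE) {
  p1 <- asPhylo(t1); p2 <- asPhylo(t2)
  if (!setequal(p1$tip.label, p2$tip.label))
    stop("trees must share an identical leaf set")
  k1 <- .cladeKeys(p1); k2 <- .cladeKeys(p2)
  if (!rooted) {
    ref <- sort(p1$tip.label)[1L]
    all_tips <- sort(p1$tip.label)
    canon <- function(keys) {
      unique(vapply(strsplit(keys, "\r", fixed = TRUE), function(s) {
        if (ref %in% s) s <- setdiff(all_tips, s)
        if (length(s) < 2L) NA_character_
        else paste(sort(s), collapse = "\r")
      }, ""))
    }
    k1 <- canon(k1); k1 <- k1[!is.na(k1)]
    k2 <- canon(k2); k2 <- k2[!is.na(k2)]
  }
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Pearson correlation between two distance matrices
#'
#' Correlation over the strictly-lower-triangle entries after aligning the
#' two matrices on their shared cultivar ordering.
#'
#' @param d1,d2 `dist` or symmetric matrices over the same cultivars.
#' @return Pearson r (NA with a warning when a triangle has zero variance).
#' @export
distanceMatrixCorrelation <- function(d1, d2) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("distance matrices must cover the same cultivars")
  m2 <- m2[rownames(m1), rownames(m1)]
  v1 <- m1[lower.tri(m1)]; v2 <- m2[lower.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in a distance matrix; correlation undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

## ---- entanglement and untangling -------------------------------------------

.leafOrder <- function(tree) {
  if (is.character(tree)) return(tree)
  if (inherits(tree, "hclust")) return(tree$labels[tree$order])
  if (inherits(tree, "phylo")) {
    po <- stats::reorder(tree, "cladewise")
    return(po$tip.label[po$edge[po$edge[, 2] <= length(po$tip.label), 2]])
  }
  if (is.list(tree)) return(unlist(tree, use.names = FALSE))  # nested form
  stop("cannot extract a leaf order")
}

#' Entanglement of a tanglegram
#'
#' The L-norm (default L = 1.5) of the rank-position differences of matched
#' leaves in the two orderings, normalized by the fully reversed ordering,
#' so 0 means perfectly aligned and 1 means worst-case crossing.
#'
#' @param t1,t2 trees (`hclust`/`phylo`) or explicit leaf-order character
#'   vectors over the same leaves.
#' @param L norm exponent (default 1.5).
#' @return entanglement in `[0, 1]`.
#' @export
entanglement <- function(t1, t2, L = 1.5) {
  o1 <- .leafOrder(t1); o2 <- .leafOrder(t2)
  if (!setequal(o1, o2)) stop("leaf sets differ")
  n <- length(o1)
  if (n < 2L) return(0)
  r2 <- match(o1, o2)
  worst <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  sum(abs(seq_len(n) - r2)^L) / worst
}

## Nested-list form of a rooted binary tree: a leaf is its label, an
## internal node a 2-element list. Rotation = swapping the two children.
.asNested <- function(tree) {
  phy <- asPhylo(tree)
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  build <- function(node) {
    if (node <= ntip) return(phy$tip.label[node])
    lapply(kids[[as.character(node)]], build)
  }
  build(ntip + 1L)
}

.flipAt <- function(nested, target) {
  cnt <- 0L
  rec <- function(nd) {
    if (!is.list(nd)) return(nd)
    cnt <<- cnt + 1L
    if (cnt == target) nd <- rev(nd)
    lapply(nd, rec)
  }
  rec(nested)
}

.nInternal <- function(nested) {
  if (!is.list(nested)) return(0L)
  1L + sum(vapply(nested, .nInternal, 0L))
}

.randomFlip <- function(nested) {
  rec <- function(nd) {
    if (!is.list(nd)) return(nd)
    if (stats::runif(1) < 0.5) nd <- rev(nd)
    lapply(nd, rec)
  }
  rec(nested)
}

#' Untangle a pair of dendrograms
#'
#' Searches node rotations of both trees to minimize the tanglegram
#' entanglement: several rounds of random rotations keeping the best state,
#' followed by a deterministic two-sided stepwise pass (each internal node
#' of each tree flipped in turn, keeping improvements, iterated to a fixed
#' point). The result never has higher entanglement than the input.
#'
#' @param t1,t2 `hclust` or rooted `phylo` over the same leaves.
#' @param rounds_random random search rounds (default 3).
#' @param tries_per_round random candidates per round.
#' @param seed RNG seed (bit-reproducible).
#' @param L entanglement norm exponent.
#' @return list: `order1`, `order2` (untangled leaf orders),
#'   `entanglement`, `entanglement_initial`, `rf` (Robinson-Foulds
#'   distance between the two topologies).
#' @export
untanglePair <- function(t1, t2, rounds_random = 3L, tries_per_round = 10L,
                         seed = 1L, L = 1.5) {
  n1 <- .asNested(t1); n2 <- .asNested(t2)
  if (!setequal(.leafOrder(n1), .leafOrder(n2))) stop("leaf sets differ")
  e0 <- entanglement(.leafOrder(n1), .leafOrder(n2), L)
  best <- list(n1 = n1, n2 = n2, e = e0)
  set.seed(seed)
  for (r in seq_len(rounds_random)) {
    for (t in seq_len(tries_per_round)) {
      c1 <- .randomFlip(best$n1); c2 <- .randomFlip(best$n2)
      e <- entanglement(.leafOrder(c1), .leafOrder(c2), L)
      if (e < best$e) best <- list(n1 = c1, n2 = c2, e = e)
    }
  }
  repeat {
    improved <- FALSE
    for (side in 1:2) {
      nd <- if (side == 1) best$n1 else best$n2
      for (i in seq_len(.nInternal(nd))) {
        cand <- .flipAt(nd, i)
        other <- if (side == 1) best$n2 else best$n1
        e <- entanglement(.leafOrder(cand), .leafOrder(other), L)
        if (e < best$e - 1e-15) {
          nd <- cand
          best$e <- e
          improved <- TRUE
        }
      }
      if (side == 1) best$n1 <- nd else best$n2 <- nd
    }
    if (!improved) break
  }
  list(order1 = .leafOrder(best$n1), order2 = .leafOrder(best$n2),
       entanglement = best$e, entanglement_initial = e0,
       rf = rfDistance(t1, t2))
}
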
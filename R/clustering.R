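#' The eight agglomerative linkage schemes
#'
#' The Lance-Williams linkages considered when choosing the clustering
#' method, in the naming of [stats::hclust]. `ward.D` and `ward.D2` follow
#' the Murtagh-Legendre distinction (Ward criterion on raw vs squared
#' dissimilarities).
#'
#' @return character vector of the eight method names.
#' @export
linkageMethods <- function() {
  c("single", "complete", "average", "mcquitty",
    "ward.D", "ward.D2", "centroid", "median")
}

#' Euclidean distances between cultivars
#'
#' @param features numeric cultivar x feature matrix (binary indicator or
#'   0-5 band sizes).
#' @return a `dist` object with cultivar labels.
#' @export
euclideanDistances <- function(features) {
  m <- as.matrix(features)
  if (anyNA(m)) stop("missing values in feature matrix")
  stats::dist(m, method = "euclidean")
}

#' Agglomerative clustering with a named linkage
#'
#' Thin wrapper over [stats::hclust] restricted to the eight supported
#' linkages; rejects non-finite dissimilarities.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param linkage one of [linkageMethods()].
#' @return an `hclust` dendrogram.
#' @export
agglomerativeTree <- function(d, linkage = "ward.D2") {
  linkage <- match.arg(linkage, linkageMethods())
  d <- stats::as.dist(d)
  if (any(!is.finite(d))) stop("non-finite distance")
  stats::hclust(d, method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' Cuts at the height yielding exactly `k` clusters and relabels clusters
#' 1..k by first appearance in the dendrogram leaf order.
#'
#' @param tree an `hclust`.
#' @param k number of clusters, 1..n.
#' @return named integer vector of cluster labels.
#' @export
cutTreeClusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must be in 1..n")
  ct <- stats::cutree(tree, k = k)
  first <- unique(ct[tree$order])
  stats::setNames(match(ct, first), names(ct))
}

#' Trait purity of a dendrogram cut
#'
#' The empirical criterion for linkage choice: cut the dendrogram into `k`
#' clusters of at least `min_size` cultivars (over-cutting stepwise and
#' keeping the `k` largest clusters when needed), count the modal
#' trait-class frequency within each evaluated cluster, and sum. Larger
#' scores mean better separation by the trait.
#'
#' @param tree `hclust` over the cultivars.
#' @param traits trait table.
#' @param trait trait column to score (`"VT"`, `"GH"` or `"VTGH"`).
#' @param k number of clusters evaluated (default 4, the number of VTGH
#'   classes).
#' @param min_size minimum cluster volume (default 3).
#' @return list: `method` (linkage, if recorded on the tree), `trait`, `k`,
#'   `cut_k` (clusters actually cut), `per_cluster` (modal counts), `score`.
#' @export
traitPurityScore <- function(tree, traits, trait = "VTGH", k = 4L,
                             min_size = 3L) {
  stopifnot(inherits(tree, "hclust"))
  lab <- stats::setNames(as.character(traits[[trait]]), traits$cultivar_id)
  if (anyNA(lab[tree$labels])) stop("tree leaves missing from trait table")
  n <- length(tree$labels)
  if (n < k * min_size)
    stop(sprintf("cannot obtain %d clusters of >= %d cultivars", k, min_size))
  score_at <- function(kk, ct) {
    sz <- sort(table(ct), decreasing = TRUE)
    eval_cl <- names(sz)[seq_len(min(k, length(sz)))]
    modal <- vapply(eval_cl, function(cl)
      max(table(lab[names(ct)[ct == cl]])), 0L)
    list(method = tree$method, trait = trait, k = k, cut_k = kk,
         per_cluster = modal, score = sum(modal))
  }
  for (kk in k:n) {
    ct <- cutTreeClusters(tree, kk)
    sz <- sort(table(ct), decreasing = TRUE)
    if (length(sz) >= k && all(sz[seq_len(k)] >= min_size)) {
      res <- score_at(kk, ct)
      res$min_size_met <- TRUE
      return(res)
    }
  }
  ## a chaining topology may never yield k simultaneous clusters of
  ## min_size; fall back to the k largest clusters of the plain k-cut
  res <- score_at(k, cutTreeClusters(tree, k))
  res$min_size_met <- FALSE
  res
}

#' Rank linkage methods by trait purity and parsimony
#'
#' For each of the eight linkages, the dendrogram is scored by (i) the
#' summed trait-purity over the tested traits (VT, GH, VTGH) and (ii) the
#' Fitch parsimony length of its topology on the binary feature matrix;
#' methods are ranked by purity (higher better), ties broken by parsimony
#' (lower better).
#'
#' @param d `dist` over cultivars.
#' @param traits trait table.
#' @param features binary cultivar x feature matrix used as parsimony
#'   characters.
#' @param traitsToScore trait columns summed into the purity criterion.
#' @param k,min_size passed to [traitPurityScore()].
#' @return `data.frame` ranked best-first: `linkage`, purity per trait,
#'   `purity_total`, `parsimony`; attribute `"trees"` holds the eight
#'   `hclust` objects.
#' @export
selectLinkageMethod <- function(d, traits, features,
                                traitsToScore = c("VT", "GH", "VTGH"),
                                k = 4L, min_size = 3L) {
  methods <- linkageMethods()
  trees <- lapply(methods, function(m) agglomerativeTree(d, m))
  names(trees) <- methods
  rows <- lapply(methods, function(m) {
    pur <- vapply(traitsToScore, function(tr)
      traitPurityScore(trees[[m]], traits, tr, k, min_size)$score, 0L)
    pars <- fitchParsimonyScore(trees[[m]], features)$length
    c(purity_total = sum(pur), parsimony = pars, pur)
  })
  tab <- data.frame(linkage = methods, do.call(rbind, rows))
  tab <- tab[order(-tab$purity_total, tab$parsimony, tab$linkage), ]
  rownames(tab) <- NULL
  attr(tab, "trees") <- trees
  tab
}

#' Standardize a distance matrix into K-means feature space
#'
#' Each column of the full symmetric distance matrix is centered and scaled
#' to unit variance; the rows (one distance profile per cultivar) are the
#' feature vectors for K-means and the gap statistic.
#' @param d `dist` or symmetric matrix.
#' @return numeric matrix, cultivars x cultivars.
#' @export
standardizedDistanceFeatures <- function(d) {
  m <- as.matrix(d)
  s <- scale(m)
  s[, attr(s, "scaled:scale") == 0] <- 0   # degenerate constant columns
  out <- matrix(as.numeric(s), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

#' K-means partition on the standardized distance matrix
#'
#' Lloyd's algorithm with 25 random restarts on the row profiles of the
#' column-standardized distance matrix; deterministic given `seed`.
#'
#' @param d `dist` over cultivars.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart random restarts (default 25).
#' @return list: `assignment` (named cluster labels 1..k), `wcss` (total
#'   within-cluster sum of squares), `kmeans` (the [stats::kmeans] fit).
#' @export
kmeansPartition <- function(d, k, seed = 1L, nstart = 25L) {
  x <- standardizedDistanceFeatures(d)
  if (k > nrow(x)) stop("k exceeds number of cultivars")
  set.seed(seed)
  ## Lloyd restarts occasionally empty a cluster; those starts are still
  ## scored and the best non-degenerate solution kept, so the warning is
  ## uninformative here
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = nstart,
                  algorithm = "Lloyd", iter.max = 100L))
  list(assignment = stats::setNames(km$cluster, rownames(x)),
       wcss = km$tot.withinss, kmeans = km)
}

#' Gap-statistic choice of the number of clusters
#'
#' Tibshirani's gap statistic on the standardized distance-matrix features,
#' with the 1-SE rule: the chosen k is the smallest k with
#' `Gap(k) >= Gap(k+1) - SE(k+1)`. The reference distribution defaults to
#' the PCA-rotated uniform box (`"scaledPCA"`): distance-profile features
#' are strongly anisotropic (they live near a low-dimensional manifold), and
#' the axis-aligned uniform box over the feature ranges is then so diffuse
#' that the gap curve keeps rising past the true k; the rotated reference
#' accounts for the data shape. The simple range-uniform reference remains
#' available via `reference = "original"`.
#'
#' @param d `dist` over cultivars.
#' @param kmax largest k examined.
#' @param B reference datasets (default 100).
#' @param seed RNG seed.
#' @param reference reference-box convention, `"scaledPCA"` (default) or
#'   `"original"` (see [cluster::clusGap]).
#' @return list: `k` (chosen), `gap` (per-k gap values), `se` (their
#'   standard errors), `table` (the [cluster::clusGap] Tab matrix).
#' @export
gapStatisticK <- function(d, kmax = 8L, B = 100L, seed = 1L,
                          reference = c("scaledPCA", "original")) {
  reference <- match.arg(reference)
  x <- standardizedDistanceFeatures(d)
  if (all(abs(x) < 1e-12)) {
    return(list(k = 1L, gap = NA_real_, se = NA_real_, table = NULL))
  }
  stopifnot(kmax < nrow(x), B >= 10L)
  set.seed(seed)
  cg <- cluster::clusGap(
    x,
    FUNcluster = function(xx, kk)
      suppressWarnings(stats::kmeans(xx, kk, nstart = 25L,
                                     algorithm = "Lloyd",
                                     iter.max = 100L)),
    K.max = kmax, B = B, spaceH0 = reference, verbose = FALSE)
  tab <- cg$Tab
  k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                      method = "Tibs2001SEmax")
  list(k = as.integer(k), gap = tab[, "gap"], se = tab[, "SE.sim"],
       table = tab)
}

#' Cluster-center coordinates of each cultivar
#'
#' For every cultivar and cluster, the mean distance between the cultivar
#' and the members of that cluster (including itself when it belongs to
#' the cluster). Standardized columns of this matrix are the input to the
#' factor analysis of the qualitative pipeline.
#'
#' @param d `dist` over cultivars.
#' @param assignment named cluster labels covering all cultivars.
#' @return numeric cultivar x cluster matrix.
#' @export
clusterCenterCoordinates <- function(d, assignment) {
  m <- as.matrix(d)
  ids <- rownames(m)
  if (!all(ids %in% names(assignment)))
    stop("assignment does not cover all cultivars")
  cl <- assignment[ids]
  lev <- sort(unique(cl))
  out <- sapply(lev, function(c0) {
    mem <- ids[cl == c0]
    if (!length(mem)) stop("empty cluster")
    rowMeans(m[, mem, drop = FALSE])
  })
  colnames(out) <- paste0("cluster", lev)
  out
}
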
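## eta^2 / cos^2 statistics of supplementary qualitative trait variables
## against ordination scores. Axes are never influenced by the traits.
.supplementaryStats <- function(scores, traits,
                                vars = c("VT", "GH", "VTGH")) {
  ids <- rownames(scores)
  n <- nrow(scores)
  i <- match(ids, traits$cultivar_id)
  if (anyNA(i)) stop("cultivars missing from trait table")
  vars <- intersect(vars, colnames(traits))
  vrows <- list(); crows <- list()
  pnorm2 <- function(r) 2 * stats::pnorm(-abs(r) * sqrt(n - 1))
  for (v in vars) {
    g <- factor(traits[[v]][i])
    for (k in seq_len(ncol(scores))) {
      y <- scores[, k]
      tot <- sum((y - mean(y))^2)
      bet <- sum(tapply(y, g, function(z) length(z) * (mean(z) - mean(y))^2))
      eta2 <- if (tot > 0) bet / tot else 0
      r <- sqrt(eta2)
      vrows[[length(vrows) + 1L]] <-
        data.frame(variable = v, dim = k, eta2 = eta2, r = r, p = pnorm2(r))
      for (lev in levels(g)) {
        ind <- as.numeric(g == lev)
        rc <- if (stats::sd(ind) > 0 && stats::sd(y) > 0)
          stats::cor(ind, y) else 0
        crows[[length(crows) + 1L]] <-
          data.frame(variable = v, category = lev, dim = k,
                     cos2 = rc^2, r = rc, p = pnorm2(rc))
      }
    }
  }
  list(variables = do.call(rbind, vrows),
       categories = do.call(rbind, crows))
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Eigendecomposition of the double-centered Gram matrix; coordinates are
#' eigenvectors scaled by the square root of the (positive) eigenvalues,
#' and explained fractions come from the positive eigenvalue mass.
#'
#' @param d `dist` or symmetric distance matrix.
#' @param ndim dimensions requested; truncated with a warning when fewer
#'   positive eigenvalues exist.
#' @return list: `coordinates` (cultivar x dim), `explained` (fractions),
#'   `eig` (all eigenvalues), `method = "MDS"`.
#' @export
classicalMDS <- function(d, ndim = 2L) {
  m <- as.matrix(d)
  stopifnot(ndim >= 1L, ndim < nrow(m))
  ## full-rank decomposition; ndim truncation is handled below, so the
  ## eigenvalue-count warning from cmdscale is redundant
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = nrow(m) - 1L, eig = TRUE))
  pos <- fit$eig > max(fit$eig) * 1e-12
  npos <- sum(pos)
  if (ndim > npos) {
    warning(sprintf("only %d positive eigenvalues; ndim truncated", npos))
    ndim <- npos
  }
  coords <- fit$points[, seq_len(ndim), drop = FALSE]
  colnames(coords) <- paste0("Dim", seq_len(ndim))
  list(coordinates = coords,
       explained = fit$eig[seq_len(ndim)] / sum(fit$eig[pos]),
       eig = fit$eig, method = "MDS")
}

#' PCA with supplementary qualitative trait variables
#'
#' Column-standardized (optionally) principal component analysis via SVD;
#' the trait variables never influence the axes and are characterized
#' afterwards by the correlation ratio (per variable: `r = sqrt(eta^2)` of
#' the scores grouped by the trait) and by category correlations
#' (`cos^2` = squared correlation of the 0/1 category indicator with the
#' scores, reported signed by the category centroid). Asymptotic p-values
#' use the normal approximation `p = 2 pnorm(-r sqrt(n-1))`.
#'
#' @param features numeric cultivar x variable matrix.
#' @param traits trait table.
#' @param standardize center and scale columns (default TRUE); constant
#'   columns are dropped with a warning.
#' @param ndim dimensions retained (default 5).
#' @return list: `ordination` (coordinates, explained, method = "PCA") and
#'   `supplementary` (`variables`, `categories` data frames).
#' @export
pcaSupplementary <- function(features, traits, standardize = TRUE,
                             ndim = 5L) {
  m <- as.matrix(features)
  v <- apply(m, 2L, stats::sd)
  if (standardize && any(v == 0)) {
    warning(sum(v == 0), " constant column(s) dropped")
    m <- m[, v > 0, drop = FALSE]
  }
  if (ncol(m) < 2L) stop("need >= 2 varying columns")
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  ndim <- min(ndim, ncol(pc$x))
  scores <- pc$x[, seq_len(ndim), drop = FALSE]
  colnames(scores) <- paste0("Dim", seq_len(ndim))
  rownames(scores) <- rownames(m)
  ord <- list(coordinates = scores,
              explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ndim)],
              method = "PCA")
  list(ordination = ord,
       supplementary = .supplementaryStats(scores, traits))
}

#' Multiple correspondence analysis with supplementary traits
#'
#' Indicator-matrix MCA of binary features: each feature contributes a
#' present and an absent level to the complete disjunctive table, which is
#' analyzed by the chi-square-weighted SVD of correspondence analysis.
#' Trait categories are projected afterwards through the transition
#' formula, without influencing the axes.
#'
#' @param binary 0/1 cultivar x feature matrix (e.g. chromosome-type
#'   indicator or band-presence matrix). Features with a single observed
#'   level are dropped with a warning.
#' @param traits trait table.
#' @param ndim dimensions retained (default 5).
#' @return list: `ordination` (row coordinates, explained inertia
#'   fractions, method = "MCA"), `supplementary` (`variables`,
#'   `categories` with projected `coord` per dimension),
#'   `category_coords` (active level coordinates).
#' @export
mcaSupplementary <- function(binary, traits, ndim = 5L) {
  X <- as.matrix(binary)
  stopifnot(all(X %in% c(0, 1)))
  lev1 <- apply(X, 2L, function(c0) length(unique(c0)) == 1L)
  if (any(lev1)) {
    warning(sum(lev1), " single-level feature(s) dropped")
    X <- X[, !lev1, drop = FALSE]
  }
  if (ncol(X) < 2L) stop("need >= 2 two-level features")
  Z <- matrix(0, nrow(X), 2L * ncol(X))
  Z[, seq(1L, ncol(Z), 2L)] <- X
  Z[, seq(2L, ncol(Z), 2L)] <- 1 - X
  colnames(Z) <- as.vector(rbind(paste0(colnames(X), ":present"),
                                 paste0(colnames(X), ":absent")))
  rownames(Z) <- rownames(X)
  G <- Z / sum(Z)
  r <- rowSums(G); cm <- colSums(G)
  S <- (G - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  keep <- sv$d > sv$d[1L] * 1e-10
  dvals <- sv$d[keep]
  ndim <- min(ndim, length(dvals))
  F <- sweep(sv$u[, keep, drop = FALSE], 2L, dvals, `*`) / sqrt(r)
  Gc <- sweep(sv$v[, keep, drop = FALSE], 2L, dvals, `*`) / sqrt(cm)
  rownames(F) <- rownames(X); rownames(Gc) <- colnames(Z)
  F <- F[, seq_len(ndim), drop = FALSE]
  Gc <- Gc[, seq_len(ndim), drop = FALSE]
  colnames(F) <- colnames(Gc) <- paste0("Dim", seq_len(ndim))
  ord <- list(coordinates = F,
              explained = (dvals^2 / sum(dvals^2))[seq_len(ndim)],
              method = "MCA")
  sup <- .supplementaryStats(F, traits)
  ## project supplementary trait categories via the CA transition formula
  ids <- rownames(X)
  i <- match(ids, traits$cultivar_id)
  proj <- list()
  for (v in intersect(c("VT", "GH", "VTGH"), colnames(traits))) {
    for (lev in unique(traits[[v]][i])) {
      z <- as.numeric(traits[[v]][i] == lev)
      h <- z / sum(z)
      co <- colSums(h * F[, seq_len(ndim), drop = FALSE]) /
        dvals[seq_len(ndim)]
      proj[[paste0(v, ":", lev)]] <- co
    }
  }
  sup$category_proj <- do.call(rbind, proj)
  list(ordination = ord, supplementary = sup, category_coords = Gc)
}

#' Project a supplementary binary column into an MCA solution
#'
#' Transition-formula projection used internally for trait categories;
#' exposed for testing that a supplementary column identical to an active
#' level lands on the same coordinates.
#'
#' @param mca result of [mcaSupplementary()].
#' @param z 0/1 vector over the MCA's cultivars.
#' @return numeric coordinate vector over the retained dimensions.
#' @export
projectSupplementaryColumn <- function(mca, z) {
  F <- mca$ordination$coordinates
  expl <- mca$ordination$explained
  ## recover singular values from inertia fractions is not robust; recompute
  ## from the principal coordinates: d_k = sd-weighted norm. Instead, store:
  d <- attr(mca$ordination, "sv")
  if (is.null(d)) {
    ## fall back: d_k = sqrt(sum(r * F_k^2)) with uniform row masses
    r <- rep(1 / nrow(F), nrow(F))
    d <- sqrt(colSums(r * F^2))
  }
  h <- z / sum(z)
  colSums(h * F) / d
}

#' Compactness of cultivar groups in an ordination plane
#'
#' The CB statistic: for each group, the mean Euclidean distance of its
#' members to the group centroid in the analyzed plane. Smaller values
#' mean a more homogeneous (compact) group.
#'
#' @param coords numeric cultivar x dimension matrix (the plane under
#'   study, typically two columns of an ordination).
#' @param groups named group labels covering the cultivars.
#' @return named numeric vector of CB values per group.
#' @export
clusterCompactness <- function(coords, groups) {
  coords <- as.matrix(coords)
  ids <- rownames(coords)
  g <- groups[ids]
  if (anyNA(g)) stop("groups must cover all cultivars in coords")
  vapply(split(ids, g), function(mem) {
    if (!length(mem)) stop("empty group")
    sub <- coords[mem, , drop = FALSE]
    ctr <- colMeans(sub)
    mean(sqrt(rowSums(sweep(sub, 2L, ctr)^2)))
  }, 0)
}
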
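#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected agreement between two partitions of the
#' same items; 1 = identical partitions, ~0 = chance agreement.
#'
#' @param a,b label vectors of equal length (aligned by position, or by
#'   names when both are named).
#' @return numeric ARI.
#' @export
adjustedRandIndex <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  sn <- comb2(sum(tab))
  exp_ <- si * sj / sn
  mx <- (si + sj) / 2
  if (mx == exp_) return(1)
  (sij - exp_) / (mx - exp_)
}

#' Pipeline configuration
#'
#' @param excluded chromosomes removed before analysis.
#' @param linkage `"auto"` (purity + parsimony selection) or a method name.
#' @param k `"auto"` (gap statistic) or an integer cluster count.
#' @param kmax,gapB gap-statistic search bound and reference count.
#' @param bootstrapB bootstrap replicates for clade support.
#' @param fitBranchLengths also fit Mk2 maximum-likelihood branch lengths
#'   on the selected topology (slower; default FALSE).
#' @param mlMaxit optimizer cap for the branch-length fit.
#' @param seed RNG seed recorded in every report.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(excluded = c("4D", "5D"), linkage = "auto",
                           k = "auto", kmax = 8L, gapB = 100L,
                           bootstrapB = 1000L, fitBranchLengths = FALSE,
                           mlMaxit = 100L, seed = 1L) {
  structure(list(excluded = excluded, linkage = linkage, k = k,
                 kmax = kmax, gapB = gapB, bootstrapB = bootstrapB,
                 fitBranchLengths = fitBranchLengths, mlMaxit = mlMaxit,
                 seed = seed),
            class = "pipelineConfig")
}

## VTGH purity of the selected tree for the summary; NA when the sample is
## too small for the 4-cluster / min-size-3 evaluation
.purityOrNA <- function(tree, traits) {
  tryCatch(traitPurityScore(tree, traits, "VTGH")$score,
           error = function(e) NA_integer_)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

.selectTree <- function(d, traits, parsimony_chars, cfg) {
  if (identical(cfg$linkage, "auto")) {
    sel <- selectLinkageMethod(d, traits, parsimony_chars)
    linkage <- sel$linkage[1L]
    list(selection = sel, linkage = linkage,
         tree = attr(sel, "trees")[[linkage]])
  } else {
    list(selection = NULL, linkage = cfg$linkage,
         tree = agglomerativeTree(d, cfg$linkage))
  }
}

.chooseK <- function(d, cfg) {
  if (identical(cfg$k, "auto")) {
    gap <- gapStatisticK(d, kmax = cfg$kmax, B = cfg$gapB, seed = cfg$seed)
    list(k = gap$k, gap = gap)
  } else list(k = as.integer(cfg$k), gap = NULL)
}

#' Qualitative classification pipeline (chromosome types)
#'
#' End-to-end analysis of a karyogram population on the qualitative
#' coding: chromosome exclusion, chromosome-type derivation,
#' associated-type groups, Fisher overrepresentation across all trait
#' subsample schemes, Euclidean distances on the type indicator matrix,
#' linkage selection by purity + parsimony, bootstrap clade support,
#' gap-statistic K-means, tree cutting with cluster-center coordinates and
#' their PCA, principal-coordinate visualization, MCA with supplementary
#' traits, and group compactness on the MCA plane.
#'
#' @param x a [CbandExperiment-class] with traits attached.
#' @param cfg a [pipelineConfig()].
#' @return report bundle (list); `$summary` holds the headline numbers
#'   (counts, selected linkage, chosen k, purity, support quartiles) plus
#'   the seed and configuration.
#' @export
runQualitativePipeline <- function(x, cfg = pipelineConfig()) {
  traits <- traitTable(x)
  x2 <- .stage("drop_excluded", dropExcludedChromosomes(x, cfg$excluded))
  ty <- .stage("derive_types", deriveChromosomeTypes(x2))
  assoc <- .stage("associated_groups",
                  findAssociatedTypeGroups(ty$indicator))
  fisher <- .stage("fisher_association",
                   fisherAssociationTable(ty$indicator, traits))
  info <- summarizeInformativeFeatures(fisher)
  d <- .stage("distances", euclideanDistances(ty$indicator))
  selt <- .stage("linkage_selection",
                 .selectTree(d, traits, ty$indicator, cfg))
  boot <- .stage("bootstrap", bootstrapCladeSupport(
    ty$indicator, selt$linkage, B = cfg$bootstrapB, seed = cfg$seed))
  kk <- .stage("gap_statistic", .chooseK(d, cfg))
  km <- .stage("kmeans", kmeansPartition(d, kk$k, seed = cfg$seed))
  cut <- .stage("cut_tree", cutTreeClusters(selt$tree, kk$k))
  centers <- .stage("cluster_centers", clusterCenterCoordinates(d, cut))
  centerPCA <- if (kk$k >= 2L)
    .stage("center_pca", pcaSupplementary(centers, traits,
                                          ndim = min(5L, kk$k))) else NULL
  mds <- .stage("mds", classicalMDS(d, 2L))
  mca <- .stage("mca", mcaSupplementary(ty$indicator, traits))
  cb <- .stage("compactness", clusterCompactness(
    mca$ordination$coordinates[, 1:2],
    stats::setNames(traits$VTGH, traits$cultivar_id)))
  ml <- if (isTRUE(cfg$fitBranchLengths))
    .stage("ml_branch_lengths",
           mlBranchLengths(selt$tree, ty$indicator,
                           maxit = cfg$mlMaxit)) else NULL
  purity <- .purityOrNA(selt$tree, traits)
  summary <- list(
    scheme = "qualitative", seed = cfg$seed,
    n_cultivars = ncol(x), n_types = ncol(ty$indicator),
    n_associated_groups = length(assoc),
    fraction_noninformative = info$fraction_noninformative,
    selected_linkage = selt$linkage,
    purity_vtgh = purity,
    chosen_k = kk$k,
    cluster_sizes = as.integer(table(cut)),
    support_q3 = unname(stats::quantile(boot$support$support, 0.75)),
    compactness = as.list(cb),
    logLik = if (!is.null(ml)) c(initial = ml$logLik_initial,
                                 optimized = ml$logLik) else NULL)
  list(scheme = "qualitative", config = cfg, traits = traits,
       types = ty, associated_groups = assoc, association = fisher,
       informative = info, distance = d, selection = selt$selection,
       linkage = selt$linkage, tree = selt$tree, bootstrap = boot,
       gap = kk$gap, kmeans = km, assignment = cut, centers = centers,
       center_pca = centerPCA, mds = mds, mca = mca, compactness = cb,
       ml = ml, features = ty$indicator, summary = summary)
}

#' Quantitative classification pipeline (C-band sizes)
#'
#' End-to-end analysis on the 0-5 band-size coding: chromosome exclusion,
#' constant-band removal, per-unit-size quasi-binomial odds (oddFC) across
#' all trait subsample schemes, Euclidean distances on the size matrix,
#' linkage selection, bootstrap support, gap-statistic K-means, tree
#' cutting, PCA with supplementary traits, and group compactness on the
#' first PCA plane.
#'
#' @inheritParams runQualitativePipeline
#' @return report bundle (list) with the same structure as the qualitative
#'   pipeline, plus `association` holding the oddFC records.
#' @export
runQuantitativePipeline <- function(x, cfg = pipelineConfig()) {
  traits <- traitTable(x)
  x2 <- .stage("drop_excluded", dropExcludedChromosomes(x, cfg$excluded))
  x2 <- .stage("drop_constant", dropConstantBands(x2))
  sizes <- bandSizes(x2)
  if (all(sizes %in% c(0L, 1L)))
    warning("band sizes are already binary; quantitative distances reduce ",
            "to the qualitative presence distances")
  assoc <- .stage("logistic_association",
                  logisticAssociationTable(sizes, traits))
  info <- summarizeInformativeFeatures(assoc)
  d <- .stage("distances", euclideanDistances(sizes))
  selt <- .stage("linkage_selection",
                 .selectTree(d, traits, binarizePresence(sizes), cfg))
  boot <- .stage("bootstrap", bootstrapCladeSupport(
    sizes, selt$linkage, B = cfg$bootstrapB, seed = cfg$seed))
  kk <- .stage("gap_statistic", .chooseK(d, cfg))
  km <- .stage("kmeans", kmeansPartition(d, kk$k, seed = cfg$seed))
  cut <- .stage("cut_tree", cutTreeClusters(selt$tree, kk$k))
  pca <- .stage("pca", pcaSupplementary(sizes, traits, standardize = TRUE))
  mds <- .stage("mds", classicalMDS(d, 2L))
  cb <- .stage("compactness", clusterCompactness(
    pca$ordination$coordinates[, 1:2],
    stats::setNames(traits$VTGH, traits$cultivar_id)))
  purity <- .purityOrNA(selt$tree, traits)
  summary <- list(
    scheme = "quantitative", seed = cfg$seed,
    n_cultivars = ncol(x), n_diagnostic_bands = ncol(sizes),
    n_significant_vt = sum(assoc$significant[assoc$scheme == "total:VT" &
                                               assoc$target == "L"] |
                             assoc$significant[assoc$scheme == "total:VT" &
                                                 assoc$target == "C"]),
    fraction_noninformative = info$fraction_noninformative,
    selected_linkage = selt$linkage,
    purity_vtgh = purity,
    chosen_k = kk$k,
    cluster_sizes = as.integer(table(cut)),
    support_q3 = unname(stats::quantile(boot$support$support, 0.75)),
    compactness = as.list(cb))
  list(scheme = "quantitative", config = cfg, traits = traits,
       association = assoc, informative = info, distance = d,
       selection = selt$selection, linkage = selt$linkage,
       tree = selt$tree, bootstrap = boot, gap = kk$gap, kmeans = km,
       assignment = cut, pca = pca, mds = mds, compactness = cb,
       features = sizes, summary = summary)
}

#' Compare a karyological classification with SNP genotyping
#'
#' Builds the SNP-based classification (marker filtering, Euclidean
#' distances, same linkage as the karyological bundle) on the shared
#' cultivars and reports the comparison surface: Pearson correlation of
#' the distance matrices, Robinson-Foulds distance, tanglegram
#' entanglement before and after untangling, bootstrap-support quartiles
#' of both trees, and per-tree trait purity.
#'
#' @param bundle a report bundle from [runQualitativePipeline()] or
#'   [runQuantitativePipeline()].
#' @param snp 0/1/NA cultivar x marker matrix; markers containing NA
#'   (ambiguous/heterozygous calls) are dropped.
#' @param cfg a [pipelineConfig()].
#' @param purity_k,purity_min_size purity-score cut for the (typically
#'   small) comparison sample.
#' @return comparison report (list) with `$summary`.
#' @export
runComparison <- function(bundle, snp, cfg = pipelineConfig(),
                          purity_k = 3L, purity_min_size = 3L) {
  snp <- as.matrix(snp)
  keep <- colSums(is.na(snp)) == 0L
  if (!all(keep)) snp <- snp[, keep, drop = FALSE]
  shared <- intersect(rownames(bundle$features), rownames(snp))
  if (length(shared) < 4L)
    stop("fewer than 4 shared cultivars between karyotype and SNP data")
  if (length(shared) < nrow(bundle$features) || length(shared) < nrow(snp))
    warning("restricting comparison to ", length(shared),
            " shared cultivars")
  traits <- bundle$traits[bundle$traits$cultivar_id %in% shared, ]
  kario_feat <- bundle$features[shared, , drop = FALSE]
  kario_feat <- kario_feat[, apply(kario_feat, 2L, stats::sd) > 0,
                           drop = FALSE]
  snp_feat <- snp[shared, , drop = FALSE]
  snp_feat <- snp_feat[, apply(snp_feat, 2L, stats::sd) > 0, drop = FALSE]
  dk <- euclideanDistances(kario_feat)
  ds <- euclideanDistances(snp_feat)
  tk <- agglomerativeTree(dk, bundle$linkage)
  ts <- agglomerativeTree(ds, bundle$linkage)
  r <- distanceMatrixCorrelation(dk, ds)
  ut <- untanglePair(tk, ts, seed = cfg$seed)
  bk <- bootstrapCladeSupport(kario_feat, bundle$linkage,
                              B = cfg$bootstrapB, seed = cfg$seed)
  bs <- bootstrapCladeSupport(snp_feat, bundle$linkage,
                              B = cfg$bootstrapB, seed = cfg$seed)
  pk <- traitPurityScore(tk, traits, "VTGH", k = purity_k,
                         min_size = purity_min_size)
  ps <- traitPurityScore(ts, traits, "VTGH", k = purity_k,
                         min_size = purity_min_size)
  mdsk <- classicalMDS(dk, 2L)
  mdss <- classicalMDS(ds, 2L)
  summary <- list(
    seed = cfg$seed, n_shared = length(shared),
    n_karyo_features = ncol(kario_feat), n_snp_features = ncol(snp_feat),
    distance_correlation = r,
    rf_distance = ut$rf,
    entanglement_initial = ut$entanglement_initial,
    entanglement_untangled = ut$entanglement,
    support_q3_karyo = unname(stats::quantile(bk$support$support, 0.75)),
    support_q3_snp = unname(stats::quantile(bs$support$support, 0.75)),
    purity_karyo = pk$score, purity_snp = ps$score)
  list(shared = shared, traits = traits, karyo_tree = tk, snp_tree = ts,
       karyo_distance = dk, snp_distance = ds, untangle = ut,
       karyo_bootstrap = bk, snp_bootstrap = bs, karyo_mds = mdsk,
       snp_mds = mdss, summary = summary)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the machine-readable artifacts of a bundle: the dendrogram as
#' Newick, the cluster assignment and association records as TSV, and the
#' summary (with seed and configuration) as JSON.
#'
#' @param bundle pipeline report bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNewick(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.table(
    data.frame(cultivar_id = names(bundle$assignment),
               cluster = bundle$assignment),
    file.path(dir, "assignment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$association, file.path(dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
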
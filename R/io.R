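#' Read a cultivar x band-size matrix from TSV
#'
#' The file has a header of band-position tokens (`CHROM.ARM.BAND`), a first
#' column of cultivar ids, and integer band sizes 0-5 in the body. Optional
#' leading lines starting with `#` are treated as provenance comments.
#'
#' @param path path to a tab-separated file.
#' @param traits optional trait `data.frame` (see [readTraitTable()]) joined
#'   into the returned object.
#' @return A [CbandExperiment-class].
#' @export
readBandMatrix <- function(path, traits = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("band matrix needs a cultivar column and >=1 band")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate cultivar id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(is.na(m) | m != round(m) | m < 0 | m > 5, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "band size outside 0..5 at cultivar '%s', band '%s' (value '%s')",
      ids[bad[1, 1]], colnames(m)[bad[1, 2]], m[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  tok <- colnames(m)
  bad <- !vapply(tok, .isBandToken, logical(1))
  if (any(bad))
    stop("malformed band-position token in header, column ",
         which(bad)[1] + 1L, ": '", tok[which(bad)[1]], "'")
  message(sprintf("read %d cultivars x %d band positions", nrow(m), ncol(m)))
  CbandExperiment(m, traits = traits)
}

#' Write a band-size matrix as TSV
#'
#' Inverse of [readBandMatrix()]; the output round-trips byte-identically.
#'
#' @param x a [CbandExperiment-class] or cultivar x band integer matrix.
#' @param path output path.
#' @param comments optional character vector of provenance lines written as
#'   leading `# ...` comments.
#' @return `path`, invisibly.
#' @export
writeBandMatrix <- function(x, path, comments = NULL) {
  m <- if (is(x, "CbandExperiment")) bandSizes(x) else as.matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c("cultivar_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read a cultivar trait table from TSV
#'
#' Expects columns `cultivar_id`, `VT` (breeding status, `L` landrace /
#' `C` modern) and `GH` (growth habit, `W` winter / `S` spring); synonymous
#' column names `breeding_status` and `growth_habit` are accepted. The
#' combined class `VTGH` is (re)derived as the concatenation of the two.
#'
#' @param path path to a tab-separated file.
#' @return `data.frame` with columns `cultivar_id`, `VT`, `GH`, `VTGH`.
#' @export
readTraitTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  nm <- names(df)
  nm[nm == "breeding_status"] <- "VT"
  nm[nm == "growth_habit"] <- "GH"
  names(df) <- nm
  if (!all(c("cultivar_id", "VT", "GH") %in% nm))
    stop("trait table needs columns cultivar_id, VT (breeding_status), GH (growth_habit)")
  bad <- which(!(df$VT %in% c("L", "C")))
  if (length(bad))
    stop("unknown breeding status '", df$VT[bad[1]], "' in row ", bad[1])
  bad <- which(!(df$GH %in% c("W", "S")))
  if (length(bad))
    stop("unknown growth habit '", df$GH[bad[1]], "' in row ", bad[1])
  if (anyDuplicated(df$cultivar_id))
    stop("duplicate cultivar id in trait table")
  df$VTGH <- paste0(df$VT, df$GH)
  tb <- table(df$VT)
  message(sprintf("read %d cultivars (%s)", nrow(df),
                  paste(names(tb), tb, sep = ":", collapse = ", ")))
  df[, c("cultivar_id", "VT", "GH", "VTGH")]
}

#' Write a trait table as TSV
#' @param traits trait `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dendrogram to a Newick file
#'
#' Accepts an `hclust` (converted via [ape::as.phylo], so branch lengths are
#' merge-height differences) or a rooted binary [ape::phylo]. Non-binary
#' trees and negative branch lengths are rejected: the clustering pipeline
#' only produces binary dendrograms.
#'
#' @param tree `hclust` or `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  if (inherits(tree, "phylo") && !ape::is.binary(tree))
    stop("tree must be binary")
  phy <- asPhylo(tree)
  if (!ape::is.binary(phy)) stop("tree must be binary")
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length")
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return an [ape::phylo] object.
#' @export
readNewick <- function(path) {
  stopifnot(file.exists(path))
  ape::read.tree(path)
}

#' Coerce a dendrogram to a rooted phylo
#'
#' Internal normalizer used by all tree-scoring functions: `hclust` objects
#' become rooted `phylo` trees with branch lengths equal to parent-child
#' merge-height differences; `phylo` objects are passed through (must be
#' rooted).
#'
#' @param tree `hclust` or `phylo`.
#' @return rooted [ape::phylo].
#' @export
asPhylo <- function(tree) {
  if (inherits(tree, "hclust")) {
    if (any(tree$height < 0)) stop("negative merge height")
    return(ape::as.phylo(tree))
  }
  if (inherits(tree, "phylo")) {
    if (!ape::is.rooted(tree)) stop("phylo tree must be rooted")
    return(tree)
  }
  stop("expected an 'hclust' or 'phylo' tree")
}
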
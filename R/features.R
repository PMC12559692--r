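#' Drop excluded chromosomes from a karyogram matrix
#'
#' C-banding cannot always resolve the polymorphic variants of some
#' chromosomes; by default 4D and 5D are removed before any analysis.
#'
#' @param x a [CbandExperiment-class].
#' @param excluded character vector of chromosome labels to drop
#'   (default `c("4D", "5D")`).
#' @return the filtered `CbandExperiment` (cultivars unchanged).
#' @export
dropExcludedChromosomes <- function(x, excluded = c("4D", "5D")) {
  stopifnot(is(x, "CbandExperiment"))
  bad <- setdiff(excluded, wheatChromosomes())
  if (length(bad)) stop("unknown chromosome label(s): ",
                        paste(bad, collapse = ", "))
  keep <- !(rowData(x)$chromosome %in% excluded)
  if (!any(keep)) stop("excluding all chromosomes leaves no bands")
  x[keep, ]
}

#' Binarize band sizes to presence/absence
#'
#' @param x a [CbandExperiment-class] or numeric matrix of sizes.
#' @return integer 0/1 matrix, cultivars x bands: 1 iff size > 0.
#' @export
binarizePresence <- function(x) {
  m <- if (is(x, "CbandExperiment")) bandSizes(x) else as.matrix(x)
  p <- (m > 0) + 0L
  dimnames(p) <- dimnames(m)
  p
}

#' Drop bands that do not vary across cultivars
#'
#' Constant bands (a single size value in every cultivar) carry no diagnostic
#' information and are excluded from the quantitative analysis; a
#' zero-variance column can never show a trait association.
#'
#' @param x a [CbandExperiment-class].
#' @return the filtered `CbandExperiment` of varying ("diagnostic") bands.
#' @export
dropConstantBands <- function(x) {
  stopifnot(is(x, "CbandExperiment"))
  a <- assay(x, "bandSize")
  varying <- apply(a, 1L, function(r) length(unique(r)) > 1L)
  if (!any(varying)) stop("all bands constant: no diagnostic features")
  x[varying, ]
}

#' Derive chromosome types from band presence patterns
#'
#' The qualitative coding of a karyogram: for each chromosome, the distinct
#' presence/absence patterns of its C-bands across cultivars define the
#' chromosome types; every cultivar carries exactly one type per chromosome.
#' Type ids are deterministic: `<chromosome>.t<ordinal>` in order of first
#' occurrence over the cultivar ordering.
#'
#' @param x a [CbandExperiment-class] (typically after
#'   [dropExcludedChromosomes()]).
#' @return list with elements
#'   \item{catalog}{per-chromosome list of types: `pattern` (0/1 vector over
#'     that chromosome's bands), `members` (cultivar ids)}
#'   \item{indicator}{binary cultivar x type matrix; within each chromosome
#'     the rows are one-hot}
#' @export
deriveChromosomeTypes <- function(x) {
  stopifnot(is(x, "CbandExperiment"), nrow(x) > 0L, ncol(x) > 0L)
  pres <- binarizePresence(x)            # cultivars x bands
  chrom <- bandCatalog(x)$chromosome
  cultivars <- rownames(pres)
  catalog <- list()
  cols <- list()
  for (ch in unique(chrom)) {
    sub <- pres[, chrom == ch, drop = FALSE]
    key <- apply(sub, 1L, paste, collapse = "")
    lev <- unique(key)                    # first-occurrence order
    types <- list()
    for (k in seq_along(lev)) {
      id <- sprintf("%s.t%d", ch, k)
      mem <- key == lev[k]
      types[[id]] <- list(
        pattern = as.integer(strsplit(lev[k], "")[[1L]]),
        members = cultivars[mem])
      cols[[id]] <- mem + 0L
    }
    catalog[[ch]] <- types
  }
  indicator <- do.call(cbind, cols)
  rownames(indicator) <- cultivars
  list(catalog = catalog, indicator = indicator)
}

#' Find groups of associated chromosome types
#'
#' Chromosome types carried by an identical set of cultivars behave as one
#' linked character; such maximal groups (size >= 2) of identical indicator
#' columns are reported, sorted by decreasing size then first type id.
#'
#' @param indicator binary cultivar x type matrix (from
#'   [deriveChromosomeTypes()]).
#' @return list of groups, each with `types` (type ids), `members`
#'   (cultivar ids) and `size` (number of types).
#' @export
findAssociatedTypeGroups <- function(indicator) {
  stopifnot(is.matrix(indicator), all(indicator %in% c(0, 1)))
  key <- apply(indicator, 2L, paste, collapse = "")
  grp <- split(colnames(indicator), key)
  grp <- grp[lengths(grp) >= 2L]
  out <- lapply(grp, function(ids) {
    list(types = ids,
         members = rownames(indicator)[indicator[, ids[1L]] == 1L],
         size = length(ids))
  })
  names(out) <- NULL
  if (!length(out)) return(out)
  ord <- order(-vapply(out, `[[`, 0L, "size"),
               vapply(out, function(g) g$types[1L], ""))
  out[ord]
}
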
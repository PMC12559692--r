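#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## The 21 chromosomes of hexaploid wheat (genomes A, B, D; homoeologous
## groups 1-7), in the conventional nomenclature order.
.WHEAT_CHROMOSOMES <- paste0(rep(1:7, times = 3), rep(c("A", "B", "D"), each = 7))

#' Valid wheat chromosome labels
#'
#' Returns the 21 chromosome labels of hexaploid common wheat (1A..7A,
#' 1B..7B, 1D..7D) used to validate band catalogs.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' wheatChromosomes()
wheatChromosomes <- function() .WHEAT_CHROMOSOMES

#' Container for C-banding karyograms of a varietal population
#'
#' `CbandExperiment` extends [SummarizedExperiment::SummarizedExperiment] to
#' hold one karyogram per cultivar, coded on the conventional 0-5 band-size
#' scale (0 = band absent, 1 = small ... 5 = very large). Rows are band
#' positions (the band catalog: chromosome, arm, position label), columns are
#' cultivars, and `colData` carries the tested traits: breeding status
#' `VT` (`"L"` landrace / `"C"` modern), growth habit `GH` (`"W"` winter /
#' `"S"` spring) and their combination `VTGH`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; the single assay
#'   is named `"bandSize"`.
#'
#' @seealso [CbandExperiment()] (constructor), [bandSizes()], [bandCatalog()],
#'   [traitTable()], [readBandMatrix()]
#' @export
setClass("CbandExperiment", contains = "SummarizedExperiment")

.validCbandExperiment <- function(object) {
  msg <- character()
  if (!("bandSize" %in% assayNames(object)))
    msg <- c(msg, "assay 'bandSize' is required")
  else {
    a <- assay(object, "bandSize")
    if (anyNA(a) || !all(a == round(a)) || any(a < 0) || any(a > 5))
      msg <- c(msg, "band sizes must be integers in 0..5 (0 = absent)")
  }
  rd <- rowData(object)
  need <- c("chromosome", "arm", "band")
  if (!all(need %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'chromosome', 'arm', 'band'")
  } else {
    if (!all(rd$chromosome %in% .WHEAT_CHROMOSOMES))
      msg <- c(msg, "chromosome labels must be among the 21 wheat chromosomes")
    if (!all(rd$arm %in% c("S", "L")))
      msg <- c(msg, "arm must be 'S' or 'L'")
    tok <- paste(rd$chromosome, rd$arm, rd$band, sep = ".")
    if (anyDuplicated(tok))
      msg <- c(msg, "duplicated band positions (chromosome, arm, band)")
  }
  cd <- colData(object)
  if (all(c("VT", "GH") %in% colnames(cd))) {
    if (!all(cd$VT %in% c("L", "C")))
      msg <- c(msg, "VT (breeding status) must be 'L' or 'C'")
    if (!all(cd$GH %in% c("W", "S")))
      msg <- c(msg, "GH (growth habit) must be 'W' or 'S'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated cultivar ids")
  if (length(msg)) msg else TRUE
}
setValidity("CbandExperiment", .validCbandExperiment)

#' Construct a CbandExperiment
#'
#' @param bandSizes integer matrix of band sizes in 0..5, either cultivars x
#'   bands (rows = cultivar ids, columns = band-position tokens
#'   `CHROM.ARM.BAND`, e.g. `"1B.S.3"`) or the transpose; orientation is
#'   detected from which dimnames parse as band tokens.
#' @param traits `data.frame` with columns `cultivar_id`, `VT`, `GH` (and
#'   optionally `VTGH`), or `NULL`.
#' @param catalog optional `data.frame`/`DataFrame` with columns
#'   `chromosome`, `arm`, `band` describing the band positions, in matrix
#'   column order; by default parsed from the band tokens.
#'
#' @return A [CbandExperiment-class] object.
#' @export
#' @examples
#' m <- matrix(c(0, 3, 5, 2, 0, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("LW01", "CW01"),
#'                             c("1A.S.1", "1A.L.2", "2B.S.1")))
#' tr <- data.frame(cultivar_id = c("LW01", "CW01"),
#'                  VT = c("L", "C"), GH = c("W", "W"))
#' CbandExperiment(m, tr)
CbandExperiment <- function(bandSizes, traits = NULL, catalog = NULL) {
  m <- as.matrix(bandSizes)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("bandSizes must have cultivar and band-position dimnames")
  colTok <- all(vapply(colnames(m), .isBandToken, logical(1)))
  rowTok <- all(vapply(rownames(m), .isBandToken, logical(1)))
  if (colTok) {
    m <- t(m)              # store bands x cultivars, SE convention
  } else if (!rowTok) {
    stop("neither dimnames of bandSizes parse as CHROM.ARM.BAND tokens")
  }
  if (is.null(catalog)) {
    catalog <- parseBandTokens(rownames(m))
  } else {
    catalog <- as.data.frame(catalog)
    stopifnot(nrow(catalog) == nrow(m))
  }
  cd <- DataFrame(row.names = colnames(m))
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    i <- match(colnames(m), traits$cultivar_id)
    if (anyNA(i))
      stop("cultivars missing from trait table: ",
           paste(colnames(m)[is.na(i)], collapse = ", "))
    cd$VT <- as.character(traits$VT[i])
    cd$GH <- as.character(traits$GH[i])
    cd$VTGH <- paste0(cd$VT, cd$GH)
  }
  se <- SummarizedExperiment(
    assays = list(bandSize = m),
    rowData = DataFrame(catalog),
    colData = cd)
  new("CbandExperiment", se)
}

.isBandToken <- function(x) {
  grepl("^[1-7][ABD]\\.[SL]\\.[A-Za-z0-9_-]+$", x)
}

#' Parse band-position tokens
#'
#' Splits `CHROM.ARM.BAND` tokens (e.g. `"3B.L.12"`) into a band-catalog
#' data frame.
#'
#' @param tokens character vector of tokens.
#' @return `data.frame` with columns `chromosome`, `arm`, `band`.
#' @export
parseBandTokens <- function(tokens) {
  bad <- !vapply(tokens, .isBandToken, logical(1))
  if (any(bad))
    stop("malformed band-position token(s): ",
         paste(tokens[bad], collapse = ", "))
  parts <- strsplit(tokens, ".", fixed = TRUE)
  data.frame(
    chromosome = vapply(parts, `[`, "", 1L),
    arm = vapply(parts, `[`, "", 2L),
    band = vapply(parts, function(p) paste(p[-(1:2)], collapse = "."), ""),
    row.names = tokens)
}

#' @describeIn CbandExperiment-class band-size matrix in analysis orientation
#'   (cultivars x band positions).
#' @param x a `CbandExperiment`.
#' @export
bandSizes <- function(x) {
  stopifnot(is(x, "CbandExperiment"))
  t(assay(x, "bandSize"))
}

#' @describeIn CbandExperiment-class the band catalog (one row per band
#'   position: chromosome, arm, band label).
#' @export
bandCatalog <- function(x) {
  stopifnot(is(x, "CbandExperiment"))
  as.data.frame(rowData(x))
}

#' @describeIn CbandExperiment-class trait table (cultivar_id, VT, GH, VTGH).
#' @export
traitTable <- function(x) {
  stopifnot(is(x, "CbandExperiment"))
  cd <- as.data.frame(colData(x))
  data.frame(cultivar_id = colnames(x), cd, row.names = NULL)
}

setMethod("show", "CbandExperiment", function(object) {
  cat("CbandExperiment:", ncol(object), "cultivars x", nrow(object),
      "band positions on", length(unique(rowData(object)$chromosome)),
      "chromosomes\n")
  if ("VTGH" %in% colnames(colData(object))) {
    tb <- table(colData(object)$VTGH)
    cat("  trait classes:",
        paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  callNextMethod()
})
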
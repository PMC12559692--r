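#' Enumerate trait subsample schemes
#'
#' The association analyses run on the total sample and on trait-homogeneous
#' subsamples. Three total-sample schemes test the breeding status (VT),
#' growth habit (GH) and their combination (VTGH, one-vs-rest), and eight
#' nested schemes test one trait inside a sample homogeneous for the other:
#' winter/spring within landraces (`W_in_L`, `S_in_L`) and within modern
#' cultivars (`W_in_C`, `S_in_C`), and vice versa landrace/modern within
#' winter (`L_in_W`, `C_in_W`) and spring (`L_in_S`, `C_in_S`) cultivars.
#'
#' @param traits trait `data.frame` with `cultivar_id`, `VT`, `GH`, `VTGH`.
#' @return named list of schemes; each has `name`, `background` (cultivar
#'   ids) and `targets` (named list of target cultivar-id sets, the classes
#'   whose overrepresentation is tested). Schemes whose background or target
#'   would be empty are dropped with a warning.
#' @export
enumerateSubsampleSchemes <- function(traits) {
  id <- traits$cultivar_id
  of <- function(var, lev) id[traits[[var]] == lev]
  schemes <- list(
    list(name = "total:VT", background = id,
         targets = list(L = of("VT", "L"), C = of("VT", "C"))),
    list(name = "total:GH", background = id,
         targets = list(W = of("GH", "W"), S = of("GH", "S"))),
    list(name = "total:VTGH", background = id,
         targets = list(LW = of("VTGH", "LW"), LS = of("VTGH", "LS"),
                        CW = of("VTGH", "CW"), CS = of("VTGH", "CS")))
  )
  nested <- list(
    c("W_in_L", "VT", "L", "GH", "W"), c("S_in_L", "VT", "L", "GH", "S"),
    c("W_in_C", "VT", "C", "GH", "W"), c("S_in_C", "VT", "C", "GH", "S"),
    c("L_in_W", "GH", "W", "VT", "L"), c("C_in_W", "GH", "W", "VT", "C"),
    c("L_in_S", "GH", "S", "VT", "L"), c("C_in_S", "GH", "S", "VT", "C"))
  for (nn in nested) {
    bg <- of(nn[2], nn[3])
    tg <- intersect(of(nn[4], nn[5]), bg)
    schemes[[length(schemes) + 1L]] <-
      list(name = nn[1], background = bg,
           targets = stats::setNames(list(tg), nn[5]))
  }
  keep <- logical(length(schemes))
  for (i in seq_along(schemes)) {
    s <- schemes[[i]]
    s$targets <- Filter(function(t) length(t) > 0L &&
                          length(t) < length(s$background), s$targets)
    schemes[[i]] <- s
    keep[i] <- length(s$background) > 0L && length(s$targets) > 0L
  }
  if (any(!keep))
    warning("dropped scheme(s) with empty class: ",
            paste(vapply(schemes[!keep], `[[`, "", "name"), collapse = ", "))
  schemes <- schemes[keep]
  stats::setNames(schemes, vapply(schemes, `[[`, "", "name"))
}

#' Fisher overrepresentation of a binary feature in a trait class
#'
#' One-sided exact test for overrepresentation of feature carriers in the
#' target class within the scheme's background sample (hypergeometric tail).
#'
#' @param feature named 0/1 vector of feature carriage, covering at least
#'   the background cultivars.
#' @param scheme one scheme from [enumerateSubsampleSchemes()].
#' @param target name of the target class within the scheme (default first).
#' @param alternative `"greater"` (overrepresentation, the default) or
#'   `"two.sided"`.
#' @param alpha significance level for the `significant` flag (0.05).
#' @return one-row `data.frame`: `scheme`, `target`, `direction`, `p`,
#'   `significant`, `informative` (FALSE when the feature does not vary in
#'   the background, in which case `p = 1`).
#' @export
fisherOverrepresentation <- function(feature, scheme,
                                     target = names(scheme$targets)[1L],
                                     alternative = c("greater", "two.sided"),
                                     alpha = 0.05) {
  alternative <- match.arg(alternative)
  bg <- scheme$background
  tg <- scheme$targets[[target]]
  stopifnot(!is.null(tg), all(tg %in% bg))
  f <- feature[bg]
  if (anyNA(f)) stop("feature undefined on background cultivars")
  N <- length(bg); n <- length(tg)
  K <- sum(f > 0); k <- sum(f[tg] > 0)
  if (K == 0L || K == N) {
    return(data.frame(scheme = scheme$name, target = target,
                      direction = "none", p = 1, significant = FALSE,
                      informative = FALSE))
  }
  tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), 2L)
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  data.frame(
    scheme = scheme$name, target = target,
    direction = if (k / n >= (K - k) / (N - n)) "enriched" else "depleted",
    p = p, significant = p < alpha, informative = TRUE)
}

#' Fisher overrepresentation for every feature and scheme
#'
#' @param features binary cultivar x feature matrix (e.g. a chromosome-type
#'   indicator matrix).
#' @param traits trait table covering the cultivars.
#' @param schemes optional scheme list; defaults to
#'   [enumerateSubsampleSchemes()].
#' @inheritParams fisherOverrepresentation
#' @return `data.frame` of association records with a leading `feature`
#'   column.
#' @export
fisherAssociationTable <- function(features, traits, schemes = NULL,
                                   alternative = "greater", alpha = 0.05) {
  if (is.null(schemes)) schemes <- enumerateSubsampleSchemes(traits)
  out <- vector("list", 0L)
  for (s in schemes) for (tg in names(s$targets)) {
    recs <- lapply(colnames(features), function(fid) {
      r <- fisherOverrepresentation(features[, fid], s, tg,
                                    alternative = alternative, alpha = alpha)
      cbind(feature = fid, r)
    })
    out[[length(out) + 1L]] <- do.call(rbind, recs)
  }
  do.call(rbind, out)
}

#' Summarize informative features across schemes
#'
#' A feature is non-informative when no scheme/target test reaches
#' significance (all p >= alpha); per-scheme significant counts are also
#' reported.
#'
#' @param records association records (from [fisherAssociationTable()] or
#'   [logisticAssociationTable()]).
#' @param alpha significance level (0.05).
#' @return list with `per_scheme` (`data.frame`: scheme, target, n_tested,
#'   n_significant), `n_features`, `n_noninformative`,
#'   `fraction_noninformative`.
#' @export
summarizeInformativeFeatures <- function(records, alpha = 0.05) {
  sig <- !is.na(records$p) & records$p < alpha
  per <- stats::aggregate(cbind(n_tested = rep(1L, nrow(records)),
                                n_significant = sig + 0L),
                          by = list(scheme = records$scheme,
                                    target = records$target), FUN = sum)
  by_feat <- tapply(sig, records$feature, any)
  n_feat <- length(by_feat)
  n_non <- sum(!by_feat)
  list(per_scheme = per, n_features = n_feat, n_noninformative = n_non,
       fraction_noninformative = n_non / n_feat)
}

#' Per-unit-size odds of class membership for one C-band
#'
#' Quasi-binomial logistic regression of target-class membership on band
#' size (0-5): `class ~ size`, logit link, dispersion estimated as Pearson
#' chi-square / df, inference by t-statistic on n-2 df. The exponentiated
#' slope `oddFC` is the multiplicative change in the odds of the class per
#' one-unit increase in band size; `oddFC < 1` marks association with the
#' absence (null allele) of the band.
#'
#' @param sizes integer band sizes (0-5) on the background cultivars.
#' @param class 0/1 (or logical) target-class membership, same length.
#' @param scheme_name label recorded in the output.
#' @param alpha significance level (0.05).
#' @return one-row `data.frame`: `scheme`, `direction`, `oddFC`, `p`,
#'   `significant`, `informative`, `unstable` (complete separation: no p).
#' @export
logisticBandAssociation <- function(sizes, class, scheme_name = "scheme",
                                    alpha = 0.05) {
  class <- as.integer(class > 0)
  stopifnot(length(sizes) == length(class))
  rec <- function(direction = "none", oddFC = NA_real_, p = NA_real_,
                  significant = FALSE, informative = TRUE, unstable = FALSE)
    data.frame(scheme = scheme_name, direction = direction, oddFC = oddFC,
               p = p, significant = significant, informative = informative,
               unstable = unstable)
  nu <- length(unique(sizes))
  if (nu < 2L || length(unique(class)) < 2L)
    return(rec(informative = FALSE))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(class ~ sizes, family = stats::quasibinomial("logit")),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[["sizes"]]
  oddFC <- exp(beta)
  if (sep_warn || abs(beta) > 15)
    return(rec(direction = if (oddFC >= 1) "presence" else "absence",
               oddFC = oddFC, unstable = TRUE))
  p <- stats::coef(summary(fit))["sizes", "Pr(>|t|)"]
  rec(direction = if (oddFC >= 1) "presence" else "absence",
      oddFC = oddFC, p = p, significant = p < alpha)
}

#' Logistic band association for every band and scheme
#'
#' @param sizes integer cultivar x band matrix (0-5), e.g. [bandSizes()] of
#'   the diagnostic bands.
#' @param traits trait table covering the cultivars.
#' @param schemes optional scheme list; defaults to
#'   [enumerateSubsampleSchemes()].
#' @param alpha significance level.
#' @return `data.frame` of records with leading `feature` and `target`
#'   columns.
#' @export
logisticAssociationTable <- function(sizes, traits, schemes = NULL,
                                     alpha = 0.05) {
  if (is.null(schemes)) schemes <- enumerateSubsampleSchemes(traits)
  out <- vector("list", 0L)
  for (s in schemes) for (tg in names(s$targets)) {
    bg <- s$background
    cls <- bg %in% s$targets[[tg]]
    recs <- lapply(colnames(sizes), function(fid) {
      r <- logisticBandAssociation(sizes[bg, fid], cls,
                                   scheme_name = s$name, alpha = alpha)
      cbind(feature = fid, target = tg, r)
    })
    out[[length(out) + 1L]] <- do.call(rbind, recs)
  }
  recs <- do.call(rbind, out)
  recs[, c("feature", "scheme", "target", "direction", "oddFC", "p",
           "significant", "informative", "unstable")]
}
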
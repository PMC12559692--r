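#' Configuration for the synthetic karyogram generator
#'
#' Defaults emulate the design of the varietal population under study:
#' 87 cultivars in four breeding-status x growth-habit classes (44
#' landraces = 22 LW + 22 LS; 43 modern = 23 CW + 20 CS), a band catalog of
#' 147 positions over the 21 wheat chromosomes (7 per chromosome), 49
#' constant bands leaving 98 varying diagnostic positions, planted groups
#' of perfectly co-occurring chromosome types (one pair, one triple, one
#' quadruple of dedicated chromosomes), a tight low-noise core of 7 modern
#' winter cultivars, and one CW outlier carrying three alien high-size
#' introgression blocks. The planted geometry is hierarchical: CW most
#' distinct, LW distinct, LS and CS similar to each other - so the
#' population's real cluster structure has three groups, recorded in the
#' generated truth.
#'
#' @param n_per_group named counts for LW, LS, CW, CS.
#' @param bands_s,bands_l band positions per short/long arm.
#' @param n_constant_free constant bands planted on non-dedicated
#'   chromosomes (besides the fully constant 4D/5D, which the analysis
#'   excludes anyway).
#' @param roles varying-band role counts: `cw`/`lw` strongly shifted
#'   presence profiles, `vt`/`gh` moderate trait-associated shifts; the
#'   remainder is undifferentiated noise.
#' @param assoc_chromosomes chromosomes dedicated to the planted
#'   associated-type groups, a list of character vectors (their lengths are
#'   the planted group sizes) with names in `c("CW","LW","LSCS")` giving
#'   the member set.
#' @param core_size number of CW cultivars drawn noise-free from the modal
#'   CW profile.
#' @param outlier_id,outlier_chromosomes the introgression outlier and the
#'   three chromosomes whose varying bands it carries at maximal size.
#' @param shift logit shift of the moderate vt/gh effects.
#' @param seed RNG seed.
#' @return a `karyoSimConfig` list.
#' @export
karyoSimConfig <- function(n_per_group = c(LW = 22L, LS = 22L,
                                           CW = 23L, CS = 20L),
                           bands_s = 4L, bands_l = 3L,
                           n_constant_free = 35L,
                           roles = c(cw = 10L, lw = 8L, vt = 6L, gh = 6L),
                           assoc_chromosomes = list(
                             CW = c("1B", "2B", "3B", "6B"),
                             LW = c("5A", "6A", "7A"),
                             LSCS = c("2D", "3D")),
                           core_size = 7L,
                           outlier_id = "CW03",
                           outlier_chromosomes = c("1A", "2A", "3A"),
                           shift = 1.0,
                           seed = 1L) {
  stopifnot(all(names(n_per_group) %in% c("LW", "LS", "CW", "CS")),
            all(n_per_group >= 3L),
            bands_s >= 1L, bands_l >= 1L,
            core_size <= n_per_group[["CW"]] - 1L)
  ded <- unlist(assoc_chromosomes)
  stopifnot(!anyDuplicated(ded), all(ded %in% wheatChromosomes()),
            !any(c("4D", "5D") %in% ded),
            !any(outlier_chromosomes %in% c(ded, "4D", "5D")))
  structure(list(n_per_group = n_per_group, bands_s = bands_s,
                 bands_l = bands_l, n_constant_free = n_constant_free,
                 roles = roles, assoc_chromosomes = assoc_chromosomes,
                 core_size = core_size, outlier_id = outlier_id,
                 outlier_chromosomes = outlier_chromosomes,
                 shift = shift, seed = seed),
            class = "karyoSimConfig")
}

#' Generate a synthetic karyogram population with planted truth
#'
#' Band presence is drawn Bernoulli from group-specific probability
#' profiles and, given presence, size is drawn as `1 + Binomial(4, p)` on
#' the 1-5 scale around a group-band mean. On dedicated chromosomes the
#' member set of the planted associated-type group shares one fixed
#' all-present pattern (other cultivars draw random patterns, never equal
#' to the fixed one), so those chromosomes' types co-occur perfectly. The
#' CW core is copied noise-free from the modal CW profile; the outlier is
#' overwritten with three maximal-size introgression blocks; 4D and 5D
#' carry only constant bands. Deterministic given `cfg$seed`.
#'
#' @param cfg a [karyoSimConfig()].
#' @return list with
#'   \item{experiment}{a [CbandExperiment-class] (traits attached)}
#'   \item{truth}{planted truth: `labels` (`data.frame` cultivar_id, VTGH,
#'     structure), `informative_bands` (per role), `constant_bands`,
#'     `varying_bands`, `assoc_groups` (planted member sets per dedicated
#'     chromosome set), `outlier`, `core`}
#' @export
generateKaryograms <- function(cfg = karyoSimConfig()) {
  stopifnot(inherits(cfg, "karyoSimConfig"))
  set.seed(cfg$seed)
  ng <- cfg$n_per_group
  ids <- unlist(lapply(names(ng), function(g)
    sprintf("%s%02d", g, seq_len(ng[[g]]))), use.names = FALSE)
  vtgh <- rep(names(ng), ng)
  names(vtgh) <- ids
  n <- length(ids)
  traits <- data.frame(cultivar_id = ids,
                       VT = substr(vtgh, 1, 1), GH = substr(vtgh, 2, 2))
  traits$VTGH <- vtgh
  structure_lab <- ifelse(vtgh == "CW", "CW",
                          ifelse(vtgh == "LW", "LW", "LSCS"))

  chroms <- wheatChromosomes()
  tokens <- unlist(lapply(chroms, function(ch)
    c(sprintf("%s.S.%d", ch, seq_len(cfg$bands_s)),
      sprintf("%s.L.%d", ch, seq_len(cfg$bands_l)))), use.names = FALSE)
  tok_chrom <- sub("\\..*$", "", tokens)
  m <- matrix(0L, n, length(tokens), dimnames = list(ids, tokens))

  ded <- unlist(cfg$assoc_chromosomes, use.names = FALSE)
  free <- setdiff(chroms, c(ded, "4D", "5D", cfg$outlier_chromosomes))
  free <- c(free, cfg$outlier_chromosomes)   # outlier blocks sit on free chroms

  ## constant bands: all of 4D/5D plus a sample of free-chromosome positions
  const_d <- tokens[tok_chrom %in% c("4D", "5D")]
  free_pos <- tokens[tok_chrom %in% free]
  stopifnot(cfg$n_constant_free <= length(free_pos) - length(cfg$roles) - 5L)
  const_free <- sort(sample(free_pos, cfg$n_constant_free))
  constant_bands <- c(const_d, const_free)
  for (b in constant_bands)
    m[, b] <- sample(0:5, 1L)

  ## varying probabilistic bands on free chromosomes, with planted roles
  vary_free <- setdiff(free_pos, const_free)
  roles <- cfg$roles
  stopifnot(sum(roles) <= length(vary_free))
  shuf <- sample(vary_free)
  role_of <- stats::setNames(rep("noise", length(vary_free)), shuf)
  idx <- 0L
  for (rr in names(roles)) {
    role_of[idx + seq_len(roles[[rr]])] <- rr
    idx <- idx + roles[[rr]]
  }
  groups <- names(ng)
  ## U-shaped presence probabilities: most band positions are nearly fixed
  ## (present or absent) with occasional polymorphism, as in real
  ## karyograms, which keeps per-chromosome pattern diversity realistic
  base_p <- 0.03 + 0.94 * stats::rbeta(length(vary_free), 0.3, 0.3)
  names(base_p) <- names(role_of)
  size_p <- stats::runif(length(vary_free), 0.3, 0.7)
  names(size_p) <- names(role_of)
  P <- matrix(rep(base_p, each = 4L), nrow = 4L,
              dimnames = list(groups, names(role_of)))
  SZ <- matrix(rep(size_p, each = 4L), nrow = 4L,
               dimnames = list(groups, names(role_of)))
  extreme <- function(p) ifelse(p < 0.5, 0.95, 0.05)
  lshift <- function(p, d) stats::plogis(stats::qlogis(p) + d)
  cwb <- names(role_of)[role_of == "cw"]
  lwb <- names(role_of)[role_of == "lw"]
  vtb <- names(role_of)[role_of == "vt"]
  ghb <- names(role_of)[role_of == "gh"]
  P["CW", cwb] <- extreme(base_p[cwb]); SZ["CW", cwb] <- 0.9
  P["LW", lwb] <- extreme(base_p[lwb])
  P[c("LW", "LS"), vtb] <- lshift(P[c("LW", "LS"), vtb], cfg$shift)
  P[c("CW", "CS"), vtb] <- lshift(P[c("CW", "CS"), vtb], -cfg$shift)
  P[c("LW", "CW"), ghb] <- lshift(P[c("LW", "CW"), ghb], cfg$shift)
  P[c("LS", "CS"), ghb] <- lshift(P[c("LS", "CS"), ghb], -cfg$shift)
  for (b in names(role_of)) {
    pres <- stats::rbinom(n, 1L, P[vtgh, b])
    size <- 1L + stats::rbinom(n, 4L, SZ[vtgh, b])
    m[, b] <- pres * size
  }

  ## dedicated chromosomes: planted associated-type groups
  member_sets <- list(CW = ids[vtgh == "CW"], LW = ids[vtgh == "LW"],
                      LSCS = ids[vtgh %in% c("LS", "CS")])
  assoc_truth <- list()
  for (gset in names(cfg$assoc_chromosomes)) {
    mem <- member_sets[[gset]]
    for (ch in cfg$assoc_chromosomes[[gset]]) {
      pos <- tokens[tok_chrom == ch]
      m[mem, pos] <- rep(3L, length(mem) * length(pos))      # fixed pattern
      other <- setdiff(ids, mem)
      ## non-members carry one of a few alternative presence patterns
      ## (guaranteed distinct from the all-present member pattern), so a
      ## dedicated chromosome has realistically few types
      n_alt <- 4L
      alt <- matrix(stats::rbinom(n_alt * length(pos), 1L, 0.5), n_alt)
      alt[, 1L] <- 0L
      pick <- sample.int(n_alt, length(other), replace = TRUE)
      sz <- matrix(1L + stats::rbinom(length(other) * length(pos), 4L, 0.5),
                   length(other))
      m[other, pos] <- alt[pick, ] * sz
    }
    assoc_truth[[gset]] <- list(chromosomes = cfg$assoc_chromosomes[[gset]],
                                size = length(cfg$assoc_chromosomes[[gset]]),
                                members = mem)
  }

  ## CW core: a shared noise-free karyogram (modal CW profile on the free
  ## varying bands; one common realization elsewhere)
  cw_ids <- ids[vtgh == "CW"]
  core <- setdiff(cw_ids, cfg$outlier_id)[seq_len(cfg$core_size)]
  modal_pres <- P["CW", ] >= 0.5
  modal_size <- 1L + round(4 * SZ["CW", ])
  template <- m[core[1L], ]
  template[names(role_of)] <- as.integer(modal_pres * modal_size)
  m[core, ] <- matrix(template, nrow = length(core), ncol = ncol(m),
                      byrow = TRUE)

  ## outlier: three alien maximal-size introgression blocks
  out_pos <- intersect(tokens[tok_chrom %in% cfg$outlier_chromosomes],
                       vary_free)
  m[cfg$outlier_id, out_pos] <- 5L

  ## guard: every intended-varying band must actually vary
  vary_all <- setdiff(tokens, constant_bands)
  for (b in vary_all) {
    if (length(unique(m[, b])) == 1L)
      m[1L, b] <- if (m[1L, b] == 0L) 3L else 0L
  }

  truth <- list(
    labels = data.frame(cultivar_id = ids, VTGH = vtgh,
                        structure = structure_lab, row.names = NULL),
    informative_bands = split(names(role_of), role_of),
    constant_bands = constant_bands,
    varying_bands = vary_all,
    assoc_groups = assoc_truth,
    outlier = cfg$outlier_id,
    core = core,
    presence_profiles = P,
    size_profiles = SZ)
  list(experiment = CbandExperiment(m, traits = traits), truth = truth)
}

#' Generate a companion binary SNP marker matrix
#'
#' Emulates an external SNP genotyping of the same cultivars with
#' unambiguous biallelic calls (no heterozygotes): a fraction
#' `concordance` of the markers is habit-informative (allele frequencies
#' differ between winter and spring cultivars only, so SNP classification
#' separates growth habit but not breeding status); the rest is noise.
#'
#' @param truth truth object from [generateKaryograms()] (uses the labels).
#' @param n_markers number of markers.
#' @param concordance fraction of habit-informative markers in `[0, 1]`.
#' @param seed RNG seed.
#' @return 0/1 cultivar x marker matrix.
#' @export
generateSnpMarkers <- function(truth, n_markers = 500L, concordance = 0.8,
                               seed = 1L) {
  stopifnot(concordance >= 0, concordance <= 1)
  lab <- truth$labels
  ids <- lab$cultivar_id
  gh <- substr(lab$VTGH, 2, 2)
  set.seed(seed)
  n_inf <- round(concordance * n_markers)
  m <- matrix(0L, length(ids), n_markers,
              dimnames = list(ids, sprintf("snp%04d", seq_len(n_markers))))
  if (n_inf > 0) {
    pW <- stats::runif(n_inf, 0.75, 0.95)
    pS <- stats::runif(n_inf, 0.05, 0.25)
    for (j in seq_len(n_inf))
      m[, j] <- stats::rbinom(length(ids), 1L,
                              ifelse(gh == "W", pW[j], pS[j]))
  }
  if (n_inf < n_markers) {
    for (j in (n_inf + 1L):n_markers)
      m[, j] <- stats::rbinom(length(ids), 1L, stats::runif(1, 0.1, 0.9))
  }
  m
}
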
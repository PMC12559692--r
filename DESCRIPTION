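Package: karyoclass
Title: Karyological Classification of Varietal Populations from C-Banding Karyograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying varietal populations (common wheat cultivars)
    from Giemsa C-banding karyograms. Karyograms coded on the 0-5 band-size scale
    are stored in a SummarizedExperiment-derived container; the package derives
    qualitative (chromosome-type) and quantitative (band-size) diagnostic
    features, tests their association with breeding status and growth habit
    (Fisher overrepresentation and quasi-binomial per-unit-size odds), selects an
    agglomerative linkage by trait-purity and Fitch parsimony, supports clades by
    character bootstrap, compares dendrograms by Robinson-Foulds distance and
    tanglegram entanglement, fits branch lengths under a two-state Markov model,
    and ordinates cultivars by principal coordinates, principal components and
    multiple correspondence analysis with supplementary trait variables. A
    synthetic-karyogram generator with planted truth supports recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    optparse
biocViews: Clustering, Classification, Cytogenetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
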
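Package: PocketScreen
Title: Structure-First Discovery of Druggable Protein Pockets and
    Screening Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for structure-first small-molecule discovery.
    Detects solvent-accessible binding pockets on protein structures
    using a voxel-grid geometric method, applies druggability filters
    (pocket area, polar lining residues, mouth count), builds
    rotation-invariant shape signatures from pairwise lining-atom
    distances and compares them with the two-sample Kolmogorov-Smirnov
    statistic, superposes pocket surfaces by least-squares (cRMSD,
    orientation-vector oRMSD) with Monte-Carlo significance and a
    volume-overlap Tanimoto score, triages compound libraries through
    drug-likeness windows and rank-based propagation funnels over
    external docking score tables, and computes colony-formation
    screening statistics (percent-of-control, efficacy ratios, per-site
    activity summaries, bone-marrow toxicity flags, four-parameter
    logistic IC50 fits).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
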
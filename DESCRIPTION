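Package: allodyn
Title: Allosteric Dynamics Analysis of Coarse-Grained Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of protein-DNA complexes at
    coarse-grained resolution (one site per residue C-alpha, one per nucleotide
    backbone phosphate). Provides structural descriptors (superposition RMSD,
    radius of gyration, RMSF, hydrogen-bond occupancy, salt-bridge scans),
    dynamic cross-correlation maps and their differences, essential-dynamics
    principal component analysis with cosine-content diagnostics and
    free-energy landscapes, anisotropic network models with perturbation
    response scanning, and linear-mutual-information residue networks with
    betweenness-centrality differencing. A synthetic-ensemble generator
    produces elastic-network Gaussian samples, two-basin closed/open mixtures
    and scripted hydrogen-bond traces with recorded ground truth, and a
    pipeline orchestrates paired wild-type versus perturbed comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
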
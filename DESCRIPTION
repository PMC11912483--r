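Package: bupo
Title: Linear-Scaling Density-Fitted Coulomb Matrices via Bubblepole Multipole Hierarchies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Gaussian-basis engine for building Coulomb matrices with
    density fitting (resolution of the identity). Implements classic RI-J, the
    Hermite-basis Split-RI-J reorganization, and the linear-scaling RI-BUPO-J
    two-step algorithm in which shell pairs and auxiliary shells are grouped into
    extent-enclosing spheres ("bubbles") by balanced k-means clustering, real
    scaled solid-harmonic multipoles are aggregated and up-translated through a
    recursive bubble hierarchy, and far-field interactions are contracted in real
    algebra. Includes full McMurchie-Davidson integral machinery (Boys function,
    E-coefficients, Hermite Coulomb integrals, 2-/3-/4-index repulsion integrals)
    that doubles as a brute-force oracle, walker-scan shell-pair extents with
    literature baselines, incremental/full build drivers with accurate rebuild,
    and seeded synthetic chain/basis/density generators for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
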
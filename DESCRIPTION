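Package: lobesym
Title: Object-Symmetry Analysis of Positional Asymmetry in Cellular Lobes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics of object symmetry between
    paired cellular sublobes, as in the desmid genus Micrasterias. Provides
    generalized Procrustes superimposition, reflect-and-relabel decomposition of
    shape into symmetric and asymmetric components, Procrustes ANOVA separating
    individual variation, positional asymmetry, fluctuating asymmetry and
    digitization error with permutation tests, principal-component morphospaces
    of mirrored and purely asymmetric configurations, squared-change parsimony
    mapping of a phylogeny into shape space with a permutation test of
    phylogenetic signal, and phylogenetic two-block partial least squares under
    a Brownian-motion model. Includes TPS landmark file input/output and a
    synthetic-data generator emulating a multi-species, replicated digitization
    design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
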
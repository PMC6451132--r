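Package: lissofret
Title: Single-Molecule FRET Titration Analysis and Contact Geometry for
    Ribosome E-Site Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how E-site binding translation inhibitors
    (lissoclimides and glutarimides such as cycloheximide) shift the
    classical/hybrid tRNA equilibrium of pre-translocation 80S ribosomes.
    Simulates single-molecule FRET (smFRET) trace datasets with three-state
    tRNA dynamics, photobleaching and donor blinking; applies standard
    smFRET trace selection criteria; idealizes FRET trajectories with a
    three-state Gaussian-emission hidden Markov model (Baum-Welch and
    Viterbi); fits equilibrium drug-binding isotherms to fraction-classical
    titration data by weighted nonlinear least squares to estimate apparent
    dissociation constants; and measures structural contact geometry
    (halogen-pi contacts to nucleobase ring centroids, polar contacts,
    least-squares superposition RMSD) on PDB/mmCIF structures, plus
    component-wise comparison of intermolecular interaction-energy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
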
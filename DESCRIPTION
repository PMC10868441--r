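Package: idpens
Title: Analysis of Weighted Conformer Ensembles of Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative analysis of weighted conformer ensembles
    of intrinsically disordered proteins and regions. Implements a
    superposition-free similarity measure between ensembles based on the
    distance root-mean-square deviation (DRMSD) metric in conformer space,
    site-specific order and Ramachandran flexibility parameters, detection of
    deviations from Flory random-coil scaling of section end-to-end distances,
    partitioning of proteins into folded domains and disordered regions from
    AlphaFold predicted aligned error (PAE) matrices or per-residue disorder
    tracks, and visualization of disordered ensembles by inertia-tensor
    principal-axes superposition with pseudo-electron density maps and
    Debye-screened electrostatic surface coloring. A Monte-Carlo backbone
    generator sampling residue-type-specific Ramachandran distributions
    provides random-coil reference ensembles and synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
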
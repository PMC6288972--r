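Package: clockwave
Title: Evolution of Oscillatory Segmentation in Growing Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of gene-regulatory-network evolution
    for body-axis segmentation in growing one-dimensional embryos. Genomes of
    transcription-factor genes and signed binding sites are compiled into
    regulatory networks whose Hill-function dynamics (OR-gated activation,
    AND-gated repression, optional multiplicative expression noise) pattern a
    tissue that grows from a posterior growth zone under a decaying morphogen
    gradient. Populations evolve on a lattice with local fitness-proportional
    competition and Margolus diffusion. An automated analysis pipeline prunes
    evolved genomes to their core circuits, censuses signed feedback loops,
    and classifies oscillators (damped, constant, or sloped frequency
    profiles) from Fourier frequency profiles across morphogen levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
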
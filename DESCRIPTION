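Package: ecosim
Title: Stochastic Simulation of a Synthetic Bacteria-Yeast Ecosystem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a synthetic microbial consortium in which
    Saccharomyces cerevisiae and Escherichia coli rescue each other from an
    antibiotic-like growth-control molecule by exchanging quorum-sensing
    signals that induce each other's resistance genes. The 17(+1)-reaction
    network is integrated as chemical Langevin equations with the
    Euler-Maruyama scheme (and a drift-only deterministic path). Tools are
    provided for replicate ensembles with per-time summary statistics,
    classification of ecological regimes (facultative and obligatory
    mutualism, commensalism, extinction) along the antibiotic axis,
    survival-threshold searches (lethal antibiotic concentration, minimum
    carrying capacity, minimum inocula), and predator-prey oscillation
    analysis: coexistence fixed points, Jacobian eigenvalues, Hopf-point
    location in the bacterial lysis rate, FFT oscillation periods, and
    noise-amplitude extinction scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
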
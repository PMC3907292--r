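Package: msnsig
Title: Kinetic Modelling of Dopamine and Glutamate Signalling in Striatal
    D1 Medium Spiny Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-action kinetic model of the convergent dopamine (D1R/Golf/
    AC5/cAMP/PKA/DARPP-32) and glutamate (NMDAR/Ca2+/RAS/ERK) signalling
    cascades of the striatal D1 medium spiny neuron, with two D1R/Golf
    signalling compartments, STEP-mediated crosstalk between the cascades,
    and the experiment machinery around the model: psychostimulant and
    slice stimulation protocols, mutant genotypes, a crosstalk-topology
    screen, an NMDAR-sensitisation assay and local parameter sensitivity
    analysis.  The network is integrated as a stiff ODE system with pulsed
    calcium and dopamine forcing functions; phenotype readouts are scored
    against a panel of published experimental targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
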
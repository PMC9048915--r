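Package: rhodofit
Title: Photoreceptor Spectral Sensitivity Analysis and Opsin Character
    Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intracellular recordings from insect
    photoreceptors: visual-pigment absorbance templates (Govardovskii A1
    and Stavenga 1993 nomograms), Naka-Rushton intensity-response fitting
    and inversion, derivation of relative spectral sensitivities with
    photon-flux correction, least-squares template estimation of peak
    sensitivity (lambda-max), forward models of screening-pigment
    filtering and opsin co-expression, photoreceptor classification and
    ommatidial-type enumeration, synthetic-recording generation, and
    ancestral-state reconstruction of binary opsin characters (Fitch
    parsimony and two-state Mk likelihood) with alignment-site mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    minpack.lm,
    pracma,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
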
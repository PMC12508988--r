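Package: helixfit
Title: Helix-Coil Thermal Denaturation Fitting with a Water-Renormalized
    Zimm-Bragg Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward evaluation and nonlinear least-squares fitting of the
    Zimm-Bragg helix-coil model with explicit water hydrogen-bonding
    renormalization. Fits normalized circular-dichroism helicity melts and
    baseline-subtracted DSC excess heat-capacity thermograms to extract the
    intra-polypeptide and polypeptide-solvent hydrogen-bond energies, the
    glass-transition reference temperature, and the cooperativity parameter.
    Includes overflow-safe transfer-matrix partition functions, analytic
    thermodynamic derivatives, a synthetic-data generator with
    parameter-recovery harness, result export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
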
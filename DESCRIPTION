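Package: bilox
Title: Membrane Antioxidant Photophysics, EPR and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for quantifying how amphiphilic antioxidants
    such as bile acids interact with lipid membranes.  Covers fitting of
    time-resolved singlet-oxygen phosphorescence decays and Stern-Volmer
    determination of bimolecular quenching constants, EPR-oximetry
    estimation of free-radical-induced oxygen-uptake rates, extraction of
    lipid order parameters and polarity (2Azz) from nitroxide spin-label
    EPR spectra, molecular-order, hydrogen-bond, density and radial
    distribution descriptors from bilayer coordinate trajectories, and
    semiquantitative Raman band-ratio analysis.  A synthetic-data module
    generates every input class with known ground truth so the full
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
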
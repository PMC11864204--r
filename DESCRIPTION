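Package: nibam
Title: Acute Nickel Bioavailability Normalization and Site-Specific Hazard Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bioavailability-based acute effects assessment of nickel
    in freshwater. Implements generalized bioavailability models (gBAM) with
    piecewise pH extensions for invertebrates, algae and fish, including the
    average invertebrate model obtained by averaging biotic-ligand stability
    constants of three cladoceran models on the linear scale; a transparent
    inorganic chemical speciation engine (Davies activity corrections, optional
    single-site dissolved organic carbon binding) translating dissolved nickel
    to free Ni2+ activity and back; ecotoxicity-record screening and chemistry
    completion rules; model-performance scoring (r-squared, factor of
    agreement, residual scores, MPS); and species sensitivity distribution
    fitting with six candidate families, Anderson-Darling best-fit selection,
    and bootstrap confidence intervals on the acute HC5 for a target water. A
    synthetic data generator with known ground truth supports offline testing
    of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    fitdistrplus,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
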
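Package: sigmaqe
Title: Linking Energy-Dependent Quenching to the Functional Absorption
    Cross-Section of Photosystem II
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for single-turnover chlorophyll fluorescence
    measurements in microalgae: fits fluorescence-induction transients to the
    cumulative one-hit Poisson model to recover Fo, Fm and the functional
    absorption cross-section of photosystem II (sigmaPSII); computes the
    quenching-parameter calculus (NPQ, Y(NPQ), Y(NO), Y(II), qL, ETR,
    de-epoxidation state) from rapid light curves; filters and regresses
    sigmaPSII against Y(NPQ), extrapolates to Y(NPQ) = 1 and compares the
    residual cross-section with a pigment-based PSII core cross-section; and
    fits time-resolved fluorescence decays to IRF-convolved multiexponentials.
    Includes a seeded synthetic generator for a panel of quenching phenotypes
    (diatom Lhcx mutant-like strains) so the whole pipeline is testable
    end-to-end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
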
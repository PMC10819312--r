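Package: sc47yield
Title: Stacked-Foil Activation Analysis and Production Planning for
    Scandium-47 from Proton-Irradiated Titanium-48
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the activation analysis of stacked-foil proton
    irradiation experiments on enriched titanium-48 targets and for
    planning scandium-47 production. Covers proton energy degradation
    and straggling through a stacked target (Bethe stopping power,
    Bohr straggling), conversion of gamma-spectrometry peak counts to
    end-of-bombardment activities, beam-flux normalisation via the
    natNi(p,x)57Ni monitor reaction, production cross-sections with a
    full uncertainty budget, shape-preserving excitation-function
    fits, thick-target yield integrals for irradiation scenarios,
    post-irradiation activity evolution with isomeric-transition
    feeding (Bateman solutions), radionuclidic-purity curves, and a
    forward simulator of complete synthetic campaigns with known
    ground truth for validating the inverse pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
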
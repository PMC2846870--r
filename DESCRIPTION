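Package: fretmap
Title: Sensitized-Emission FRET Quantification and Per-Pixel Efficiency Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies Förster resonance energy transfer (FRET) from
    three-channel sensitized-emission microscopy: donor-excitation/donor-emission
    (DD), donor-excitation/acceptor-emission (DA) and
    acceptor-excitation/acceptor-emission (AA) images. Provides flat-field
    (shading) correction, random-square background estimation, spectral
    bleed-through calibration from single-fluorophore control cells, per-pixel
    net-FRET and efficiency maps with dynamic-range masking,
    frequency-weighted efficiency versus acceptor/donor-ratio curves with
    sigmoid (Hill) fits, comparison against a random-FRET baseline, and
    Förster-distance estimation from plateau efficiency. Includes a forward
    simulator that generates ground-truth acquisitions and single-fluorophore
    controls so every stage can be validated without microscope data, and a
    command-line workflow (simulate, calibrate, analyze, compare).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
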
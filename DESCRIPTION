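Package: frickedose
Title: Fricke Ferrous-Sulfate Dosimetry Pipeline for HDR Ir-192 Absorbed Dose to Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes spectrophotometric optical-density readings of
    ferrous-sulfate (Fricke) dosimeters into absorbed dose to water for
    high-dose-rate Ir-192 brachytherapy sources. Implements
    temperature-corrected net optical density referenced to 25 degrees C,
    the conversion from optical density to dose in the Fricke solution and
    on to dose in water through Monte Carlo derived correction factors, a
    TG-43 air-kerma-strength ionometric reference for cross-checking, an
    LET-based radiolysis model for the ferric-ion chemical yield G(Fe3+),
    a declarative GUM-style uncertainty budget with quadrature combination,
    and a seeded synthetic-experiment generator for end-to-end validation
    and dose parameter recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
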
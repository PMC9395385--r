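Package: sfeperf
Title: Multifactor Performance Assessment for Supercritical CO2 Extraction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess supercritical CO2 extraction of medicinal
    herbs with an ethanol-water co-solvent on three axes at once:
    extraction performance (response-surface models fitted to a
    three-factor central composite design of pressure, temperature and
    water content in ethanol), operational cost (raw materials,
    utilities and labour), and chemical safety (Le Chatelier mixture
    flash point plus logistic hazard scores summed into a Chemical
    Safety Total Score). Per-condition results are combined through a
    rank-based overall performance index that selects the operating
    condition giving high solubility at low cost in the safest
    co-solvent environment. Ships the Gynura procumbens case-study
    design and responses as fixtures and a synthetic response
    generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
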
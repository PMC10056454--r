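Package: emolr
Title: Electron-Mole Accounting for Gas Fermentation and Chain Elongation Batches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Degree-of-reduction (electron-mole) bookkeeping for batch
    gas-fermentation and chain-elongation experiments on syngas and CO2/H2.
    Converts liquid concentrations and headspace gas amounts into electron
    moles, computes per-compound e-mol yields, electron recovery and
    net-product distribution, evaluates the Syngas Quality Index of a feed
    gas, checks element and electron balance of a stoichiometric reaction
    network for acetogenesis, reverse beta-oxidation and solventogenesis,
    estimates reaction extents from net production vectors by non-negative
    least squares, and simulates serial-transfer enrichment series with
    best-vial selection for end-to-end testing of the accounting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
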
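Package: catdesc
Title: Reactive Descriptors for Enzyme Catalytic Power in SN2 Reactions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes geometric and charge-transfer reactivity descriptors
    for SN2 reaction steps from stationary-point geometries and atomic
    partial charges, fits linear descriptor-barrier scaling relationships
    across a series of active-site environments, and predicts activation
    barriers for held-out environments such as aqueous solution. Includes
    a nudged-elastic-band (NEB) reaction-path optimizer with climbing-image
    refinement and saddle-point verification on analytic two-dimensional
    model potential-energy surfaces, plus a synthetic-series generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
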
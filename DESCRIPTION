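Package: coperator
Title: Operator-Site Scanning and Biolayer-Interferometry Kinetics for
    CopR-CopY Copper-Operon Repressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the DNA operator of the CopR-CopY
    family of bacterial copper-export repressors. Implements degenerate
    (IUPAC) consensus-motif scanning of promoter sequences on both strands
    with optional mismatches, operator counting, inter-operator spacing and
    palindromy analysis; preprocessing (Savitzky-Golay smoothing, reference
    baseline subtraction, interstep alignment) and kinetic analysis of
    biolayer-interferometry sensorgrams, including pseudo-first-order
    segment fits and a global 1:1 Langmuir fit yielding association and
    dissociation rate constants and the equilibrium dissociation constant;
    and synthetic-data generators for sensorgram series and promoter panels
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
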
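Package: memstab
Title: Selection of Thermostabilising Point Variants of Alpha-Helical
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate stabilising point variants of alpha-helical
    membrane proteins from three independent evidence streams: a
    data-driven scoring matrix derived by abundance-weighted,
    rank-based scoring of alanine-scan stability datasets; a
    deep-sequence stream based on residue frequencies in large
    multiple sequence alignments; and a model-based stream aggregating
    per-model unfolding ddG tables. Includes selection policies with
    exclusion lists and overlap resolution, design of non-overlapping
    inverse-PCR mutagenic primer pairs with nearest-neighbour melting
    temperatures, four-parameter logistic melting-curve analysis with
    quadrature error propagation, ranked-list enrichment evaluation,
    and seeded synthetic-data generators for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
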
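Package: phosmet
Title: Phosphosite Flanking-Window Analysis of Methionine Proximity and
    Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Proteome-wide analysis of potential crosstalk between
    Ser/Thr/Tyr phosphorylation and methionine oxidation. Extracts
    flanking windows around phosphosites, computes methionine-proximity
    proportions, positional residue distributions, amino-acid
    composition and Kyte-Doolittle hydropathy scores; scores
    cross-taxa methionine conservation of phosphosite windows and
    classifies candidate crosstalk scenarios; performs local
    hypergeometric GO-term enrichment with Bonferroni correction; and
    generates fully synthetic proteomes, phosphosite tables, homolog
    families and GO annotations with planted effects so that every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
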
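Package: satcomp
Title: Comparative Satellitome Discovery and Quantification from Short Reads
Version: 0.1.0
Authors@R:
    person("Satcomp", "Developers", email = "satcomp@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing satellite DNA (satDNA) catalogs
    ("satellitomes") directly from unassembled paired-end short reads and for
    comparing them across related species. Provides a synthetic multi-species
    read generator with planted satellite families and machine-readable truth;
    an iterative discovery stage (k-mer read clustering, de Bruijn cycle
    detection of tandemness, consensus monomer reconstruction with a
    short-period fallback); masking-based abundance and divergence estimation
    under the Kimura two-parameter model, repeat landscapes, sex-bias (F/M)
    classification and sub-region quantification of composite satellites; and
    cross-species comparative analyses (shuffle-null homology detection,
    consensus K2P distances, consensus turnover rates, and paired t-tests of
    landscape profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
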
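Package: spliceinfo
Title: Information-Theoretic Analysis of mRNA Splice Sites and Splicing
    Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Individual-information models (position weight matrices in
    bits) of donor, acceptor, branch-point and splicing-regulatory binding
    sites; scoring and scanning of sequences for candidate sites with
    sequence-walker decompositions; variant application and interpretation
    via changes in site information (delta R_i), minimum fold-changes in
    spliceosome binding affinity, residual strength and severity bins;
    exon-definition totals with gap surprisal; cryptic splice-site
    activation typing and genome-pipeline flagging rules; and a synthetic
    data generator for planted-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
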
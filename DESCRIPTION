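Package: ltpscan
Title: Genome-Wide Survey of Plant Non-Specific Lipid Transfer Protein Families
Version: 0.1.0
Authors@R:
    person("ltpscan", "developers", email = "ltpscan@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide annotation of plant non-specific lipid
    transfer protein (nsLTP) gene families. Detects the conserved
    eight-cysteine motif (ECM, C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C) in protein
    sequences and assigns nsLTP types from inter-cysteine spacing templates,
    computes per-protein descriptors (length, molecular weight, isoelectric
    point), calls tandem-duplication clusters from gene coordinates,
    estimates Ka/Ks by the Nei-Gojobori (1986) method with Jukes-Cantor
    correction and dates duplications from Ks, builds neighbor-joining
    phylogenies with p-distances and bootstrap support, tabulates
    cis-regulatory elements in promoters, and simulates ground-truthed
    proteomes, gene maps and codon pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
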
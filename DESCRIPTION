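Package: paralogdiv
Title: Gene-Family Duplication, Ka/Ks Dating, and Expression Divergence of Paralogs
Version: 0.1.0
Authors@R: person("Paralogdiv", "Developers", email = "paralogdiv@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide gene-family evolution analyses of
    the kind routinely applied to plant transporter families: neighbor-joining
    phylogeny with bootstrap supports and clade-based subfamily assignment,
    tandem/proximal/segmental duplicate classification from gene ranks and
    collinear anchor chains, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction and molecular-clock dating of duplicate pairs, 2^-ddCt relative
    expression with fold-change calls, and Pearson-correlation classification of
    expression divergence between paralogs. A synthetic-data module generates
    gene orders with planted tandem arrays and collinear segments, codon pairs
    diverged under a controlled dN/dS, and replicated Ct tables with planted
    fold changes, so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
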
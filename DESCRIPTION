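Package: RiboSeek
Title: Structure-Based Riboswitch Discovery by Inverse RNA Folding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Searches nucleotide databases for riboswitch aptamer candidates by
    transforming a structure-conservation search into sequence space. Starting
    from a known aptamer and its secondary structure, random mutations push the
    sequence out of its similarity neighbourhood, a constrained flexible inverse
    folding solver (simulated annealing over a five-term structural objective)
    restores the aptamer shape, and the designed sequences are screened against
    a database with a built-in seed-and-extend local aligner. Hits are vetted
    structurally by minimum free energy folding, base-pair distance and the
    Shapiro coarse-grained tree edit distance. Includes a deterministic
    Nussinov-style fold engine, an adapter for ViennaRNA's RNAfold, and a
    synthetic-genome fixture generator with planted, structure-preserved
    aptamer homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
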
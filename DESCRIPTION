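Package: parallevol
Title: Parallel Evolution Analysis for Small Circular Genomes with
    Overlapping Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify repeated (parallel and convergent) evolution
    in experimentally evolved lineages of small circular viruses such as the
    microvirid bacteriophage phiX174. Maps nucleotide substitutions onto a
    circular genome with overlapping reading frames, tallies per-site and
    per-residue events across lineages, evaluates a combinatorial null model
    for coincident substitutions, tests enrichment of substitutions per gene,
    compares laboratory-adaptive sites with natural variation in a wild
    isolate panel (including the silent-to-missense ratio), and generates
    synthetic datasets with planted substitution hotspots for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    ggplot2,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
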
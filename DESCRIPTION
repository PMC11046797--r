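Package: pgcquant
Title: Quantification of Germ-Cell Epigenetic Signatures from Images and
    ChIP-Seq Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify epigenetic signatures of primordial germ
    cells relative to somatic cells. The imaging arm measures per-nucleus
    histone-mark levels normalized to chromatin and to the somatic cells of
    the same image, chromatin density per unit area, radial (eroded
    volume fraction) signal distributions over equal-area concentric
    shells, and enrichment of co-detected proteins at segmented nuclear
    foci. The genomic arm combines SICER islands and MACS2 broad peaks
    into final broad histone-mark domains, classifies domain bases of two
    cell types into shared core, expansion and cell-type-specific
    compartments, relates per-gene domain coverage to expression (TPM),
    and summarizes repeat-element enrichment from IP/input count tables
    and depth tracks. A synthetic-data generator produces nucleus images
    and toy genomes with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
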
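Package: venomics
Title: Integrated Transcriptomic and Proteomic Identification of
    Parasitoid Venom Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for identifying putative venom proteins in
    parasitoid wasps by integrating three evidence streams: venom-gland
    enriched expression (FPKM with a conditional exact binomial test and
    Benjamini-Hochberg correction), presence of a secretion signal
    peptide (annotation transfer through best hits with complete
    N-termini, a built-in weight-matrix/hydropathy heuristic, or
    external predictions), and proteomic confirmation (charge-dependent
    Xcorr/DeltaCn filtering of peptide-spectrum matches mapped onto
    in-silico translated proteins). Downstream comparative analysis
    partitions a venom-protein set against two reference venom sets by
    dual e-value/bit-score homology cutoffs (three-set Venn), and tests
    score differences with an exact Wilcoxon matched-pairs signed-rank
    test and category enrichment with a Fisher exact test. A synthetic
    data module generates every input with planted ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
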
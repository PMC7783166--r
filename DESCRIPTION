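Package: readthru
Title: Stop-Codon Read-Through Error Rates and 3'-UTR Fail-Safe Stop Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing local mitigation of translational
    read-through errors in eukaryotic genomes. Extracts filtered stop-codon
    contexts (terminal codons plus 97 nt of 3'-UTR) from genome sequence and
    annotation, compares primary stop-codon usage between highly and lowly
    expressed genes, tests enrichment of in-frame additional stop codons
    (ASCs) at 3'-UTR codon positions +1 to +6 against a dinucleotide-controlled
    Markov simulation null and an analytic first-stop geometric null, profiles
    substitution rates around the stop by outgroup parsimony on three-taxon
    ortholog alignments, and relates per-genome enrichment scores to effective
    population size and cellularity by phylogenetic generalised least squares
    with Pagel's lambda estimated by maximum likelihood. Includes synthetic-data
    generators with recorded ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    yaml
Config/testthat/edition: 3
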
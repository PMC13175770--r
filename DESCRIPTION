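Package: otsentry
Title: CRISPR-Cas9 Off-Target Nomination, Prioritization, and Confirmation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A safety-assessment toolkit for CRISPR-Cas9 gene-editing
    products. Implements tag-integration (dsODN/GUIDE-seq-style) off-target
    nomination with UMI consensus, semi-global ("glocal") Needleman-Wunsch
    guide alignment with post-alignment Levenshtein distances, hypergeometric
    enrichment testing of treatment versus pooled control samples with
    Benjamini-Hochberg correction, and tier assignment; a mismatch- and
    indel-tolerant in silico genome search with optional population-variant
    expansion; multi-method panel prioritization and deduplication; amplicon
    deep-sequencing indel quantification and treatment-versus-control
    confirmation with coverage QC and background characterization; droplet
    digital PCR knockout-efficiency calibration; and a synthetic-data
    generator (reference genomes, planted off-target loci, tag-integration
    and amplicon reads, ddPCR droplet counts) with ground-truth tables so
    every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
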
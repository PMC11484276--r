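Package: orthotol
Title: Domain-Curated Ortholog Alignments for Missense Variant Tolerance Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds domain-wise curated multiple sequence alignments of protein
    orthologs and classifies missense variants as evolutionarily tolerant,
    intolerant or uninterpretable from per-column conservation. Provides
    ortholog clade selection from a gene tree (paralog exclusion), reference
    coordinate to alignment column mapping, partitioning of a full-length
    alignment into domain and non-domain segments, per-segment quality control
    (incomplete-sequence discard, indel-proximity masking) and realignment with
    a built-in center-star aligner or an external command, reassembly of the
    refined alignment, conservation-rule based variant verdicts with an
    adjoining-position co-substitution caveat, a seeded synthetic-data
    generator with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
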
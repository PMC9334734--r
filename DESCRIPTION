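Package: immunome
Title: Domain-Signature Screening, Orthology Vetting and Phylogenetics for In Silico Immunomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying a proteome for candidate innate-immune gene
    families from protein functional annotation. Reads InterProScan tabular
    annotation, OrthoFinder orthogroup tables, BLAST tabular homology hits and
    protein FASTA; classifies proteins and genes into immune families with a
    declarative strict/relaxed conserved-domain rule catalog; vets and rescues
    candidates by shared orthogroup membership with reference immune genes;
    summarises domain architectures, extracts named domain regions from the
    longest isoform per gene, and builds neighbor-joining trees of extracted
    domains from pairwise maximum-likelihood distances under the
    Jones-Taylor-Thornton model with invariant sites and discrete-gamma rate
    heterogeneity, with bootstrap branch supports. A synthetic-data generator
    with planted ground truth makes the whole pipeline testable without any
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
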
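Package: polyamp
Title: Multi-Kingdom Long-Read Amplicon Toolkit with Real-Time Saturation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for simultaneous multi-kingdom (16S rRNA gene + fungal ITS)
    long-read amplicon sequencing runs. Segregates nanopore reads by kingdom via
    degenerate-primer matching with edit distance, applies length and mean-quality
    filters, performs fast k-mer naive-Bayes taxonomic classification with bootstrap
    confidence, monitors per-barcode species saturation in real time through analytic
    rarefaction and Chao1 extrapolation with a run-stop rule, builds ITS classification
    databases from UNITE-style taxonomy-annotated FASTA, and reports control conformity,
    contamination screens, top-taxa tables and resource effectiveness. Includes a
    synthetic nanopore-like run generator with complete ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
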
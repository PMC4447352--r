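Package: ksdup
Title: Detection and Dating of Ancient Gene Duplications from Transcriptome Ks Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting paleopolyploidy and other
    ancient gene duplication events from an assembled transcriptome. Starting
    from nucleotide transcripts (CDS FASTA), the package finds paralog pairs by
    an all-vs-all seed-and-extend similarity search with reciprocal-hit
    filtering, estimates per-pair synonymous divergence (Ks) by protein-guided
    codon alignment with Nei-Gojobori site counting and Jukes-Cantor multiple-hit
    correction, locates duplication peaks in the Ks distribution by EM-fitted
    Gaussian mixtures selected with BIC, tests peak significance with a SiZer
    (SIgnificant ZERo crossings of derivatives) map, and converts peak locations
    to ages under a constant synonymous substitution rate. A coding-sequence
    simulator that plants paralog pairs at known Ks depths provides ground truth
    for end-to-end parameter-recovery testing, and assembly-quality metrics
    (N50, scaffold counts above a length threshold) support choosing among
    candidate assemblies. Ortholog utilities build three-way reciprocal-best-hit
    triples across samples, majority-vote consensus sequences, per-sequence SNP
    reports with synonymous/nonsynonymous classification, and in-frame deletion
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
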
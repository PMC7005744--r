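Package: spliceSI
Title: Junction-Read Splicing Index Quantification and Differential
    Splicing Calls for Regulator Perturbation Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative splicing from spliced RNA-seq
    alignments using the splicing index (SI), the ratio of inclusion
    junction reads to the sum of inclusion and skipping junction reads,
    for cassette exons, retained introns and alternative 5'/3' splice
    sites. Classifies reads into exon-exon junction, exon-intron
    bridging and fully intronic groups, calls differential events per
    perturbation contrast with Fisher's exact test and
    Benjamini-Hochberg FDR, and joins knockdown and overexpression
    contrasts under a bidirectional consistency filter to produce
    high-confidence calls. Includes GA-rich motif context extraction
    around regulated exons, a premature-termination-codon rule for
    splicing-coupled nonsense-mediated decay, small closed-form clinical
    rules (tumor-pair classification, RIP percent-input, xenograft
    tumor volume), and a seeded synthetic-data generator producing
    annotation, junction tables and SAM reads with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
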
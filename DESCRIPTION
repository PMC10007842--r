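Package: allelecat
Title: Gene-Level Allele Catalogs from Multi-Sample Variant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds gene-level allele catalogs for re-sequenced germplasm
    panels. Starting from a multi-sample VCF, a GFF3 gene annotation, a
    reference genome and an accession meta-information table, the package
    predicts coding-region functional effects of SNPs and indels (missense,
    nonsense, frameshift, in-frame indels, splice-core and start/stop
    changes) with compact amino-acid-change notation, fills missing
    genotypes with a flagged majority rule, collates the modifying variant
    positions of every gene into gene-level alleles, tabulates allele
    frequencies by accession category, and serves gene- and
    accession-oriented queries over the resulting catalog. A deterministic
    synthetic-panel generator with a ground-truth manifest makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
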
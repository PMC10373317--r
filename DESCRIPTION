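Package: ltrscape
Title: Structural Annotation, Dating and Epigenomic Profiling of LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects intact LTR retrotransposons from genome sequence by their
    structural hallmarks (paired near-identical long terminal repeats, TG...CA
    terminal motifs, 4-6 bp target site duplications), classifies them into
    Copia and Gypsy superfamilies and REXdb-style lineages from protein-domain
    order, estimates insertion times from inter-LTR divergence (T = K/2r with
    Jukes-Cantor correction), identifies solo LTRs with TSD verification and
    computes solo:intact ratios, classifies insertions relative to gene models
    (promoter, exon, intron, downstream) and compares associated gene
    expression, calls transcriptionally active elements from read counts
    (CPM > 1), and builds strand-pooled CG/CHG/CHH methylation metaprofiles
    over element bodies and 2-kb flanks stratified by lineage and activity.
    Includes a synthetic-genome simulator that plants every feature class with
    a complete ground-truth registry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
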
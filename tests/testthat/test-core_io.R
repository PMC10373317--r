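# readers/writers, coordinate conventions, round trips

test_that("FASTA reading handles records, masking and error paths", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g), c(s1 = "ACGT"))

  writeLines(c(">a", "AC", "GT", ">b", "NN"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g), c(a = "ACGT", b = "NN"))

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_genome_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_error(read_genome_fasta(f))

  writeLines(c(">a", "ACgtN"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g), c(a = "ACGTN"))
  mask <- S4Vectors::metadata(g)$mask$a
  expect_equal(IRanges::start(mask), 3L)   # soft-masked gt retained as mask
  expect_equal(IRanges::width(mask), 2L)

  writeLines(c(">a", "ACXT"), f)
  expect_error(read_genome_fasta(f), "non-ACGTN")
})

test_that("gene GFF3 conversion is 1-based to 0-based, strand-aware", {
  f <- tempfile(fileext = ".gff3")
  write_tiny_gene_gff(f, 101L, 200L, "+", exons = list(c(101L, 200L)))
  gm <- read_gff3_genes(f)
  expect_equal(gm$genes$start, 100L)
  expect_equal(gm$genes$end, 200L)
  expect_equal(gm$genes$tss, 100L)
  expect_equal(gm$genes$tts, 199L)

  write_tiny_gene_gff(f, 101L, 200L, "-", exons = list(c(101L, 200L)))
  gm <- read_gff3_genes(f)
  expect_equal(gm$genes$tss, 199L)   # last base, 0-based
  expect_equal(gm$genes$tts, 100L)

  # introns derived from exon gaps
  write_tiny_gene_gff(f, 101L, 200L, "+",
                      exons = list(c(101L, 140L), c(161L, 200L)))
  gm <- read_gff3_genes(f)
  expect_equal(gm$introns$start, 140L)
  expect_equal(gm$introns$end, 160L)
})

test_that("canonical transcript is the longest mRNA, tie first in file", {
  f <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
    "chr1\tt\tgene\t1\t2000\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t1\t2000\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\texon\t1\t500\t.\t+\t.\tParent=m1",
    "chr1\tt\tmRNA\t1\t2000\t.\t+\t.\tID=m2;Parent=g1",
    "chr1\tt\texon\t1\t400\t.\t+\t.\tParent=m2",
    "chr1\tt\texon\t1001\t1400\t.\t+\t.\tParent=m2")
  writeLines(lines, f)
  gm <- read_gff3_genes(f)
  expect_equal(gm$genes$mrna_id, "m2")   # 800 bp beats 500 bp
  expect_equal(nrow(gm$exons), 2L)
})

test_that("gene GFF3 error paths: exon outside mRNA, orphan features", {
  f <- tempfile(fileext = ".gff3")
  lines <- c("##gff-version 3",
    "chr1\tt\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t100\t200\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\texon\t100\t300\t.\t+\t.\tParent=m1")
  writeLines(lines, f)
  expect_error(read_gff3_genes(f), "outside")

  lines <- c("##gff-version 3",
    "chr1\tt\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t100\t200\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tt\texon\t100\t200\t.\t+\t.\tParent=m1",
    "chr1\tt\tmRNA\t100\t200\t.\t+\t.\tID=m9")
  writeLines(lines, f)
  expect_warning(gm <- read_gff3_genes(f), "skipped")
  expect_equal(gm$genes$mrna_id, "m1")
})

test_that("element GFF3 writes parent + children and round-trips", {
  el <- data.table(element_id = "E1", seq_id = "chr1",
                   start = 100L, end = 700L,
                   ltr5_start = 100L, ltr5_end = 250L,
                   ltr3_start = 550L, ltr3_end = 700L,
                   tsd = "GATCA", motif_ok = TRUE, ltr_identity = 0.95,
                   superfamily = "Copia", lineage = "SIRE")
  f <- tempfile(fileext = ".gff3")
  write_elements_gff3(el, f)
  lines <- readLines(f)
  expect_equal(length(lines) - 1L, 5L)   # parent + 2 LTR + 2 TSD
  expect_equal(sum(grepl("\ttarget_site_duplication\t", lines)), 2L)
  el2 <- read_elements_gff3(f)
  expect_equal(el2, el, tolerance = 1e-9, ignore_attr = TRUE)

  # solo-derived element without TSD: TSD children omitted
  el$tsd <- NA_character_
  write_elements_gff3(el, f)
  expect_equal(sum(grepl("target_site_duplication", readLines(f))), 0L)

  # ten random valid elements round-trip identically
  withr::with_seed(5, {
    n <- 10L
    s <- sort(sample.int(100000L, n)) * 3L
    els <- data.table(element_id = sprintf("E%02d", 1:n), seq_id = "chrZ",
                      start = s, end = s + 2000L,
                      ltr5_start = s, ltr5_end = s + 300L,
                      ltr3_start = s + 1700L, ltr3_end = s + 2000L,
                      tsd = replicate(n, fix_seq(5L, sample.int(1e6, 1))),
                      motif_ok = sample(c(TRUE, FALSE), n, replace = TRUE),
                      ltr_identity = round(runif(n, 0.9, 1), 6),
                      superfamily = sample(c("Copia", "Gypsy"), n, TRUE),
                      lineage = sample(c("SIRE", "CRM", "Tork"), n, TRUE))
  })
  write_elements_gff3(els, f)
  expect_equal(read_elements_gff3(f), els, tolerance = 1e-9,
               ignore_attr = TRUE)

  # child outside parent span is refused
  bad <- copy(el)
  bad$ltr3_end <- 800L
  expect_error(write_elements_gff3(bad), "outside|malformed")
})

test_that("CX report parses 1-based positions and validates context", {
  # reference with a CG at 0-based 4: positions 1..8 = A T C G C G A T
  g <- c(chr1 = "ATCGCGATT")
  f <- tempfile()
  writeLines("chr1\t5\t+\t3\t1\tCG\tCGA", f)
  calls <- read_cx_report(f, g)
  expect_equal(calls$pos, 4L)
  expect_equal(calls$context, "CG")
  expect_equal(calls$meth_count, 3L)
  expect_equal(calls$unmeth_count, 1L)

  # context contradiction is an error naming the position
  writeLines("chr1\t5\t+\t3\t1\tCHH\tCGA", f)
  expect_error(read_cx_report(f, g), "5")

  # zero-coverage cytosines are retained
  writeLines("chr1\t5\t+\t0\t0\tCG\tCGA", f)
  calls <- read_cx_report(f, g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$meth_count + calls$unmeth_count, 0L)
})

test_that("cytosine contexts are derived correctly on both strands", {
  # CCGG: pos0 C -> CGG? C at 0: next G? seq C C G G
  ctx <- ltrscape:::derive_contexts("CCGGA")
  # + strand: pos 0 (C, next C,G -> CHG), pos 1 (C, next G -> CG)
  plus <- ctx[strand == "+"]
  expect_equal(plus$pos, c(0L, 1L))
  expect_equal(plus$context, c("CHG", "CG"))
  # - strand: G at pos 2: 5'->3' on minus = comp(pos1)=G -> CG
  minus <- ctx[strand == "-"]
  expect_equal(minus$context[minus$pos == 2L], "CG")
  expect_equal(minus$context[minus$pos == 3L], "CHG")
})

test_that("repeat-hit tables read both dialects", {
  hits <- data.table(seq_id = "chr1", start = 100L, end = 400L, strand = ".",
                     consensus_id = "CONS_X", consensus_start = 0L,
                     consensus_end = 300L, identity = 0.93)
  f <- tempfile()
  write_repeat_hits(hits, f)
  expect_equal(read_repeat_hits(f), hits, ignore_attr = TRUE)

  # classic RepeatMasker .out dialect with 3-line header
  rm_lines <- c(
    "   SW   perc perc perc  query      position in query  matching repeat",
    "score   div. del. ins.  sequence   begin  end  (left)  repeat  class/family begin end (left) ID",
    "",
    "  239    7.0  0.0  0.0  chr1        101    400  (599) + CONS_X  LTR/Copia  1  300  (0)  1")
  writeLines(rm_lines, f)
  h2 <- read_repeat_hits(f)
  expect_equal(h2$start, 100L)
  expect_equal(h2$end, 400L)
  expect_equal(h2$consensus_id, "CONS_X")
  expect_equal(h2$identity, 0.93)
})

test_that("count tables round-trip and reject bad input", {
  m <- matrix(c(5L, 0L, 7L, 2L), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  f <- tempfile()
  write_counts(m, f)
  expect_identical(read_counts(f), m)
  writeLines(c("feature_id\ts1", "a\t1", "a\t2"), f)
  expect_error(read_counts(f), "duplicate")
})
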
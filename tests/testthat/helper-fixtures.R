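# shared fixture builders; everything is generated in code at test time

library(data.table)

# deterministic random sequence without touching the global RNG state
fix_seq <- function(n, seed = 1L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# minimal single-gene GFF3 written to a temp file; coords are 1-based GFF
write_tiny_gene_gff <- function(path, gene_start = 101L, gene_end = 200L,
                                strand = "+",
                                exons = list(c(101L, 140L), c(161L, 200L)),
                                extra_mrna = NULL) {
  lines <- c("##gff-version 3",
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=g1", gene_start, gene_end, strand),
    sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=m1;Parent=g1",
            gene_start, gene_end, strand),
    vapply(exons, function(e)
      sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tID=m1.e;Parent=m1",
              e[1], e[2], strand), character(1)))
  if (!is.null(lines) && !is.null(extra_mrna)) lines <- c(lines, extra_mrna)
  writeLines(lines, path)
  path
}

# one hand-built intact element embedded in background, with exact truth
make_manual_element <- function(ltr = "TG__CA", ltr_len = 120L, tsd = "GATCA",
                                internal_len = 300L, seed = 3L) {
  withr::with_seed(seed, {
    anc <- paste0("TG", fix_seq(ltr_len - 4L, seed + 1L), "CA")
    internal <- fix_seq(internal_len, seed + 2L)
    left_bg <- fix_seq(400L, seed + 3L)
    right_bg <- fix_seq(400L, seed + 4L)
    s <- paste0(left_bg, tsd, anc, internal, anc, tsd, right_bg)
    start <- 400L + nchar(tsd)
    list(genome = stats::setNames(s, "chr1"),
         start = start, end = start + 2L * ltr_len + internal_len,
         ltr5_start = start, ltr5_end = start + ltr_len,
         ltr3_start = start + ltr_len + internal_len,
         ltr3_end = start + 2L * ltr_len + internal_len,
         tsd = tsd, ltr = anc, internal = internal)
  })
}

# minimal in-memory gene_models object with one gene
simple_models <- function(gene_start = 20000L, gene_end = 23000L,
                          strand = "+",
                          exons = rbind(c(20000L, 21000L), c(22000L, 23000L))) {
  g <- data.table(gene_id = "g1", seq_id = "chr1", start = gene_start,
                  end = gene_end, strand = strand,
                  tss = if (strand == "-") gene_end - 1L else gene_start,
                  tts = if (strand == "-") gene_start else gene_end - 1L,
                  mrna_id = "g1.t1")
  ex <- data.table(gene_id = "g1", seq_id = "chr1",
                   start = as.integer(exons[, 1]), end = as.integer(exons[, 2]))
  intr <- ex[, .(seq_id = seq_id[-1L], start = end[-.N], end = start[-1L]),
             by = gene_id][end > start]
  structure(list(genes = g, exons = ex, introns = intr),
            class = "gene_models")
}

el_at <- function(start, end, id = "E1")
  data.table(element_id = id, seq_id = "chr1",
             start = as.integer(start), end = as.integer(end))

# brute-force per-base association oracle, independent of the package's
# interval logic: checks each region type base by base, then applies the
# exon > intron > promoter > downstream precedence per (gene, element) pair
oracle_associate <- function(el, genes, promoter_bp = 5000L,
                             downstream_bp = 5000L) {
  res <- list()
  bases <- function(a, b) if (b > a) seq.int(a, b - 1L) else integer(0)
  for (ei in seq_len(nrow(el))) {
    ebase <- bases(el$start[ei], el$end[ei])
    for (gi in seq_len(nrow(genes$genes))) {
      g <- genes$genes[gi]
      if (g$seq_id != el$seq_id[ei]) next
      ex <- genes$exons[gene_id == g$gene_id]
      exb <- unlist(lapply(seq_len(nrow(ex)), function(k)
        bases(ex$start[k], ex$end[k])))
      gb <- bases(g$start, g$end)
      inb <- setdiff(gb, exb)
      if (g$strand == "-") {
        prb <- bases(g$end, g$end + promoter_bp)
        dnb <- bases(max(0L, g$start - downstream_bp), g$start)
      } else {
        prb <- bases(max(0L, g$start - promoter_bp), g$start)
        dnb <- bases(g$end, g$end + downstream_bp)
      }
      cat_found <- NA_character_
      if (length(intersect(ebase, exb))) cat_found <- "exon"
      else if (length(intersect(ebase, inb))) cat_found <- "intron"
      else if (length(intersect(ebase, prb))) cat_found <- "promoter"
      else if (length(intersect(ebase, dnb))) cat_found <- "downstream"
      if (!is.na(cat_found))
        res[[length(res) + 1L]] <- data.table(
          gene_id = g$gene_id, element_id = el$element_id[ei],
          category = cat_found)
    }
  }
  if (length(res)) rbindlist(res)[order(gene_id, element_id)] else
    data.table(gene_id = character(0), element_id = character(0),
               category = character(0))
}

# brute-force metaprofile oracle: plain loops over features and cytosines
oracle_metaprofile <- function(calls, features, strata = NULL,
                               flank_bp = 2000L, bins_flank = 20L,
                               bins_body = 20L, min_cov = 4L) {
  cc <- as.data.table(calls)
  cc <- cc[meth_count + unmeth_count >= min_cov]
  ft <- as.data.table(features)
  if (!"strand" %in% names(ft)) ft[, strand := "."]
  acc <- new.env()
  add <- function(key, m, u) {
    cur <- acc[[key]]
    if (is.null(cur)) cur <- c(0, 0, 0)
    acc[[key]] <- cur + c(m, u, 1)
  }
  for (fi in seq_len(nrow(ft))) {
    f <- ft[fi]
    sk <- if (is.null(strata)) "all" else
      paste(unlist(f[, strata, with = FALSE]), collapse = "|")
    sub <- cc[seq_id == f$seq_id]
    for (ri in seq_len(nrow(sub))) {
      p <- sub$pos[ri]
      if (p >= f$start - flank_bp && p < f$start) {
        reg <- "upstream"; o <- p - (f$start - flank_bp); w <- flank_bp
        nb <- bins_flank
      } else if (p >= f$start && p < f$end) {
        reg <- "body"; o <- p - f$start; w <- f$end - f$start; nb <- bins_body
      } else if (p >= f$end && p < f$end + flank_bp) {
        reg <- "downstream"; o <- p - f$end; w <- flank_bp; nb <- bins_flank
      } else next
      if (f$strand == "-") {
        o <- w - 1L - o
        reg <- c(upstream = "downstream", body = "body",
                 downstream = "upstream")[reg]
      }
      b <- min(nb - 1L, floor(o / w * nb))
      if (reg != "body") b <- floor(o / (w / nb))
      add(paste(sk, sub$context[ri], reg, b, sep = "\r"),
          sub$meth_count[ri], sub$unmeth_count[ri])
    }
  }
  keys <- ls(acc)
  rbindlist(lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    v <- acc[[k]]
    data.table(stratum = parts[1], context = parts[2], region = parts[3],
               bin = as.integer(parts[4]),
               level = v[1] / (v[1] + v[2]), n_cytosines = as.integer(v[3]))
  }))
}
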
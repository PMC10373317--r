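#' Read gene models from GFF3
#'
#' Expects the usual gene -> mRNA -> exon hierarchy with `Parent` attributes.
#' One canonical transcript is kept per gene: the mRNA with the largest summed
#' exon length (tie: first in file). Introns are the gaps between sorted
#' exons. TSS and TTS are strand-aware single-base positions (0-based).
#'
#' @param path GFF3 file
#' @return a list of class `gene_models` with data.tables `genes`
#'   (gene_id, seq_id, start, end, strand, tss, tts, mrna_id), `exons` and
#'   `introns` (gene_id, seq_id, start, end); coordinates 0-based half-open
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  dt <- data.table(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,    # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = typ,
    id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  )
  genes <- dt[type == "gene"]
  mrnas <- dt[type == "mRNA"]
  exons <- dt[type == "exon"]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  if (any(is.na(genes$id))) stop("gene feature without ID attribute")

  orphan <- is.na(mrnas$parent) | !(mrnas$parent %in% genes$id)
  if (any(orphan)) {
    warning(sum(orphan), " mRNA feature(s) without a known Parent gene; skipped")
    mrnas <- mrnas[!orphan]
  }
  orphan <- is.na(exons$parent) | !(exons$parent %in% mrnas$id)
  if (any(orphan)) {
    warning(sum(orphan), " exon feature(s) without a known Parent mRNA; skipped")
    exons <- exons[!orphan]
  }
  # exon must lie inside its mRNA span
  ex <- merge(exons, mrnas[, .(id, m_start = start, m_end = end)],
              by.x = "parent", by.y = "id", sort = FALSE)
  if (any(ex$start < ex$m_start | ex$end > ex$m_end))
    stop("exon outside the span of its mRNA")

  # canonical transcript: largest summed exon length, tie -> first in file
  mrnas[, ord := .I]
  exlen <- exons[, .(tx_len = sum(end - start)), by = parent]
  mrnas <- merge(mrnas, exlen, by.x = "id", by.y = "parent", all.x = TRUE)
  mrnas[is.na(tx_len), tx_len := 0L]
  setorder(mrnas, ord)
  canon <- mrnas[, .SD[which.max(tx_len)], by = parent]

  g <- merge(genes[, .(gene_id = id, seq_id, start, end, strand)],
             canon[, .(parent, mrna_id = id)],
             by.x = "gene_id", by.y = "parent", all.x = TRUE, sort = FALSE)
  if (any(is.na(g$mrna_id))) stop("gene without mRNA/exons: ",
                                  paste(g$gene_id[is.na(g$mrna_id)], collapse = ", "))
  g[, tss := ifelse(strand == "-", end - 1L, start)]
  g[, tts := ifelse(strand == "-", start, end - 1L)]

  cex <- merge(exons[, .(mrna_id = parent, seq_id, start, end)],
               g[, .(gene_id, mrna_id)], by = "mrna_id", sort = FALSE)
  if (any(!g$gene_id %in% cex$gene_id))
    stop("gene without exons: ",
         paste(setdiff(g$gene_id, cex$gene_id), collapse = ", "))
  setorder(cex, gene_id, start)
  cex <- cex[, .(gene_id, seq_id, start, end)]
  introns <- cex[, {
    if (.N > 1L) .(seq_id = seq_id[-1L], start = end[-.N], end = start[-1L])
    else .(seq_id = character(0), start = integer(0), end = integer(0))
  }, by = gene_id]
  introns <- introns[end > start]
  structure(list(genes = g[], exons = cex[], introns = introns[]),
            class = "gene_models")
}

#' Write gene models to GFF3 (gene -> mRNA -> exon)
#'
#' @param models a `gene_models` object (as from [read_gff3_genes()])
#' @param path output file
#' @export
write_gff3_genes <- function(models, path) {
  g <- models$genes
  ex <- copy(models$exons)
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gi <- g[i]
    gex <- ex[gene_id == gi$gene_id]
    lines <- c(lines,
      sprintf("%s\tltrscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              gi$seq_id, gi$start + 1L, gi$end, gi$strand, gi$gene_id),
      sprintf("%s\tltrscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gi$seq_id, gi$start + 1L, gi$end, gi$strand, gi$mrna_id, gi$gene_id),
      sprintf("%s\tltrscape\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              gex$seq_id, gex$start + 1L, gex$end, gi$strand, gi$mrna_id,
              seq_len(nrow(gex)), gi$mrna_id))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---- intact-element GFF3 ----------------------------------------------------

elements_required_cols <- c("element_id", "seq_id", "start", "end",
                            "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")

check_element_table <- function(el) {
  miss <- setdiff(elements_required_cols, names(el))
  if (length(miss)) stop("element table missing columns: ",
                         paste(miss, collapse = ", "))
  with(el, {
    if (any(ltr5_start < start | ltr3_end > end))
      stop("LTR child outside parent element span")
    if (any(!(ltr5_start < ltr5_end & ltr5_end <= ltr3_start &
              ltr3_start < ltr3_end)))
      stop("malformed LTR coordinates within element")
  })
  invisible(el)
}

#' Write intact LTR-RT elements to GFF3
#'
#' Each element becomes a parent `LTR_retrotransposon` feature with two
#' `long_terminal_repeat` children and, when a TSD was found, two
#' `target_site_duplication` children flanking the element.
#'
#' @param elements element table (see [detect_ltr_elements()])
#' @param path output file
#' @export
write_elements_gff3 <- function(elements, path) {
  el <- as.data.table(elements)
  check_element_table(el)
  num <- function(x) ifelse(is.na(x), ".", sprintf("%.10g", x))
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(el))) {
    e <- el[i]
    attrs <- sprintf("ID=%s", e$element_id)
    if (!is.null(e$ltr_identity) && !is.na(e$ltr_identity))
      attrs <- paste0(attrs, ";ltr_identity=", sprintf("%.10g", e$ltr_identity))
    if (!is.null(e$motif_ok) && !is.na(e$motif_ok))
      attrs <- paste0(attrs, ";terminal_motif=", ifelse(e$motif_ok, "TG..CA", "none"))
    if (!is.null(e$superfamily) && !is.na(e$superfamily))
      attrs <- paste0(attrs, ";superfamily=", e$superfamily)
    if (!is.null(e$lineage) && !is.na(e$lineage))
      attrs <- paste0(attrs, ";lineage=", e$lineage)
    has_tsd <- !is.null(e$tsd) && !is.na(e$tsd) && nzchar(e$tsd)
    if (has_tsd) attrs <- paste0(attrs, ";tsd=", e$tsd)
    lines <- c(lines,
      sprintf("%s\tltrscape\tLTR_retrotransposon\t%d\t%d\t%s\t.\t.\t%s",
              e$seq_id, e$start + 1L, e$end, num(e$ltr_identity), attrs),
      sprintf("%s\tltrscape\tlong_terminal_repeat\t%d\t%d\t.\t.\t.\tParent=%s",
              e$seq_id, e$ltr5_start + 1L, e$ltr5_end, e$element_id),
      sprintf("%s\tltrscape\tlong_terminal_repeat\t%d\t%d\t.\t.\t.\tParent=%s",
              e$seq_id, e$ltr3_start + 1L, e$ltr3_end, e$element_id))
    if (has_tsd) {
      k <- nchar(e$tsd)
      lines <- c(lines,
        sprintf("%s\tltrscape\ttarget_site_duplication\t%d\t%d\t.\t.\t.\tParent=%s",
                e$seq_id, e$start - k + 1L, e$start, e$element_id),
        sprintf("%s\tltrscape\ttarget_site_duplication\t%d\t%d\t.\t.\t.\tParent=%s",
                e$seq_id, e$end + 1L, e$end + k, e$element_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read intact LTR-RT elements from GFF3 written by [write_elements_gff3()]
#'
#' @param path GFF3 file
#' @return element data.table (0-based half-open coordinates)
#' @export
read_elements_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  par <- gr[typ == "LTR_retrotransposon"]
  ltr <- gr[typ == "long_terminal_repeat"]
  if (length(par) == 0L)
    return(data.table(element_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      tsd = character(0), motif_ok = logical(0),
                      ltr_identity = numeric(0), superfamily = character(0),
                      lineage = character(0)))
  getm <- function(g, f) if (f %in% names(mcols(g))) as.character(mcols(g)[[f]])
                         else rep(NA_character_, length(g))
  ldt <- data.table(parent = vapply(as.list(ltr$Parent), `[[`, character(1), 1L),
                    start = GenomicRanges::start(ltr) - 1L,
                    end = GenomicRanges::end(ltr))
  setorder(ldt, parent, start)
  if (any(ldt[, .N, by = parent]$N != 2L))
    stop("element without exactly two long_terminal_repeat children")
  l5 <- ldt[, .SD[1L], by = parent]
  l3 <- ldt[, .SD[2L], by = parent]
  el <- data.table(
    element_id = as.character(par$ID),
    seq_id = as.character(GenomicRanges::seqnames(par)),
    start = GenomicRanges::start(par) - 1L,
    end = GenomicRanges::end(par),
    tsd = getm(par, "tsd"),
    motif_ok = getm(par, "terminal_motif") == "TG..CA",
    ltr_identity = suppressWarnings(as.numeric(getm(par, "ltr_identity"))),
    superfamily = getm(par, "superfamily"),
    lineage = getm(par, "lineage"))
  el <- merge(el, l5[, .(element_id = parent, ltr5_start = start, ltr5_end = end)],
              by = "element_id", sort = FALSE)
  el <- merge(el, l3[, .(element_id = parent, ltr3_start = start, ltr3_end = end)],
              by = "element_id", sort = FALSE)
  setcolorder(el, c(elements_required_cols,
                    "tsd", "motif_ok", "ltr_identity", "superfamily", "lineage"))
  check_element_table(el)
  el[]
}

#' Export elements as BED6
#'
#' Score is `round(1000 * ltr_identity)` (bedtools convention for a 0-1000
#' confidence score); strand is "." for LTR-RT elements.
#'
#' @param elements element table
#' @param path output file
#' @export
write_elements_bed <- function(elements, path) {
  el <- as.data.table(elements)
  score <- if ("ltr_identity" %in% names(el))
    as.integer(round(1000 * el$ltr_identity)) else 0L
  fwrite(data.table(el$seq_id, el$start, el$end, el$element_id, score, "."),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
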
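# LTR-RT / gene association and expression comparison.
#
# An element is associated with a gene when it overlaps (>= 1 bp) the gene's
# exons, introns, promoter (5 kb upstream of the TSS, strand-aware) or
# downstream region (5 kb past the TTS). When one (gene, element) pair
# overlaps several region types, precedence is exon > intron > promoter >
# downstream: inside-gene evidence outranks flanking evidence.

CATEGORY_LEVELS <- c("exon", "intron", "promoter", "downstream")

#' Associate elements with gene models
#'
#' @param elements element table (needs seq_id, start, end, element_id)
#' @param genes a `gene_models` object from [read_gff3_genes()]
#' @param promoter_bp promoter window upstream of the TSS
#' @param downstream_bp window past the TTS
#' @return data.table: gene_id, element_id, category; one row per
#'   (gene, element) pair
#' @export
associate_elements_genes <- function(elements, genes, promoter_bp = 5000L,
                                     downstream_bp = 5000L) {
  el <- as.data.table(elements)
  g <- genes$genes
  ex <- genes$exons
  intr <- genes$introns
  if (nrow(ex) == 0L) stop("gene set without exons")
  if (any(!g$gene_id %in% ex$gene_id))
    stop("gene without exons: ",
         paste(setdiff(g$gene_id, ex$gene_id), collapse = ", "))
  # strand-aware flanking windows; never extending into the gene body
  prom <- g[, .(gene_id, seq_id,
                start = ifelse(strand == "-", end, pmax(0L, start - promoter_bp)),
                end = ifelse(strand == "-", end + promoter_bp, start))]
  down <- g[, .(gene_id, seq_id,
                start = ifelse(strand == "-", pmax(0L, start - downstream_bp), end),
                end = ifelse(strand == "-", start, end + downstream_bp))]
  regions <- rbind(
    ex[, .(gene_id, seq_id, start, end, category = "exon")],
    if (nrow(intr)) intr[, .(gene_id, seq_id, start, end, category = "intron")],
    prom[end > start][, .(gene_id, seq_id, start, end, category = "promoter")],
    down[end > start][, .(gene_id, seq_id, start, end, category = "downstream")])
  if (nrow(el) == 0L || nrow(regions) == 0L)
    return(data.table(gene_id = character(0), element_id = character(0),
                      category = character(0)))
  ov <- findOverlaps(as_granges0(el[, .(seq_id, start, end, strand = ".")]),
                     as_granges0(regions[, .(seq_id, start, end, strand = ".")]),
                     ignore.strand = TRUE)
  if (length(ov) == 0L)
    return(data.table(gene_id = character(0), element_id = character(0),
                      category = character(0)))
  assoc <- data.table(element_id = el$element_id[queryHits(ov)],
                      gene_id = regions$gene_id[subjectHits(ov)],
                      category = regions$category[subjectHits(ov)])
  assoc[, category := factor(category, levels = CATEGORY_LEVELS)]
  assoc <- assoc[order(category), .SD[1L], by = .(gene_id, element_id)]
  assoc[, category := as.character(category)]
  setorder(assoc, gene_id, element_id)
  assoc[]
}

#' Transcripts per million
#'
#' rate_i = count_i / length_i(kb); TPM_i = rate_i / sum(rates) * 1e6,
#' per sample.
#'
#' @param counts feature x sample matrix
#' @param feature_lengths named vector of feature lengths in bp
#' @return TPM matrix of the same shape
#' @export
tpm <- function(counts, feature_lengths) {
  counts <- as.matrix(counts)
  len <- feature_lengths[rownames(counts)]
  if (any(is.na(len))) stop("missing feature length")
  if (any(len <= 0)) stop("feature lengths must be positive")
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) stop("sample with zero total rate")
  sweep(rate, 2L, tot, "/") * 1e6
}

#' Compare expression of an associated gene group against the whole gene set
#'
#' Welch two-sample t-test on log2(TPM + 1); TPM is averaged across
#' replicates first. The background is the entire gene set (including the
#' group). Direction is reported from the sign of the mean difference when
#' p < 0.05.
#'
#' @param associations output of [associate_elements_genes()]
#' @param tpm_table TPM matrix (genes x samples)
#' @param category one of exon/intron/promoter/downstream
#' @param alpha significance level for calling a direction
#' @return one-row data.table: category, n_genes, mean_group, mean_background,
#'   t_statistic, p_value, direction
#' @export
compare_expression <- function(associations, tpm_table, category,
                               alpha = 0.05) {
  assoc <- as.data.table(associations)
  stopifnot(category %in% CATEGORY_LEVELS)
  grp_genes <- unique(assoc$gene_id[assoc$category == category])
  if (length(grp_genes) < 2L) stop("fewer than 2 genes in group '", category, "'")
  if (!all(grp_genes %in% rownames(tpm_table)))
    stop("TPM missing for some associated genes")
  avg <- rowMeans(as.matrix(tpm_table))
  lg <- log2(avg + 1)
  gvals <- lg[grp_genes]
  bvals <- lg
  tt <- tryCatch(t.test(gvals, bvals, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {          # essentially constant data: no difference
    tstat <- 0; pval <- 1
  } else { tstat <- unname(tt$statistic); pval <- tt$p.value }
  dirn <- if (pval < alpha) {
    if (mean(gvals) < mean(bvals)) "lower" else "higher"
  } else "ns"
  data.table(category = category, n_genes = length(gvals),
             mean_group = mean(gvals), mean_background = mean(bvals),
             t_statistic = tstat, p_value = pval, direction = dirn)
}

#' Category-level association and expression summary
#'
#' @param associations association table
#' @param tpm_table TPM matrix
#' @return data.table with one row per category present (with >= 2 genes)
#' @export
expression_summary <- function(associations, tpm_table) {
  cats <- intersect(CATEGORY_LEVELS, unique(associations$category))
  rbindlist(lapply(cats, function(cc) {
    if (sum(associations$category == cc) < 2L) return(NULL)
    compare_expression(associations, tpm_table, cc)
  }))
}
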
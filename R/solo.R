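# Solo-LTR detection and solo:intact (S/I) ratio analysis.
#
# A solo LTR is the footprint of intra-element unequal recombination: a
# single LTR, no internal sequence, still flanked by the original TSD.
# Detection operates on repeat-annotation hits against LTR consensus
# sequences: hits must cover most of the consensus at >80% identity, lie
# away from any intact element's span, and carry an exact 4-6 bp TSD
# anchored at the hit boundaries.

#' Detect solo LTRs from repeat hits
#'
#' @param repeat_hits hit table (see [read_repeat_hits()])
#' @param intact_elements element table; their spans (and internal regions)
#'   define exclusion zones
#' @param genome genome sequence for flank extraction
#' @param consensus_lengths named integer vector of consensus lengths (e.g.
#'   `Biostrings::width` of the consensus FASTA); needed for the coverage
#'   rule
#' @param ltr_consensus_ids restrict to hits against these consensus ids
#'   (NULL: all hits are treated as LTR-consensus hits)
#' @param min_identity identity threshold (exclusive), default 0.80
#' @param min_coverage minimum fraction of the consensus covered by the hit
#' @param margin exclusion margin (bp) around intact elements
#' @param tsd_range TSD lengths searched, longest first
#' @param tsd_slack allowed offset of the TSD from the hit boundary (0 =
#'   flush anchoring)
#' @return list(solos = data.table, rejected = data.table with reasons)
#' @export
detect_solo_ltrs <- function(repeat_hits, intact_elements, genome,
                             consensus_lengths = NULL,
                             ltr_consensus_ids = NULL,
                             min_identity = 0.80, min_coverage = 0.80,
                             margin = 100L, tsd_range = c(4L, 6L),
                             tsd_slack = 0L) {
  hits <- as.data.table(repeat_hits)
  gc <- genome_chars(genome)
  if (!is.null(ltr_consensus_ids))
    hits <- hits[consensus_id %in% ltr_consensus_ids]
  el <- if (!is.null(intact_elements) && nrow(intact_elements))
    as.data.table(intact_elements) else NULL
  out <- list(); rej <- list()
  reject <- function(h, why)
    rej[[length(rej) + 1L]] <<- data.table(seq_id = h$seq_id, start = h$start,
                                           end = h$end, reason = why)
  tmax <- max(tsd_range); tmin <- min(tsd_range)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i]
    if (h$identity <= min_identity) { reject(h, "low_identity"); next }
    if (!is.null(consensus_lengths)) {
      clen <- consensus_lengths[h$consensus_id]
      if (is.na(clen)) { reject(h, "unknown_consensus"); next }
      if ((h$consensus_end - h$consensus_start) / clen < min_coverage) {
        reject(h, "low_coverage"); next
      }
    }
    if (!is.null(el)) {
      near <- el[seq_id == h$seq_id &
                 start - margin < h$end & end + margin > h$start]
      if (nrow(near)) { reject(h, "near_internal"); next }
    }
    s <- gc[[h$seq_id]]
    n <- nchar(s)
    if (h$start - tmin < 0L || h$end + tmin > n) { reject(h, "edge"); next }
    tsd <- NA_character_
    for (off in 0:tsd_slack) {
      for (kk in tmax:tmin) {
        ls <- h$start - off
        re <- h$end + off
        if (ls - kk < 0L || re + kk > n) next
        left <- substr(s, ls - kk + 1L, ls)
        right <- substr(s, re + 1L, re + kk)
        if (left == right && !grepl("N", left, fixed = TRUE)) { tsd <- left; break }
      }
      if (!is.na(tsd)) break
    }
    if (is.na(tsd)) { reject(h, "no_tsd"); next }
    cov <- if (!is.null(consensus_lengths))
      (h$consensus_end - h$consensus_start) / consensus_lengths[h$consensus_id]
    else NA_real_
    out[[length(out) + 1L]] <- data.table(
      seq_id = h$seq_id, start = h$start, end = h$end, strand = h$strand,
      consensus_id = h$consensus_id, identity = h$identity,
      consensus_coverage = cov, tsd = tsd)
  }
  solos <- if (length(out)) rbindlist(out) else
    data.table(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), consensus_id = character(0),
               identity = numeric(0), consensus_coverage = numeric(0),
               tsd = character(0))
  rejected <- if (length(rej)) rbindlist(rej) else
    data.table(seq_id = character(0), start = integer(0), end = integer(0),
               reason = character(0))
  setorder(solos, seq_id, start)
  list(solos = solos[], rejected = rejected[])
}

#' Solo:intact ratio
#'
#' @param n_solo,n_intact counts from the same genome (or tables, in which
#'   case rows are counted)
#' @param genome_id label carried through to the output
#' @return one-row data.table: genome_id, n_solo, n_intact, ratio,
#'   defined (FALSE when n_intact = 0)
#' @export
si_ratio <- function(n_solo, n_intact, genome_id = "genome") {
  if (is.data.frame(n_solo)) n_solo <- nrow(n_solo)
  if (is.data.frame(n_intact)) n_intact <- nrow(n_intact)
  data.table(genome_id = genome_id, n_solo = n_solo, n_intact = n_intact,
             ratio = if (n_intact > 0) n_solo / n_intact else NA_real_,
             defined = n_intact > 0)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y equal-length numeric vectors, n >= 3
#' @return list(r, p_value, n)
#' @export
correlate_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  r <- cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) == 1) 0 else 2 * pt(-abs(tt), df = n - 2)
  list(r = r, p_value = p, n = n)
}
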
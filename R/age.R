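# Insertion-time estimation from inter-LTR divergence.
#
# At insertion the two LTRs of an element are identical; they then diverge
# at twice the per-site substitution rate. The insertion time is
# T = K / (2 r), with K the (Jukes-Cantor corrected) divergence between the
# 5' and 3' LTR and r the substitution rate per site per year.

#' Divergence between the two LTRs of an element
#'
#' The LTRs are globally aligned with the same scoring used for detection
#' identity, so identity and K stay mutually consistent. Columns containing
#' a gap or N are excluded from the aligned sites. The raw mismatch fraction
#' p is corrected with Jukes-Cantor: K = -(3/4) ln(1 - 4p/3).
#'
#' @param ltr5_seq,ltr3_seq LTR sequences (character)
#' @return list: p (raw mismatch fraction), K (corrected divergence,
#'   NA when saturated), aligned_sites, flags (character vector, possibly
#'   empty; "saturated" when p >= 0.75, "short_alignment" when
#'   aligned_sites < 50)
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq) {
  if (!nzchar(ltr5_seq) || !nzchar(ltr3_seq)) stop("empty LTR sequence")
  aln <- align_pair(toupper(ltr5_seq), toupper(ltr3_seq))
  a <- strsplit(as.character(pattern(aln)), "", fixed = TRUE)[[1]]
  b <- strsplit(as.character(subject(aln)), "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  aligned_sites <- sum(ok)
  if (aligned_sites == 0L) stop("no aligned sites without gaps or Ns")
  p <- sum(a[ok] != b[ok]) / aligned_sites
  flags <- character(0)
  if (aligned_sites < 50L) flags <- c(flags, "short_alignment")
  if (p >= 0.75) {
    flags <- c(flags, "saturated")
    K <- NA_real_
  } else {
    K <- -0.75 * log(1 - 4 * p / 3)
  }
  list(p = p, K = K, aligned_sites = aligned_sites, flags = flags)
}

#' Insertion time from divergence
#'
#' T = K / (2 r), reported in million years (MY). The default rate is the
#' widely used plant synonymous substitution rate 1.3e-8 per site per year.
#'
#' @param K divergence in substitutions/site (scalar or vector)
#' @param rate substitution rate r per site per year
#' @return insertion time in MY
#' @export
insertion_time <- function(K, rate = 1.3e-8) {
  if (rate <= 0) stop("rate must be positive")
  if (any(K < 0, na.rm = TRUE)) stop("negative divergence")
  K / (2 * rate) / 1e6
}

#' Estimate insertion ages for a table of elements
#'
#' @param elements element table (from [detect_ltr_elements()] or
#'   [read_elements_gff3()])
#' @param genome the genome the coordinates refer to
#' @param rate substitution rate per site per year
#' @param correction "jc69" (default) or "raw" (use the uncorrected mismatch
#'   fraction as K)
#' @return data.table: element_id, p, K, T_MY, aligned_sites, flags
#' @export
estimate_ages <- function(elements, genome, rate = 1.3e-8,
                          correction = c("jc69", "raw")) {
  correction <- match.arg(correction)
  gc <- genome_chars(genome)
  el <- as.data.table(elements)
  rows <- lapply(seq_len(nrow(el)), function(i) {
    e <- el[i]
    s <- gc[[e$seq_id]]
    dv <- ltr_divergence(substr(s, e$ltr5_start + 1L, e$ltr5_end),
                         substr(s, e$ltr3_start + 1L, e$ltr3_end))
    Kuse <- if (correction == "raw") dv$p else dv$K
    data.table(element_id = e$element_id, p = dv$p, K = dv$K,
               T_MY = if (is.na(Kuse)) NA_real_ else insertion_time(Kuse, rate),
               aligned_sites = dv$aligned_sites,
               flags = paste(dv$flags, collapse = ","))
  })
  rbindlist(rows)
}

#' Summarise insertion-time distributions
#'
#' Reports per-genome (and, when lineages are supplied, per-lineage) mean
#' and median ages, a 0.1-MY-bin histogram, and the fraction of elements
#' inserted within the last 0.5 MY (the recent-burst statistic).
#'
#' @param ages data.table from [estimate_ages()] (needs T_MY)
#' @param lineages optional named character vector: element_id -> lineage
#' @param bin_my histogram bin width in MY
#' @return list: overall (data.table), histogram (data.table),
#'   by_lineage (data.table or NULL)
#' @export
age_summary <- function(ages, lineages = NULL, bin_my = 0.1) {
  dt <- as.data.table(ages)[!is.na(T_MY)]
  if (nrow(dt) == 0L) stop("no dated elements")
  overall <- dt[, .(n = .N, mean_MY = mean(T_MY), median_MY = median(T_MY),
                    frac_le_0.5 = mean(T_MY <= 0.5))]
  dt[, bin := floor(T_MY / bin_my)]
  histo <- dt[, .N, by = bin][order(bin)]
  histo[, `:=`(bin_start_MY = bin * bin_my, bin_end_MY = (bin + 1) * bin_my)]
  by_lineage <- NULL
  if (!is.null(lineages)) {
    dt[, lineage := lineages[element_id]]
    by_lineage <- dt[!is.na(lineage),
                     .(n = .N, mean_MY = mean(T_MY), median_MY = median(T_MY),
                       frac_le_0.5 = mean(T_MY <= 0.5)), by = lineage]
  }
  list(overall = overall, histogram = histo[], by_lineage = by_lineage)
}
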
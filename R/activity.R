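# Transcriptional-activity classification of LTR-RT elements.

#' Counts per million
#'
#' CPM_ij = count_ij / library_size_j * 1e6, library size = column sum.
#'
#' @param counts feature x sample count matrix
#' @return CPM matrix
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Call transcriptionally active elements
#'
#' An element is active when its mean CPM across replicates is strictly
#' greater than the threshold (default 1, the conventional expressed/silent
#' cut for TE read counts).
#'
#' @param cpm_matrix CPM matrix from [cpm()]
#' @param threshold activity threshold (strict inequality)
#' @return data.table: element_id, mean_cpm, active, plus one cpm_<sample>
#'   column per sample
#' @export
call_activity <- function(cpm_matrix, threshold = 1.0) {
  m <- as.matrix(cpm_matrix)
  if (ncol(m) < 1L) stop("need at least one sample")
  out <- data.table(element_id = rownames(m), mean_cpm = rowMeans(m))
  for (j in seq_len(ncol(m)))
    out[, (paste0("cpm_", colnames(m)[j])) := m[, j]]
  out[, active := mean_cpm > threshold]
  out[]
}

#' Compare length and age between active and silent elements
#'
#' Welch t-tests of element length (bp) and insertion age (MY) between the
#' transcriptionally active and silent groups.
#'
#' @param elements element table (seq_id, start, end, element_id)
#' @param ages ages table from [estimate_ages()] (element_id, T_MY)
#' @param activity activity calls from [call_activity()]
#' @param alpha significance level for calling a direction
#' @return data.table with one row per variable (length, age): group means,
#'   t statistic, p value, and direction ("active_lower"/"active_higher"/"ns")
#' @export
compare_active_silent <- function(elements, ages, activity, alpha = 0.05) {
  el <- as.data.table(elements)[, .(element_id, len = end - start)]
  dt <- merge(el, as.data.table(ages)[, .(element_id, T_MY)],
              by = "element_id")
  dt <- merge(dt, as.data.table(activity)[, .(element_id, active)],
              by = "element_id")
  one <- function(vals, name) {
    a <- vals[dt$active]; s <- vals[!dt$active]
    a <- a[!is.na(a)]; s <- s[!is.na(s)]
    if (length(a) < 2L || length(s) < 2L)
      stop("need >= 2 elements per activity group")
    tt <- t.test(a, s, var.equal = FALSE)
    data.table(variable = name,
               n_active = length(a), n_silent = length(s),
               mean_active = mean(a), median_active = median(a),
               mean_silent = mean(s), median_silent = median(s),
               t_statistic = unname(tt$statistic), p_value = tt$p.value,
               direction = if (tt$p.value < alpha) {
                 if (mean(a) < mean(s)) "active_lower" else "active_higher"
               } else "ns")
  }
  rbind(one(dt$len, "length_bp"), one(dt$T_MY, "age_MY"))
}
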
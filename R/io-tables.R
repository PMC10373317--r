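# Tabular I/O: repeat-hit tables (RepeatMasker .out dialect or native TSV),
# count tables, and protein-domain hit tables.

#' Read a repeat-annotation hit table
#'
#' Two dialects are accepted and auto-detected from the first line:
#' the classic RepeatMasker `.out` format (3-line header, whitespace
#' delimited, 1-based inclusive coordinates, divergence as a percentage),
#' or the package's native headerless TSV
#' (seq_id, start, end, strand, consensus_id, consensus_start, consensus_end,
#' identity; 0-based half-open, identity in [0,1]).
#'
#' @param path hit-table file
#' @return data.table: seq_id, start, end, strand, consensus_id,
#'   consensus_start, consensus_end, identity (all 0-based half-open)
#' @export
read_repeat_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*(SW|score)", first)) {
    lines <- readLines(path)
    lines <- lines[-seq_len(min(3L, length(lines)))]
    lines <- lines[nzchar(trimws(lines))]
    f <- strsplit(trimws(lines), "\\s+")
    hits <- rbindlist(lapply(f, function(x) {
      strandc <- x[9]
      rpos <- suppressWarnings(as.integer(gsub("[()]", "", x[12:14])))
      # for C-strand hits the consensus columns are permuted; the two
      # non-parenthesised values always bound the matched consensus region
      paren <- grepl("\\(", x[12:14])
      rr <- sort(rpos[!paren])[1:2]
      data.table(seq_id = x[5],
                 start = as.integer(x[6]) - 1L, end = as.integer(x[7]),
                 strand = ifelse(strandc == "C", "-", "+"),
                 consensus_id = x[10],
                 consensus_start = rr[1] - 1L, consensus_end = rr[2],
                 identity = (100 - as.numeric(x[2])) / 100)
    }))
  } else {
    hits <- fread(path, header = FALSE, sep = "\t",
                  col.names = c("seq_id", "start", "end", "strand",
                                "consensus_id", "consensus_start",
                                "consensus_end", "identity"))
    hits[, `:=`(seq_id = as.character(seq_id), start = as.integer(start),
                end = as.integer(end), consensus_start = as.integer(consensus_start),
                consensus_end = as.integer(consensus_end))]
  }
  if (any(hits$identity < 0 | hits$identity > 1))
    stop("repeat-hit identity outside [0,1]")
  if (any(hits$consensus_start >= hits$consensus_end))
    stop("repeat hit with consensus_start >= consensus_end")
  validate_intervals(hits)
  hits[]
}

#' Write repeat hits in the native TSV dialect
#' @param hits data.table as from [read_repeat_hits()]
#' @param path output file
#' @export
write_repeat_hits <- function(hits, path) {
  fwrite(as.data.table(hits)[, .(seq_id, start, end, strand, consensus_id,
                                 consensus_start, consensus_end, identity)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a feature x sample count table
#'
#' TSV with a header line: first column feature id, one column per sample.
#'
#' @param path counts file
#' @return integer matrix, rownames = feature ids
#' @export
read_counts <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in count table")
  m <- as.matrix(dt[, -1L, with = FALSE])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0L)) stop("counts must be non-negative integers")
  rownames(m) <- ids
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with rownames
#' @param path output file
#' @param id_col name of the feature-id column
#' @export
write_counts <- function(counts, path, id_col = "feature_id") {
  dt <- data.table(feature_id = rownames(counts))
  setnames(dt, "feature_id", id_col)
  fwrite(cbind(dt, as.data.table(counts)), path, sep = "\t")
  invisible(path)
}

#' Read a protein-domain hit table
#'
#' TSV with header: element_id, domain, start, end and an optional lineage
#' column. Positions are relative to the element's internal region (0-based
#' half-open).
#'
#' @param path domain-hit file
#' @return data.table
#' @export
read_domain_hits <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  need <- c("element_id", "domain", "start", "end")
  if (!all(need %in% names(dt)))
    stop("domain-hit table must have columns: ", paste(need, collapse = ", "))
  if (!"lineage" %in% names(dt)) dt[, lineage := NA_character_]
  dt[]
}

#' Write a protein-domain hit table
#' @param hits data.table with element_id, domain, start, end, lineage
#' @param path output file
#' @export
write_domain_hits <- function(hits, path) {
  fwrite(as.data.table(hits), path, sep = "\t")
  invisible(path)
}
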
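# Coordinate conventions
#
# All coordinates inside the package are 0-based, half-open [start, end).
# GFF3 and CX-report I/O is 1-based (their standards); the conversion happens
# exactly once, inside the reader/writer concerned.

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open. Strand is "+", "-" or "." (repeats and
#' LTR-RT elements carry "." because both LTRs lie on the same, unresolved
#' strand).
#'
#' @param seq_id character vector of sequence names
#' @param start 0-based inclusive start
#' @param end exclusive end
#' @param strand "+", "-" or "."; recycled
#' @return a `data.table` with columns seq_id, start, end, strand
#' @export
genomic_interval <- function(seq_id, start, end, strand = ".") {
  dt <- data.table(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand)
  validate_intervals(dt)
  dt
}

validate_intervals <- function(dt, seqlens = NULL) {
  if (any(is.na(dt$start)) || any(is.na(dt$end)))
    stop("interval with NA coordinates")
  if (any(dt$start < 0L)) stop("interval start < 0")
  if (any(dt$start >= dt$end)) stop("interval with start >= end")
  if (!all(dt$strand %in% c("+", "-", "."))) stop("invalid strand")
  if (!is.null(seqlens)) {
    len <- seqlens[dt$seq_id]
    if (any(is.na(len))) stop("interval on unknown sequence")
    if (any(dt$end > len)) stop("interval beyond sequence end")
  }
  invisible(dt)
}

# IRanges view of 0-based half-open intervals (1-based closed internally)
as_iranges0 <- function(start, end) IRanges(start = start + 1L, end = end)

# GRanges view of an interval table
as_granges0 <- function(dt) {
  GRanges(dt$seq_id, as_iranges0(dt$start, dt$end),
          strand = ifelse(dt$strand == ".", "*", dt$strand))
}

# extract [start, end) from a character-mode genome (named list or vector)
seq_window <- function(seqchar, start, end) {
  substr(seqchar, start + 1L, end)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
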
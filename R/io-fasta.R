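#' Read a genome FASTA file
#'
#' Sequences are uppercased on read; soft-masked (lowercase) stretches are
#' retained as a mask attached to the result, so masking information is not
#' lost but never silently alters sequence comparisons.
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet]; `S4Vectors::metadata(x)$mask` is a
#'   named list of `IRanges` (1-based) giving the soft-masked stretches of
#'   each sequence
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA: ", path)
  # FASTA descriptions: id = first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chr <- as.character(raw)
  mask <- lapply(chr, function(s) {
    m <- gregexpr("[acgtn]+", s)[[1]]
    if (m[1] == -1L) return(IRanges())
    IRanges(start = as.integer(m), width = attr(m, "match.length"))
  })
  names(mask) <- ids
  up <- toupper(chr)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  out <- DNAStringSet(up)
  names(out) <- ids
  S4Vectors::metadata(out)$mask <- mask
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or `DNAStringSet`
#' @param path output file
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

# genome as named character vector (fast substr access); accepts DNAStringSet,
# named character, or a path
genome_chars <- function(genome) {
  if (is(genome, "DNAStringSet")) return(setNames(as.character(genome), names(genome)))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTN]+$", genome))
    return(genome_chars(read_genome_fasta(genome)))
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome character vector must be named")
    return(toupper(genome))
  }
  stop("unsupported genome representation")
}
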
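# Bismark-style CX report I/O and cytosine-context derivation.
#
# Plant methylation contexts: CG, CHG, CHH with H = A, T or C, read 5'->3'
# on the strand of the cytosine.

# contexts of every cytosine in one sequence; returns 0-based positions
derive_contexts <- function(seqchar) {
  ch <- strsplit(seqchar, "", fixed = TRUE)[[1]]
  n <- length(ch)
  ctx_of <- function(b1, b2) {
    # b1, b2: next two bases 5'->3' on the cytosine's strand
    ifelse(b1 == "G", "CG",
      ifelse(b1 %in% c("A", "T", "C") & b2 == "G", "CHG",
        ifelse(b1 %in% c("A", "T", "C") & b2 %in% c("A", "T", "C"),
               "CHH", NA_character_)))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # plus strand: C at i (1-based), needs i+1, i+2
  ip <- which(ch == "C")
  ip <- ip[ip + 2L <= n]
  plus <- data.table(pos = ip - 1L, strand = "+",
                     context = ctx_of(ch[ip + 1L], ch[ip + 2L]),
                     tri = paste0(ch[ip], ch[ip + 1L], ch[ip + 2L]))
  # minus strand: G at i; next bases 5'->3' on minus strand are comp(i-1), comp(i-2)
  im <- which(ch == "G")
  im <- im[im - 2L >= 1L]
  minus <- data.table(pos = im - 1L, strand = "-",
                      context = ctx_of(comp[ch[im - 1L]], comp[ch[im - 2L]]),
                      tri = paste0(comp[ch[im]], comp[ch[im - 1L]], comp[ch[im - 2L]]))
  out <- rbind(plus, minus)
  out <- out[!is.na(context)]
  setorder(out, pos, strand)
  out[]
}

# context table for a whole genome: seq_id, pos, strand, context, tri
genome_contexts <- function(genome) {
  gc <- genome_chars(genome)
  rbindlist(lapply(names(gc), function(sid)
    cbind(seq_id = sid, derive_contexts(gc[[sid]]))))
}

#' Read a Bismark-style CX report
#'
#' Tab-separated columns: sequence, 1-based position, strand, methylated
#' count, unmethylated count, context (CG/CHG/CHH), trinucleotide. Positions
#' are converted to 0-based. Each line's context is re-derived from the
#' reference and a contradiction is an error (it indicates a genome/report
#' mismatch). Zero-coverage cytosines are retained; coverage filtering is
#' applied later, at the methylation-level computation stage.
#'
#' @param path CX report file
#' @param genome reference the calls were made against (`DNAStringSet`,
#'   named character vector, or FASTA path); NULL skips the cross-check
#' @return data.table: seq_id, pos (0-based), strand, context, meth_count,
#'   unmeth_count
#' @export
read_cx_report <- function(path, genome = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("seq_id", "pos1", "strand", "meth_count",
                            "unmeth_count", "context", "tri"))
  if (!all(dt$strand %in% c("+", "-"))) stop("invalid strand in CX report")
  if (!all(dt$context %in% c("CG", "CHG", "CHH")))
    stop("invalid context in CX report")
  calls <- dt[, .(seq_id = as.character(seq_id), pos = as.integer(pos1) - 1L,
                  strand, context,
                  meth_count = as.integer(meth_count),
                  unmeth_count = as.integer(unmeth_count))]
  if (any(calls$meth_count < 0L | calls$unmeth_count < 0L))
    stop("negative counts in CX report")
  if (!is.null(genome)) {
    ref <- genome_contexts(genome)
    m <- merge(calls, ref[, .(seq_id, pos, strand, ref_context = context)],
               by = c("seq_id", "pos", "strand"), all.x = TRUE, sort = FALSE)
    bad <- which(is.na(m$ref_context) | m$ref_context != m$context)
    if (length(bad)) {
      b <- m[bad[1L]]
      stop(sprintf(
        "CX context mismatch at %s:%d(%s): file says %s, reference says %s",
        b$seq_id, b$pos + 1L, b$strand, b$context,
        ifelse(is.na(b$ref_context), "no cytosine", b$ref_context)))
    }
  }
  calls[]
}

#' Write cytosine calls as a Bismark-style CX report
#'
#' @param calls data.table as from [read_cx_report()]; an optional `tri`
#'   column supplies the trinucleotide, otherwise it is derived from `genome`
#' @param path output file
#' @param genome reference used to fill trinucleotides when absent
#' @export
write_cx_report <- function(calls, path, genome = NULL) {
  dt <- as.data.table(calls)
  if (!"tri" %in% names(dt)) {
    if (is.null(genome)) stop("need genome to derive trinucleotides")
    ref <- genome_contexts(genome)
    dt <- merge(dt, ref[, .(seq_id, pos, strand, tri)],
                by = c("seq_id", "pos", "strand"), all.x = TRUE, sort = FALSE)
  }
  fwrite(dt[, .(seq_id, pos + 1L, strand, meth_count, unmeth_count, context, tri)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}
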
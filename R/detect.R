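# Structural detection of intact LTR retrotransposons.
#
# Strategy: exact k-mer seed matches on the same strand are grouped by
# diagonal and chained; each chain is extended by X-drop into a maximal
# near-identical block pair (the two candidate LTRs); pairs passing the
# length, spacing and identity rules are validated for the TG...CA terminal
# motif and an exact 4-6 bp target site duplication, with a small joint
# boundary-refinement search mirroring how micro-structure evidence is used
# to polish LTR boundaries.

#' Detection parameters
#'
#' @param k seed k-mer length
#' @param max_chain_gap maximum gap (bp) between chained seeds on a diagonal
#' @param min_ltr,max_ltr LTR length bounds (bp)
#' @param min_internal,max_internal internal-region length bounds (bp)
#' @param min_identity minimum global pairwise identity of the two LTRs
#' @param xdrop X-drop threshold for block extension (score units; match +1,
#'   mismatch -1)
#' @param max_kmer_occ seeds occurring more often than this are skipped
#'   (high-copy repeats)
#' @param refine_bp half-width of the joint boundary-refinement window used
#'   when searching for the terminal motif and TSD
#' @param tsd_range TSD lengths searched, longest first
#' @param strict require both TSD and TG...CA motif (lenient: TSD only)
#' @param allow_nested keep candidates nested inside accepted elements
#' @return list of parameters
#' @export
detect_params <- function(k = 20L, max_chain_gap = 50L,
                          min_ltr = 100L, max_ltr = 7000L,
                          min_internal = 200L, max_internal = 15000L,
                          min_identity = 0.90, xdrop = 12L,
                          max_kmer_occ = 20L, refine_bp = 25L,
                          tsd_range = c(4L, 6L), strict = TRUE,
                          allow_nested = FALSE) {
  as.list(environment())
}

# alignment scoring shared by detection identity and divergence estimation
ALN_MAT <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
align_pair <- function(a, b) {
  pairwiseAlignment(DNAStringSet(a), DNAStringSet(b), type = "global",
                    substitutionMatrix = ALN_MAT,
                    gapOpening = 4, gapExtension = 1)
}

# global identity = matches / alignment columns (gaps included)
pair_identity <- function(a, b) {
  aln <- align_pair(a, b)
  nmatch(aln) / nchar(as.character(pattern(aln)))
}

# X-drop extension over the match indicator m (logical, in extension order);
# returns the number of positions to keep
xdrop_extend <- function(m, xdrop) {
  if (length(m) == 0L) return(0L)
  sc <- cumsum(ifelse(m, 1L, -1L))
  run_max <- cummax(sc)
  stopat <- which(run_max - sc >= xdrop)
  lim <- if (length(stopat)) stopat[1L] else length(m)
  if (lim == 0L) return(0L)
  best <- which.max(sc[seq_len(lim)])
  if (sc[best] <= 0L) 0L else best
}

#' Find candidate LTR pairs in a genome
#'
#' @param genome DNAStringSet, named character vector or FASTA path
#' @param params [detect_params()]
#' @return data.table of candidate pairs: seq_id, ltr5_start, ltr5_end,
#'   ltr3_start, ltr3_end (0-based half-open), ltr_identity
#' @export
find_ltr_pairs <- function(genome, params = detect_params()) {
  gc <- genome_chars(genome)
  out <- rbindlist(lapply(names(gc), function(sid)
    find_ltr_pairs_one(gc[[sid]], sid, params)))
  if (nrow(out) == 0L)
    out <- data.table(seq_id = character(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), ltr_identity = numeric(0))
  out[]
}

find_ltr_pairs_one <- function(s, sid, p) {
  n <- nchar(s)
  empty <- data.table(seq_id = character(0), ltr5_start = integer(0),
                      ltr5_end = integer(0), ltr3_start = integer(0),
                      ltr3_end = integer(0), ltr_identity = numeric(0))
  if (n < 2L * p$min_ltr + p$min_internal) return(empty)
  k <- p$k
  st <- seq_len(n - k + 1L)
  km <- substring(s, st, st + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  dt <- data.table(pos = st[keep], kmer = km[keep])
  dt <- dt[, if (.N >= 2L && .N <= p$max_kmer_occ) .(pos = pos), by = kmer]
  if (nrow(dt) == 0L) return(empty)
  d_min <- p$min_ltr + p$min_internal
  d_max <- p$max_ltr + p$max_internal
  seeds <- dt[, {
    pp <- sort(pos)
    if (length(pp) > 1L) {
      cb <- utils::combn(pp, 2L)
      .(i = cb[1L, ], j = cb[2L, ])
    } else .(i = integer(0), j = integer(0))
  }, by = kmer]
  seeds[, diag := j - i]
  seeds <- seeds[diag >= d_min & diag <= d_max]
  if (nrow(seeds) == 0L) return(empty)
  setorder(seeds, diag, i)
  brk <- c(TRUE, diff(seeds$diag) != 0L | diff(seeds$i) > p$max_chain_gap + k)
  seeds[, chain := cumsum(brk)]
  chains <- seeds[, .(a0 = min(i) - 1L, a1 = max(i) + k - 1L, d = diag[1L]),
                  by = chain]

  rw <- charToRaw(s)
  cand <- vector("list", nrow(chains))
  for (ci in seq_len(nrow(chains))) {
    a0 <- chains$a0[ci]; a1 <- chains$a1[ci]; d <- chains$d[ci]
    # left extension: compare s[a0 - t] with s[a0 + d - t], t = 1..
    lmax <- min(a0, p$max_ltr - (a1 - a0) + p$refine_bp)
    if (lmax > 0L) {
      idx <- a0 - seq_len(lmax)
      m <- rw[idx + 1L] == rw[idx + d + 1L]
      a0 <- a0 - xdrop_extend(m, p$xdrop)
    }
    # right extension: compare s[a1 + t] with s[a1 + d + t]
    rmax <- min(n - (a1 + d), a0 + d - a1,            # keep blocks disjoint
                p$max_ltr - (a1 - a0) + p$refine_bp)
    if (rmax > 0L) {
      idx <- a1 + seq_len(rmax) - 1L
      m <- rw[idx + 1L] == rw[idx + d + 1L]
      a1 <- a1 + xdrop_extend(m, p$xdrop)
    }
    llen <- a1 - a0
    ilen <- d - llen
    if (llen < p$min_ltr || llen > p$max_ltr) next
    if (ilen < p$min_internal || ilen > p$max_internal) next
    cand[[ci]] <- data.table(a0 = a0, a1 = a1, d = d)
  }
  cand <- rbindlist(cand)
  if (nrow(cand) == 0L) return(empty)
  cand <- unique(cand)
  # chains split by seed gaps converge after extension; collapse overlapping
  # same-diagonal candidates to one
  setorder(cand, d, a0, -a1)
  cand <- cand[, {
    keep <- rep(TRUE, .N)
    if (.N > 1L) for (ii in 2:.N)
      if (a0[ii] <= max(a1[seq_len(ii - 1L)][keep[seq_len(ii - 1L)]])) keep[ii] <- FALSE
    .SD[keep]
  }, by = d]
  res <- cand[, {
    idt <- vapply(seq_len(.N), function(ii)
      pair_identity(substr(s, a0[ii] + 1L, a1[ii]),
                    substr(s, a0[ii] + d[ii] + 1L, a1[ii] + d[ii])),
      numeric(1))
    .(ltr5_start = a0, ltr5_end = a1, ltr3_start = a0 + d, ltr3_end = a1 + d,
      ltr_identity = idt)
  }]
  res <- res[ltr_identity >= p$min_identity]
  if (nrow(res) == 0L) return(empty)
  cbind(seq_id = sid, res)
}

#' Validate a candidate LTR pair into an intact element
#'
#' Checks the TG...CA terminal motif and an exact 4-6 bp TSD (searched
#' longest-first) immediately flanking the element, jointly refining both
#' LTR boundaries within a small window so that micro-structure evidence can
#' polish the alignment-derived boundaries. Strict mode (default) requires
#' both TSD and motif; lenient mode requires only the TSD.
#'
#' @param pair one row of [find_ltr_pairs()] output (or a list with the same
#'   fields)
#' @param genome genome the pair was found in
#' @param params [detect_params()]
#' @return a one-row element data.table, or NULL with attribute-free
#'   rejection recorded via the `reason` attribute of NULL being unavailable;
#'   use [validate_elements()] for tabulated rejections
#' @export
validate_element <- function(pair, genome, params = detect_params()) {
  gc <- genome_chars(genome)
  s <- gc[[pair$seq_id]]
  n <- nchar(s)
  r <- params$refine_bp
  tmax <- max(params$tsd_range); tmin <- min(params$tsd_range)
  # edge: no room for even the shortest TSD at zero offset
  if (pair$ltr5_start - tmin < 0L || pair$ltr3_end + tmin > n)
    return(structure(list(reason = "edge"), class = "ltr_rejection"))
  if (params$strict) {
    # motif-anchored refinement: both LTR copies of a genuine element carry
    # the TG start and CA end, which pins the boundary offsets far more
    # strongly than the alignment extension alone
    cand_s <- (-r):r
    cand_s <- cand_s[vapply(cand_s, function(o) {
      s1 <- pair$ltr5_start + o; s2 <- pair$ltr3_start + o
      s1 >= 0L && substr(s, s1 + 1L, s1 + 2L) == "TG" &&
        substr(s, s2 + 1L, s2 + 2L) == "TG"
    }, logical(1))]
    cand_e <- (-r):r
    cand_e <- cand_e[vapply(cand_e, function(o) {
      e1 <- pair$ltr5_end + o; e2 <- pair$ltr3_end + o
      e2 <= n && substr(s, e1 - 1L, e1) == "CA" &&
        substr(s, e2 - 1L, e2) == "CA"
    }, logical(1))]
    if (length(cand_s) == 0L || length(cand_e) == 0L)
      return(structure(list(reason = "no_motif"), class = "ltr_rejection"))
    offs <- CJ(o_s = cand_s, o_e = cand_e)
  } else {
    w <- min(r, 10L)
    offs <- CJ(o_s = (-w):w, o_e = (-w):w)
  }
  offs <- offs[order(abs(o_s) + abs(o_e), abs(o_s), abs(o_e))]
  for (oi in seq_len(nrow(offs))) {
    o_s <- offs$o_s[oi]; o_e <- offs$o_e[oi]
    s1 <- pair$ltr5_start + o_s; e1 <- pair$ltr5_end + o_e
    s2 <- pair$ltr3_start + o_s; e2 <- pair$ltr3_end + o_e
    llen <- e1 - s1
    if (llen < params$min_ltr || llen > params$max_ltr) next
    if (s1 - tmin < 0L || e2 + tmin > n) next
    motif_ok <- substr(s, s1 + 1L, s1 + 2L) == "TG" &&
                substr(s, e2 - 1L, e2) == "CA"
    if (params$strict && !motif_ok) next
    tsd <- NA_character_
    for (kk in tmax:tmin) {
      if (s1 - kk < 0L || e2 + kk > n) next
      left <- substr(s, s1 - kk + 1L, s1)
      right <- substr(s, e2 + 1L, e2 + kk)
      if (left == right && !grepl("N", left, fixed = TRUE)) { tsd <- left; break }
    }
    if (is.na(tsd)) next
    idt <- pair_identity(substr(s, s1 + 1L, e1), substr(s, s2 + 1L, e2))
    if (idt < params$min_identity) next
    return(data.table(
      seq_id = pair$seq_id, start = s1, end = e2,
      ltr5_start = s1, ltr5_end = e1, ltr3_start = s2, ltr3_end = e2,
      tsd = tsd, motif_ok = motif_ok, ltr_identity = idt))
  }
  structure(list(reason = if (params$strict) "no_tsd_or_motif" else "no_tsd"),
            class = "ltr_rejection")
}

#' Validate all candidate pairs and resolve overlaps
#'
#' Overlapping validated candidates are resolved greedily by descending
#' identity, then element length; accepted elements mask their span unless
#' `allow_nested` is set.
#'
#' @param pairs output of [find_ltr_pairs()]
#' @param genome the genome
#' @param params [detect_params()]
#' @return list(elements = data.table, rejections = data.table of reasons)
#' @export
validate_elements <- function(pairs, genome, params = detect_params()) {
  pairs <- as.data.table(pairs)
  els <- list(); rej <- list()
  for (i in seq_len(nrow(pairs))) {
    v <- validate_element(pairs[i], genome, params)
    if (inherits(v, "ltr_rejection"))
      rej[[length(rej) + 1L]] <- data.table(seq_id = pairs$seq_id[i],
                                            ltr5_start = pairs$ltr5_start[i],
                                            reason = v$reason)
    else els[[length(els) + 1L]] <- v
  }
  els <- rbindlist(els)
  rej <- if (length(rej)) rbindlist(rej) else
    data.table(seq_id = character(0), ltr5_start = integer(0),
               reason = character(0))
  if (nrow(els)) {
    els <- unique(els, by = c("seq_id", "start", "end"))
    els[, len := end - start]
    setorder(els, -ltr_identity, -len)
    keep <- logical(nrow(els))
    accepted <- data.table(seq_id = character(0), start = integer(0),
                           end = integer(0))
    for (i in seq_len(nrow(els))) {
      ov <- accepted[seq_id == els$seq_id[i] &
                     start < els$end[i] & end > els$start[i]]
      if (nrow(ov) == 0L || params$allow_nested) {
        keep[i] <- TRUE
        accepted <- rbind(accepted, els[i, .(seq_id, start, end)])
      }
    }
    els <- els[keep]
    els[, len := NULL]
    setorder(els, seq_id, start)
  }
  list(elements = els, rejections = rej)
}

#' Detect intact LTR-RT elements end to end
#'
#' Runs seed-and-extend pair finding, micro-structure validation, overlap
#' resolution, element naming, and (when domain hits are supplied)
#' superfamily and lineage classification.
#'
#' @param genome DNAStringSet, named character vector or FASTA path
#' @param domain_hits optional protein-domain hit table with genomic
#'   coordinates (columns seq_id, gstart, gend, domain, lineage)
#' @param params [detect_params()]
#' @return element data.table with superfamily/lineage columns
#' @export
detect_ltr_elements <- function(genome, domain_hits = NULL,
                                params = detect_params()) {
  pairs <- find_ltr_pairs(genome, params)
  v <- validate_elements(pairs, genome, params)
  els <- v$elements
  if (nrow(els) == 0L) {
    els[, `:=`(element_id = character(0), superfamily = character(0),
               lineage = character(0), lineage_conflict = logical(0))]
    setcolorder(els, c("element_id"))
    return(els[])
  }
  els[, element_id := sprintf("LTRRT_%04d", seq_len(.N))]
  els[, superfamily := "Unknown"]
  els[, lineage := NA_character_]
  els[, lineage_conflict := FALSE]
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    dh <- as.data.table(domain_hits)
    if (!all(c("seq_id", "gstart", "gend") %in% names(dh)))
      stop("domain_hits need genomic coordinates (seq_id, gstart, gend)")
    for (i in seq_len(nrow(els))) {
      e <- els[i]
      hits <- dh[seq_id == e$seq_id & gstart >= e$ltr5_end & gend <= e$ltr3_start]
      if (nrow(hits) == 0L) next
      setorder(hits, gstart)
      sf <- classify_superfamily(hits[, .(domain, start = gstart)])
      lin <- assign_lineage(hits, sf)
      els[i, `:=`(superfamily = sf, lineage = lin$lineage,
                  lineage_conflict = lin$conflict)]
    }
  }
  setcolorder(els, c("element_id", "seq_id", "start", "end", "ltr5_start",
                     "ltr5_end", "ltr3_start", "ltr3_end", "tsd", "motif_ok",
                     "ltr_identity", "superfamily", "lineage",
                     "lineage_conflict"))
  els[]
}

#' Classify an element into a superfamily from its Pol domain order
#'
#' Copia internal regions carry GAG-PR-INT-RT-RH, Gypsy GAG-PR-RT-RH-INT;
#' the decision uses the relative order of INT, RT and RH restricted to the
#' domains present. Fewer than two of the three, or an order consistent with
#' both superfamilies (or neither), yields Unknown.
#'
#' @param domain_hits data.table with columns `domain` and `start`
#'   (positions in a shared frame, e.g. the internal region)
#' @return "Copia", "Gypsy" or "Unknown"
#' @export
classify_superfamily <- function(domain_hits) {
  dh <- as.data.table(domain_hits)
  setorder(dh, start)
  if (anyDuplicated(dh$domain)) {
    warning("duplicated domain names within one element; using first occurrence")
    dh <- dh[!duplicated(domain)]
  }
  key <- dh$domain[dh$domain %in% c("INT", "RT", "RH")]
  if (length(key) < 2L) return("Unknown")
  consistent <- function(ord) {
    ref <- match(key, ord)
    !is.unsorted(ref, strictly = TRUE)
  }
  cop <- consistent(c("INT", "RT", "RH"))
  gyp <- consistent(c("RT", "RH", "INT"))
  if (cop && !gyp) "Copia" else if (gyp && !cop) "Gypsy" else "Unknown"
}

#' Assign a lineage label from annotated domain hits
#'
#' Majority vote over the element's domain-hit lineage labels; ties or no
#' labels give NA. A label illegal for the assigned superfamily raises a
#' conflict flag (REXdb lineages are superfamily-specific).
#'
#' @param domain_hits data.table with an optional `lineage` column
#' @param superfamily "Copia", "Gypsy" or "Unknown"
#' @return list(lineage = character or NA, conflict = logical)
#' @export
assign_lineage <- function(domain_hits, superfamily = "Unknown") {
  dh <- as.data.table(domain_hits)
  if (!"lineage" %in% names(dh) || all(is.na(dh$lineage)))
    return(list(lineage = NA_character_, conflict = FALSE))
  tab <- table(dh$lineage[!is.na(dh$lineage)])
  top <- names(tab)[tab == max(tab)]
  if (length(top) != 1L) return(list(lineage = NA_character_, conflict = FALSE))
  legal <- switch(superfamily, Copia = COPIA_LINEAGES, Gypsy = GYPSY_LINEAGES,
                  c(COPIA_LINEAGES, GYPSY_LINEAGES))
  list(lineage = top, conflict = !(top %in% legal))
}
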
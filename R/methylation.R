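# Per-context methylation metaprofiles over feature bodies and 2-kb flanks.
#
# The per-bin estimator is the weighted methylation level
# sum(meth) / sum(meth + unmeth), pooled over all cytosines of all features
# in the stratum: robust to coverage heterogeneity, unlike a mean of
# per-site fractions.

#' Methylation metaprofile over features and flanks
#'
#' For each (context, stratum) the profile has `bins_flank` fixed-width bins
#' over the upstream flank, `bins_body` proportionally scaled bins over the
#' feature body, and `bins_flank` bins over the downstream flank (half-open
#' bins, so no cytosine is counted twice within a region). Cytosines with
#' coverage below `min_cov` are excluded; bins with no covered cytosine get
#' level NA (missing, never 0). Features with a `strand` column set to "-"
#' are profiled in 5'->3' orientation; strand "." or "+" is profiled as-is.
#'
#' @param calls cytosine calls (seq_id, pos, strand, context, meth_count,
#'   unmeth_count), both DNA strands pooled per position
#' @param features feature table: seq_id, start, end, optionally strand and
#'   stratum columns
#' @param strata character vector of feature columns defining strata
#'   (e.g. c("lineage", "active")); NULL pools everything
#' @param flank_bp flank width (bp) on each side
#' @param bins_flank,bins_body bin counts
#' @param min_cov minimum coverage (meth + unmeth) per cytosine
#' @return data.table: strata columns, context, region
#'   (upstream/body/downstream), bin (0-based), level, n_cytosines,
#'   total_meth, total_unmeth; complete grid, missing bins have level NA
#' @export
metaprofile <- function(calls, features, strata = NULL, flank_bp = 2000L,
                        bins_flank = 20L, bins_body = 20L, min_cov = 4L) {
  ft <- as.data.table(features)
  if (nrow(ft) == 0L) stop("empty feature set")
  cc <- as.data.table(calls)[meth_count + unmeth_count >= min_cov]
  if (!"strand" %in% names(ft)) ft[, strand := "."]
  ft[, feat_idx := .I]

  # region table in nominal coordinates (may extend past sequence limits;
  # bins falling outside simply collect no cytosines)
  reg <- rbind(
    ft[, .(feat_idx, seq_id, rstart = start - flank_bp, rend = start,
           region = ifelse(strand == "-", "downstream", "upstream"))],
    ft[, .(feat_idx, seq_id, rstart = start, rend = end, region = "body")],
    ft[, .(feat_idx, seq_id, rstart = end, rend = end + flank_bp,
           region = ifelse(strand == "-", "upstream", "downstream"))])
  setkey(reg, seq_id, rstart, rend)
  q <- cc[, .(seq_id, pos, pos2 = pos + 1L, context, meth_count, unmeth_count)]
  ov <- foverlaps(q, reg, by.x = c("seq_id", "pos", "pos2"),
                  by.y = c("seq_id", "rstart", "rend"), type = "within",
                  nomatch = NULL)
  # 'within' with half-open intent: drop pos == rend matches
  ov <- ov[pos < rend & pos >= rstart]
  ov <- merge(ov, ft[, c("feat_idx", "strand", strata), with = FALSE],
              by = "feat_idx")
  binw <- flank_bp / bins_flank
  ov[, off := ifelse(strand == "-", rend - 1L - pos, pos - rstart)]
  ov[, bin := ifelse(region == "body",
                     pmin(bins_body - 1L,
                          floor(off / (rend - rstart) * bins_body)),
                     floor(off / binw))]
  grp <- c(strata, "context", "region", "bin")
  prof <- ov[, .(total_meth = sum(meth_count),
                 total_unmeth = sum(unmeth_count),
                 n_cytosines = .N), by = grp]
  prof[, level := total_meth / (total_meth + total_unmeth)]
  # complete grid
  strata_grid <- if (is.null(strata)) data.table(dummy = 1L) else
    unique(ft[, strata, with = FALSE])
  grid <- CJ(context = c("CG", "CHG", "CHH"),
             region = c("upstream", "body", "downstream"), bin = 0L, sorted = FALSE)
  grid <- rbindlist(lapply(seq_len(nrow(strata_grid)), function(i) {
    g <- rbind(CJ(context = c("CG", "CHG", "CHH"), region = "upstream",
                  bin = 0:(bins_flank - 1L)),
               CJ(context = c("CG", "CHG", "CHH"), region = "body",
                  bin = 0:(bins_body - 1L)),
               CJ(context = c("CG", "CHG", "CHH"), region = "downstream",
                  bin = 0:(bins_flank - 1L)))
    if (!is.null(strata)) cbind(strata_grid[i], g) else g
  }))
  out <- merge(grid, prof, by = grp, all.x = TRUE)
  out[is.na(n_cytosines), n_cytosines := 0L]
  out[, region := factor(region, levels = c("upstream", "body", "downstream"))]
  setorderv(out, c(strata, "context", "region", "bin"))
  out[, region := as.character(region)]
  out[]
}

#' TE density in element flanks, per lineage
#'
#' Fraction of flanking bases (both 2-kb flanks pooled, the element's own
#' span excluded) covered by at least one repeat annotation.
#'
#' @param elements element table with a lineage column
#' @param repeat_hits repeat annotation table
#' @param flank_bp flank width on each side
#' @param seq_lengths optional named vector to clamp flanks at sequence ends
#' @return data.table: lineage, flank_bases, covered_bases, density
#' @export
flank_te_density <- function(elements, repeat_hits, flank_bp = 2000L,
                             seq_lengths = NULL) {
  el <- as.data.table(elements)
  if (!"lineage" %in% names(el)) stop("elements need a lineage column")
  hits <- as.data.table(repeat_hits)
  fl <- rbind(el[, .(lineage, seq_id, start = start - flank_bp, end = start)],
              el[, .(lineage, seq_id, start = end, end = end + flank_bp)])
  fl[, start := pmax(start, 0L)]
  if (!is.null(seq_lengths)) fl[, end := pmin(end, seq_lengths[seq_id])]
  fl <- fl[end > start]
  out <- fl[, {
    # per-flank intersection with the reduced repeat cover, so flanks that
    # happen to overlap each other are weighted consistently with the
    # denominator (each flank contributes its own bases)
    covered <- 0
    total <- sum(end - start)
    for (sid in unique(seq_id)) {
      f <- as_iranges0(start[seq_id == sid], end[seq_id == sid])
      h <- hits[seq_id == sid]
      if (nrow(h)) {
        rcov <- IRanges::reduce(as_iranges0(h$start, h$end))
        covered <- covered + sum(vapply(seq_along(f), function(k)
          sum(IRanges::width(IRanges::intersect(f[k], rcov))), numeric(1)))
      }
    }
    .(flank_bases = total, covered_bases = as.integer(covered))
  }, by = lineage]
  out[, density := covered_bases / flank_bases]
  out[]
}

#' Paired gene and LTR-RT methylation profiles
#'
#' Applies the same binning to gene bodies (strand-oriented) and element
#' bodies, for side-by-side comparison.
#'
#' @param calls cytosine calls
#' @param genes `gene_models` object
#' @param elements element table
#' @param ... passed to [metaprofile()]
#' @return list(gene = profile, ltr = profile)
#' @export
gene_vs_ltr_profile <- function(calls, genes, elements, ...) {
  if (is.null(genes) || nrow(genes$genes) == 0L) stop("empty gene set")
  if (nrow(as.data.table(elements)) == 0L) stop("empty element set")
  gp <- metaprofile(calls, genes$genes[, .(seq_id, start, end, strand)], ...)
  lp <- metaprofile(calls,
                    as.data.table(elements)[, .(seq_id, start, end)], ...)
  list(gene = gp, ltr = lp)
}
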
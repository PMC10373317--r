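# Synthetic genome simulator with a complete planted-truth registry.
#
# Plants intact LTR-RTs (TSD + 5'LTR + internal domain sentinels + 3'LTR +
# TSD, the two LTRs being independently mutated copies of one ancestral LTR),
# solo LTRs with and without TSDs, truncated LTR fragments, and multi-exon
# gene models; emits repeat-hit and domain-hit tables, replicate count tables
# with a known active subset, and strand/context-resolved cytosine calls with
# class-dependent methylation means.

COPIA_LINEAGES <- c("Ale", "Alesia", "Angela", "Bianca", "Ikeros", "Ivana",
                    "SIRE", "TAR", "Tork")
GYPSY_LINEAGES <- c("Athila", "CRM", "Galadriel", "Ogre", "Reina", "Retand",
                    "Tekay")
DOMAIN_ORDER <- list(Copia = c("GAG", "PR", "INT", "RT", "RH"),
                     Gypsy = c("GAG", "PR", "RT", "RH", "INT"))

# fixed 30-bp sentinel motif per domain name: deterministic, so domain hits
# are verifiable against the sequence without any profile search
DOMAIN_MOTIFS <- c(
  GAG = "ATGGGACAGACTGTTACCACTCCCTTAAGT",
  PR  = "CCTCAGATCACTCTTTGGCAACGACCCCTC",
  INT = "TTTTTAGATGGAATAGATAAGGCCCAAGAA",
  RT  = "ATTAGATACCAGTACAATGTGCTTCCACAG",
  RH  = "GCTGTCCATAAGGGATGGATAGGAAAATAT")

#' Simulation configuration
#'
#' Defaults describe a compact plant-like test genome. Ages are in million
#' years (MY); the planted inter-LTR divergence of an element of age T is
#' k = 2 r T 1e6 substitutions/site, applied as independent per-site
#' substitutions with probability k/2 on each LTR copy (terminal TG/CA
#' dinucleotides are exempt so every planted element keeps its diagnostic
#' micro-structure).
#'
#' @param genome_length total length (bp) of the single simulated chromosome
#' @param n_intact,n_solo,n_solo_without_tsd,n_truncated,n_genes feature counts
#' @param ltr_length_range,internal_length_range bp ranges (LTR range must
#'   stay within the structural bounds 100-7000 bp)
#' @param age_range MY range for planted insertion ages
#' @param rate substitution rate r per site per year
#' @param tsd_length_range TSD length range, within 4-6 bp
#' @param active_fraction fraction of intact elements that are
#'   transcriptionally active
#' @param n_assoc named counts of gene-associated elements to plant, names
#'   from promoter/intron/downstream/exon
#' @param assoc_expr_mult named expression multipliers applied to the mean
#'   count of genes carrying each association category
#' @param methylation_params list with per-context means for background,
#'   gene, active and silent element bodies, plus optional per-lineage
#'   overrides (`lineage_overrides = list(CRM = list(silent = c(...)))`)
#' @param coverage_mean mean Poisson read coverage per cytosine
#' @param cluster_lineages lineages whose flanks are annotated as dense
#'   repeat clusters (emulating pericentromeric nesting)
#' @param flank_repeat_fraction fraction of the 2-kb flank annotated as
#'   repeat for clustered lineages
#' @param emit_cx generate per-cytosine methylation calls (skip for large
#'   detection-only genomes)
#' @param seed RNG seed; the whole simulation is a deterministic function of
#'   the config
#' @return a list of class `sim_config`
#' @export
sim_config <- function(genome_length = 200000L,
                       n_intact = 10L, n_solo = 5L, n_solo_without_tsd = 2L,
                       n_truncated = 3L, n_genes = 10L,
                       ltr_length_range = c(400L, 1500L),
                       internal_length_range = c(1000L, 5000L),
                       age_range = c(0, 4),
                       rate = 1.3e-8,
                       tsd_length_range = c(4L, 6L),
                       active_fraction = 0.3,
                       n_assoc = c(promoter = 0L, intron = 0L,
                                   downstream = 0L, exon = 0L),
                       assoc_expr_mult = c(promoter = 0.2, intron = 5,
                                           downstream = 0.2, exon = 1),
                       methylation_params = list(
                         background = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                         gene = c(CG = 0.05, CHG = 0.05, CHH = 0.05),
                         active = c(CG = 0.45, CHG = 0.30, CHH = 0.06),
                         silent = c(CG = 0.85, CHG = 0.70, CHH = 0.10),
                         lineage_overrides = list()),
                       coverage_mean = 20,
                       cluster_lineages = c("CRM", "SIRE", "Athila"),
                       flank_repeat_fraction = 0.85,
                       emit_cx = TRUE,
                       seed = 42L) {
  cfg <- as.list(environment())
  if (ltr_length_range[1] < 100L || ltr_length_range[2] > 7000L)
    stop("ltr_length_range must lie within [100, 7000] bp")
  if (tsd_length_range[1] < 4L || tsd_length_range[2] > 6L)
    stop("tsd_length_range must lie within [4, 6] bp")
  if (age_range[1] < 0) stop("ages must be non-negative")
  if (internal_length_range[1] < 200L)
    stop("internal_length_range minimum must be >= 200 bp")
  if (rate <= 0) stop("substitution rate must be positive")
  full <- c(promoter = 0L, intron = 0L, downstream = 0L, exon = 0L)
  full[names(cfg$n_assoc)] <- as.integer(cfg$n_assoc)
  cfg$n_assoc <- full
  if (sum(full) > cfg$n_genes)
    stop("more associated elements requested than genes")
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# uniform integer in [a, b]; safe when a == b (unlike sample(a:b, 1))
rint <- function(a, b) if (a >= b) as.integer(a) else
  a + sample.int(b - a + 1L, 1L) - 1L

# shift every genomic-coordinate column of a local-coordinate table
shift_coords <- function(dt, by) {
  d <- copy(dt)
  for (cl in intersect(c("start", "end", "ltr5_start", "ltr5_end",
                         "ltr3_start", "ltr3_end"), names(d)))
    d[, (cl) := get(cl) + as.integer(by)]
  d
}

# per-site substitution with probability q, never touching `protect` positions
# (1-based); substituted bases change to one of the other three
mutate_seq <- function(seq, q, protect = integer(0)) {
  if (q <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < q)
  hit <- setdiff(hit, protect)
  if (length(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(b) sample(alt[[b]], 1L), character(1))
  }
  paste(ch, collapse = "")
}

# build one intact element's sequence parts; returns list of strings + truth
build_intact <- function(id, cfg, superfamily, lineage, age) {
  llen <- rint(cfg$ltr_length_range[1], cfg$ltr_length_range[2])
  ilen <- rint(cfg$internal_length_range[1], cfg$internal_length_range[2])
  k <- 2 * cfg$rate * age * 1e6
  anc <- rand_seq(llen)
  anc <- paste0("TG", substr(anc, 3L, llen - 2L), "CA")
  protect <- c(1L, 2L, llen - 1L, llen)
  ltr5 <- mutate_seq(anc, k / 2, protect)
  ltr3 <- mutate_seq(anc, k / 2, protect)
  doms <- DOMAIN_ORDER[[superfamily]]
  internal <- rand_seq(ilen)
  # evenly spaced 30-bp sentinels, order encodes the superfamily
  slots <- floor(seq(1L, ilen - 30L, length.out = length(doms) + 1L))[1:length(doms)]
  for (j in seq_along(doms))
    substr(internal, slots[j], slots[j] + 29L) <- DOMAIN_MOTIFS[[doms[j]]]
  tlen <- rint(cfg$tsd_length_range[1], cfg$tsd_length_range[2])
  tsd <- rand_seq(tlen)
  list(id = id, tsd = tsd, ltr5 = ltr5, internal = internal, ltr3 = ltr3,
       ltr_len = llen, internal_len = ilen, age = age, divergence = k,
       superfamily = superfamily, lineage = lineage, anc = anc,
       dom_starts = slots - 1L, dom_names = doms)
}

place_by_gaps <- function(lengths, genome_length, margin) {
  # random non-overlapping placement: feature order is given; gaps are a
  # random composition of the free space with a minimum margin
  n <- length(lengths)
  free <- genome_length - sum(lengths) - (n + 1L) * margin
  if (free < 0)
    stop("cannot place planted features in genome_length = ", genome_length,
         "; increase genome_length")
  cuts <- sort(sample.int(free + 1L, n, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts)) + margin
  starts <- cumsum(gaps) + cumsum(c(0L, lengths[-n]))
  as.integer(starts)
}

#' Simulate a genome with planted LTR-RT features and full ground truth
#'
#' @param cfg a [sim_config()]
#' @return list with: `genome` (DNAStringSet), `genes` (`gene_models`),
#'   `repeat_hits`, `domain_hits`, `consensi` (DNAStringSet),
#'   `ltr_counts`, `gene_counts`, `gene_lengths`, `cx` (cytosine calls or
#'   NULL), and `truth` (registry of every planted feature)
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- as.integer(cfg$genome_length)
  seqid <- "chr1"

  n_act <- round(cfg$active_fraction * cfg$n_intact)
  active_idx <- sample.int(cfg$n_intact, n_act)

  # ---- element/gene specs ---------------------------------------------------
  intacts <- vector("list", cfg$n_intact)
  for (i in seq_len(cfg$n_intact)) {
    sf <- sample(c("Copia", "Gypsy"), 1L)
    lin <- if (sf == "Copia") sample(COPIA_LINEAGES, 1L) else sample(GYPSY_LINEAGES, 1L)
    age <- runif(1L, cfg$age_range[1], cfg$age_range[2])
    intacts[[i]] <- build_intact(sprintf("LTRRT_%04d", i), cfg, sf, lin, age)
    intacts[[i]]$active <- i %in% active_idx
  }
  # gene structural specs; the first sum(n_assoc) genes carry an element
  assoc_cat <- rep(names(cfg$n_assoc), times = cfg$n_assoc)
  gene_specs <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    ne <- sample(2:4, 1L)
    exlens <- sample(150:500, ne, replace = TRUE)
    inlens <- sample(150:400, ne - 1L, replace = TRUE)
    gene_specs[[g]] <- list(id = sprintf("GENE_%04d", g),
                            strand = sample(c("+", "-"), 1L),
                            exlens = exlens, inlens = inlens,
                            assoc = if (g <= length(assoc_cat)) assoc_cat[g]
                                    else NA_character_)
  }

  solo_age <- runif(cfg$n_solo + cfg$n_solo_without_tsd,
                    cfg$age_range[1], cfg$age_range[2])
  solos <- lapply(seq_len(cfg$n_solo + cfg$n_solo_without_tsd), function(i) {
    llen <- rint(cfg$ltr_length_range[1], cfg$ltr_length_range[2])
    anc <- rand_seq(llen)
    anc <- paste0("TG", substr(anc, 3L, llen - 2L), "CA")
    with_tsd <- i <= cfg$n_solo
    tlen <- rint(cfg$tsd_length_range[1], cfg$tsd_length_range[2])
    list(id = sprintf(if (with_tsd) "SOLO_%04d" else "SOLONT_%04d", i),
         anc = anc, llen = llen, age = solo_age[i], with_tsd = with_tsd,
         seq = mutate_seq(anc, cfg$rate * solo_age[i] * 1e6,
                          c(1L, 2L, llen - 1L, llen)),
         tsd = rand_seq(tlen))
  })
  truncs <- lapply(seq_len(cfg$n_truncated), function(i) {
    llen <- rint(cfg$ltr_length_range[1], cfg$ltr_length_range[2])
    anc <- rand_seq(llen)
    cov <- runif(1L, 0.3, 0.6)
    flen <- max(60L, as.integer(round(cov * llen)))
    off <- sample.int(llen - flen + 1L, 1L) - 1L
    list(id = sprintf("TRUNC_%04d", i), anc = anc, llen = llen,
         cstart = off, cend = off + flen,
         seq = mutate_seq(substr(anc, off + 1L, off + flen), 0.05))
  })

  # ---- block assembly -------------------------------------------------------
  # a block is a self-contained stretch: either one standalone feature or a
  # gene plus its associated element; blocks are placed with random gaps
  blocks <- list()
  gi <- 0L
  assoc_gene_of <- character(0)
  for (g in seq_len(cfg$n_genes)) {
    sp <- gene_specs[[g]]
    if (is.na(sp$assoc)) {
      blocks[[length(blocks) + 1L]] <- list(type = "gene", gene = sp)
    } else {
      gi <- gi + 1L
      el <- intacts[[gi]]
      assoc_gene_of[el$id] <- sp$id
      blocks[[length(blocks) + 1L]] <-
        list(type = "gene_assoc", gene = sp, element = el, cat = sp$assoc)
    }
  }
  if (gi < cfg$n_intact)
    for (i in (gi + 1L):cfg$n_intact)
      blocks[[length(blocks) + 1L]] <- list(type = "intact", element = intacts[[i]])
  for (s in solos) blocks[[length(blocks) + 1L]] <- list(type = "solo", solo = s)
  for (tr in truncs) blocks[[length(blocks) + 1L]] <- list(type = "trunc", trunc = tr)
  blocks <- blocks[sample.int(length(blocks))]

  # realized block sequences and within-block feature offsets
  render <- lapply(blocks, render_block, cfg = cfg)
  lens <- vapply(render, function(b) nchar(b$seq), integer(1))
  starts <- place_by_gaps(lens, L, margin = 300L)

  ch <- strsplit(rand_seq(L), "", fixed = TRUE)[[1]]
  truth <- list(); rep_hits <- list(); dom_hits <- list()
  genes_tab <- list(); exons_tab <- list()
  consensi <- character(0)
  for (b in seq_along(render)) {
    r <- render[[b]]
    s0 <- starts[b]
    ch[(s0 + 1L):(s0 + nchar(r$seq))] <- strsplit(r$seq, "", fixed = TRUE)[[1]]
    if (!is.null(r$truth)) { truth[[length(truth) + 1L]] <-
                               shift_coords(r$truth, s0) }
    if (!is.null(r$rep)) { h <- copy(r$rep); h[, start := start + s0]
                           h[, end := end + s0]; rep_hits[[length(rep_hits) + 1L]] <- h }
    if (!is.null(r$dom)) { d <- copy(r$dom); d[, gstart := gstart + s0]
                           d[, gend := gend + s0]
                           dom_hits[[length(dom_hits) + 1L]] <- d }
    if (!is.null(r$gene)) { gtab <- copy(r$gene); gtab[, start := start + s0]
                            gtab[, end := end + s0]
                            genes_tab[[length(genes_tab) + 1L]] <- gtab }
    if (!is.null(r$exons)) { etab <- copy(r$exons); etab[, start := start + s0]
                             etab[, end := end + s0]
                             exons_tab[[length(exons_tab) + 1L]] <- etab }
    consensi <- c(consensi, r$consensi)
  }
  truth <- rbindlist(truth, fill = TRUE)
  truth[, seq_id := seqid]
  rep_hits <- if (length(rep_hits)) rbindlist(rep_hits)[, seq_id := seqid][] else
    data.table(seq_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), consensus_id = character(0),
               consensus_start = integer(0), consensus_end = integer(0),
               identity = numeric(0))
  dom_hits <- if (length(dom_hits)) rbindlist(dom_hits)[, seq_id := seqid][] else
    data.table(element_id = character(0), domain = character(0),
               start = integer(0), end = integer(0), lineage = character(0),
               gstart = integer(0), gend = integer(0), seq_id = character(0))
  setcolorder(rep_hits, c("seq_id", "start", "end", "strand", "consensus_id",
                          "consensus_start", "consensus_end", "identity"))

  # flanking repeat-cluster annotation for pericentromeric-like lineages
  tr_int <- truth[kind == "intact" & lineage %in% cfg$cluster_lineages]
  if (nrow(tr_int)) {
    fr <- cfg$flank_repeat_fraction
    flank <- rbind(
      tr_int[, .(start = pmax(0L, start - 2000L), end = start)],
      tr_int[, .(start = end, end = pmin(L, end + 2000L))])
    flank <- flank[end > start]
    covlen <- as.integer(round(fr * (flank$end - flank$start)))
    rep_hits <- rbind(rep_hits, data.table(
      seq_id = seqid, start = flank$start, end = flank$start + covlen,
      strand = ".", consensus_id = "MISC_repeat",
      consensus_start = 0L, consensus_end = covlen, identity = 0.9))
  }

  genome <- DNAStringSet(setNames(paste(ch, collapse = ""), seqid))

  genes_dt <- rbindlist(genes_tab)
  exons_dt <- rbindlist(exons_tab)
  models <- NULL
  if (nrow(genes_dt)) {
    genes_dt[, seq_id := seqid]; exons_dt[, seq_id := seqid]
    genes_dt[, `:=`(tss = ifelse(strand == "-", end - 1L, start),
                    tts = ifelse(strand == "-", start, end - 1L),
                    mrna_id = paste0(gene_id, ".t1"))]
    setorder(exons_dt, gene_id, start)
    introns_dt <- exons_dt[, {
      if (.N > 1L) .(seq_id = seq_id[-1L], start = end[-.N], end = start[-1L])
      else .(seq_id = character(0), start = integer(0), end = integer(0))
    }, by = gene_id]
    models <- structure(list(genes = genes_dt[], exons = exons_dt[],
                             introns = introns_dt[end > start]),
                        class = "gene_models")
  }

  # ---- counts ---------------------------------------------------------------
  tr_el <- truth[kind == "intact"]
  ltr_counts <- NULL
  if (nrow(tr_el)) {
    lam <- ifelse(tr_el$active, runif(nrow(tr_el), 50, 500), 0)
    ltr_counts <- cbind(rep1 = rpois(nrow(tr_el), lam),
                        rep2 = rpois(nrow(tr_el), lam))
    rownames(ltr_counts) <- tr_el$feature_id
    storage.mode(ltr_counts) <- "integer"
  }
  gene_counts <- NULL; gene_lengths <- NULL
  if (!is.null(models)) {
    g <- models$genes
    mu <- exp(rnorm(nrow(g), log(200), 0.5))
    cat_of <- vapply(gene_specs, function(s) s$assoc, character(1))
    names(cat_of) <- vapply(gene_specs, function(s) s$id, character(1))
    mult <- ifelse(is.na(cat_of[g$gene_id]), 1,
                   cfg$assoc_expr_mult[cat_of[g$gene_id]])
    gene_counts <- cbind(rep1 = rnbinom(nrow(g), mu = mu * mult, size = 5),
                         rep2 = rnbinom(nrow(g), mu = mu * mult, size = 5))
    rownames(gene_counts) <- g$gene_id
    storage.mode(gene_counts) <- "integer"
    gene_lengths <- models$exons[, .(len = sum(end - start)), by = gene_id]
    gene_lengths <- setNames(gene_lengths$len, gene_lengths$gene_id)
  }

  # ---- cytosine calls -------------------------------------------------------
  cx <- NULL
  if (cfg$emit_cx) cx <- simulate_cx(genome, truth, models, cfg)

  cons_seqs <- DNAStringSet(consensi)
  list(genome = genome, genes = models, repeat_hits = rep_hits,
       domain_hits = dom_hits, consensi = cons_seqs,
       ltr_counts = ltr_counts, gene_counts = gene_counts,
       gene_lengths = gene_lengths, cx = cx, truth = truth[],
       config = cfg)
}

# render one block into (sequence, local-coordinate truth/annotation rows)
render_block <- function(blk, cfg) {
  if (blk$type == "intact") return(render_intact(blk$element, pad = 10L))
  if (blk$type == "solo") return(render_solo(blk$solo, pad = 10L,
                                             rate = cfg$rate))
  if (blk$type == "trunc") return(render_trunc(blk$trunc, pad = 10L))
  if (blk$type == "gene") return(render_gene(blk$gene, el = NULL))
  if (blk$type == "gene_assoc") return(render_gene(blk$gene, el = blk$element,
                                                   cat = blk$cat))
  stop("unknown block type")
}

render_intact <- function(el, pad = 10L, offset0 = 0L) {
  # pad | TSD | LTR5 | internal | LTR3 | TSD | pad
  seq <- paste0(rand_seq(pad), el$tsd, el$ltr5, el$internal, el$ltr3, el$tsd,
                rand_seq(pad))
  tl <- nchar(el$tsd); ll <- el$ltr_len; il <- el$internal_len
  s <- pad + tl                      # element start (0-based, excl. TSD)
  truth <- data.table(
    kind = "intact", feature_id = el$id, start = s, end = s + 2L * ll + il,
    ltr5_start = s, ltr5_end = s + ll,
    ltr3_start = s + ll + il, ltr3_end = s + 2L * ll + il,
    tsd = el$tsd, age = el$age, divergence = el$divergence,
    superfamily = el$superfamily, lineage = el$lineage, active = el$active,
    consensus_id = paste0("CONS_", el$id))
  rep <- data.table(
    start = c(s, s + ll + il), end = c(s + ll, s + 2L * ll + il),
    strand = ".", consensus_id = paste0("CONS_", el$id),
    consensus_start = 0L, consensus_end = ll,
    identity = 1 - el$divergence / 2)
  dom <- data.table(element_id = el$id, domain = el$dom_names,
                    start = el$dom_starts, end = el$dom_starts + 30L,
                    lineage = el$lineage,
                    gstart = s + ll + el$dom_starts,
                    gend = s + ll + el$dom_starts + 30L)
  cons <- setNames(el$anc, paste0("CONS_", el$id))
  list(seq = seq, truth = truth, rep = rep, dom = dom, consensi = cons)
}

render_solo <- function(s, pad = 10L, rate = 1.3e-8) {
  tl <- nchar(s$tsd)
  if (s$with_tsd) {
    seq <- paste0(rand_seq(pad), s$tsd, s$seq, s$tsd, rand_seq(pad))
    st <- pad + tl
  } else {
    # control the full 6-bp flanks: the first base right of the LTR differs
    # from every base it would be compared against in the anchored 6/5/4-bp
    # scans, so no TSD of any permitted length can be found
    left6 <- rand_seq(6L)
    bad <- strsplit(substr(left6, 1L, 3L), "", fixed = TRUE)[[1]]
    first <- setdiff(c("A", "C", "G", "T"), bad)[1L]
    right6 <- paste0(first, rand_seq(5L))
    seq <- paste0(rand_seq(pad), left6, s$seq, right6, rand_seq(pad))
    st <- pad + 6L
  }
  truth <- data.table(
    kind = if (s$with_tsd) "solo" else "solo_no_tsd",
    feature_id = s$id, start = st, end = st + s$llen,
    tsd = if (s$with_tsd) s$tsd else NA_character_,
    age = s$age, divergence = 2 * rate * s$age * 1e6,
    consensus_id = paste0("CONS_", s$id))
  rep <- data.table(start = st, end = st + s$llen, strand = ".",
                    consensus_id = paste0("CONS_", s$id),
                    consensus_start = 0L, consensus_end = s$llen,
                    identity = 1 - rate * s$age * 1e6)
  list(seq = seq, truth = truth, rep = rep,
       consensi = setNames(s$anc, paste0("CONS_", s$id)))
}

render_trunc <- function(tr, pad = 10L) {
  seq <- paste0(rand_seq(pad), tr$seq, rand_seq(pad))
  flen <- nchar(tr$seq)
  truth <- data.table(kind = "truncated", feature_id = tr$id,
                      start = pad, end = pad + flen,
                      consensus_id = paste0("CONS_", tr$id))
  rep <- data.table(start = pad, end = pad + flen, strand = ".",
                    consensus_id = paste0("CONS_", tr$id),
                    consensus_start = tr$cstart, consensus_end = tr$cend,
                    identity = 0.95)
  list(seq = seq, truth = truth, rep = rep,
       consensi = setNames(tr$anc, paste0("CONS_", tr$id)))
}

render_gene <- function(sp, el = NULL, cat = NULL) {
  exl <- sp$exlens; inl <- sp$inlens
  el_parts <- NULL
  # embed the element by widening one intron/exon, or reserve flank space
  if (!is.null(el)) {
    el_r <- render_intact(el, pad = 20L)
    el_len <- nchar(el_r$seq)
    if (cat == "intron") {
      w <- sample(seq_along(inl), 1L)
      inl[w] <- inl[w] + el_len
      el_off_in_intron <- rint(50L, inl[w] - el_len - 50L)
      embed <- list(where = "intron", which = w, off = el_off_in_intron)
    } else if (cat == "exon") {
      w <- sample(seq_along(exl), 1L)
      exl[w] <- exl[w] + el_len
      embed <- list(where = "exon", which = w,
                    off = rint(20L, exl[w] - el_len - 20L))
    } else embed <- list(where = cat)
  }
  glen <- sum(exl) + sum(inl)
  # lay out gene body
  body <- rand_seq(glen)
  bnd <- integer(0); p <- 0L
  ex_iv <- data.table(start = integer(0), end = integer(0))
  for (i in seq_along(exl)) {
    ex_iv <- rbind(ex_iv, data.table(start = p, end = p + exl[i]))
    p <- p + exl[i] + if (i < length(exl)) inl[i] else 0L
  }
  gene_seq <- body
  truth <- NULL; rep <- NULL; dom <- NULL; cons <- character(0)
  left_pad <- 40L
  pre <- rand_seq(left_pad); post <- rand_seq(left_pad)
  if (!is.null(el)) {
    if (embed$where %in% c("intron", "exon")) {
      iv <- if (embed$where == "intron")
        data.table(start = ex_iv$end[embed$which],
                   end = ex_iv$start[embed$which + 1L])
      else ex_iv[embed$which]
      at <- iv$start + embed$off          # element block offset in gene body
      gene_seq <- paste0(substr(body, 1L, at),
                         el_r$seq,
                         substr(body, at + nchar(el_r$seq) + 1L, glen))
      gene_seq <- substr(gene_seq, 1L, glen)  # lengths were pre-widened
      el_shift <- at
    } else if (embed$where == "promoter") {
      d <- rint(50L, 800L)
      if (sp$strand == "+") { pre <- paste0(el_r$seq, rand_seq(d)); el_shift <- -nchar(pre) }
      else { post <- paste0(rand_seq(d), el_r$seq); el_shift <- glen + d }
      left_pad <- nchar(pre)
    } else if (embed$where == "downstream") {
      d <- rint(50L, 800L)
      if (sp$strand == "+") { post <- paste0(rand_seq(d), el_r$seq); el_shift <- glen + d }
      else { pre <- paste0(el_r$seq, rand_seq(d)); el_shift <- -nchar(pre) }
      left_pad <- nchar(pre)
    }
    sh <- function(dt) shift_coords(dt, el_shift + left_pad)
    truth <- sh(el_r$truth)
    truth[, `:=`(assoc_gene = sp$id, assoc_category = cat)]
    rep <- sh(el_r$rep)
    dom <- copy(el_r$dom)
    dom[, `:=`(gstart = gstart + el_shift + left_pad,
               gend = gend + el_shift + left_pad)]
    cons <- el_r$consensi
  } else left_pad <- 40L
  seq <- paste0(pre, gene_seq, post)
  gs <- left_pad
  gene <- data.table(gene_id = sp$id, start = gs, end = gs + glen,
                     strand = sp$strand)
  exons <- data.table(gene_id = sp$id, start = ex_iv$start + gs,
                      end = ex_iv$end + gs)
  gtruth <- data.table(kind = "gene", feature_id = sp$id,
                       start = gs, end = gs + glen)
  truth <- rbind(gtruth, truth, fill = TRUE)
  list(seq = seq, truth = truth, rep = rep, dom = dom,
       gene = gene, exons = exons, consensi = cons)
}

# class-mean methylation per cytosine + binomial sampling
simulate_cx <- function(genome, truth, models, cfg) {
  ctx <- genome_contexts(genome)
  mp <- cfg$methylation_params
  mean_of <- rep(NA_real_, nrow(ctx))
  bg <- mp$background
  mean_of <- bg[ctx$context]
  assign_region <- function(iv, means_by_context) {
    if (nrow(iv) == 0L) return()
    o <- findOverlaps(as_iranges0(ctx$pos, ctx$pos + 1L),
                      as_iranges0(iv$start, iv$end))
    qh <- queryHits(o); sh <- subjectHits(o)
    mean_of[qh] <<- means_by_context[cbind(sh, match(ctx$context[qh],
                                                     colnames(means_by_context)))]
  }
  if (!is.null(models)) {
    g <- models$genes
    gm <- matrix(rep(mp$gene, each = nrow(g)), nrow = nrow(g),
                 dimnames = list(NULL, names(mp$gene)))
    assign_region(g, gm)
  }
  te <- truth[kind %in% c("intact", "solo", "solo_no_tsd", "truncated")]
  if (nrow(te)) {
    if (!"active" %in% names(te)) te[, active := FALSE]
    if (!"lineage" %in% names(te)) te[, lineage := NA_character_]
    cls <- ifelse(!is.na(te$active) & te$active, "active", "silent")
    mm <- t(vapply(seq_len(nrow(te)), function(i) {
      base <- mp[[cls[i]]]
      ov <- mp$lineage_overrides[[te$lineage[i]]]
      if (!is.null(ov) && !is.null(ov[[cls[i]]])) base <- ov[[cls[i]]]
      base[c("CG", "CHG", "CHH")]
    }, numeric(3)))
    colnames(mm) <- c("CG", "CHG", "CHH")
    assign_region(te, mm)
  }
  cov <- rpois(nrow(ctx), cfg$coverage_mean)
  meth <- rbinom(nrow(ctx), cov, mean_of)
  data.table(seq_id = ctx$seq_id, pos = ctx$pos, strand = ctx$strand,
             context = ctx$context, meth_count = meth,
             unmeth_count = cov - meth, tri = ctx$tri)
}

#' Shuffle each sequence of a genome, preserving base composition
#'
#' A negative control: same length and composition, no planted structure.
#'
#' @param genome DNAStringSet or named character vector
#' @param seed RNG seed
#' @return DNAStringSet
#' @export
shuffle_background <- function(genome, seed = 1L) {
  gc <- genome_chars(genome)
  set.seed(seed)
  out <- vapply(gc, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(ch[sample.int(length(ch))], collapse = "")
  }, character(1))
  DNAStringSet(out)
}

#' Write all simulator outputs to a directory
#'
#' @param sim result of [simulate_genome()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(sim$genome, p("genome.fa"))
  write_genome_fasta(sim$consensi, p("ltr_consensi.fa"))
  if (!is.null(sim$genes)) write_gff3_genes(sim$genes, p("genes.gff3"))
  write_repeat_hits(sim$repeat_hits, p("repeats.tsv"))
  write_domain_hits(sim$domain_hits, p("domains.tsv"))
  if (!is.null(sim$ltr_counts)) write_counts(sim$ltr_counts, p("ltr_counts.tsv"))
  if (!is.null(sim$gene_counts)) write_counts(sim$gene_counts, p("gene_counts.tsv"),
                                              id_col = "gene_id")
  if (!is.null(sim$cx)) write_cx_report(sim$cx, p("genome.CX_report.txt"))
  fwrite(sim$truth, p("truth.tsv"), sep = "\t")
  invisible(dir)
}
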
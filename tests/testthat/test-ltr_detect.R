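# structural detector: pair finding, validation, classification

test_that("a planted pair is found with near-exact boundaries", {
  me <- make_manual_element(ltr_len = 300L, internal_len = 600L, seed = 11)
  pairs <- find_ltr_pairs(me$genome)
  expect_equal(nrow(pairs), 1L)
  expect_lte(abs(pairs$ltr5_start - me$ltr5_start), 5L)
  expect_lte(abs(pairs$ltr3_end - me$ltr3_end), 5L)
  v <- validate_element(pairs[1], me$genome)
  expect_false(inherits(v, "ltr_rejection"))
  expect_equal(v$start, me$start)
  expect_equal(v$end, me$end)
  expect_equal(v$tsd, me$tsd)
  expect_true(v$motif_ok)
})

test_that("a diverged pair below 90% identity is rejected", {
  # plant a pair at divergence ~0.15 (identity ~0.85)
  withr::with_seed(8, {
    anc <- paste0("TG", fix_seq(996L, 1), "CA")
    mut <- function(s, q) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < q)
      hit <- setdiff(hit, c(1:2, 999:1000))
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste(ch, collapse = "")
    }
    g <- c(chr1 = paste0(fix_seq(300L, 2), "GATCA", mut(anc, 0.075),
                         fix_seq(800L, 3), mut(anc, 0.075), "GATCA",
                         fix_seq(300L, 4)))
  })
  pairs <- find_ltr_pairs(g)
  if (nrow(pairs) > 0L) expect_true(all(pairs$ltr_identity < 0.90))
  expect_equal(nrow(detect_ltr_elements(g)), 0L)
})

test_that("mismatching flanks (3/4) are not accepted as a TSD", {
  # same element, flanks GATC ... GATG: no anchored exact match of 4-6 bp
  withr::with_seed(9, {
    anc <- paste0("TG", fix_seq(296L, 5), "CA")
    g <- c(chr1 = paste0(fix_seq(300L, 6), "GATC", anc, fix_seq(600L, 7),
                         anc, "GATG", fix_seq(300L, 8)))
  })
  pairs <- find_ltr_pairs(g)
  expect_equal(nrow(pairs), 1L)
  v <- validate_element(pairs[1], g, detect_params(refine_bp = 0L))
  expect_s3_class(v, "ltr_rejection")
})

test_that("elements at the sequence edge are rejected with reason edge", {
  withr::with_seed(10, {
    anc <- paste0("TG", fix_seq(296L, 9), "CA")
    g <- c(chr1 = paste0(anc, fix_seq(600L, 10), anc))  # no flanks at all
  })
  pairs <- find_ltr_pairs(g)
  expect_equal(nrow(pairs), 1L)
  v <- validate_element(pairs[1], g)
  expect_s3_class(v, "ltr_rejection")
  expect_equal(v$reason, "edge")
})

test_that("detector output is invariant under adding an unrelated sequence", {
  sim <- simulate_genome(sim_config(seed = 17, n_intact = 5L, n_genes = 0L,
                                    n_solo = 0L, n_solo_without_tsd = 0L,
                                    n_truncated = 0L, emit_cx = FALSE,
                                    genome_length = 60000L))
  g1 <- as.character(sim$genome)
  els1 <- detect_ltr_elements(g1)
  g2 <- c(g1, chrBG = fix_seq(30000L, 99))
  els2 <- detect_ltr_elements(g2)
  expect_equal(els2[seq_id == "chr1"], els1, ignore_attr = TRUE)
})

test_that("reported elements always satisfy the structural invariants", {
  for (sd in c(23, 24)) {
    sim <- simulate_genome(sim_config(seed = sd, emit_cx = FALSE))
    els <- detect_ltr_elements(sim$genome, sim$domain_hits)
    if (nrow(els) == 0L) next
    expect_true(all(els$ltr5_end - els$ltr5_start >= 100L))
    expect_true(all(els$ltr5_end - els$ltr5_start <= 7000L))
    expect_true(all(els$ltr5_end <= els$ltr3_start))
    expect_true(all(els$ltr_identity >= 0.90))
    expect_true(all(nchar(els$tsd) %in% 4:6))
    cop <- els$superfamily == "Copia" & !is.na(els$lineage)
    gyp <- els$superfamily == "Gypsy" & !is.na(els$lineage)
    expect_true(all(els$lineage[cop] %in% c("Ale", "Alesia", "Angela",
      "Bianca", "Ikeros", "Ivana", "SIRE", "TAR", "Tork")))
    expect_true(all(els$lineage[gyp] %in% c("Athila", "CRM", "Galadriel",
      "Ogre", "Reina", "Retand", "Tekay")))
    # accepted elements do not overlap (no nesting by default)
    setkey(els, seq_id, start)
    if (nrow(els) > 1L)
      expect_true(all(els$start[-1L] >= els$end[-nrow(els)] |
                      els$seq_id[-1L] != els$seq_id[-nrow(els)]))
  }
})

test_that("superfamily classification follows the canonical domain orders", {
  mk <- function(doms) data.table(domain = doms,
                                  start = seq(0L, by = 100L,
                                              length.out = length(doms)))
  expect_equal(classify_superfamily(mk(c("GAG", "PR", "INT", "RT", "RH"))),
               "Copia")
  expect_equal(classify_superfamily(mk(c("GAG", "PR", "RT", "RH", "INT"))),
               "Gypsy")
  expect_equal(classify_superfamily(mk(c("GAG"))), "Unknown")
  # two shared-order domains are ambiguous
  expect_equal(classify_superfamily(mk(c("RT", "RH"))), "Unknown")
  # two discriminating domains suffice
  expect_equal(classify_superfamily(mk(c("INT", "RT"))), "Copia")
  expect_equal(classify_superfamily(mk(c("RH", "INT"))), "Gypsy")
  # duplicated domains: first occurrence wins, with a warning
  expect_warning(sf <- classify_superfamily(mk(c("INT", "RT", "RH", "INT"))),
                 "duplicated")
  expect_equal(sf, "Copia")
})

test_that("lineage assignment is majority vote with a legality check", {
  dh <- data.table(domain = c("GAG", "PR", "RT", "RH"),
                   start = 1:4,
                   lineage = c("SIRE", "SIRE", "SIRE", "Tork"))
  expect_equal(assign_lineage(dh, "Copia"),
               list(lineage = "SIRE", conflict = FALSE))
  dh$lineage <- c("Athila", "Athila", "Athila", "Athila")
  expect_equal(assign_lineage(dh, "Copia"),
               list(lineage = "Athila", conflict = TRUE))
  dh$lineage <- NULL
  expect_equal(assign_lineage(dh, "Copia")$lineage, NA_character_)
  dh$lineage <- c("SIRE", "SIRE", "Tork", "Tork")
  expect_equal(assign_lineage(dh, "Copia")$lineage, NA_character_)
})
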
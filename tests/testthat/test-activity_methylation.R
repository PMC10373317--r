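# CPM activity rule, active/silent contrasts, methylation metaprofiles

test_that("CPM normalization and the strict >1 activity rule", {
  m <- matrix(c(100L, 1L, 999899L), ncol = 1,
              dimnames = list(c("e1", "e2", "bg"), "s1"))
  cp <- cpm(m)
  expect_equal(cp["e1", 1], 100)
  expect_equal(cp["e2", 1], 1)
  expect_equal(sum(cp[, 1]), 1e6, tolerance = 1e-6)
  act <- call_activity(cp)
  expect_true(act[element_id == "e1"]$active)
  expect_false(act[element_id == "e2"]$active)   # CPM exactly 1 is silent
  expect_error(cpm(matrix(0L, ncol = 1, dimnames = list("a", "s"))), "zero")
})

test_that("activity is the mean over replicates", {
  cpmat <- matrix(c(0.4, 3.0, 0.8, 1.5), 2,
                  dimnames = list(c("e1", "e2"), c("r1", "r2")))
  act <- call_activity(cpmat)
  expect_false(act[element_id == "e1"]$active)   # mean 0.6
  expect_true(act[element_id == "e2"]$active)    # mean 2.25
})

test_that("active/silent contrasts recover planted length and age shifts", {
  withr::with_seed(81, {
    n <- 60L
    el <- data.table(element_id = sprintf("e%02d", 1:n), seq_id = "chr1",
                     start = 0L, end = 0L)
    el$end <- as.integer(c(rnorm(n / 2, 2500, 300), rnorm(n / 2, 8500, 300)))
    ages <- data.table(element_id = el$element_id,
                       T_MY = c(runif(n / 2, 0, 0.5), runif(n / 2, 2, 4)))
    act <- data.table(element_id = el$element_id,
                      active = rep(c(TRUE, FALSE), each = n / 2))
  })
  res <- compare_active_silent(el, ages, act)
  expect_equal(res[variable == "length_bp"]$direction, "active_lower")
  expect_equal(res[variable == "age_MY"]$direction, "active_lower")
  expect_true(all(res$p_value < 0.05))
  # identical groups (first half duplicated into the second): p near 1
  ages2 <- copy(ages)[, T_MY := rep(ages$T_MY[1:(n / 2)], 2)]
  el2 <- copy(el)[, end := rep(el$end[1:(n / 2)], 2)]
  res2 <- compare_active_silent(el2, ages2, act)
  expect_true(all(res2$p_value > 0.5))
})

test_that("a single covered cytosine lands in the right body bin", {
  el <- data.table(seq_id = "chr1", start = 1000L, end = 3000L)
  calls <- data.table(seq_id = "chr1", pos = 1050L, strand = "+",
                      context = "CG", meth_count = 3L, unmeth_count = 1L)
  prof <- metaprofile(calls, el)
  hit <- prof[region == "body" & !is.na(level)]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$level, 0.75)
  expect_equal(hit$bin, 0L)   # 1050 is in the first of 20 body bins
  # all other bins are missing, not zero
  expect_true(all(is.na(prof[region == "body" & bin > 0L & context == "CG"]$level)))
})

test_that("low-coverage cytosines are excluded by min_cov", {
  el <- data.table(seq_id = "chr1", start = 0L, end = 2000L)
  calls <- data.table(seq_id = "chr1", pos = c(10L, 20L), strand = "+",
                      context = "CG", meth_count = c(3L, 1L),
                      unmeth_count = c(1L, 1L))
  prof <- metaprofile(calls, el, min_cov = 4L)
  expect_equal(prof[region == "body" & bin == 0L & context == "CG"]$n_cytosines, 1L)
})

test_that("metaprofile equals the brute-force oracle bin by bin", {
  sim <- simulate_genome(sim_config(seed = 82, genome_length = 60000L,
                                    n_intact = 4L, n_solo = 0L,
                                    n_solo_without_tsd = 0L, n_truncated = 0L,
                                    n_genes = 0L,
                                    ltr_length_range = c(150L, 300L),
                                    internal_length_range = c(300L, 800L)))
  el <- sim$truth[kind == "intact", .(seq_id, start, end, active)]
  got <- metaprofile(sim$cx, el, strata = "active")
  want <- oracle_metaprofile(sim$cx, el, strata = "active")
  got[, stratum := as.character(active)]
  m <- merge(got[n_cytosines > 0L],
             want, by = c("stratum", "context", "region", "bin"),
             all = TRUE)
  expect_true(all(!is.na(m$level.x) & !is.na(m$level.y)))
  expect_equal(m$level.x, m$level.y, tolerance = 1e-12)
  expect_equal(m$n_cytosines.x, m$n_cytosines.y)
})

test_that("pooled coverage is conserved across bins (no double counting)", {
  sim <- simulate_genome(sim_config(seed = 83, genome_length = 50000L,
                                    n_intact = 3L, n_solo = 0L,
                                    n_solo_without_tsd = 0L, n_truncated = 0L,
                                    n_genes = 0L,
                                    ltr_length_range = c(150L, 250L),
                                    internal_length_range = c(300L, 600L)))
  el <- sim$truth[kind == "intact", .(seq_id, start, end)]
  prof <- metaprofile(sim$cx, el, min_cov = 4L)
  cc <- sim$cx[meth_count + unmeth_count >= 4L]
  # total coverage inside each element body, recounted independently
  body_cov <- sum(vapply(seq_len(nrow(el)), function(i)
    cc[seq_id == el$seq_id[i] & pos >= el$start[i] & pos < el$end[i],
       sum(meth_count + unmeth_count)], numeric(1)))
  expect_equal(prof[region == "body",
                    sum(total_meth + total_unmeth, na.rm = TRUE)], body_cov)
})

test_that("metaprofile is invariant under row order of calls and elements", {
  sim <- simulate_genome(sim_config(seed = 84, genome_length = 40000L,
                                    n_intact = 3L, n_solo = 0L,
                                    n_solo_without_tsd = 0L, n_truncated = 0L,
                                    n_genes = 0L,
                                    ltr_length_range = c(150L, 250L),
                                    internal_length_range = c(300L, 600L)))
  el <- sim$truth[kind == "intact", .(seq_id, start, end)]
  p1 <- metaprofile(sim$cx, el)
  withr::with_seed(1, {
    p2 <- metaprofile(sim$cx[sample.int(nrow(sim$cx))],
                      el[sample.int(nrow(el))])
  })
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("elements at a sequence edge keep present bins, missing flanks", {
  el <- data.table(seq_id = "chr1", start = 100L, end = 600L)
  calls <- data.table(seq_id = "chr1", pos = c(50L, 150L), strand = "+",
                      context = "CG", meth_count = 5L, unmeth_count = 5L)
  prof <- metaprofile(calls, el)
  up <- prof[region == "upstream" & context == "CG"]
  # only the bins overlapping real sequence can have data; the rest are NA
  expect_true(any(!is.na(up$level)))
  expect_true(any(is.na(up$level)))
})

test_that("flank TE density hits the 0 and 1 endpoints", {
  el <- data.table(element_id = "E1", seq_id = "chr1", start = 5000L,
                   end = 8000L, lineage = "CRM")
  full <- data.table(seq_id = "chr1", start = 0L, end = 20000L, strand = ".",
                     consensus_id = "X", consensus_start = 0L,
                     consensus_end = 20000L, identity = 0.9)
  d <- flank_te_density(el, full)
  expect_equal(d$density, 1.0)
  none <- full[0L]
  d0 <- flank_te_density(el, none)
  expect_equal(d0$density, 0.0)
})

test_that("clustered lineages show denser flanks in simulation", {
  sim <- simulate_genome(sim_config(seed = 85, genome_length = 400000L,
                                    n_intact = 24L, n_genes = 0L,
                                    n_solo = 0L, n_solo_without_tsd = 0L,
                                    n_truncated = 0L, emit_cx = FALSE))
  el <- sim$truth[kind == "intact", .(element_id = feature_id, seq_id,
                                      start, end, lineage)]
  d <- flank_te_density(el, sim$repeat_hits)
  clustered <- d[lineage %in% c("CRM", "SIRE", "Athila")]
  others <- d[!lineage %in% c("CRM", "SIRE", "Athila")]
  if (nrow(clustered) && nrow(others))
    expect_gt(min(clustered$density), max(others$density))
})

test_that("gene and LTR profiles separate when planted to differ", {
  sim <- simulate_genome(sim_config(seed = 86, genome_length = 300000L,
                                    n_intact = 10L, n_genes = 10L,
                                    n_solo = 0L, n_solo_without_tsd = 0L,
                                    n_truncated = 0L, active_fraction = 0))
  el <- sim$truth[kind == "intact", .(seq_id, start, end)]
  pp <- gene_vs_ltr_profile(sim$cx, sim$genes, el)
  gb <- pp$gene[region == "body" & context == "CG"]
  lb <- pp$ltr[region == "body" & context == "CG"]
  expect_gt(mean(lb$level, na.rm = TRUE), mean(gb$level, na.rm = TRUE) + 0.5)
  expect_error(gene_vs_ltr_profile(sim$cx, NULL, el), "gene")
  # shared code path: same features give identical body bins
  direct <- metaprofile(sim$cx, el)
  expect_equal(pp$ltr, direct, ignore_attr = TRUE)
})
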
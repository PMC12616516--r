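test_that("high-confidence filter applies the four criteria with inclusive bounds", {
  cases <- bind_rows(
    valid_call(uuid = "ok"),
    valid_call(uuid = "cov_low", unmap_cover = 0.79),
    valid_call(uuid = "cov_edge", unmap_cover = 0.80),
    valid_call(uuid = "no_tsd", tsd_seq = ""),
    valid_call(uuid = "trunc3", three_prime_intact = 0L),
    valid_call(uuid = "fail", filter = "FAIL")
  )
  out <- filter_high_confidence(cases)
  tiers <- setNames(as.character(out$tier), out$uuid)
  expect_equal(tiers[["ok"]], "high_confidence")
  expect_equal(tiers[["cov_edge"]], "high_confidence")
  expect_equal(tiers[["cov_low"]], "rejected")
  expect_true("unmap_cover" %in% out$failure_reasons[[2]])
  expect_equal(unname(tiers[c("no_tsd", "trunc3", "fail")]), rep("rejected", 3))
  expect_equal(nrow(filter_high_confidence(valid_call()[0, ])), 0)
})

test_that("singleton tier needs a private locus, one support read and >= 10 spanning reads", {
  calls <- bind_rows(
    valid_call(uuid = "a", sample_id = "S01", pos = 1000L),
    valid_call(uuid = "b", sample_id = "S02", pos = 1030L), # same locus
    valid_call(uuid = "c", sample_id = "S01", pos = 9000L,
               n_spanning_nonsupport_reads = 11L),
    valid_call(uuid = "d", sample_id = "S01", pos = 20000L,
               n_spanning_nonsupport_reads = 9L),
    valid_call(uuid = "e", sample_id = "S01", pos = 30000L,
               n_support_reads = 2L)
  )
  out <- classify_singletons(filter_high_confidence(calls))
  tiers <- setNames(as.character(out$tier), out$uuid)
  expect_equal(unname(tiers[c("a", "b")]), rep("high_confidence", 2))
  expect_equal(tiers[["c"]], "singleton")
  expect_equal(tiers[["d"]], "unique_nonreference")
  expect_true("spanning_reads" %in%
                out$failure_reasons[[which(out$uuid == "d")]])
  expect_equal(tiers[["e"]], "unique_nonreference")
})

test_that("L1en tier enforces inclusive TSD bounds, read length, polyA and motif", {
  mk <- function(uuid, ...) valid_call(uuid = uuid, pos = sample.int(1e6, 1), ...)
  set.seed(1)
  calls <- bind_rows(
    mk("tsd4", tsd_seq = strrep("A", 4)),
    mk("tsd5", tsd_seq = strrep("A", 5)),
    mk("tsd31", tsd_seq = strrep("A", 31)),
    mk("tsd32", tsd_seq = strrep("A", 32)),
    mk("short_read", support_read_len_bp = 9999L),
    mk("edge_read", support_read_len_bp = 10000L),
    mk("no_polya", polyA = 0L),
    mk("no_motif", junction_seq = "CCGGCCGGCCGGCCGGCCGG"),
    mk("short_junction", junction_seq = "ACGT")
  )
  out <- classify_insertions(calls)
  tiers <- setNames(as.character(out$tier), out$uuid)
  reasons <- setNames(out$failure_reasons, out$uuid)
  expect_equal(unname(tiers[c("tsd5", "tsd31", "edge_read")]),
               rep("l1en_singleton", 3))
  expect_equal(tiers[["tsd4"]], "singleton")
  expect_true("tsd_len" %in% reasons[["tsd4"]])
  expect_equal(tiers[["tsd32"]], "singleton")
  expect_equal(tiers[["short_read"]], "singleton")
  expect_equal(tiers[["no_polya"]], "singleton")
  expect_equal(tiers[["no_motif"]], "singleton")
  expect_true("motif" %in% reasons[["no_motif"]])
  expect_true("junction_too_short" %in% reasons[["short_junction"]])
})

test_that("the endonuclease motif matcher honours mismatches, strand and anchoring", {
  # planted motif at the cleavage point, forward and reverse complement
  expect_true(has_l1en_motif("ACGTACGTTAAAACGTACGT"))
  expect_true(has_l1en_motif("ACGTACGTTTTAACGTACGT")) # TTTTAA = revcomp
  # one mismatch tolerated, two not
  expect_true(has_l1en_motif("ACGTACGTTACAACGTACGT"))
  expect_false(has_l1en_motif("ACGTACGTGACAACGTACGT", max_mismatch = 1))
  # perfect motif far from the cleavage point is not anchored
  expect_false(has_l1en_motif("TTAAAACCCCCCCGGGGGGGCCCCCCCC"))
  expect_true(is.na(has_l1en_motif("ACG")))
})

test_that("tier nesting holds and the pipeline matches a naive per-criterion oracle", {
  lay <- toy_layout()
  meta <- toy_meta()
  sim <- simulate_insertion_calls(lay, meta, 4, 3, noise = 0.5, seed = 21)
  out <- classify_insertions(sim$calls)
  # nesting: each tier implies the lower tiers' criteria all pass
  cfg <- dg_config()
  hc_ok <- out$tsd_len > 0 & out$unmap_cover >= cfg$unmap_cover_min &
    out$three_prime_intact == 1 & out$filter == "PASS"
  expect_true(all(hc_ok[out$tier >= "high_confidence"]))
  expect_true(all(out$n_support_reads[out$tier >= "singleton"] == 1))
  expect_true(all(out$tsd_len[out$tier == "l1en_singleton"] >= cfg$tsd_min))
  # oracle equivalence on every call
  expect_equal(as.character(out$tier), unname(naive_tiers(sim$calls)))
})

test_that("noise-free simulation is recovered with perfect precision and recall", {
  lay <- toy_layout()
  meta <- toy_meta()
  sim <- simulate_insertion_calls(lay, meta, 4, 3, noise = 0, seed = 22)
  out <- classify_insertions(sim$calls)
  pred <- out$uuid[out$tier == "l1en_singleton"]
  truth <- sim$truth$uuid[sim$truth$class == "singleton"]
  expect_gt(length(truth), 0)
  expect_setequal(pred, truth)
})

test_that("characterization labels centromere classes and L1-Ta diagnostics", {
  lay <- toy_layout()
  hor <- lay$tracks$active_HOR[1, ]
  calls <- bind_rows(
    valid_call(uuid = "cen", chrom = hor$chrom,
               pos = as.integer(floor((hor$start + hor$end) / 2))),
    valid_call(uuid = "arm", chrom = "chr1", pos = 1000L)
  )
  out <- classify_insertions(calls)
  out$utr3_seq <- c("ACAxyG", "ACAxyT")
  out$subfamily <- "L1Hs"
  ann <- characterize_insertions(out, lay)
  expect_equal(ann$calls$region_class[ann$calls$uuid == "cen"], "active_HOR")
  expect_true(ann$calls$centromeric[ann$calls$uuid == "cen"])
  expect_false(ann$calls$centromeric[ann$calls$uuid == "arm"])
  expect_equal(ann$calls$l1ta, c(TRUE, FALSE))
})

test_that("normalisation divides by diploid genomes sequenced and is linear", {
  expect_equal(normalize_count(4, 6.4), 4)
  expect_equal(normalize_count(4, 12.8), 2)
  expect_equal(normalize_count(0, 8.0), 0)
  expect_error(normalize_count(1, 0), "positive")
  set.seed(3)
  n <- runif(20, 0, 100)
  g <- runif(20, 1, 20)
  expect_equal(normalize_count(3 * n, g), 3 * normalize_count(n, g))
  expect_equal(normalize_count(n, 2 * g), normalize_count(n, g) / 2)
})

test_that("group comparison reproduces hand-computed ANOVA and t edge cases", {
  df <- tibble(
    value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    group = rep(c("g1", "g2", "g3"), each = 3)
  )
  # sums of squares by hand: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  res <- compare_groups(df)
  expect_equal(res$statistic, 3)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(unname(res$group_means), c(2, 3, 4))

  same <- tibble(value = rep(c(1, 2, 3), 3), group = rep(c("a", "b", "c"), each = 3))
  res0 <- compare_groups(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  tt <- compare_groups(
    tibble(value = rep(c(1, 2, 3), 2), group = rep(c("a", "b"), each = 3)),
    mode = "t"
  )
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  expect_error(compare_groups(tibble(value = c(1, 2, 3), group = c("a", "a", "b"))),
               "at least 2 values")
  g <- glance(res)
  expect_equal(g$statistic, 3)
  expect_equal(tidy(res)$mean, c(2, 3, 4))
})

test_that("Fisher region enrichment matches exhaustive hypergeometric enumeration", {
  lay <- toy_layout()
  arms <- lay$arms[1, ]
  cen_pos <- as.integer((arms$cen_start + arms$cen_end) / 2)
  mk_calls <- function(n, pos) {
    tibble(chrom = "chr1", pos = pos + seq_len(n) * 10L)
  }
  # all-foreground-in vs all-background-out: OR infinite, tiny p
  fg <- mk_calls(10, cen_pos)
  bg <- mk_calls(10, 1000L)
  cen_tracks <- c("active_HOR", "inactive_HOR", "monomeric_alphasat",
                  "beta_satellite", "classical_satellite")
  res <- fisher_region_enrichment(fg, bg, lay, cen_tracks)
  expect_equal(unname(res$table[1, ]), c(10, 0))
  expect_true(is.infinite(res$odds_ratio))
  expect_lt(res$p, 0.001)
  expect_equal(res$p, fisher_bruteforce(res$table), tolerance = 1e-10)

  # balanced table: p = 1
  fg2 <- bind_rows(mk_calls(5, cen_pos), mk_calls(5, 1000L))
  bg2 <- bind_rows(mk_calls(5, cen_pos + 200L), mk_calls(5, 3000L))
  res2 <- fisher_region_enrichment(fg2, bg2, lay, cen_tracks)
  expect_equal(res2$p, 1)
  expect_equal(res2$p, fisher_bruteforce(res2$table))

  # random tables agree with the enumeration oracle
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(stats::fisher.test(tab)$p.value, fisher_bruteforce(tab),
                 tolerance = 1e-8)
  }
  expect_error(fisher_region_enrichment(fg[0, ], bg, lay, cen_tracks),
               "non-empty")
})

test_that("per-sample tier counts normalise by sequencing depth", {
  lay <- toy_layout()
  meta <- toy_meta()
  sim <- simulate_insertion_calls(lay, meta, 2, 3, seed = 30)
  out <- classify_insertions(sim$calls)
  counts <- normalized_tier_counts(out, meta)
  expect_equal(nrow(counts), nrow(meta))
  expect_equal(counts$normalized,
               counts$n / (meta$gbp_sequenced / 6.4))
  truth_n <- sim$truth %>%
    filter(class == "singleton") %>%
    count(sample_id)
  joined <- left_join(counts, truth_n, by = "sample_id") %>%
    mutate(n.y = tidyr::replace_na(n.y, 0L))
  expect_equal(joined$n.x, joined$n.y)
})
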
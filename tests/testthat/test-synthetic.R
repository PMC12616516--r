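test_that("make_toy_genome is deterministic, band-structured and bounded", {
  a <- toy_layout(seed = 7)
  b <- toy_layout(seed = 7)
  expect_identical(a, b)
  c <- toy_layout(seed = 8)
  expect_false(identical(a$tracks$repeat_element, c$tracks$repeat_element))

  expect_error(make_toy_genome(centromere_frac = 0.6), "centromere_frac")
  expect_error(make_toy_genome(centromere_frac = 0.45, dark_frac = 0.5,
                               rdna_frac = 0.1), "exceed")

  # centromere span is frac * length, split into contiguous bands
  expect_equal(a$arms$cen_end - a$arms$cen_start, rep(1e6, 2))
  cen_tracks <- c("active_HOR", "inactive_HOR", "monomeric_alphasat",
                  "beta_satellite", "classical_satellite")
  for (ch in a$chromosomes$chrom) {
    spans <- dplyr::bind_rows(a$tracks[cen_tracks]) %>% filter(chrom == ch)
    expect_equal(sum(spans$end - spans$start), 1e6)
    expect_equal(min(spans$start), a$arms$cen_start[a$arms$chrom == ch])
    expect_equal(max(spans$end), a$arms$cen_end[a$arms$chrom == ch])
  }
  expect_equal(a$tracks$rDNA_array$chrom, "chr2")
})

test_that("insertion simulator plants singletons satisfying every criterion and labels noise", {
  lay <- toy_layout()
  meta <- toy_meta()
  sim <- simulate_insertion_calls(lay, meta, 3, 3, noise = 0.5, seed = 2)
  expect_true(all(sim$truth$uuid %in% sim$calls$uuid))

  cfg <- dg_config()
  sing <- sim$calls %>% filter(uuid %in% sim$truth$uuid[sim$truth$class == "singleton"])
  expect_true(all(nchar(sing$tsd_seq) >= cfg$tsd_min &
                    nchar(sing$tsd_seq) <= cfg$tsd_max))
  expect_true(all(sing$unmap_cover >= cfg$unmap_cover_min))
  expect_true(all(sing$n_support_reads == 1))
  expect_true(all(sing$n_spanning_nonsupport_reads >= cfg$min_spanning_reads))
  expect_true(all(sing$support_read_len_bp >= cfg$singleton_read_len_min))
  expect_true(all(sing$polyA == 1))
  expect_true(all(vapply(sing$junction_seq, has_l1en_motif, logical(1))))

  noise <- sim$truth %>% filter(class == "noise")
  expect_true(all(!is.na(noise$violated)))

  # determinism and the zero-rate edge
  sim2 <- simulate_insertion_calls(lay, meta, 3, 3, noise = 0.5, seed = 2)
  expect_identical(sim$calls, sim2$calls)
  none <- simulate_insertion_calls(lay, meta, 2, 0, seed = 3)
  expect_equal(sum(none$truth$class == "singleton"), 0)
})

test_that("unbiased placement puts a binomial fraction of insertions in the centromere", {
  lay <- toy_layout()
  meta <- toy_meta(20, groups = c("A", "B"))
  sim <- simulate_insertion_calls(lay, meta, 0, 50, centromere_bias = 1, seed = 13)
  n <- nrow(sim$calls)
  expect_gt(n, 1500)
  q <- tibble(chrom = sim$calls$chrom, start = sim$calls$pos,
              end = sim$calls$pos + 1)
  arms <- lay$arms
  in_cen <- mapply(function(ch, p) {
    p >= arms$cen_start[arms$chrom == ch] & p < arms$cen_end[arms$chrom == ch]
  }, sim$calls$chrom, sim$calls$pos)
  cen_frac <- sum(arms$cen_end - arms$cen_start) / sum(lay$chromosomes$length)
  ci <- binom_ci(sum(in_cen), n)
  expect_true(cen_frac >= ci[1] && cen_frac <= ci[2])
})

test_that("NAHR simulator respects hotspots, scores and determinism", {
  lay <- toy_layout()
  meta <- toy_meta()
  hot <- lay$tracks$rDNA_array %>% mutate(multiplier = 10)
  sim <- simulate_nahr_events(lay, meta, 0.5, hotspot_windows = hot, seed = 4)
  expect_identical(
    sim$events,
    simulate_nahr_events(lay, meta, 0.5, hotspot_windows = hot, seed = 4)$events
  )
  kept <- sim$truth$kept
  expect_true(all(sim$events$score[kept] <= 1e-4))
  expect_true(all(sim$events$singleton[kept] == 1))
  # every reject fails at least one of the two filters
  expect_true(all(sim$events$score[!kept] > 1e-4 |
                    sim$events$singleton[!kept] == 0))
  expect_error(
    simulate_nahr_events(lay, meta, 0.5,
                         hotspot_windows = tibble(chrom = "chr9", start = 0,
                                                  end = 1e5, multiplier = 2)),
    "outside layout"
  )
  expect_error(
    simulate_nahr_events(lay, meta, 0.5,
                         hotspot_windows = mutate(hot, multiplier = 0.5)),
    "multiplier"
  )
})

test_that("methylation simulator obeys the law of large numbers and plants DMRs", {
  lay <- toy_layout()
  meta <- toy_meta(3, groups = c("Braak0", "BraakIII"))
  reg <- tibble(chrom = "chr1", start = 0, end = 5e4)
  # phi = 0, large depth, no DMRs: group means agree within 1%
  sim <- simulate_methylation_calls(lay, meta, depth = 2000, dispersion = 0,
                                    regions = reg, satellite_rate = 0, seed = 6)
  mat <- build_site_matrix(sim$tables, meta)
  freq <- mat$meth / mat$total
  g <- meta$group
  m0 <- mean(freq[, g == "Braak0"])
  m1 <- mean(freq[, g == "BraakIII"])
  expect_lt(abs(m0 - m1), 0.01)

  # planted delta outside [0,1] errors
  expect_error(
    simulate_methylation_calls(
      lay, meta, baseline = c(.default = 0.9),
      planted_dmrs = tibble(chrom = "chr1", start = 1e4, end = 2e4,
                            delta = 0.3, group = "BraakIII"),
      regions = reg
    ),
    "outside"
  )

  # same seed gives identical tables
  s1 <- simulate_methylation_calls(lay, meta, regions = reg, seed = 9)
  s2 <- simulate_methylation_calls(lay, meta, regions = reg, seed = 9)
  expect_identical(s1$tables, s2$tables)
})

test_that("SV simulator plants group-unique variants and honours missing-rate edges", {
  lay <- toy_layout()
  meta <- toy_meta()
  none <- simulate_sv_calls(lay, meta, 5, 0, missing_gt_rate = 0, seed = 2)
  expect_equal(sum(none$truth$class == "group_unique"), 0)

  all_missing <- simulate_sv_calls(lay, meta, 5, 5, missing_gt_rate = 1, seed = 2)
  r <- filter_and_group_unique(all_missing$variants, meta)
  expect_equal(nrow(r$group_unique), 0)

  s1 <- simulate_sv_calls(lay, meta, 5, 5, seed = 3)
  s2 <- simulate_sv_calls(lay, meta, 5, 5, seed = 3)
  expect_identical(s1$variants, s2$variants)
})
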
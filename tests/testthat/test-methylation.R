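meth_records <- function(pos, chrom = "chr1", depth = 10, meth = 5) {
  tibble(
    chromosome = chrom, start = pos, end = pos,
    num_cpgs_in_group = 1L, called_sites = depth,
    called_sites_methylated = meth,
    methylated_frequency = meth / depth
  )
}

test_that("CpG cluster dedup keeps the most 5' record with transitive chaining", {
  expect_equal(dedup_cpg_clusters(meth_records(c(100, 105, 109)))$start, 100)
  expect_equal(dedup_cpg_clusters(meth_records(c(100, 111)))$start, c(100, 111))
  expect_equal(dedup_cpg_clusters(meth_records(c(100, 109, 118)))$start, 100)
  expect_equal(dedup_cpg_clusters(meth_records(c(100, 110, 121)))$start,
               c(100, 121))
  # chromosomes do not chain into each other
  two <- bind_rows(meth_records(c(100, 105)), meth_records(5, chrom = "chr2"))
  expect_equal(nrow(dedup_cpg_clusters(two)), 2)
  expect_error(dedup_cpg_clusters(meth_records(c(200, 100))), "sorted")
})

test_that("site matrix applies the read-support and 3-sample filters", {
  meta <- toy_meta(2, groups = c("Braak0", "BraakIII"))[1:4, ]
  tabs <- list(
    S01 = bind_rows(meth_records(100), meth_records(200), meth_records(300, depth = 2, meth = 1)),
    S02 = bind_rows(meth_records(100), meth_records(200), meth_records(300)),
    S03 = bind_rows(meth_records(100), meth_records(300)),
    S04 = bind_rows(meth_records(100))
  )
  m <- build_site_matrix(tabs, meta[1:4, ])
  # site 100: 4 samples; 200: 2 samples (dropped); 300: depth-2 entry of S01
  # masked, so only S02+S03 remain (dropped)
  expect_equal(m$sites$pos, 100)
  expect_equal(m$sites$n_samples_called, 4)
  expect_error(
    build_site_matrix(list(S01 = bind_rows(meth_records(100), meth_records(100))),
                      meta[1, ]),
    "duplicate"
  )
})

test_that("counts are reconstructed from frequency when not carried", {
  meta <- toy_meta(2, groups = c("A", "B"))[1:4, ]
  tab <- meth_records(c(100, 150, 200))
  tab$called_sites_methylated <- NULL
  tab$methylated_frequency <- c(0.3, 0.7, 1)
  tabs <- setNames(rep(list(tab), 4), meta$sample_id)
  m <- build_site_matrix(tabs, meta)
  expect_equal(unname(m$meth[, 1]), c(3, 7, 10))
})

test_that("MDS screen flags a planted outlier and is exact for planar configurations", {
  meta <- tibble(sample_id = sprintf("S%02d", 1:7), group = "g")
  set.seed(5)
  pos <- seq(100, 100 + 199 * 60, by = 60)
  base <- runif(200, 0.3, 0.9)
  tabs <- lapply(1:7, function(i) {
    lvl <- base
    if (i == 7) lvl[1:100] <- pmin(1, lvl[1:100] + 0.3)
    lvl <- pmin(1, pmax(0, lvl + rnorm(200, 0, 0.01)))
    m <- round(lvl * 50)
    tibble(chromosome = "chr1", start = pos, end = pos,
           num_cpgs_in_group = 1L, called_sites = 50L,
           called_sites_methylated = m, methylated_frequency = m / 50)
  })
  names(tabs) <- meta$sample_id
  mat <- build_site_matrix(tabs, meta)
  scr <- mds_outlier_screen(mat)
  expect_equal(scr$sample_id[scr$outlier], "S07")
  # identical samples: nothing flagged
  tabs0 <- setNames(rep(list(tabs[[1]]), 4), meta$sample_id[1:4])
  scr0 <- mds_outlier_screen(build_site_matrix(tabs0, meta[1:4, ]))
  expect_equal(sum(scr0$outlier), 0)
  expect_error(mds_outlier_screen(build_site_matrix(tabs0[1:3], meta[1:3, ])),
               "4 samples")
  # rank-2 configurations embed with distances preserved
  emb_pts <- matrix(c(0, 0, 3, 0, 0, 4, 3, 4), ncol = 2, byrow = TRUE)
  d <- dist(emb_pts)
  emb <- cmdscale(d, k = 2)
  expect_equal(as.numeric(dist(emb)), as.numeric(d), tolerance = 1e-9)
})

test_that("the Wald test is zero for identical groups and extreme for separated ones", {
  meta <- toy_meta(3, groups = c("Braak0", "BraakIII"))
  mk_mat <- function(meth1, meth2, depth = 10) {
    pos <- c(100, 200)
    tabs <- lapply(seq_len(nrow(meta)), function(i) {
      m <- if (meta$group[i] == "BraakIII") meth1 else meth2
      tibble(chromosome = "chr1", start = pos, end = pos,
             num_cpgs_in_group = 1L, called_sites = depth,
             called_sites_methylated = m, methylated_frequency = m / depth)
    })
    names(tabs) <- meta$sample_id
    build_site_matrix(tabs, meta)
  }
  same <- betabinom_dm_test(mk_mat(c(5, 5), c(5, 5)), "BraakIII", "Braak0")
  expect_equal(same$stat, c(0, 0))
  expect_equal(same$p, c(1, 1))

  sep <- betabinom_dm_test(mk_mat(c(10, 10), c(0, 0)), "BraakIII", "Braak0")
  expect_true(all(sep$p < 1e-6))
  expect_true(all(sep$stat > 0))
  expect_equal(sep$diff, c(1, 1))
})

test_that("statistic sign always matches the sign of the group difference", {
  lay <- toy_layout()
  meta <- toy_meta(3, groups = c("Braak0", "BraakIII"))
  sim <- simulate_methylation_calls(
    lay, meta, depth = 12,
    regions = tibble(chrom = "chr1", start = 0, end = 3e4), seed = 31
  )
  res <- betabinom_dm_test(build_site_matrix(sim$tables, meta),
                           "BraakIII", "Braak0")
  expect_gt(nrow(res), 100)
  expect_true(all(sign(res$stat) == sign(res$diff) | res$diff == 0))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$q[order(res$p)] == cummax(res$q[order(res$p)])))
})

test_that("type-I error is calibrated at the beta-binomial null", {
  lay <- make_toy_genome(1, 2e6, 0.1, seed = 7, repeat_density = 0.1,
                         dark_frac = 0.01)
  meta <- toy_meta(6, groups = c("Braak0", "BraakIII"))
  sim <- simulate_methylation_calls(
    lay, meta, depth = 10, dispersion = 0.05,
    regions = tibble(chrom = "chr1", start = 0, end = 100050),
    grid_step = 50, satellite_rate = 0, seed = 2
  )
  res <- betabinom_dm_test(build_site_matrix(sim$tables, meta),
                           "BraakIII", "Braak0")
  expect_equal(nrow(res), 2000)
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("DMR chaining follows the p, sign, gap and size rules; areaStat sums members", {
  site <- function(pos, stat, p, diff) {
    tibble(chrom = "chr1", pos = pos, p1 = 0.5 + diff, p2 = 0.5, diff = diff,
           phi = 0.05, stat = stat, p = p, n1 = 6, n2 = 6, q = p)
  }
  res <- bind_rows(
    site(100, 2.1, 0.01, 0.2), site(150, 3.0, 0.001, 0.25),
    site(200, 2.4, 0.02, 0.22), # one DMR, areaStat 7.5
    site(400, 2.5, 0.01, 0.2), site(450, -2.5, 0.01, -0.2),
    site(500, 2.5, 0.01, 0.2), # alternating signs: no chain of 3
    site(800, 2.2, 0.01, 0.2), site(850, 2.2, 0.01, 0.2),
    site(900, 2.2, 0.01, 0.2),
    site(1051, 2.2, 0.01, 0.2), site(1101, 2.2, 0.01, 0.2),
    site(1151, 2.2, 0.01, 0.2) # gap 151 > 100 splits the runs
  )
  dmrs <- call_dmrs(res)
  expect_equal(nrow(dmrs), 3)
  expect_equal(dmrs$areaStat[1], 7.5)
  expect_equal(dmrs$n_cpg, c(3, 3, 3))
  expect_equal(dmrs$start[2:3], c(800, 1051))
  expect_true(all(dmrs$direction == "hyper"))

  # areaStat additivity: splitting any DMR at an interior site reproduces it
  run <- bind_rows(lapply(1:6, function(i) site(100 + 50 * i, 2 + i / 10, 0.01, 0.2)))
  whole <- call_dmrs(run)
  left <- call_dmrs(run[1:3, ])
  right <- call_dmrs(run[4:6, ])
  expect_equal(whole$areaStat, left$areaStat + right$areaStat)

  # non-significant sites break chains
  expect_equal(nrow(call_dmrs(bind_rows(
    site(100, 2, 0.01, 0.2), site(150, 1, 0.2, 0.1), site(200, 2, 0.01, 0.2)
  ))), 0)
})

test_that("planted DMRs are recovered with correct sign and high site Jaccard", {
  lay <- make_toy_genome(1, 2e6, 0.1, seed = 7, repeat_density = 0.1,
                         dark_frac = 0.01)
  meta <- toy_meta(6, groups = c("Braak0", "BraakIII"))
  planted <- tibble(
    chrom = "chr1",
    start = seq(1e5, 1e5 + 4 * 5e4, by = 5e4),
    end = start + 975,
    delta = c(-0.3, 0.3, -0.3, 0.3, -0.3),
    group = "BraakIII"
  )
  score_seed <- function(s) {
    sim <- simulate_methylation_calls(
      lay, meta, depth = 10, dispersion = 0.05, baseline = c(.default = 0.5),
      planted_dmrs = planted,
      regions = tibble(chrom = "chr1", start = 0, end = 4e5),
      grid_step = 50, satellite_rate = 0, seed = s
    )
    res <- betabinom_dm_test(build_site_matrix(sim$tables, meta),
                             "BraakIII", "Braak0")
    dmrs <- call_dmrs(res)
    truth_sites <- lapply(seq_len(nrow(planted)), function(i) {
      sim$sites$pos[!is.na(sim$sites$dmr_id) & sim$sites$dmr_id == i]
    })
    all_pos <- res$pos
    vapply(seq_len(nrow(planted)), function(i) {
      hit <- dmrs[dmrs$start <= planted$end[i] & dmrs$end >= planted$start[i] &
                    (dmrs$direction == ifelse(planted$delta[i] > 0, "hyper", "hypo")), ]
      # a DMR is an interval: its site set is every tested CpG it contains
      got <- unique(unlist(lapply(seq_len(nrow(hit)), function(j) {
        all_pos[all_pos >= hit$start[j] & all_pos < hit$end[j]]
      })))
      jac <- length(intersect(got, truth_sites[[i]])) /
        length(union(got, truth_sites[[i]]))
      jac >= 0.8
    }, logical(1))
  }
  rec <- unlist(lapply(1:4, score_seed))
  expect_gte(mean(rec), 0.8)
})

test_that("retroelement loci face strict length and CpG-count thresholds", {
  reps <- tibble(
    chrom = "chr1",
    start = c(1e4, 3e4, 5e4, 7e4),
    end = c(1e4 + 5900, 3e4 + 5901, 5e4 + 290, 7e4 + 290),
    family = c("L1", "L1", "Alu", "Alu"),
    subfamily = c("L1Hs", "L1Hs", "AluYa5", "AluYa5"),
    strand = "+"
  )
  lay <- genome_layout(tibble(chrom = "chr1", length = 1e6),
                       tracks = list(repeat_element = reps))
  meta <- toy_meta(2, groups = c("A", "B"))[1:4, ]
  # 12 CpG sites inside each of the first three loci, 9 in the fourth
  pos <- c(seq(1e4 + 10, by = 480, length.out = 12),
           seq(3e4 + 10, by = 480, length.out = 12),
           seq(5e4 + 10, by = 24, length.out = 12),
           seq(7e4 + 10, by = 30, length.out = 9))
  tabs <- setNames(rep(list(meth_records(sort(pos))), 4), meta$sample_id)
  m <- build_site_matrix(tabs, meta)
  out <- retroelement_methylation(m, lay)
  # L1Hs at exactly 5900 bp excluded (strict), 5901 included;
  # AluYa5 290 bp with 12 sites included, 9 sites excluded
  expect_setequal(out$loci$start, c(3e4, 5e4))
  expect_equal(out$loci$mean_freq, rep(0.5, 2))
  expect_equal(out$family_summary$n_loci, c(1, 1))
  # unknown family: retained with a warning
  lay2 <- lay
  lay2$tracks$repeat_element$subfamily <- "MER41"
  expect_warning(retroelement_methylation(m, lay2), "threshold")
})

test_that("promoters count at most once per methylation direction", {
  dmrs <- tibble(
    chrom = "chr1",
    start = c(100, 300, 500, 2000),
    end = c(200, 400, 600, 2100),
    n_cpg = 3L, mean_diff = c(-0.2, -0.3, 0.25, -0.2),
    areaStat = c(-7, -8, 7, -6),
    direction = c("hypo", "hypo", "hyper", "hypo")
  )
  promoters <- tibble(
    chrom = "chr1", start = c(0, 1900, 5000), end = c(1000, 2200, 6000),
    gene = c("GENE1", "GENE2", "GENE3")
  )
  out <- promoter_dm_summary(dmrs, promoters)
  # promoter 1 holds 2 hypo + 1 hyper DMRs: one count per direction
  expect_equal(out$promoters$hypo, c(1, 1, 0))
  expect_equal(out$promoters$hyper, c(1, 0, 0))
  expect_equal(out$genes$hypo[out$genes$gene == "GENE1"], 1)
  expect_equal(out$genes$hypo[out$genes$gene == "GENE3"], 0)
})
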
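# Seeded generators emulating the upstream callers' outputs with planted,
# labelled truth. Every generator is a pure function of (parameters, seed);
# one global seed fans out to fixed per-generator child seeds so modules can
# be regenerated independently.

child_seed <- function(seed, stream) {
  # double arithmetic: exact below 2^53, avoids 32-bit overflow
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483563)
}

#' Build a toy genome layout with centromere band structure
#'
#' Chromosomes carry a mid-chromosome centromere split into an active
#' alpha-satellite HOR core flanked symmetrically by inactive HOR,
#' monomeric alpha satellite, beta satellite and classical satellite bands;
#' designated chromosomes get an rDNA array on the p arm (acrocentric
#' mimic); dark regions and a genome-wide mix of repeat elements
#' (Alu/L1/SVA/LTR subfamilies) are placed at random. Deterministic for a
#' fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (shared).
#' @param centromere_frac fraction of each chromosome occupied by the
#'   centromere (0 < frac < 0.5).
#' @param rdna_chroms chromosome names (e.g. `"chr2"`) receiving a p-arm
#'   rDNA array.
#' @param dark_frac fraction of each chromosome covered by dark regions.
#' @param repeat_density repeat elements per kbp.
#' @param rdna_frac fraction of a designated chromosome occupied by its
#'   rDNA array.
#' @param seed integer seed.
#' @return a [genome_layout()].
#' @export
make_toy_genome <- function(n_chrom = 2, chrom_len = 1e7, centromere_frac = 0.1,
                            rdna_chroms = character(0), dark_frac = 0.05,
                            repeat_density = 1.0, rdna_frac = 0.04, seed = 1) {
  if (centromere_frac <= 0 || centromere_frac >= 0.5) {
    stop("centromere_frac must be in (0, 0.5)")
  }
  if (centromere_frac + dark_frac + rdna_frac >= 1) {
    stop("region fractions exceed chromosome length")
  }
  set.seed(child_seed(seed, 1L))
  chroms <- paste0("chr", seq_len(n_chrom))
  chromosomes <- tibble(chrom = chroms, length = chrom_len)

  cen_len <- centromere_frac * chrom_len
  cen_start <- chrom_len / 2 - cen_len / 2
  cen_end <- cen_start + cen_len
  # band widths, centre outward: active core 1/3 of the centromere, then
  # four satellite classes at 1/12 per side
  core <- cen_len / 3
  band <- cen_len / 12
  band_classes <- c("inactive_HOR", "monomeric_alphasat",
                    "beta_satellite", "classical_satellite")
  cen_tracks <- list(active_HOR = tibble(
    chrom = chroms,
    start = cen_start + 4 * band,
    end = cen_start + 4 * band + core
  ))
  for (i in seq_along(band_classes)) {
    off <- (4 - i) * band
    cen_tracks[[band_classes[i]]] <- bind_rows(
      tibble(chrom = chroms, start = cen_start + off, end = cen_start + off + band),
      tibble(chrom = chroms, start = cen_end - off - band, end = cen_end - off)
    )
  }

  rdna <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  if (length(rdna_chroms)) {
    bad <- setdiff(rdna_chroms, chroms)
    if (length(bad)) stop("rdna_chroms not in layout: ", paste(bad, collapse = ", "))
    rdna <- tibble(
      chrom = rdna_chroms,
      start = 0.02 * chrom_len,
      end = 0.02 * chrom_len + rdna_frac * chrom_len
    )
  }

  dark <- purrr::map_dfr(chroms, function(ch) {
    n_seg <- 5L
    seg <- dark_frac * chrom_len / n_seg
    starts <- sort(stats::runif(n_seg, 0, chrom_len - seg))
    tibble(chrom = ch, start = starts, end = starts + seg)
  })

  sub_mix <- c(
    AluYa5 = 0.3, AluYb8 = 0.15, L1Hs = 0.15, L1PA3 = 0.15,
    `SVA-E` = 0.1, `SVA-F` = 0.05, LTR5_Hs = 0.05, `HERV-K` = 0.05
  )
  sub_len <- c(
    AluYa5 = 300, AluYb8 = 300, L1Hs = 6000, L1PA3 = 6000,
    `SVA-E` = 1400, `SVA-F` = 1400, LTR5_Hs = 970, `HERV-K` = 7000
  )
  repeats <- purrr::map_dfr(chroms, function(ch) {
    n_rep <- round(repeat_density * chrom_len / 1000)
    subf <- sample(names(sub_mix), n_rep, replace = TRUE, prob = sub_mix)
    len <- round(sub_len[subf] * stats::runif(n_rep, 0.5, 1.1))
    start <- round(stats::runif(n_rep, 0, chrom_len - max(sub_len) * 1.1))
    tibble(
      chrom = ch, start = start, end = start + len,
      family = family_of(subf), subfamily = subf,
      strand = sample(c("+", "-"), n_rep, replace = TRUE)
    )
  })

  genome_layout(
    chromosomes,
    tracks = c(cen_tracks, list(
      rDNA_array = rdna, dark_region = dark, repeat_element = repeats
    )),
    arms = tibble(chrom = chroms, cen_start = cen_start, cen_end = cen_end)
  )
}

#' Collapse a repeat subfamily label to its family
#'
#' `L1PA3`/`L1Hs` -> `L1`; `AluYa5` -> `Alu`; `SVA-E` -> `SVA`;
#' `LTR5_Hs`/`HERV-K` -> `LTR`; anything else keeps its leading
#' alphanumeric token.
#' @param subfamily character vector of subfamily names.
#' @return character vector of family names.
#' @export
family_of <- function(subfamily) {
  dplyr::case_when(
    startsWith(subfamily, "L1") | startsWith(subfamily, "LINE1") ~ "L1",
    startsWith(subfamily, "Alu") ~ "Alu",
    startsWith(subfamily, "SVA") ~ "SVA",
    startsWith(subfamily, "LTR") | startsWith(subfamily, "HERV") ~ "LTR",
    TRUE ~ sub("[^A-Za-z0-9].*$", "", subfamily)
  )
}

#' Build a synthetic sample-metadata table
#'
#' @param n_per_group samples per group.
#' @param groups ordered group labels (Braak staging by default).
#' @param seed integer seed.
#' @return sample-metadata tibble in the `sample_meta` dialect.
#' @export
make_sample_meta <- function(n_per_group = 6,
                             groups = c("Braak0", "BraakIII", "BraakV_VI"),
                             seed = 1) {
  set.seed(child_seed(seed, 9L))
  n <- n_per_group * length(groups)
  tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    group = rep(groups, each = n_per_group),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(stats::runif(n, 65, 95)),
    pmi = round(stats::runif(n, 3, 24), 1),
    gbp_sequenced = round(stats::runif(n, 5, 10), 2),
    mean_coverage = round(stats::runif(n, 8, 20), 1)
  )
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# junction with the endonuclease motif planted flush at the cleavage point
motif_junction <- function(n, motif = "TTAAAA", flank = 10L) {
  left <- random_seq(n, flank)
  right <- random_seq(n, flank)
  paste0(substr(left, 1, flank - 3), motif,
         substr(right, 1, flank + 3 - nchar(motif)))
}

junction_without_motif <- function(n, motif = "TTAAAA", flank = 10L) {
  out <- character(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- random_seq(length(need), 2 * flank)
    ok <- !vapply(cand, has_l1en_motif, logical(1),
                  motif = motif, max_mismatch = 1L, anchor_bp = 3L)
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

sample_positions <- function(layout, n, centromere_bias = 1, lattice = 1000) {
  # disjoint locus lattice so distinct planted loci never share a 50 bp
  # merge window; centromere bias reweights lattice points inside the
  # centromere span
  pts <- purrr::map_dfr(seq_len(nrow(layout$chromosomes)), function(i) {
    ch <- layout$chromosomes$chrom[i]
    len <- layout$chromosomes$length[i]
    tibble(chrom = ch, pos = seq(lattice / 2, len - lattice / 2, by = lattice))
  })
  arms <- layout$arms
  pts <- left_join(pts, arms[, c("chrom", "cen_start", "cen_end")], by = "chrom") %>%
    mutate(cen = .data$pos >= .data$cen_start & .data$pos < .data$cen_end)
  w <- ifelse(pts$cen, centromere_bias, 1)
  if (n > nrow(pts)) stop("not enough lattice points for requested loci")
  idx <- sample(nrow(pts), n, prob = w)
  pts[idx, c("chrom", "pos")]
}

#' Simulate a retrotransposon insertion call table with planted truth
#'
#' Plants three classes of calls: true L1-endonuclease-mediated singletons
#' satisfying every filter criterion (TSD length in the configured bounds,
#' endonuclease motif at the junction, polyA tail, a single supporting read
#' of at least 10 kbp, at least 10 spanning insertion-free reads);
#' polymorphic insertions shared across samples; and noise calls each
#' violating exactly one named criterion, recorded in the truth table.
#'
#' @param layout a [genome_layout()].
#' @param samples sample-metadata tibble.
#' @param polymorphic_rate expected polymorphic loci per sample.
#' @param singleton_rate expected true singletons per sample.
#' @param centromere_bias placement weight for centromeric loci (1 = none).
#' @param subfamily_mix named probability vector over subfamilies.
#' @param noise expected noise calls per sample as a multiple of
#'   `singleton_rate + polymorphic_rate`.
#' @param cfg a [dg_config()].
#' @param seed integer seed.
#' @return list with `calls` (insertion dialect tibble) and `truth`
#'   (uuid, sample_id, chrom, pos, class in
#'   singleton/polymorphic/noise, violated criterion for noise calls).
#' @export
simulate_insertion_calls <- function(layout, samples, polymorphic_rate = 5,
                                     singleton_rate = 3, centromere_bias = 1,
                                     subfamily_mix = c(AluYa5 = 0.5, L1Hs = 0.3, `SVA-E` = 0.2),
                                     noise = 0, cfg = dg_config(), seed = 1) {
  if (polymorphic_rate < 0 || singleton_rate < 0 || noise < 0) {
    stop("rates must be non-negative")
  }
  if (centromere_bias < 1) stop("centromere_bias must be >= 1")
  set.seed(child_seed(seed, 2L))
  n_s <- nrow(samples)
  n_sing <- stats::rpois(n_s, singleton_rate)
  n_poly_loci <- stats::rpois(1, polymorphic_rate * n_s / 2)
  n_noise <- stats::rpois(n_s, noise * (singleton_rate + polymorphic_rate))
  n_loci <- sum(n_sing) + n_poly_loci + sum(n_noise)

  loci <- if (n_loci > 0) {
    sample_positions(layout, n_loci, centromere_bias)
  } else {
    tibble(chrom = character(0), pos = numeric(0))
  }
  li <- 0L
  take_locus <- function() {
    li <<- li + 1L
    loci[li, ]
  }

  flank <- 10L
  mk_valid <- function(sample_id, locus) {
    tsd_len <- sample(seq(cfg$tsd_min, cfg$tsd_max), 1)
    tibble(
      uuid = paste0("ins_", sample_id, "_", round(locus$pos), "_", li),
      sample_id = sample_id,
      chrom = locus$chrom,
      pos = round(locus$pos),
      subfamily = sample(names(subfamily_mix), 1, prob = subfamily_mix),
      filter = "PASS",
      unmap_cover = round(stats::runif(1, cfg$unmap_cover_min, 1), 3),
      three_prime_intact = 1L,
      tsd_seq = random_seq(1, tsd_len),
      n_support_reads = 1L,
      support_read_len_bp = round(cfg$singleton_read_len_min * stats::runif(1, 1, 3)),
      n_spanning_nonsupport_reads = cfg$min_spanning_reads + stats::rpois(1, 5),
      polyA = 1L,
      junction_seq = motif_junction(1, cfg$l1en_motif, flank),
      mapq = sample(c(1L, 20L, 60L), 1)
    )
  }

  calls <- list()
  truth <- list()

  for (i in seq_len(n_s)) {
    sid <- samples$sample_id[i]
    for (k in seq_len(n_sing[i])) {
      loc <- take_locus()
      row <- mk_valid(sid, loc)
      calls[[length(calls) + 1L]] <- row
      truth[[length(truth) + 1L]] <- tibble(
        uuid = row$uuid, sample_id = sid, chrom = row$chrom, pos = row$pos,
        class = "singleton", violated = NA_character_
      )
    }
  }

  for (k in seq_len(n_poly_loci)) {
    loc <- take_locus()
    carriers <- sample(samples$sample_id, sample(2:min(4, n_s), 1))
    for (sid in carriers) {
      row <- mk_valid(sid, loc)
      row$uuid <- paste0(row$uuid, "_", sid)
      row$pos <- round(loc$pos + sample(-10:10, 1))
      row$n_support_reads <- 2L + stats::rpois(1, 3)
      calls[[length(calls) + 1L]] <- row
      truth[[length(truth) + 1L]] <- tibble(
        uuid = row$uuid, sample_id = sid, chrom = row$chrom, pos = row$pos,
        class = "polymorphic", violated = NA_character_
      )
    }
  }

  noise_criteria <- c(
    "tsd_missing", "unmap_cover", "three_prime_intact", "filter",
    "support_reads", "spanning_reads", "tsd_len", "read_len", "polyA", "motif"
  )
  for (i in seq_len(n_s)) {
    sid <- samples$sample_id[i]
    for (k in seq_len(n_noise[i])) {
      loc <- take_locus()
      row <- mk_valid(sid, loc)
      crit <- sample(noise_criteria, 1)
      if (crit == "tsd_missing") row$tsd_seq <- ""
      if (crit == "unmap_cover") row$unmap_cover <- round(stats::runif(1, 0.3, cfg$unmap_cover_min - 0.01), 3)
      if (crit == "three_prime_intact") row$three_prime_intact <- 0L
      if (crit == "filter") row$filter <- "FAIL"
      if (crit == "support_reads") row$n_support_reads <- 2L
      if (crit == "spanning_reads") row$n_spanning_nonsupport_reads <- sample(0:(cfg$min_spanning_reads - 1L), 1)
      if (crit == "tsd_len") {
        bad_len <- sample(c(seq_len(cfg$tsd_min - 1), cfg$tsd_max + 1:5), 1)
        row$tsd_seq <- random_seq(1, bad_len)
      }
      if (crit == "read_len") row$support_read_len_bp <- round(stats::runif(1, 1000, cfg$singleton_read_len_min - 1))
      if (crit == "polyA") row$polyA <- 0L
      if (crit == "motif") row$junction_seq <- junction_without_motif(1, cfg$l1en_motif, flank)
      calls[[length(calls) + 1L]] <- row
      truth[[length(truth) + 1L]] <- tibble(
        uuid = row$uuid, sample_id = sid, chrom = row$chrom, pos = row$pos,
        class = "noise", violated = crit
      )
    }
  }

  calls <- if (length(calls)) bind_rows(calls) else
    validate_calls("insertion", tibble())
  truth <- if (length(truth)) bind_rows(truth) else
    tibble(uuid = character(0), sample_id = character(0), chrom = character(0),
           pos = numeric(0), class = character(0), violated = character(0))
  list(calls = calls, truth = truth)
}

#' Simulate an NAHR event table with planted hotspots
#'
#' Events are placed per 100-kbp window as Poisson draws with rate
#' `base_rate` times the window's hotspot multiplier; endpoint A lands in
#' the window (snapped to a repeat element of the drawn pair class when one
#' is available), endpoint B is interchromosomal with probability
#' `frac_inter`, otherwise intrachromosomal at a nearby locus. True events
#' get caller scores at or below 1e-4 and the singleton flag; planted
#' rejects (a `reject_rate` fraction) fail one of the two filters.
#'
#' @param layout a [genome_layout()].
#' @param samples sample-metadata tibble.
#' @param base_rate expected retained events per window.
#' @param hotspot_windows tibble `chrom`, `start`, `end`, `multiplier`
#'   (>= 1); windows overlapping these intervals get the multiplier.
#' @param pair_mix named probabilities over family pair classes
#'   (e.g. `c("L1-L1" = .4, "Alu-Alu" = .4, "SVA-SVA" = .2)`).
#' @param frac_inter fraction of interchromosomal events.
#' @param reject_rate expected rejects as a fraction of true events.
#' @param cfg a [dg_config()].
#' @param seed integer seed.
#' @return list with `events` (NAHR dialect tibble) and `truth` (event_id,
#'   kept flag, window id, hotspot flag).
#' @export
simulate_nahr_events <- function(layout, samples, base_rate = 0.5,
                                 hotspot_windows = NULL,
                                 pair_mix = c("L1-L1" = 0.4, "Alu-Alu" = 0.4, "SVA-SVA" = 0.2),
                                 frac_inter = 0.3, reject_rate = 0.2,
                                 cfg = dg_config(), seed = 1) {
  if (!is.null(hotspot_windows) && any(hotspot_windows$multiplier < 1)) {
    stop("hotspot multiplier must be >= 1")
  }
  set.seed(child_seed(seed, 3L))
  win <- tile_windows(layout, cfg$window_size)
  win$multiplier <- 1
  if (!is.null(hotspot_windows)) {
    bad <- setdiff(unique(hotspot_windows$chrom), layout$chromosomes$chrom)
    if (length(bad)) stop("hotspot window outside layout: ", paste(bad, collapse = ", "))
    ov <- interval_overlap_pairs(win, hotspot_windows)
    if (nrow(ov)) {
      agg <- tapply(hotspot_windows$multiplier[ov$subject_id], ov$query_id, max)
      win$multiplier[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  reps <- layout$tracks$repeat_element
  chroms <- layout$chromosomes
  len_of <- stats::setNames(chroms$length, chroms$chrom)
  pairs <- names(pair_mix)

  n_true <- stats::rpois(nrow(win), base_rate * win$multiplier)
  n_rej <- stats::rpois(nrow(win), base_rate * reject_rate)
  mk_events <- function(widx, n, kept) {
    if (n == 0) return(NULL)
    w <- win[widx, ]
    pc <- sample(pairs, n, replace = TRUE, prob = pair_mix)
    fams <- stringr::str_split_fixed(pc, "-", 2)
    posA <- numeric(n)
    for (j in seq_len(n)) {
      cand <- reps[reps$chrom == w$chrom & reps$start >= w$start &
                     reps$start < w$end & reps$family == fams[j, 1], ]
      posA[j] <- if (nrow(cand)) {
        cand$start[sample(nrow(cand), 1)]
      } else {
        round(stats::runif(1, w$start, w$end - 1))
      }
    }
    inter <- stats::runif(n) < frac_inter
    chromB <- ifelse(inter,
                     sample(chroms$chrom, n, replace = TRUE),
                     w$chrom)
    posB <- ifelse(inter,
                   round(stats::runif(n) * (len_of[chromB] - 1)),
                   pmin(pmax(posA + round(stats::rnorm(n, 0, 2e5)), 0),
                        len_of[w$chrom] - 1))
    tibble(
      event_id = paste0("nahr_", widx, "_", seq_len(n), "_", kept),
      sample_id = sample(samples$sample_id, n, replace = TRUE),
      chromA = w$chrom, posA = posA,
      familyA = fams[, 1],
      chromB = chromB, posB = posB,
      familyB = fams[, 2],
      score = if (kept) stats::runif(n, 1e-8, cfg$nahr_score_max) else
        stats::runif(n, cfg$nahr_score_max * 1.1, 1e-2),
      singleton = if (kept) 1L else sample(c(0L, 1L), n, replace = TRUE),
      orientation = sample(c("++", "+-", "-+", "--"), n, replace = TRUE),
      kept = kept, window_id = w$window_id, hotspot = w$multiplier > 1
    )
  }
  ev <- bind_rows(
    purrr::map_dfr(seq_len(nrow(win)), ~ mk_events(.x, n_true[.x], TRUE)),
    purrr::map_dfr(seq_len(nrow(win)), ~ mk_events(.x, n_rej[.x], FALSE))
  )
  if (nrow(ev) == 0) {
    ev <- tibble(event_id = character(0), sample_id = character(0),
                 chromA = character(0), posA = numeric(0), familyA = character(0),
                 chromB = character(0), posB = numeric(0), familyB = character(0),
                 score = numeric(0), singleton = integer(0),
                 orientation = character(0), kept = logical(0),
                 window_id = integer(0), hotspot = logical(0))
  }
  # rejects that drew singleton = 1 must fail on score; those with score ok
  # were built to fail: keep invariant by construction (score > 1e-4 there)
  list(
    events = ev[, DIALECTS$nahr],
    truth = ev[, c("event_id", "kept", "window_id", "hotspot")]
  )
}

# generic all-pairs overlap between two interval tables (half-open)
interval_overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query_id = integer(0), subject_id = integer(0)))
  }
  lv <- union(unique(query$chrom), unique(subject$chrom))
  h <- GenomicRanges::findOverlaps(as_granges(query, lv), as_granges(subject, lv))
  tibble(query_id = S4Vectors::queryHits(h),
         subject_id = S4Vectors::subjectHits(h))
}

#' Simulate per-sample CpG methylation frequency tables
#'
#' CpG sites sit on a fixed grid (plus occasional satellite records within
#' 10 bp, to exercise cluster dedup); per-site per-sample methylated counts
#' are beta-binomial with mean equal to the regional baseline level and the
#' given dispersion. Planted DMRs shift the mean by `delta` in the affected
#' group only.
#'
#' @param layout a [genome_layout()].
#' @param samples sample-metadata tibble.
#' @param depth either a single integer (fixed read depth) or a function
#'   `n -> integer vector` drawing depths.
#' @param baseline named numeric vector of methylation levels per region
#'   class, with a `.default` entry; classes are matched against the
#'   centromere tracks and `rDNA_array`.
#' @param planted_dmrs tibble `chrom`, `start`, `end`, `delta`, `group`;
#'   `delta` added to the baseline for samples of `group`.
#' @param dispersion beta-binomial dispersion phi >= 0 (variance
#'   `t p (1-p) (1 + (t-1) phi)`).
#' @param regions optional tibble of intervals to restrict CpG placement
#'   (default: whole genome).
#' @param grid_step spacing of the CpG grid in bp.
#' @param satellite_rate fraction of grid sites that also emit a clustered
#'   satellite record 3-9 bp downstream.
#' @param seed integer seed.
#' @return list with `tables` (named list of methylation-dialect tibbles,
#'   one per sample), `truth` (the planted DMR table) and `sites` (the
#'   deduplicated grid with per-site region class and DMR membership).
#' @export
simulate_methylation_calls <- function(layout, samples, depth = 10,
                                       baseline = c(.default = 0.7),
                                       planted_dmrs = NULL, dispersion = 0.05,
                                       regions = NULL, grid_step = 50,
                                       satellite_rate = 0.05, seed = 1) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  set.seed(child_seed(seed, 4L))
  if (is.null(regions)) {
    regions <- mutate(layout$chromosomes, start = 0, end = .data$length)
  }
  sites <- purrr::pmap_dfr(regions[, c("chrom", "start", "end")],
    function(chrom, start, end) {
      tibble(chrom = chrom, pos = seq(start + grid_step, end - 1, by = grid_step))
    }) %>% distinct(.data$chrom, .data$pos)

  cls <- centromere_class(mutate(sites, start = .data$pos, end = .data$pos + 1), layout)
  if ("rDNA_array" %in% names(layout$tracks)) {
    rh <- interval_overlap(mutate(sites, start = .data$pos, end = .data$pos + 1),
                           layout, "rDNA_array")
    cls[unique(rh$query_id)] <- "rDNA_array"
  }
  base_of <- function(cl) {
    ifelse(!is.na(cl) & cl %in% names(baseline), baseline[cl], baseline[".default"])
  }
  sites$region_class <- cls
  sites$level0 <- as.numeric(base_of(cls))

  sites$dmr_id <- NA_integer_
  sites$delta <- 0
  sites$dmr_group <- NA_character_
  if (!is.null(planted_dmrs) && nrow(planted_dmrs)) {
    ov <- interval_overlap_pairs(
      mutate(sites, start = .data$pos, end = .data$pos + 1), planted_dmrs
    )
    sites$dmr_id[ov$query_id] <- ov$subject_id
    sites$delta[ov$query_id] <- planted_dmrs$delta[ov$subject_id]
    sites$dmr_group[ov$query_id] <- planted_dmrs$group[ov$subject_id]
    shifted <- sites$level0 + ifelse(is.na(sites$dmr_id), 0, sites$delta)
    if (any(shifted < 0 | shifted > 1)) {
      stop("planted delta pushes methylation level outside [0, 1]")
    }
  }

  draw_depth <- if (is.function(depth)) depth else function(n) rep(as.integer(depth), n)
  rbetabinom <- function(n, size, mean, phi) {
    if (phi == 0) return(stats::rbinom(n, size, mean))
    a <- mean * (1 - phi) / phi
    b <- (1 - mean) * (1 - phi) / phi
    p <- stats::rbeta(n, a, b)
    stats::rbinom(n, size, p)
  }

  satellites <- sites %>%
    filter(stats::runif(n()) < satellite_rate) %>%
    mutate(pos = .data$pos + sample(3:9, n(), replace = TRUE))

  tables <- stats::setNames(vector("list", nrow(samples)), samples$sample_id)
  for (i in seq_len(nrow(samples))) {
    grp <- samples$group[i]
    lvl <- sites$level0 +
      ifelse(!is.na(sites$dmr_group) & sites$dmr_group == grp, sites$delta, 0)
    dep <- draw_depth(nrow(sites))
    m <- rbetabinom(nrow(sites), dep, lvl, dispersion)
    tab <- tibble(
      chromosome = sites$chrom, start = sites$pos, end = sites$pos,
      num_cpgs_in_group = 1L, called_sites = dep,
      called_sites_methylated = m,
      methylated_frequency = ifelse(dep > 0, m / dep, 0)
    )
    if (nrow(satellites)) {
      dep2 <- draw_depth(nrow(satellites))
      m2 <- rbetabinom(nrow(satellites), dep2, satellites$level0, dispersion)
      tab <- bind_rows(tab, tibble(
        chromosome = satellites$chrom, start = satellites$pos,
        end = satellites$pos, num_cpgs_in_group = 1L, called_sites = dep2,
        called_sites_methylated = m2,
        methylated_frequency = ifelse(dep2 > 0, m2 / dep2, 0)
      ))
    }
    tables[[i]] <- arrange(tab, match(.data$chromosome, layout$chromosomes$chrom),
                           .data$start)
  }

  truth <- if (is.null(planted_dmrs)) {
    tibble(chrom = character(0), start = numeric(0), end = numeric(0),
           delta = numeric(0), group = character(0))
  } else {
    as_tibble(planted_dmrs)
  }
  list(tables = tables, truth = truth, sites = sites)
}

#' Generate a synthetic query-region set with planted track overlap
#'
#' Builds `n` fixed-size regions of which a `frac_in` fraction start inside
#' intervals of the chosen target (the centromere span or a named track)
#' and the rest are placed uniformly across the genome. Used to exercise
#' the permutation overlap test with a known excess overlap.
#'
#' @param layout a [genome_layout()].
#' @param n number of regions.
#' @param size region size in bp.
#' @param frac_in fraction of regions planted inside the target.
#' @param target `"centromere"` (the arms' centromere spans) or a track
#'   label.
#' @param seed integer seed.
#' @return tibble `chrom`, `start`, `end`.
#' @export
synthetic_dmr_regions <- function(layout, n = 200, size = 5000, frac_in = 0.3,
                                  target = "centromere", seed = 1) {
  set.seed(child_seed(seed, 7L))
  tgt <- if (identical(target, "centromere")) {
    tibble(chrom = layout$arms$chrom, start = layout$arms$cen_start,
           end = layout$arms$cen_end)
  } else {
    layout$tracks[[target]]
  }
  if (is.null(tgt) || nrow(tgt) == 0) stop("no target intervals for: ", target)
  n_in <- round(frac_in * n)
  pick <- sample(nrow(tgt), n_in, replace = TRUE,
                 prob = tgt$end - tgt$start)
  start_in <- floor(stats::runif(n_in, tgt$start[pick],
                                 pmax(tgt$start[pick] + 1, tgt$end[pick] - size)))
  chrom_len <- stats::setNames(layout$chromosomes$length,
                               layout$chromosomes$chrom)
  ch_out <- sample(names(chrom_len), n - n_in, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
  start_out <- floor(stats::runif(n - n_in, 0, chrom_len[ch_out] - size))
  tibble(
    chrom = c(tgt$chrom[pick], ch_out),
    start = c(start_in, start_out),
    end = c(start_in, start_out) + size
  )
}

#' Simulate a multi-sample structural-variant call set
#'
#' Plants shared variants (present across groups) and group-unique variants
#' (present only in samples of one group, genotyped everywhere); a
#' `missing_gt_rate` fraction of variants get one `./.` genotype, which
#' disqualifies them from the group-uniqueness analysis.
#'
#' @param layout a [genome_layout()].
#' @param samples sample-metadata tibble with `group`.
#' @param shared_rate expected shared variants (total).
#' @param group_unique_rate expected group-unique variants per group.
#' @param missing_gt_rate probability a variant carries a missing genotype.
#' @param short_rate expected sub-50-bp variants planted to exercise the
#'   length filter.
#' @param seed integer seed.
#' @return list with `variants` (tibble in [parse_sv_vcf()] layout) and
#'   `truth` (id, class in shared/group_unique/short, group, has_missing).
#' @export
simulate_sv_calls <- function(layout, samples, shared_rate = 10,
                              group_unique_rate = 5, missing_gt_rate = 0.1,
                              short_rate = 2, seed = 1) {
  if (shared_rate < 0 || group_unique_rate < 0 || short_rate < 0 ||
      missing_gt_rate < 0 || missing_gt_rate > 1) {
    stop("rates must be non-negative (missing_gt_rate in [0,1])")
  }
  set.seed(child_seed(seed, 5L))
  groups <- unique(samples$group)
  n_shared <- stats::rpois(1, shared_rate)
  n_gu <- stats::rpois(length(groups), group_unique_rate)
  n_short <- stats::rpois(1, short_rate)
  total <- n_shared + sum(n_gu) + n_short
  if (total == 0) {
    empty <- tibble(id = character(0), chrom = character(0), start = numeric(0),
                    end = numeric(0), svtype = character(0), length = numeric(0))
    for (s in samples$sample_id) empty[[paste0("status_", s)]] <- character(0)
    return(list(variants = empty,
                truth = tibble(id = character(0), class = character(0),
                               group = character(0), has_missing = logical(0))))
  }
  loci <- sample_positions(layout, total)
  svtypes <- sample(c("INS", "DEL", "DUP", "INV"), total, replace = TRUE)
  lens <- round(stats::rlnorm(total, log(500), 1)) + 50
  lens[seq_len(n_short) + n_shared + sum(n_gu)] <-
    sample(10:49, n_short, replace = TRUE)

  status <- matrix("absent", nrow = total, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  cls <- character(total)
  grp <- rep(NA_character_, total)
  idx <- 0L
  for (k in seq_len(n_shared)) {
    idx <- idx + 1L
    carriers <- sample(samples$sample_id, max(2L, stats::rbinom(1, nrow(samples), 0.4)))
    # ensure carriers span at least two groups
    if (length(unique(samples$group[samples$sample_id %in% carriers])) < 2) {
      extra <- samples$sample_id[!samples$group %in%
                                   samples$group[samples$sample_id %in% carriers]][1]
      carriers <- c(carriers, extra)
    }
    status[idx, carriers] <- "present"
    cls[idx] <- "shared"
  }
  for (g in seq_along(groups)) {
    members <- samples$sample_id[samples$group == groups[g]]
    for (k in seq_len(n_gu[g])) {
      idx <- idx + 1L
      carriers <- sample(members, sample(seq_along(members), 1))
      status[idx, carriers] <- "present"
      cls[idx] <- "group_unique"
      grp[idx] <- groups[g]
    }
  }
  for (k in seq_len(n_short)) {
    idx <- idx + 1L
    status[idx, sample(samples$sample_id, 2)] <- "present"
    cls[idx] <- "short"
  }

  has_missing <- stats::runif(total) < missing_gt_rate
  for (i in which(has_missing)) {
    status[i, sample(ncol(status), 1)] <- "missing"
  }

  variants <- tibble(
    id = sprintf("sv%04d", seq_len(total)),
    chrom = loci$chrom,
    start = round(loci$pos),
    end = round(loci$pos) + ifelse(svtypes == "INS", 1, lens),
    svtype = svtypes,
    length = lens
  )
  for (s in samples$sample_id) variants[[paste0("status_", s)]] <- status[, s]
  list(
    variants = variants,
    truth = tibble(id = variants$id, class = cls, group = grp,
                   has_missing = has_missing)
  )
}
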
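# Singleton / L1-endonuclease insertion filter chain. Tiers are nested:
# l1en_singleton => singleton => unique_nonreference => high_confidence;
# every classification carries the full list of failed criteria.

TIERS <- c("rejected", "high_confidence", "unique_nonreference",
           "singleton", "l1en_singleton")

tier_factor <- function(x) factor(x, levels = TIERS, ordered = TRUE)

#' Test a junction sequence for the L1 endonuclease motif
#'
#' The junction sequence is the +/- flank around the cleavage point (the
#' boundary between the two halves of the string). The motif (canonical
#' 5'-TTAAAA) or its reverse complement must occur with at most
#' `max_mismatch` mismatches, with the matched window touching the region
#' within `anchor_bp` of the cleavage point.
#'
#' @param junction_seq character scalar (even length; cleavage at the
#'   midpoint).
#' @param motif consensus 6-mer.
#' @param max_mismatch mismatch budget.
#' @param anchor_bp anchoring distance in bp.
#' @return TRUE/FALSE, or NA when the sequence is shorter than the motif.
#' @export
has_l1en_motif <- function(junction_seq, motif = "TTAAAA",
                           max_mismatch = 1L, anchor_bp = 3L) {
  n <- nchar(junction_seq)
  m <- nchar(motif)
  if (n < m) return(NA)
  cp <- floor(n / 2) # 0-based cleavage boundary
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]), collapse = ""))
  seq_chars <- strsplit(toupper(junction_seq), "")[[1]]
  pat_list <- list(strsplit(motif, "")[[1]], strsplit(rc, "")[[1]])
  for (o in 0:(n - m)) { # 0-based window start
    # window [o, o+m) must intersect [cp - anchor_bp, cp + anchor_bp)
    if (o >= cp + anchor_bp || (o + m) <= cp - anchor_bp) next
    win <- seq_chars[(o + 1):(o + m)]
    for (pat in pat_list) {
      if (sum(win != pat) <= max_mismatch) return(TRUE)
    }
  }
  FALSE
}

#' High-confidence insertion filter
#'
#' First stage of the filter chain: an insertion call is retained as
#' high-confidence iff it has a target-site duplication (non-empty
#' `tsd_seq`), UnmapCover at or above the configured 0.8, an intact 3' end
#' and a PASS caller filter. Failed criteria are listed per call; nothing
#' is dropped.
#'
#' @param calls insertion-call tibble (the `insertion` dialect).
#' @param cfg a [dg_config()].
#' @return `calls` with `tsd_len`, `tier` (ordered factor) and
#'   `failure_reasons` (list-column of criterion names) added.
#' @export
filter_high_confidence <- function(calls, cfg = dg_config()) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$tsd_len <- integer(0)
    calls$tier <- tier_factor(character(0))
    calls$failure_reasons <- list()
    return(calls)
  }
  calls$tsd_seq[is.na(calls$tsd_seq)] <- ""
  calls$tsd_len <- nchar(calls$tsd_seq)
  fails <- list(
    tsd_missing = calls$tsd_len == 0,
    unmap_cover = calls$unmap_cover < cfg$unmap_cover_min,
    three_prime_intact = calls$three_prime_intact != 1,
    filter = calls$filter != "PASS"
  )
  calls$failure_reasons <- purrr::map(seq_len(nrow(calls)), function(i) {
    names(fails)[vapply(fails, `[`, logical(1), i)]
  })
  calls$tier <- tier_factor(
    ifelse(lengths(calls$failure_reasons) == 0, "high_confidence", "rejected")
  )
  calls
}

#' Promote high-confidence calls to unique non-reference and singleton tiers
#'
#' Calls are merged into loci across samples (same chromosome, positions
#' within the configured 50-bp jitter window, transitively chained). A
#' high-confidence call becomes `unique_nonreference` when its locus is
#' seen in exactly one sample, and `singleton` when additionally it is
#' supported by exactly one read with at least the configured 10 spanning
#' insertion-free reads.
#'
#' @param calls output of [filter_high_confidence()] (all calls, so that
#'   rejected calls still witness locus sharing).
#' @param cfg a [dg_config()].
#' @return `calls` with `locus_id` added and `tier`/`failure_reasons`
#'   updated.
#' @export
classify_singletons <- function(calls, cfg = dg_config()) {
  if (nrow(calls) == 0) {
    calls$locus_id <- integer(0)
    return(calls)
  }
  ord <- order(calls$chrom, calls$pos)
  locus <- integer(nrow(calls))
  cur <- 0L
  prev_chrom <- ""
  prev_pos <- -Inf
  for (i in ord) {
    if (calls$chrom[i] != prev_chrom || calls$pos[i] - prev_pos > cfg$locus_merge_bp) {
      cur <- cur + 1L
    }
    locus[i] <- cur
    prev_chrom <- calls$chrom[i]
    prev_pos <- calls$pos[i]
  }
  calls$locus_id <- locus
  n_samples_at <- tapply(calls$sample_id, locus, function(s) length(unique(s)))
  shared <- as.integer(names(n_samples_at))[n_samples_at > 1]

  for (i in seq_len(nrow(calls))) {
    if (calls$tier[i] < "high_confidence") next
    reasons <- character(0)
    if (calls$locus_id[i] %in% shared) reasons <- c(reasons, "multi_sample_locus")
    if (length(reasons) == 0) {
      calls$tier[i] <- "unique_nonreference"
      if (calls$n_support_reads[i] != 1) reasons <- c(reasons, "support_reads")
      if (calls$n_spanning_nonsupport_reads[i] < cfg$min_spanning_reads) {
        reasons <- c(reasons, "spanning_reads")
      }
      if (length(reasons) == 0) calls$tier[i] <- "singleton"
    }
    calls$failure_reasons[[i]] <- c(calls$failure_reasons[[i]], reasons)
  }
  calls
}

#' Promote singletons to the L1-endonuclease tier
#'
#' A singleton becomes an `l1en_singleton` iff its TSD length is within
#' the inclusive 5-31 bp bounds, the single supporting read is at least
#' 10 kbp, a polyA tail is present, and the junction carries the L1
#' endonuclease motif (see [has_l1en_motif()]).
#'
#' @param calls output of [classify_singletons()].
#' @param cfg a [dg_config()].
#' @return `calls` with `tier`/`failure_reasons` updated.
#' @export
classify_l1en <- function(calls, cfg = dg_config()) {
  for (i in seq_len(nrow(calls))) {
    if (calls$tier[i] < "singleton") next
    reasons <- character(0)
    if (calls$tsd_len[i] < cfg$tsd_min || calls$tsd_len[i] > cfg$tsd_max) {
      reasons <- c(reasons, "tsd_len")
    }
    if (calls$support_read_len_bp[i] < cfg$singleton_read_len_min) {
      reasons <- c(reasons, "read_len")
    }
    if (calls$polyA[i] != 1) reasons <- c(reasons, "polyA")
    motif_ok <- has_l1en_motif(calls$junction_seq[i], cfg$l1en_motif,
                               cfg$l1en_max_mismatch, cfg$l1en_anchor_bp)
    if (is.na(motif_ok)) {
      reasons <- c(reasons, "junction_too_short")
    } else if (!motif_ok) {
      reasons <- c(reasons, "motif")
    }
    if (length(reasons) == 0) calls$tier[i] <- "l1en_singleton"
    calls$failure_reasons[[i]] <- c(calls$failure_reasons[[i]], reasons)
  }
  calls
}

#' Run the full insertion classification chain
#'
#' Convenience wrapper: [filter_high_confidence()], then
#' [classify_singletons()], then [classify_l1en()].
#' @inheritParams filter_high_confidence
#' @return classified calls tibble.
#' @export
classify_insertions <- function(calls, cfg = dg_config()) {
  calls %>%
    filter_high_confidence(cfg) %>%
    classify_singletons(cfg) %>%
    classify_l1en(cfg)
}

#' Annotate insertions by centromere region class and L1-Ta diagnostics
#'
#' Labels each call with the centromere-repeat class it falls in (NA on
#' chromosome arms) and a `centromeric` flag. When a 3'-UTR sequence column
#' `utr3_seq` is present, L1Hs calls are flagged `l1ta` if the configured
#' diagnostic offsets carry the ACA trinucleotide and G nucleotide.
#'
#' @param calls classified calls tibble.
#' @param layout a [genome_layout()] with centromere repeat tracks.
#' @param aca_offset,g_offset 1-based offsets of the diagnostic ACA and G
#'   within `utr3_seq`.
#' @return list with `calls` (annotated) and `class_counts` (per
#'   region-class, per-tier tally).
#' @export
characterize_insertions <- function(calls, layout, aca_offset = 1L, g_offset = 6L) {
  q <- tibble(chrom = calls$chrom, start = calls$pos, end = calls$pos + 1)
  calls$region_class <- centromere_class(q, layout)
  calls$centromeric <- !is.na(calls$region_class)
  if (!is.null(calls$utr3_seq)) {
    calls$l1ta <- startsWith(calls$subfamily, "L1") &
      substr(calls$utr3_seq, aca_offset, aca_offset + 2) == "ACA" &
      substr(calls$utr3_seq, g_offset, g_offset) == "G"
  }
  class_counts <- calls %>%
    mutate(region_class = ifelse(is.na(.data$region_class), "arm", .data$region_class)) %>%
    count(.data$region_class, .data$tier, name = "n")
  list(calls = calls, class_counts = class_counts)
}

#' Normalise a count by diploid genomes sequenced
#'
#' Divides a raw count by the number of diploid human genomes sequenced,
#' i.e. Gbp sequenced / 6.4 Gbp.
#'
#' @param count raw count (vectorised).
#' @param gbp_sequenced gigabases sequenced for the sample (vectorised).
#' @param cfg a [dg_config()] (supplies `diploid_gbp`).
#' @return normalised count per diploid genome.
#' @examples
#' normalize_count(4, 6.4) # 4
#' normalize_count(4, 12.8) # 2
#' @export
normalize_count <- function(count, gbp_sequenced, cfg = dg_config()) {
  if (any(gbp_sequenced <= 0)) stop("gbp_sequenced must be positive")
  count / (gbp_sequenced / cfg$diploid_gbp)
}

#' Compare per-sample values across groups
#'
#' One-way fixed-effects ANOVA across k groups, or a two-sided
#' pooled-variance Student's t-test when exactly two groups are supplied
#' and `mode = "t"`.
#'
#' @param data tibble with a value column and a group column.
#' @param value,group column names (strings).
#' @param mode `"anova"` or `"t"`.
#' @return object of class `dg_group_test`: list with `statistic`, `df`,
#'   `p`, `group_means`, `mode`. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @export
compare_groups <- function(data, value = "value", group = "group",
                           mode = c("anova", "t")) {
  mode <- match.arg(mode)
  v <- data[[value]]
  g <- factor(data[[group]])
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values (",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  }
  means <- c(tapply(v, g, mean))
  if (mode == "t") {
    if (length(sizes) != 2) stop("t mode requires exactly 2 groups")
    if (stats::var(v) == 0) {
      out <- list(statistic = 0, df = length(v) - 2, p = 1)
    } else {
      tt <- stats::t.test(v ~ g, var.equal = TRUE)
      out <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
    }
  } else {
    k <- length(sizes)
    n <- length(v)
    ssb <- sum(sizes * (means - mean(v))^2)
    ssw <- sum((v - means[g])^2)
    df1 <- k - 1
    df2 <- n - k
    if (ssw == 0 && ssb == 0) {
      f <- 0
      p <- 1
    } else {
      f <- (ssb / df1) / (ssw / df2)
      p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    }
    out <- list(statistic = f, df = c(df1, df2), p = p)
  }
  out$group_means <- means
  out$mode <- mode
  class(out) <- "dg_group_test"
  out
}

#' @export
print.dg_group_test <- function(x, ...) {
  cat(sprintf(
    "<dg_group_test> %s: statistic = %.4g, df = %s, p = %.4g\n",
    if (x$mode == "anova") "one-way ANOVA" else "Student's t",
    x$statistic, paste(x$df, collapse = ","), x$p
  ))
  cat("group means:", paste(names(x$group_means),
    round(x$group_means, 4),
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}

#' @export
tidy.dg_group_test <- function(x, ...) {
  tibble(
    group = names(x$group_means),
    mean = as.numeric(x$group_means)
  )
}

#' @export
glance.dg_group_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, p.value = x$p,
    df = x$df[1], df.residual = x$df[length(x$df)], method = x$mode
  )
}

#' Fisher's exact test for region enrichment of one call set over another
#'
#' Builds the 2x2 table {in-region, out-of-region} x {foreground,
#' background} by half-open overlap of call points with a layout track and
#' tests it two-sided (hypergeometric tail summation over tables with
#' probability at most the observed one).
#'
#' @param calls_a,calls_b foreground and background call tibbles with
#'   `chrom`, `pos`.
#' @param layout a [genome_layout()].
#' @param region_track track label, or a character vector of labels whose
#'   union defines the region (e.g. the centromere classes).
#' @return object of class `dg_fisher`: list with `table`, `odds_ratio`,
#'   `p`.
#' @export
fisher_region_enrichment <- function(calls_a, calls_b, layout, region_track) {
  if (nrow(calls_a) == 0 || nrow(calls_b) == 0) {
    stop("foreground and background call sets must be non-empty")
  }
  in_region <- function(calls) {
    q <- tibble(chrom = calls$chrom, start = calls$pos, end = calls$pos + 1)
    hit <- rep(FALSE, nrow(q))
    for (tr in region_track) {
      hit[unique(interval_overlap(q, layout, tr)$query_id)] <- TRUE
    }
    hit
  }
  a_in <- sum(in_region(calls_a))
  b_in <- sum(in_region(calls_b))
  tab <- matrix(
    c(a_in, nrow(calls_a) - a_in, b_in, nrow(calls_b) - b_in),
    nrow = 2,
    dimnames = list(c("in_region", "out_of_region"), c("foreground", "background"))
  )
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  structure(
    list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value),
    class = "dg_fisher"
  )
}

#' @export
print.dg_fisher <- function(x, ...) {
  cat("<dg_fisher> two-sided Fisher's exact test\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, p = %.4g\n", x$odds_ratio, x$p))
  invisible(x)
}

#' Per-sample normalised tier counts
#'
#' Counts calls at or above a tier per sample and normalises by diploid
#' genomes sequenced ([normalize_count()]).
#'
#' @param calls classified calls.
#' @param samples sample-metadata tibble (`sample_id`, `group`,
#'   `gbp_sequenced`).
#' @param tier minimum tier to count.
#' @param cfg a [dg_config()].
#' @return tibble `sample_id`, `group`, `n`, `normalized`.
#' @export
normalized_tier_counts <- function(calls, samples, tier = "l1en_singleton",
                                   cfg = dg_config()) {
  tier <- tier_factor(tier)
  counts <- calls %>%
    filter(.data$tier >= !!tier) %>%
    count(.data$sample_id, name = "n")
  samples %>%
    select("sample_id", "group", "gbp_sequenced") %>%
    left_join(counts, by = "sample_id") %>%
    mutate(
      n = tidyr::replace_na(.data$n, 0L),
      normalized = normalize_count(.data$n, .data$gbp_sequenced, cfg)
    )
}
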
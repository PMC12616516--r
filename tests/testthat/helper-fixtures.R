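# Shared fixtures, all built in code.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# 2 x 10 Mb layout, centromere 4.5-5.5 Mb, rDNA on chr2
toy_layout <- function(seed = 7, ...) {
  make_toy_genome(
    n_chrom = 2, chrom_len = 1e7, centromere_frac = 0.1,
    rdna_chroms = "chr2", dark_frac = 0.05, repeat_density = 1.0,
    seed = seed, ...
  )
}

toy_meta <- function(n_per_group = 3, groups = c("Braak0", "BraakIII", "BraakV_VI"),
                     seed = 1) {
  make_sample_meta(n_per_group, groups, seed = seed)
}

# a fully valid insertion call; override fields to break one criterion
valid_call <- function(...) {
  base <- tibble(
    uuid = "u1", sample_id = "S01", chrom = "chr1", pos = 1000L,
    subfamily = "AluYa5", filter = "PASS", unmap_cover = 0.9,
    three_prime_intact = 1L, tsd_seq = "AAGTTTAAGC",
    n_support_reads = 1L, support_read_len_bp = 12000L,
    n_spanning_nonsupport_reads = 11L, polyA = 1L,
    junction_seq = "ACGTACGTTAAAACGTACGT", mapq = 60L
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# independent per-criterion re-evaluation of the whole tier chain,
# deliberately naive: no shared code with the pipeline
naive_tiers <- function(calls, cfg = dg_config()) {
  hc <- nchar(ifelse(is.na(calls$tsd_seq), "", calls$tsd_seq)) > 0 &
    calls$unmap_cover >= cfg$unmap_cover_min &
    calls$three_prime_intact == 1 & calls$filter == "PASS"
  # locus sharing: brute-force single-linkage per chromosome
  uniq <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    same <- which(calls$chrom == calls$chrom[i])
    cluster <- i
    repeat {
      grow <- same[vapply(same, function(j) {
        any(abs(calls$pos[j] - calls$pos[cluster]) <= cfg$locus_merge_bp)
      }, logical(1))]
      if (length(grow) == length(cluster)) break
      cluster <- grow
    }
    uniq[i] <- length(unique(calls$sample_id[cluster])) == 1
  }
  sing <- hc & uniq & calls$n_support_reads == 1 &
    calls$n_spanning_nonsupport_reads >= cfg$min_spanning_reads
  tsd_len <- nchar(ifelse(is.na(calls$tsd_seq), "", calls$tsd_seq))
  naive_motif <- function(s, motif = cfg$l1en_motif,
                          mm = cfg$l1en_max_mismatch,
                          anchor = cfg$l1en_anchor_bp) {
    n <- nchar(s); m <- nchar(motif)
    if (n < m) return(FALSE)
    cp <- floor(n / 2)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", motif), "")[[1]]),
                collapse = "")
    for (o in 0:(n - m)) {
      if (o >= cp + anchor || (o + m) <= cp - anchor) next
      w <- substr(s, o + 1, o + m)
      for (p in c(motif, rc)) {
        d <- sum(strsplit(w, "")[[1]] != strsplit(p, "")[[1]])
        if (d <= mm) return(TRUE)
      }
    }
    FALSE
  }
  motif <- vapply(calls$junction_seq, naive_motif, logical(1))
  l1en <- sing & tsd_len >= cfg$tsd_min & tsd_len <= cfg$tsd_max &
    calls$support_read_len_bp >= cfg$singleton_read_len_min &
    calls$polyA == 1 & motif
  ifelse(l1en, "l1en_singleton",
         ifelse(sing, "singleton",
                ifelse(hc & uniq, "unique_nonreference",
                       ifelse(hc, "high_confidence", "rejected"))))
}

binom_ci <- function(x, n) as.numeric(stats::binom.test(x, n)$conf.int)

# exhaustive two-sided Fisher p over all 2x2 tables with fixed margins
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
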
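#' Analysis configuration with every pipeline threshold
#'
#' Central container for the numeric thresholds used across the insertion
#' filter chain, NAHR filtering and windowing, structural-variant logic,
#' differential methylation, metachromosome profiling and the permutation
#' test. Defaults are the values used throughout the analysis; any can be
#' overridden by name.
#'
#' @param ... named overrides for any default listed below.
#'
#' @details Defaults:
#' \describe{
#'   \item{unmap_cover_min}{0.8 — minimum fraction of the inserted sequence
#'     covered by retrotransposon sequence (UnmapCover).}
#'   \item{tsd_min, tsd_max}{5, 31 bp — inclusive target-site-duplication
#'     length bounds for an L1-endonuclease-mediated singleton.}
#'   \item{singleton_read_len_min}{10000 bp — minimum length of the single
#'     insertion-supporting read.}
#'   \item{min_spanning_reads}{10 — minimum insertion-free reads spanning the
#'     locus in the same individual.}
#'   \item{sv_min_len}{50 bp — structural-variant length filter.}
#'   \item{nahr_score_max}{1e-4 — maximum caller score for a retained NAHR
#'     event.}
#'   \item{window_size}{1e5 bp — genomic window width for NAHR enrichment and
#'     metachromosome ranking.}
#'   \item{diploid_gbp}{6.4 — gigabases per diploid human genome, the
#'     denominator of depth normalisation.}
#'   \item{mapq_min}{20 — recorded alignment-quality floor (methylation
#'     calling context; not an insertion filter).}
#'   \item{site_min_samples}{3 — minimum samples with a retained call at a
#'     CpG site.}
#'   \item{site_min_called}{3 — minimum read support (called_sites) for a
#'     per-sample CpG entry.}
#'   \item{dmr_site_p}{0.05 — uncorrected per-site p threshold for DMR
#'     aggregation.}
#'   \item{dmr_fdr}{0.05 — BH FDR threshold for site-level significance.}
#'   \item{dmr_min_cpg}{3 — minimum CpG sites per DMR.}
#'   \item{dmr_merge_gap}{100 bp — maximum gap between chained DMR sites.}
#'   \item{dispersion_shrink}{0.5 — weight pulling per-site dispersion toward
#'     the genome-wide median.}
#'   \item{roll_span}{11 windows — rolling-average span (about 1 Mb).}
#'   \item{n_metabins}{500 — metachromosome bins (0 = q telomere, 500 = p
#'     telomere).}
#'   \item{n_perm}{10000 — permutation count for the region-overlap test.}
#'   \item{locus_min_cpg}{10 — minimum called CpG sites for a retroelement
#'     locus.}
#'   \item{family_len_min}{named vector of strict length thresholds excluding
#'     fragmented retroelement loci: HERV-K 6000, LTR5_Hs/A/B 900, LINE1-Hs
#'     5900, AluYa5/Yb8 280, SVA-E/F 1000 bp.}
#'   \item{l1en_motif}{"TTAAAA" — L1 endonuclease cleavage consensus.}
#'   \item{l1en_max_mismatch}{1 — mismatch budget for the motif match.}
#'   \item{l1en_anchor_bp}{3 — the motif must sit within this many bp of the
#'     cleavage point.}
#'   \item{locus_merge_bp}{50 bp — junction jitter window merging calls into
#'     one locus across samples.}
#'   \item{snp_proximity_bp}{10000 bp — "near a SNP" window for variant
#'     annotation.}
#'   \item{mds_k}{3 — MAD multiplier of the MDS outlier screen.}
#'   \item{cpg_cluster_bp}{10 bp — CpG grouping distance; only the most 5'
#'     CpG of a cluster keeps its methylation value.}
#' }
#'
#' @return a list of class `dg_config`.
#' @examples
#' cfg <- dg_config(n_perm = 1000)
#' cfg$tsd_min
#' @export
dg_config <- function(...) {
  cfg <- list(
    unmap_cover_min = 0.8,
    tsd_min = 5L,
    tsd_max = 31L,
    singleton_read_len_min = 10000L,
    min_spanning_reads = 10L,
    sv_min_len = 50L,
    nahr_score_max = 1e-4,
    window_size = 100000L,
    diploid_gbp = 6.4,
    mapq_min = 20L,
    site_min_samples = 3L,
    site_min_called = 3L,
    dmr_site_p = 0.05,
    dmr_fdr = 0.05,
    dmr_min_cpg = 3L,
    dmr_merge_gap = 100L,
    dispersion_shrink = 0.5,
    roll_span = 11L,
    n_metabins = 500L,
    n_perm = 10000L,
    locus_min_cpg = 10L,
    family_len_min = c(
      `HERV-K` = 6000, `LTR5_Hs/A/B` = 900, `LINE1-Hs` = 5900,
      `AluYa5/Yb8` = 280, `SVA-E/F` = 1000
    ),
    l1en_motif = "TTAAAA",
    l1en_max_mismatch = 1L,
    l1en_anchor_bp = 3L,
    locus_merge_bp = 50L,
    snp_proximity_bp = 10000L,
    mds_k = 3,
    cpg_cluster_bp = 10L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == "")) {
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(over)] <- over
  }
  scalars <- c(
    "unmap_cover_min", "tsd_min", "tsd_max", "singleton_read_len_min",
    "min_spanning_reads", "sv_min_len", "nahr_score_max", "window_size",
    "diploid_gbp", "site_min_samples", "site_min_called", "dmr_site_p",
    "dmr_fdr", "dmr_min_cpg", "dmr_merge_gap", "roll_span", "n_metabins",
    "n_perm", "locus_min_cpg", "locus_merge_bp", "snp_proximity_bp",
    "cpg_cluster_bp"
  )
  for (s in scalars) {
    if (!is.numeric(cfg[[s]]) || length(cfg[[s]]) != 1L || cfg[[s]] <= 0) {
      stop("config field '", s, "' must be a positive scalar")
    }
  }
  if (cfg$tsd_min > cfg$tsd_max) stop("tsd_min must not exceed tsd_max")
  structure(cfg, class = "dg_config")
}

#' @export
print.dg_config <- function(x, ...) {
  cat("<dg_config> analysis thresholds\n")
  flat <- x[!vapply(x, function(v) length(v) > 1L, logical(1))]
  for (nm in names(flat)) cat(sprintf("  %-24s %s\n", nm, format(flat[[nm]])))
  cat("  family_len_min:", paste(names(x$family_len_min),
    x$family_len_min,
    sep = "=", collapse = ", "
  ), "\n")
  invisible(x)
}
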
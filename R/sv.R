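# Structural-variant length filtering, group-unique detection and
# dark-region / SNP-proximity annotation.

sv_status_matrix <- function(variants, samples) {
  cols <- paste0("status_", samples$sample_id)
  missing <- setdiff(cols, names(variants))
  if (length(missing)) stop("missing status column(s): ",
                            paste(missing, collapse = ", "))
  m <- as.matrix(variants[, cols])
  colnames(m) <- samples$sample_id
  m
}

#' Length-filter structural variants and find group-unique ones
#'
#' Retains variants 50 bp or larger (breakend records without a usable
#' length are retained but flagged out of length-based analyses). A
#' variant is eligible for the group comparison only when genotyped in
#' every sample (no missing status); it is unique to group g when all
#' samples carrying it belong to g. "Carrying" means a genotype with at
#' least one alternate allele; homozygous reference counts as absent.
#'
#' @param variants tibble from [parse_sv_vcf()] or the simulator.
#' @param samples sample-metadata tibble with `sample_id`, `group`.
#' @param cfg a [dg_config()].
#' @return list with `retained` (length-filtered variants, plus
#'   `n_present`, `fully_genotyped`, `unique_group` columns),
#'   `group_unique` (the unique subset) and `per_sample_counts`
#'   (`sample_id`, `group`, `n_group_unique`), ready for
#'   [compare_groups()].
#' @export
filter_and_group_unique <- function(variants, samples, cfg = dg_config()) {
  if (any(is.na(samples$group)) || any(samples$group == "")) {
    stop("every sample needs a group label")
  }
  keep <- is.na(variants$length) & variants$svtype == "BND" |
    (!is.na(variants$length) & variants$length >= cfg$sv_min_len)
  retained <- variants[keep, ]
  st <- sv_status_matrix(retained, samples)
  present <- st == "present"
  retained$n_present <- rowSums(present)
  retained$fully_genotyped <- rowSums(st == "missing") == 0
  grp <- samples$group
  retained$unique_group <- vapply(seq_len(nrow(retained)), function(i) {
    if (!retained$fully_genotyped[i] || retained$n_present[i] == 0) {
      return(NA_character_)
    }
    gs <- unique(grp[present[i, ]])
    if (length(gs) == 1) gs else NA_character_
  }, character(1))
  group_unique <- filter(retained, !is.na(.data$unique_group))
  per_sample <- purrr::map_dfr(seq_len(nrow(samples)), function(j) {
    tibble(
      sample_id = samples$sample_id[j],
      group = samples$group[j],
      n_group_unique = sum(!is.na(retained$unique_group) & present[, j])
    )
  })
  list(retained = retained, group_unique = group_unique,
       per_sample_counts = per_sample)
}

#' Annotate variants with dark-region overlap and nearest risk SNP
#'
#' Flags variants whose interval overlaps the dark-region track
#' (half-open), and annotates the nearest SNP within the configured
#' proximity window (signed distance = variant start - SNP position;
#' positive when the variant lies downstream of the SNP).
#'
#' @param variants tibble with `chrom`, `start`, `end`, `svtype`.
#' @param layout a [genome_layout()] with a `dark_region` track.
#' @param snps optional tibble `chrom`, `pos`, `id` (or a BED path).
#' @param cfg a [dg_config()] (supplies `snp_proximity_bp`).
#' @return `variants` with `overlaps_dark`, `nearest_snp`, `snp_distance`
#'   added, plus attribute `dark_counts` (dark-overlapping counts by
#'   svtype).
#' @export
annotate_dark_and_snp <- function(variants, layout, snps = NULL,
                                  cfg = dg_config()) {
  if (!"dark_region" %in% names(layout$tracks)) {
    stop("layout has no dark_region track")
  }
  ov <- interval_overlap(variants[, c("chrom", "start", "end")],
                         layout, "dark_region")
  variants$overlaps_dark <- seq_len(nrow(variants)) %in% ov$query_id
  variants$nearest_snp <- NA_character_
  variants$snp_distance <- NA_real_
  if (!is.null(snps)) {
    if (is.character(snps)) {
      b <- read_bed(snps)
      snps <- tibble(chrom = b$chrom, pos = b$start,
                     id = if (!is.null(b$name)) b$name else
                       paste0("snp", seq_len(nrow(b))))
    }
    if (nrow(snps)) {
      for (i in seq_len(nrow(variants))) {
        cand <- snps[snps$chrom == variants$chrom[i], ]
        if (!nrow(cand)) next
        d <- variants$start[i] - cand$pos
        j <- which.min(abs(d))
        if (abs(d[j]) <= cfg$snp_proximity_bp) {
          variants$nearest_snp[i] <- cand$id[j]
          variants$snp_distance[i] <- d[j]
        }
      }
    }
  }
  dark_counts <- variants %>%
    filter(.data$overlaps_dark) %>%
    count(.data$svtype, name = "n")
  attr(variants, "dark_counts") <- dark_counts
  variants
}
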
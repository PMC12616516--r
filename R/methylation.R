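# CpG dedup and support filtering, MDS outlier screen, beta-binomial
# differential methylation with DMR aggregation and areaStat, retroelement
# locus summaries and promoter counting.

#' Deduplicate clustered CpG records
#'
#' The upstream caller groups CpGs within 10 bp into one methylation call;
#' to avoid artificial inflation of depth only the most 5' CpG of any
#' maximal chain of records whose consecutive positions differ by at most
#' 10 bp keeps its value (chaining is transitive). Counts are not summed:
#' the grouped caller already aggregated them.
#'
#' @param records one sample's methylation-dialect tibble, sorted by
#'   position within chromosome.
#' @param cfg a [dg_config()] (supplies `cpg_cluster_bp`).
#' @return deduplicated records.
#' @export
dedup_cpg_clusters <- function(records, cfg = dg_config()) {
  n <- nrow(records)
  if (n == 0) return(records)
  same_chrom <- c(FALSE, records$chromosome[-1] == records$chromosome[-n])
  gap <- c(Inf, diff(records$start))
  if (any(same_chrom & gap < 0)) {
    stop("records must be sorted by position within chromosome")
  }
  records[!(same_chrom & gap <= cfg$cpg_cluster_bp), ]
}

#' Build the CpG site-by-sample count matrix
#'
#' Deduplicates each sample's records, masks per-sample entries supported
#' by fewer than 3 called sites, and retains a CpG site only when at least
#' 3 samples keep an entry there. Methylated counts are reconstructed as
#' `round(frequency x called_sites)` when not carried explicitly.
#'
#' @param tables named list of per-sample methylation-dialect tibbles.
#' @param samples sample-metadata tibble.
#' @param cfg a [dg_config()].
#' @return object of class `dg_site_matrix`: list with `sites` (tibble
#'   `chrom`, `pos`, `n_samples_called`), `meth` and `total` (site x
#'   sample integer matrices, NA = missing) and `samples`.
#' @export
build_site_matrix <- function(tables, samples, cfg = dg_config()) {
  stopifnot(all(samples$sample_id %in% names(tables)))
  long <- purrr::imap_dfr(tables[samples$sample_id], function(tab, sid) {
    if (anyDuplicated(paste(tab$chromosome, tab$start))) {
      stop("duplicate CpG position within sample ", sid)
    }
    tab <- dedup_cpg_clusters(tab, cfg)
    meth <- if ("called_sites_methylated" %in% names(tab)) {
      tab$called_sites_methylated
    } else {
      round(tab$methylated_frequency * tab$called_sites)
    }
    tibble(
      sample_id = sid, chrom = tab$chromosome, pos = tab$start,
      total = tab$called_sites, meth = meth
    )
  })
  long <- filter(long, .data$total >= cfg$site_min_called)
  if (nrow(long) == 0) stop("no entries survive the support filter")
  site_key <- long %>%
    count(.data$chrom, .data$pos, name = "n_samples_called") %>%
    filter(.data$n_samples_called >= cfg$site_min_samples) %>%
    arrange(.data$chrom, .data$pos)
  long <- dplyr::semi_join(long, site_key, by = c("chrom", "pos"))
  key <- paste(site_key$chrom, site_key$pos)
  ridx <- match(paste(long$chrom, long$pos), key)
  cidx <- match(long$sample_id, samples$sample_id)
  meth <- total <- matrix(NA_real_, nrow = nrow(site_key), ncol = nrow(samples),
                          dimnames = list(key, samples$sample_id))
  meth[cbind(ridx, cidx)] <- long$meth
  total[cbind(ridx, cidx)] <- long$total
  structure(
    list(sites = site_key, meth = meth, total = total, samples = samples),
    class = "dg_site_matrix"
  )
}

#' @export
print.dg_site_matrix <- function(x, ...) {
  cat(sprintf("<dg_site_matrix> %d CpG sites x %d samples (%.1f%% called)\n",
              nrow(x$sites), ncol(x$meth),
              100 * mean(!is.na(x$total))))
  invisible(x)
}

#' MDS outlier screen on per-sample methylation profiles
#'
#' Classical metric MDS (two dimensions) of Euclidean distances between
#' per-sample methylation-frequency vectors over sites called in every
#' sample. A sample is flagged as an outlier when its distance to the
#' embedding centroid exceeds median + k * MAD.
#'
#' @param matrix a `dg_site_matrix`.
#' @param cfg a [dg_config()] (supplies `mds_k`).
#' @return tibble `sample_id`, `dim1`, `dim2`, `centroid_dist`, `outlier`.
#' @export
mds_outlier_screen <- function(matrix, cfg = dg_config()) {
  if (ncol(matrix$meth) < 4) stop("MDS screen needs at least 4 samples")
  complete <- stats::complete.cases(matrix$total)
  if (!any(complete)) stop("no sites complete across samples")
  freq <- (matrix$meth / matrix$total)[complete, , drop = FALSE]
  d <- stats::dist(t(freq))
  # identical samples give zero eigenvalues; cmdscale warns and returns
  # fewer dimensions
  emb <- suppressWarnings(stats::cmdscale(d, k = 2))
  if (ncol(emb) < 2) { # degenerate configurations embed in < 2 dimensions
    emb <- cbind(emb, matrix(0, nrow = ncol(freq), ncol = 2 - ncol(emb)))
    rownames(emb) <- colnames(freq)
  }
  centroid <- colMeans(emb)
  cd <- sqrt(rowSums(sweep(emb, 2, centroid)^2))
  thr <- stats::median(cd) + cfg$mds_k * stats::mad(cd)
  tibble(
    sample_id = rownames(emb), dim1 = emb[, 1], dim2 = emb[, 2],
    centroid_dist = cd, outlier = cd > thr & thr > 0
  )
}

#' Beta-binomial differential methylation test
#'
#' Per retained CpG site, compares two groups with a Wald statistic under
#' a beta-binomial model. The group methylation estimate pools counts,
#' `p_g = sum(m) / sum(t)`; the per-site dispersion is a method-of-moments
#' estimate pooled across both groups' samples, floored at 0 and shrunk
#' halfway toward the genome-wide median dispersion; the variance of the
#' pooled estimate is `sum(t_i p (1-p) (1 + (t_i - 1) phi)) / (sum t_i)^2`.
#' Two-sided p from the normal reference; BH q across tested sites. Sites
#' with fewer than 2 called samples in either group are skipped.
#'
#' @param matrix a `dg_site_matrix`.
#' @param group1,group2 group labels to compare (difference is group1 -
#'   group2).
#' @param cfg a [dg_config()].
#' @return tibble `chrom`, `pos`, `p1`, `p2`, `diff`, `phi`, `stat`, `p`,
#'   `q`, `n1`, `n2`.
#' @export
betabinom_dm_test <- function(matrix, group1, group2, cfg = dg_config()) {
  g <- matrix$samples$group
  i1 <- which(g == group1)
  i2 <- which(g == group2)
  if (length(i1) == 0 || length(i2) == 0) stop("unknown group label")
  m1 <- matrix$meth[, i1, drop = FALSE]; t1 <- matrix$total[, i1, drop = FALSE]
  m2 <- matrix$meth[, i2, drop = FALSE]; t2 <- matrix$total[, i2, drop = FALSE]
  n1 <- rowSums(!is.na(t1)); n2 <- rowSums(!is.na(t2))
  T1 <- rowSums(t1, na.rm = TRUE); T2 <- rowSums(t2, na.rm = TRUE)
  testable <- n1 >= 2 & n2 >= 2 & T1 > 0 & T2 > 0
  M1 <- rowSums(m1, na.rm = TRUE); M2 <- rowSums(m2, na.rm = TRUE)
  p1 <- ifelse(T1 > 0, M1 / T1, NA); p2 <- ifelse(T2 > 0, M2 / T2, NA)

  # method-of-moments dispersion pooled over both groups. Because p is the
  # pooled estimate from the same samples, the residual m_i - t_i p has
  # shrunken variance c_i * Var(m_i) with c_i = 1 - 2 t_i / T + sum(t_j^2) / T^2
  # (the usual within-group degrees-of-freedom loss); solving the corrected
  # moment equation keeps phi unbiased at small n.
  mom_parts <- function(m, t, p) {
    tot <- rowSums(t, na.rm = TRUE)
    sq <- rowSums(t^2, na.rm = TRUE)
    ci <- 1 - 2 * t / tot + sq / tot^2
    e <- (m - t * p)^2
    v0 <- t * p * (1 - p)
    num <- rowSums(e - ci * v0, na.rm = TRUE)
    den <- rowSums(ci * t * (t - 1) * p * (1 - p), na.rm = TRUE)
    list(num = num, den = den)
  }
  a <- mom_parts(m1, t1, p1)
  b <- mom_parts(m2, t2, p2)
  den <- a$den + b$den
  phi_raw <- ifelse(den > 0, pmax(0, (a$num + b$num) / den), 0)
  phi_med <- stats::median(phi_raw[testable])
  w <- cfg$dispersion_shrink
  phi <- (1 - w) * phi_raw + w * phi_med

  # variance uses a half-count continuity estimate of p so that fully
  # methylated / unmethylated groups keep a positive variance (at 5/10 vs
  # 5/10 it is exactly 0.5 and the statistic stays 0)
  vg <- function(t, M, T, phi) {
    pt <- (M + 0.5) / (T + 1)
    rowSums(t * pt * (1 - pt) * (1 + (t - 1) * phi), na.rm = TRUE) / T^2
  }
  v <- vg(t1, M1, T1, phi) + vg(t2, M2, T2, phi)
  stat <- ifelse(v > 0, (p1 - p2) / sqrt(v), 0)
  p <- ifelse(v > 0, 2 * stats::pnorm(-abs(stat)), 1)

  out <- tibble(
    chrom = matrix$sites$chrom, pos = matrix$sites$pos,
    p1 = unname(p1), p2 = unname(p2), diff = unname(p1 - p2),
    phi = unname(phi), stat = unname(stat), p = unname(p),
    n1 = unname(n1), n2 = unname(n2)
  )[testable, ]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Aggregate significant neighbouring CpG sites into DMRs
#'
#' Greedily chains consecutive tested sites with uncorrected p below 0.05
#' and a common difference sign, allowing gaps of at most 100 bp between
#' chained sites; chains with at least 3 CpGs are emitted as DMRs.
#' areaStat is the sum of the member Wald statistics; mean_diff the mean
#' member difference; direction hyper/hypo from the shared sign.
#'
#' @param site_results output of [betabinom_dm_test()], sorted by
#'   position.
#' @param cfg a [dg_config()].
#' @return tibble `chrom`, `start`, `end`, `n_cpg`, `mean_diff`,
#'   `areaStat`, `direction`, plus a `sites` list-column of member
#'   positions.
#' @export
call_dmrs <- function(site_results, cfg = dg_config()) {
  empty <- tibble(
    chrom = character(0), start = numeric(0), end = numeric(0),
    n_cpg = integer(0), mean_diff = numeric(0), areaStat = numeric(0),
    direction = character(0), sites = list()
  )
  sig <- site_results %>%
    filter(.data$p < cfg$dmr_site_p, .data$diff != 0) %>%
    arrange(.data$chrom, .data$pos)
  if (nrow(sig) == 0) return(empty)
  sgn <- sign(sig$diff)
  new_chain <- c(TRUE, sig$chrom[-1] != sig$chrom[-nrow(sig)] |
                   diff(sig$pos) > cfg$dmr_merge_gap |
                   sgn[-1] != sgn[-nrow(sig)])
  chain <- cumsum(new_chain)
  sig$chain <- chain
  sig %>%
    group_by(.data$chain) %>%
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$pos),
      end = max(.data$pos) + 1,
      n_cpg = n(),
      mean_diff = mean(.data$diff),
      areaStat = sum(.data$stat),
      direction = if (first(sign(.data$diff)) > 0) "hyper" else "hypo",
      sites = list(.data$pos),
      .groups = "drop"
    ) %>%
    filter(.data$n_cpg >= cfg$dmr_min_cpg) %>%
    select(-"chain")
}

#' Per-locus retroelement methylation summaries
#'
#' Averages CpG methylation frequencies over retroelement loci. A locus is
#' retained only when its length strictly exceeds the family-specific
#' threshold (HERV-K 6000, LTR5_Hs/A/B 900, LINE1-Hs 5900, AluYa5/Yb8 280,
#' SVA-E/F 1000 bp) and at least 10 called CpG sites fall inside it; a
#' family without a configured threshold is retained with a warning.
#'
#' @param matrix a `dg_site_matrix`.
#' @param layout a [genome_layout()] whose `repeat_element` track carries
#'   `family`/`subfamily`.
#' @param cfg a [dg_config()].
#' @param dmrs optional DMR tibble from [call_dmrs()] to join per locus.
#' @return list with `loci` (per-locus mean frequency per sample plus
#'   overall mean and any overlapping-DMR count) and `family_summary`.
#' @export
retroelement_methylation <- function(matrix, layout, cfg = dg_config(),
                                     dmrs = NULL) {
  reps <- layout$tracks$repeat_element
  if (is.null(reps)) stop("layout has no repeat_element track")
  reps <- mutate(reps, locus_id = row_number(),
                 length = .data$end - .data$start)
  thr_of <- function(subfamily) {
    thr <- cfg$family_len_min
    out <- dplyr::case_when(
      subfamily %in% c("HERV-K") ~ thr[["HERV-K"]],
      startsWith(subfamily, "LTR5") ~ thr[["LTR5_Hs/A/B"]],
      subfamily %in% c("L1Hs", "LINE1-Hs") ~ thr[["LINE1-Hs"]],
      subfamily %in% c("AluYa5", "AluYb8") ~ thr[["AluYa5/Yb8"]],
      startsWith(subfamily, "SVA") ~ thr[["SVA-E/F"]],
      TRUE ~ NA_real_
    )
    if (any(is.na(out))) {
      warning("no length threshold for subfamilies: ",
              paste(unique(subfamily[is.na(out)]), collapse = ", "),
              "; retained without length filter")
      out[is.na(out)] <- -Inf
    }
    out
  }
  reps$len_thr <- thr_of(reps$subfamily)
  sites <- mutate(matrix$sites, start = .data$pos, end = .data$pos + 1,
                  site_id = row_number())
  ov <- interval_overlap_pairs(sites[, c("chrom", "start", "end")],
                               reps[, c("chrom", "start", "end")])
  n_cpg <- tabulate(ov$subject_id, nbins = nrow(reps))
  reps$n_cpg <- n_cpg
  kept <- reps$length > reps$len_thr & reps$n_cpg >= cfg$locus_min_cpg
  reps_kept <- reps[kept, ]
  freq <- matrix$meth / matrix$total
  loci <- purrr::map_dfr(which(kept), function(li) {
    sidx <- ov$query_id[ov$subject_id == li]
    f <- freq[sidx, , drop = FALSE]
    per_sample <- colMeans(f, na.rm = TRUE)
    tibble(
      locus_id = li, chrom = reps$chrom[li], start = reps$start[li],
      end = reps$end[li], family = reps$family[li],
      subfamily = reps$subfamily[li], length = reps$length[li],
      n_cpg = reps$n_cpg[li],
      mean_freq = mean(f, na.rm = TRUE),
      sample_means = list(per_sample)
    )
  })
  if (!is.null(dmrs) && nrow(loci)) {
    dov <- interval_overlap_pairs(loci[, c("chrom", "start", "end")], dmrs)
    loci$n_dmrs <- tabulate(dov$query_id, nbins = nrow(loci))
    loci$dmr_areastat <- vapply(seq_len(nrow(loci)), function(i) {
      sum(dmrs$areaStat[dov$subject_id[dov$query_id == i]])
    }, numeric(1))
  }
  family_summary <- if (nrow(loci)) {
    loci %>%
      group_by(.data$family, .data$subfamily) %>%
      summarise(
        n_loci = n(), mean_freq = mean(.data$mean_freq),
        sd_freq = stats::sd(.data$mean_freq), .groups = "drop"
      )
  } else {
    tibble(family = character(0), subfamily = character(0),
           n_loci = integer(0), mean_freq = numeric(0), sd_freq = numeric(0))
  }
  list(loci = loci, family_summary = family_summary)
}

#' Promoter-level DMR counting
#'
#' For each promoter and each methylation direction (hyper/hypo), counts 1
#' when at least one DMR of that direction overlaps the promoter — a
#' promoter is counted once per direction no matter how many DMRs fall in
#' it — and rolls the counts up per gene.
#'
#' @param dmrs DMR tibble from [call_dmrs()].
#' @param promoters tibble `chrom`, `start`, `end`, `gene` (one promoter
#'   per row; a gene may own several promoters).
#' @return list with `promoters` (per-promoter 0/1 hyper and hypo flags)
#'   and `genes` (per-gene totals).
#' @export
promoter_dm_summary <- function(dmrs, promoters) {
  promoters <- mutate(as_tibble(promoters), promoter_id = row_number())
  promoters$hyper <- 0L
  promoters$hypo <- 0L
  if (nrow(dmrs)) {
    for (dir in c("hyper", "hypo")) {
      dd <- filter(dmrs, .data$direction == dir)
      if (!nrow(dd)) next
      ov <- interval_overlap_pairs(promoters[, c("chrom", "start", "end")], dd)
      promoters[[dir]][unique(ov$query_id)] <- 1L
    }
  }
  genes <- promoters %>%
    group_by(.data$gene) %>%
    summarise(hyper = sum(.data$hyper), hypo = sum(.data$hypo),
              .groups = "drop")
  list(promoters = promoters, genes = genes)
}
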
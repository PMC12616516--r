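# Metachromosome ranking, rolling averages, 500-bin meta-profiles, and the
# length-preserving permutation region-overlap test.

#' Rank genomic windows along the metachromosome axis
#'
#' Tiles each chromosome into fixed windows and assigns each a rank from
#' the p-arm telomere (rank 1) through the centromere (rank 0) to the
#' q-arm telomere (rank -1). A window fully contained in the active
#' alpha-satellite HOR region ranks exactly 0; other windows are ranked by
#' the distance of their midpoint from the centromere boundary divided by
#' the arm length (midpoints inside the centromere span also rank 0).
#'
#' @param layout a [genome_layout()] with `arms` and an `active_HOR`
#'   track.
#' @param cfg a [dg_config()] (supplies `window_size`).
#' @param chroms optional chromosome subset (e.g. autosomes only).
#' @return tibble `chrom`, `start`, `end`, `window_id`, `arm` (p/q/cen),
#'   `rank`.
#' @export
rank_windows <- function(layout, cfg = dg_config(), chroms = NULL) {
  if (is.null(layout$arms)) stop("layout has no arm definitions")
  win <- tile_windows(layout, cfg$window_size, chroms)
  missing_arm <- setdiff(unique(win$chrom), layout$arms$chrom)
  if (length(missing_arm)) {
    stop("chromosome without arm definition: ",
         paste(missing_arm, collapse = ", "))
  }
  win <- left_join(win, layout$arms, by = "chrom")
  hor <- layout$tracks$active_HOR
  in_hor <- rep(FALSE, nrow(win))
  if (!is.null(hor) && nrow(hor)) {
    ov <- interval_overlap_pairs(win[, c("chrom", "start", "end")], hor)
    contained <- ov[win$start[ov$query_id] >= hor$start[ov$subject_id] &
                      win$end[ov$query_id] <= hor$end[ov$subject_id], ]
    in_hor[unique(contained$query_id)] <- TRUE
  }
  mid <- (win$start + win$end) / 2
  p_len <- win$cen_start
  q_len <- win$length - win$cen_end
  win$arm <- ifelse(in_hor | (mid >= win$cen_start & mid < win$cen_end), "cen",
                    ifelse(mid < win$cen_start, "p", "q"))
  win$rank <- dplyr::case_when(
    win$arm == "cen" ~ 0,
    win$arm == "p" ~ pmin(1, (win$cen_start - mid) / p_len),
    TRUE ~ -pmin(1, (mid - win$cen_end) / q_len)
  )
  select(win, "chrom", "start", "end", "window_id", "arm", "rank")
}

#' Centred rolling mean with truncated edges
#'
#' Moving average over an odd span; at sequence edges the window truncates
#' to the available neighbours, and missing values are excluded from each
#' local mean.
#'
#' @param values numeric vector ordered by genomic position within an arm.
#' @param span odd window span (default 11 windows, about 1 Mb).
#' @return numeric vector of the same length.
#' @export
rolling_mean <- function(values, span = 11L) {
  if (span %% 2 == 0) stop("span must be odd")
  h <- (span - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i) {
    w <- values[max(1, i - h):min(n, i + h)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Collapse ranked windows into a metachromosome profile
#'
#' Maps each window rank r in [-1, 1] to meta-bin
#' `round((r + 1) * n_bins / 2)` (round half away from zero, clipped to
#' [0, n_bins]), so bin 0 is the q telomere, bin 250 the centromere and
#' bin 500 the p telomere with the default 500 bins; bins 249-251 are
#' marked centromeric and bins 0-1/499-500 telomeric. `mean` mode averages
#' window values per bin across chromosomes; `normalized_count` mode
#' divides the per-bin mean count by the global mean count over windows
#' with a positive count.
#'
#' @param ranked tibble from [rank_windows()] with a `value` column.
#' @param cfg a [dg_config()] (supplies `n_metabins`).
#' @param mode `"mean"` or `"normalized_count"`.
#' @return tibble `bin`, `value`, `n_windows`, `region` (centromeric /
#'   telomeric / arm); bins with no contributing window are absent.
#' @export
metabin_profile <- function(ranked, cfg = dg_config(),
                            mode = c("mean", "normalized_count")) {
  mode <- match.arg(mode)
  if (!"value" %in% names(ranked)) stop("ranked windows need a 'value' column")
  nb <- cfg$n_metabins
  ok <- !is.na(ranked$value)
  r <- ranked$rank[ok]
  v <- ranked$value[ok]
  bin <- pmin(nb, pmax(0, floor((r + 1) * nb / 2 + 0.5)))
  prof <- tibble(bin = bin, value = v) %>%
    group_by(.data$bin) %>%
    summarise(value = mean(.data$value), n_windows = n(), .groups = "drop")
  if (mode == "normalized_count") {
    global_mean <- mean(v[v > 0])
    prof$value <- prof$value / global_mean
  }
  half <- nb / 2
  prof$region <- dplyr::case_when(
    abs(prof$bin - half) <= 1 ~ "centromeric",
    prof$bin <= 1 | prof$bin >= nb - 1 ~ "telomeric",
    TRUE ~ "arm"
  )
  arrange(prof, .data$bin)
}

#' Length-preserving permutation test of region overlap
#'
#' Counts query regions overlapping a target track, then re-places every
#' query region uniformly at random on its own chromosome (length
#' preserved, mutual overlaps allowed) `n_perm` times and recounts. The
#' empirical p is `(1 + #{perm >= obs}) / (1 + n_perm)`; z is the observed
#' count standardised by the permutation mean and SD.
#'
#' @param query tibble `chrom`, `start`, `end` of query regions (e.g.
#'   DMRs).
#' @param layout a [genome_layout()].
#' @param target_track track label, or character vector of labels whose
#'   union is the target.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed for the permutation draws.
#' @param genome_wide if TRUE regions may be re-placed on any chromosome
#'   (weighted by length) instead of their own.
#' @return object of class `dg_permtest`: list with `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `p`, `n_perm`, `n_query`,
#'   `perm_counts`.
#' @export
permutation_overlap_test <- function(query, layout, target_track,
                                     n_perm = 10000, seed = 1,
                                     genome_wide = FALSE) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  chrom_len <- stats::setNames(layout$chromosomes$length,
                               layout$chromosomes$chrom)
  qlen <- query$end - query$start
  if (any(qlen > chrom_len[query$chrom])) {
    stop("query region longer than its chromosome")
  }
  target <- bind_rows(lapply(target_track, function(tr) {
    if (!tr %in% names(layout$tracks)) stop("unknown track label: ", tr)
    layout$tracks[[tr]][, c("chrom", "start", "end")]
  }))
  count_overlaps <- function(q) {
    length(unique(interval_overlap_pairs(q, target)$query_id))
  }
  observed <- count_overlaps(query)

  set.seed(child_seed(seed, 8L))
  n_q <- nrow(query)
  counts <- integer(n_perm)
  # a region [s, s+len) overlaps the merged target iff s falls in the
  # target expanded left by len - 1; precompute merged boundaries per
  # (chromosome, length) group and test placements with findInterval
  if (genome_wide) {
    chrom_draws <- matrix(
      sample(names(chrom_len), n_perm * n_q, replace = TRUE,
             prob = chrom_len / sum(chrom_len)),
      nrow = n_perm
    )
  }
  # iterate groups in sorted key order so the RNG stream does not depend
  # on query-region input order
  grp_key <- if (genome_wide) qlen else paste(query$chrom, qlen)
  for (key in sort(unique(grp_key))) {
    idx <- which(grp_key == key)
    len <- qlen[idx[1]]
    if (genome_wide) {
      # placement chromosome varies per draw; handle per chromosome
      for (ch in names(chrom_len)) {
        tmask <- target$chrom == ch
        bounds <- merge_expanded(target[tmask, ], len, chrom_len[ch])
        sel <- chrom_draws[, idx, drop = FALSE] == ch
        n_draw <- sum(sel)
        if (n_draw == 0) next
        starts <- floor(stats::runif(n_draw, 0, chrom_len[ch] - len + 1))
        hit <- findInterval(starts, bounds) %% 2 == 1
        inc <- matrix(0L, nrow = n_perm, ncol = length(idx))
        inc[sel] <- as.integer(hit)
        counts <- counts + rowSums(inc)
      }
    } else {
      ch <- query$chrom[idx[1]]
      bounds <- merge_expanded(target[target$chrom == ch, ], len, chrom_len[ch])
      starts <- matrix(
        floor(stats::runif(n_perm * length(idx), 0, chrom_len[ch] - len + 1)),
        nrow = n_perm
      )
      hit <- matrix(findInterval(starts, bounds) %% 2 == 1, nrow = n_perm)
      counts <- counts + rowSums(hit)
    }
  }
  perm_mean <- mean(counts)
  perm_sd <- stats::sd(counts)
  structure(list(
    observed = observed,
    perm_mean = perm_mean,
    perm_sd = perm_sd,
    z = if (perm_sd > 0) (observed - perm_mean) / perm_sd else NA_real_,
    p = (1 + sum(counts >= observed)) / (1 + n_perm),
    n_perm = n_perm,
    n_query = n_q,
    perm_counts = counts
  ), class = "dg_permtest")
}

# merged half-open boundaries of target intervals expanded left by len - 1
# (membership of a start in an odd findInterval stratum = overlap)
merge_expanded <- function(target, len, chrom_length) {
  if (nrow(target) == 0) return(numeric(0))
  s <- pmax(0, target$start - len + 1)
  e <- pmin(chrom_length, target$end)
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out <- c(out, ms, me)
      ms <- s[i]; me <- e[i]
    }
  }
  c(out, ms, me)
}

#' @export
print.dg_permtest <- function(x, ...) {
  cat(sprintf(
    "<dg_permtest> %d regions, %d permutations\nobserved overlap = %d, permutation mean = %.2f (sd %.2f)\nz = %.2f, empirical p = %.4g\n",
    x$n_query, x$n_perm, x$observed, x$perm_mean, x$perm_sd, x$z, x$p
  ))
  invisible(x)
}

#' @export
tidy.dg_permtest <- function(x, ...) {
  tibble(
    observed = x$observed, perm_mean = x$perm_mean, perm_sd = x$perm_sd,
    z = x$z, p.value = x$p, n_perm = x$n_perm, n_query = x$n_query
  )
}

#' @export
glance.dg_permtest <- function(x, ...) tidy.dg_permtest(x)
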
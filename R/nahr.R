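# NAHR event filtering, windowed enrichment and recombination geometry.

#' Filter NAHR events on caller score and singleton status
#'
#' Retains events with a caller score at or below 1e-4 that were
#' identified as singleton events.
#'
#' @param events NAHR-dialect tibble.
#' @param cfg a [dg_config()].
#' @return retained events tibble.
#' @export
filter_nahr_events <- function(events, cfg = dg_config()) {
  filter(events, .data$score <= cfg$nahr_score_max, .data$singleton == 1)
}

#' Windowed NAHR enrichment
#'
#' Tiles the genome into fixed 100-kbp windows and computes, per window,
#' the ratio of NAHR event endpoints to the number of repeat elements
#' (each event contributes its two junction endpoints to their respective
#' windows; a repeat is counted in the window holding its midpoint).
#' Windows with zero repeats get an undefined (NA) enrichment and are
#' flagged.
#'
#' @param events filtered NAHR events.
#' @param layout a [genome_layout()] with a `repeat_element` track.
#' @param cfg a [dg_config()].
#' @return tibble `chrom`, `start`, `end`, `window_id`, `n_events`,
#'   `n_repeats`, `enrichment`, `undefined`.
#' @export
window_enrichment <- function(events, layout, cfg = dg_config()) {
  win <- tile_windows(layout, cfg$window_size)
  endpoints <- bind_rows(
    tibble(chrom = events$chromA, pos = events$posA),
    tibble(chrom = events$chromB, pos = events$posB)
  )
  ep_hit <- interval_overlap_pairs(
    mutate(endpoints, start = .data$pos, end = .data$pos + 1), win
  )
  n_events <- tabulate(ep_hit$subject_id, nbins = nrow(win))
  reps <- layout$tracks$repeat_element
  if (is.null(reps)) stop("layout has no repeat_element track")
  mids <- mutate(reps,
    start = floor((.data$start + .data$end) / 2),
    end = .data$start + 1
  )
  rep_hit <- interval_overlap_pairs(mids[, c("chrom", "start", "end")], win)
  n_repeats <- tabulate(rep_hit$subject_id, nbins = nrow(win))
  win %>%
    mutate(
      n_events = n_events,
      n_repeats = n_repeats,
      enrichment = ifelse(n_repeats > 0, n_events / n_repeats, NA_real_),
      undefined = n_repeats == 0
    )
}

GEOMETRY_OF <- c(`++` = "inversion", `--` = "inversion",
                 `+-` = "deletion", `-+` = "duplication")

#' Classify NAHR partner pairs and event geometry
#'
#' Derives the order-insensitive family pair class (e.g. `L1-L1`,
#' `Alu-Alu`) from the two junction families, the event geometry
#' (interchromosomal when the chromosomes differ, otherwise from the
#' orientation code: `++`/`--` inversion, `+-` deletion, `-+`
#' duplication), and the intrachromosomal span. Also cross-tabulates
#' region class (of endpoint A) against pair class.
#'
#' @param events filtered NAHR events.
#' @param layout a [genome_layout()].
#' @return list with `events` (annotated: `pair_class`, `geometry`,
#'   `intra`, `span`, `region_class`) and `summary` (region class x pair
#'   class counts).
#' @export
classify_pairs_and_geometry <- function(events, layout) {
  bad <- setdiff(unique(events$orientation), names(GEOMETRY_OF))
  if (length(bad)) stop("unknown orientation code: ", paste(bad, collapse = ", "))
  famA <- family_of(events$familyA)
  famB <- family_of(events$familyB)
  events$pair_class <- purrr::map2_chr(famA, famB, function(a, b) {
    paste(sort(c(a, b)), collapse = "-")
  })
  events$intra <- events$chromA == events$chromB
  events$span <- ifelse(events$intra, abs(events$posB - events$posA), NA_real_)
  events$geometry <- ifelse(events$intra,
                            GEOMETRY_OF[events$orientation],
                            "interchromosomal")
  qa <- tibble(chrom = events$chromA, start = events$posA, end = events$posA + 1)
  events$region_class <- centromere_class(qa, layout)
  if ("rDNA_array" %in% names(layout$tracks)) {
    rh <- interval_overlap(qa, layout, "rDNA_array")
    events$region_class[setdiff(unique(rh$query_id),
                                which(!is.na(events$region_class)))] <- "rDNA_array"
  }
  summary <- events %>%
    mutate(region_class = ifelse(is.na(.data$region_class), "arm",
                                 .data$region_class)) %>%
    count(.data$region_class, .data$pair_class, name = "n")
  list(events = events, summary = summary)
}

#' Region-set enrichment of NAHR-bearing windows
#'
#' For each region set, builds the 2x2 table of 100-kbp windows {contains
#' at least one event endpoint, none} x {overlaps the set, not}, tests it
#' with Fisher's exact test and adjusts across sets by Benjamini-Hochberg.
#' Empty region sets are skipped with a warning.
#'
#' @param events filtered NAHR events.
#' @param region_sets named list of interval tibbles (`chrom`, `start`,
#'   `end`), or a character vector of layout track labels.
#' @param layout a [genome_layout()].
#' @param cfg a [dg_config()].
#' @return tibble `set`, `n11`..`n22`, `odds_ratio`, `p`, `q`.
#' @export
regionset_enrichment <- function(events, region_sets, layout, cfg = dg_config()) {
  if (is.character(region_sets)) {
    region_sets <- stats::setNames(
      lapply(region_sets, function(tr) layout$tracks[[tr]]), region_sets
    )
  }
  win <- window_enrichment(events, layout, cfg)
  has_event <- win$n_events > 0
  rows <- purrr::imap_dfr(region_sets, function(set, label) {
    if (is.null(set) || nrow(set) == 0) {
      warning("empty region set skipped: ", label)
      return(NULL)
    }
    ov <- interval_overlap_pairs(win[, c("chrom", "start", "end")], set)
    in_set <- seq_len(nrow(win)) %in% ov$query_id
    tab <- matrix(c(
      sum(has_event & in_set), sum(has_event & !in_set),
      sum(!has_event & in_set), sum(!has_event & !in_set)
    ), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    tibble(
      set = label,
      n_event_in = tab[1, 1], n_event_out = tab[1, 2],
      n_empty_in = tab[2, 1], n_empty_out = tab[2, 2],
      odds_ratio = unname(ft$estimate), p = ft$p.value
    )
  })
  if (nrow(rows)) rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows
}
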
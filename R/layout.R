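#' @importFrom dplyr %>% arrange mutate filter select left_join group_by
#'   summarise ungroup bind_rows rename n across all_of row_number distinct
#'   if_else pull slice count first
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# Region-class vocabulary. Centromere-repeat classes drive the
# centromeric/non-centromeric split used downstream.
CEN_CLASSES <- c(
  "active_HOR", "inactive_HOR", "monomeric_alphasat",
  "beta_satellite", "classical_satellite"
)

#' Construct a validated genome layout
#'
#' A genome layout bundles chromosome sizes, interval tracks keyed by
#' region-class label (centromere repeat classes, rDNA arrays, dark regions,
#' segmental duplications, repeat elements), and per-chromosome arm structure
#' derived from centromere spans. All coordinates are 0-based half-open.
#'
#' @param chromosomes tibble with columns `chrom`, `length`.
#' @param tracks named list of tibbles, each with `chrom`, `start`, `end` and
#'   optionally `family`, `subfamily`, `strand` (repeat elements) or other
#'   annotation columns.
#' @param arms tibble with `chrom`, `cen_start`, `cen_end`: the single
#'   contiguous centromere span per chromosome. The p arm is
#'   `[0, cen_start)`, the q arm `[cen_end, length)`.
#' @return object of class `genome_layout`.
#' @export
genome_layout <- function(chromosomes, tracks = list(), arms = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  len_of <- stats::setNames(chromosomes$length, chromosomes$chrom)

  tracks <- lapply(tracks, function(tr) {
    tr <- as_tibble(tr)
    stopifnot(all(c("chrom", "start", "end") %in% names(tr)))
    if (nrow(tr) == 0) return(tr)
    unknown <- setdiff(unique(tr$chrom), chromosomes$chrom)
    if (length(unknown)) {
      stop("track interval on unknown chromosome: ", paste(unknown, collapse = ", "))
    }
    if (any(tr$start < 0) || any(tr$start >= tr$end)) {
      stop("track intervals must satisfy 0 <= start < end")
    }
    if (any(tr$end > len_of[tr$chrom])) {
      stop("track interval exceeds chromosome length")
    }
    arrange(tr, match(.data$chrom, chromosomes$chrom), .data$start)
  })

  if (!is.null(arms)) {
    arms <- as_tibble(arms)
    stopifnot(all(c("chrom", "cen_start", "cen_end") %in% names(arms)))
    missing_arm <- setdiff(chromosomes$chrom, arms$chrom)
    if (length(missing_arm)) {
      stop("no centromere span for chromosome(s): ",
           paste(missing_arm, collapse = ", "))
    }
    arms <- arms %>%
      filter(.data$chrom %in% chromosomes$chrom) %>%
      mutate(length = len_of[.data$chrom])
    if (any(arms$cen_start <= 0) || any(arms$cen_end >= arms$length) ||
        any(arms$cen_start >= arms$cen_end)) {
      stop("centromere span must lie strictly inside the chromosome")
    }
    arms <- arrange(arms, match(.data$chrom, chromosomes$chrom))
  }

  structure(
    list(chromosomes = chromosomes, tracks = tracks, arms = arms),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d chromosomes (%.1f Mb), %d tracks\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, length(x$tracks)
  ))
  for (nm in names(x$tracks)) {
    cat(sprintf("  track %-24s %d intervals\n", nm, nrow(x$tracks[[nm]])))
  }
  invisible(x)
}

#' Read a genome layout from standard files
#'
#' @param chrom_sizes path to a two-column TSV (chrom, length).
#' @param track_beds named list or character vector mapping region-class
#'   label to a BED3+ path; repeat-element BEDs may carry name
#'   (`family:subfamily`), score and strand columns.
#' @param cytobands path to a UCSC-style cytoBand TSV (chrom, start, end,
#'   band, gieStain); rows stained `acen` define the centromere span and
#'   hence the p/q arms.
#' @return a [genome_layout()].
#' @export
parse_genome_layout <- function(chrom_sizes, track_beds = list(), cytobands = NULL) {
  chromosomes <- readr::read_tsv(
    chrom_sizes,
    col_names = c("chrom", "length"),
    col_types = readr::cols(chrom = "c", length = "d"),
    progress = FALSE
  )
  tracks <- lapply(track_beds, read_bed)
  arms <- NULL
  if (!is.null(cytobands)) {
    cyto <- readr::read_tsv(
      cytobands,
      col_names = c("chrom", "start", "end", "band", "gieStain"),
      col_types = "ciicc", progress = FALSE
    )
    acen <- filter(cyto, .data$gieStain == "acen")
    no_acen <- setdiff(chromosomes$chrom, unique(acen$chrom))
    if (length(no_acen)) {
      stop("cytoband file has no 'acen' rows for: ",
           paste(no_acen, collapse = ", "))
    }
    arms <- acen %>%
      group_by(.data$chrom) %>%
      summarise(cen_start = min(.data$start), cen_end = max(.data$end))
  }
  genome_layout(chromosomes, tracks, arms)
}

#' Read a BED3+ file as a tibble
#'
#' Columns beyond the first three are interpreted as name, score, strand
#' (BED6). A name of the form `family:subfamily` is split into the two
#' repeat-annotation columns.
#' @param path BED file path.
#' @return tibble with `chrom`, `start`, `end` and any extra columns.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  out <- tibble(
    chrom = raw[[1]],
    start = as.numeric(raw[[2]]),
    end = as.numeric(raw[[3]])
  )
  if (ncol(raw) >= 4) {
    nm <- raw[[4]]
    if (all(grepl(":", nm))) {
      parts <- stringr::str_split_fixed(nm, ":", 2)
      out$family <- parts[, 1]
      out$subfamily <- parts[, 2]
    } else {
      out$name <- nm
    }
  }
  if (ncol(raw) >= 6) out$strand <- raw[[6]]
  out
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()]: emits BED3, or BED6 when annotation columns are
#' present (`family`/`subfamily` re-joined as `family:subfamily`).
#' @param x tibble with `chrom`, `start`, `end` and optional annotations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                   end = format(x$end, scientific = FALSE, trim = TRUE))
  has <- function(col) col %in% names(x)
  if (has("family") || has("name")) {
    df$name <- if (has("family")) paste0(x$family, ":", x$subfamily) else x$name
    df$score <- 0
    df$strand <- if (has("strand")) x$strand else "."
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome layout to a directory of standard files
#'
#' Emits `chrom.sizes`, one `<label>.bed` per track, and `cytoBand.txt`
#' with `acen` centromere rows, so that [parse_genome_layout()] round-trips.
#' @param layout a [genome_layout()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_layout <- function(layout, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(layout$chromosomes$chrom,
               format(layout$chromosomes$length, scientific = FALSE, trim = TRUE)),
    file.path(dir, "chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  for (nm in names(layout$tracks)) {
    write_bed(layout$tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
  }
  if (!is.null(layout$arms)) {
    a <- layout$arms
    cyto <- rbind(
      data.frame(chrom = a$chrom, start = 0, end = a$cen_start,
                 band = "p11", stain = "gpos50"),
      data.frame(chrom = a$chrom, start = a$cen_start,
                 end = (a$cen_start + a$cen_end) / 2, band = "p11.1", stain = "acen"),
      data.frame(chrom = a$chrom, start = (a$cen_start + a$cen_end) / 2,
                 end = a$cen_end, band = "q11.1", stain = "acen"),
      data.frame(chrom = a$chrom, start = a$cen_end, end = a$length,
                 band = "q11", stain = "gpos50")
    )
    cyto <- cyto[order(match(cyto$chrom, layout$chromosomes$chrom), cyto$start), ]
    cyto$start <- format(cyto$start, scientific = FALSE, trim = TRUE)
    cyto$end <- format(cyto$end, scientific = FALSE, trim = TRUE)
    utils::write.table(cyto, file.path(dir, "cytoBand.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

as_granges <- function(x, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels %||% unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlap query intervals with a layout track
#'
#' Half-open overlap against one region-class track; a query overlapping k
#' track intervals yields k hit rows. Strand is ignored. Point queries
#' (`end = start + 1`) are supported.
#'
#' @param query tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param layout a [genome_layout()].
#' @param track region-class label naming a track in `layout`.
#' @return tibble with `query_id` (row index into `query`), the hit
#'   interval's coordinates and any track annotation columns, plus
#'   `region_class` = `track`.
#' @export
interval_overlap <- function(query, layout, track) {
  if (!track %in% names(layout$tracks)) {
    stop("unknown track label: ", track)
  }
  tr <- layout$tracks[[track]]
  empty <- tibble(query_id = integer(0), chrom = character(0),
                  start = numeric(0), end = numeric(0),
                  region_class = character(0))
  if (nrow(tr) == 0 || nrow(query) == 0) return(empty)
  lv <- union(unique(query$chrom), unique(tr$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(query, lv), as_granges(tr, lv))
  out <- tr[S4Vectors::subjectHits(hits), ]
  out$query_id <- S4Vectors::queryHits(hits)
  out$region_class <- track
  select(out, "query_id", dplyr::everything())
}

#' Label points by centromere-repeat region class
#'
#' Convenience over [interval_overlap()]: checks each centromere-repeat
#' track in turn and reports, per query row, the region class hit (NA when
#' the point lies on a chromosome arm outside all centromere tracks).
#' When a query overlaps several classes the first in the fixed class order
#' (active_HOR, inactive_HOR, monomeric_alphasat, beta_satellite,
#' classical_satellite) wins.
#'
#' @param query tibble with `chrom`, `start`, `end`.
#' @param layout a [genome_layout()].
#' @return character vector of region classes, NA for non-centromeric.
#' @export
centromere_class <- function(query, layout) {
  out <- rep(NA_character_, nrow(query))
  for (cls in intersect(CEN_CLASSES, names(layout$tracks))) {
    h <- interval_overlap(query, layout, cls)
    idx <- setdiff(unique(h$query_id), which(!is.na(out)))
    out[idx] <- cls
  }
  out
}

#' Tile the genome into fixed-width windows
#'
#' Non-overlapping tiling from each chromosome start; the last window of a
#' chromosome may be short.
#' @param layout a [genome_layout()].
#' @param window_size window width in bp.
#' @param chroms optional subset of chromosomes.
#' @return tibble `chrom`, `start`, `end`, `window_id`.
#' @export
tile_windows <- function(layout, window_size = 1e5, chroms = NULL) {
  chr <- layout$chromosomes
  if (!is.null(chroms)) chr <- filter(chr, .data$chrom %in% chroms)
  purrr::pmap_dfr(chr, function(chrom, length, ...) {
    starts <- seq(0, length - 1, by = window_size)
    tibble(chrom = chrom, start = starts,
           end = pmin(starts + window_size, length))
  }) %>%
    mutate(window_id = row_number())
}
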
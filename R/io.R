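# Column dialects of the four caller-output table kinds. Readers validate
# the header verbatim and range-check numeric fields; writers emit the same
# dialect so tables round-trip exactly.

DIALECTS <- list(
  insertion = c(
    "uuid", "sample_id", "chrom", "pos", "subfamily", "filter",
    "unmap_cover", "three_prime_intact", "tsd_seq", "n_support_reads",
    "support_read_len_bp", "n_spanning_nonsupport_reads", "polyA",
    "junction_seq", "mapq"
  ),
  nahr = c(
    "event_id", "sample_id", "chromA", "posA", "familyA", "chromB", "posB",
    "familyB", "score", "singleton", "orientation"
  ),
  methylation = c(
    "chromosome", "start", "end", "num_cpgs_in_group", "called_sites",
    "called_sites_methylated", "methylated_frequency"
  ),
  sample_meta = c(
    "sample_id", "group", "sex", "age", "pmi", "gbp_sequenced",
    "mean_coverage"
  )
)

#' Read a caller-output table
#'
#' Reads and validates one of the four TSV dialects the pipeline consumes:
#' retrotransposon insertion calls, NAHR junction events, per-sample CpG
#' methylation frequencies (nanopore-frequency style), or sample metadata.
#'
#' @param kind one of `"insertion"`, `"nahr"`, `"methylation"`,
#'   `"sample_meta"`.
#' @param path TSV path with the dialect's exact header.
#' @return tibble of typed, range-checked records; a header-only file gives
#'   an empty tibble.
#' @export
parse_calls <- function(kind = c("insertion", "nahr", "methylation", "sample_meta"),
                        path) {
  kind <- match.arg(kind)
  want <- DIALECTS[[kind]]
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, want)) {
    stop(sprintf(
      "unexpected %s header; expected columns: %s",
      kind, paste(want, collapse = ", ")
    ))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       show_col_types = FALSE)
  x <- as_tibble(x)
  validate_calls(kind, x)
}

validate_calls <- function(kind, x) {
  fail_row <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s: %s at row %d", kind, what, which(!ok)[1]))
    }
  }
  if (nrow(x) == 0) return(x)
  if (kind == "insertion") {
    x$chrom <- as.character(x$chrom)
    x$tsd_seq <- ifelse(is.na(x$tsd_seq), "", as.character(x$tsd_seq))
    fail_row(x$unmap_cover >= 0 & x$unmap_cover <= 1, "unmap_cover outside [0,1]")
    fail_row(x$pos >= 0, "negative position")
    fail_row(x$n_support_reads >= 1, "n_support_reads < 1")
    fail_row(x$three_prime_intact %in% c(0, 1), "three_prime_intact not 0/1")
    fail_row(x$polyA %in% c(0, 1), "polyA not 0/1")
  } else if (kind == "nahr") {
    x$chromA <- as.character(x$chromA)
    x$chromB <- as.character(x$chromB)
    fail_row(x$score > 0, "score must be positive")
    fail_row(x$singleton %in% c(0, 1), "singleton not 0/1")
    fail_row(x$orientation %in% c("++", "+-", "-+", "--"), "bad orientation code")
  } else if (kind == "methylation") {
    x$chromosome <- as.character(x$chromosome)
    fail_row(x$called_sites_methylated <= x$called_sites,
             "called_sites_methylated > called_sites")
    fail_row(x$methylated_frequency >= 0 & x$methylated_frequency <= 1,
             "methylated_frequency outside [0,1]")
    fail_row(x$start <= x$end, "start > end")
  } else if (kind == "sample_meta") {
    fail_row(x$gbp_sequenced > 0, "gbp_sequenced must be positive")
    x$group <- as.character(x$group)
  }
  x
}

#' Write a caller-output table
#'
#' Inverse of [parse_calls()]: writes the dialect's exact header and fields
#' so that reading the file back reproduces the records.
#' @inheritParams parse_calls
#' @param x tibble of records for the dialect.
#' @return `path`, invisibly.
#' @export
write_calls <- function(kind = c("insertion", "nahr", "methylation", "sample_meta"),
                        x, path) {
  kind <- match.arg(kind)
  want <- DIALECTS[[kind]]
  missing <- setdiff(want, names(x))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  readr::write_tsv(x[, want], path, progress = FALSE)
  invisible(path)
}

#' Read a multi-sample structural-variant VCF
#'
#' Parses a Sniffles2-style multi-sample VCF (v4.2) into one row per
#' variant with per-sample genotype status. `./.` genotypes are `missing`,
#' genotypes carrying at least one alternate allele are `present`,
#' homozygous-reference genotypes are `absent`. Variant length comes from
#' INFO/SVLEN (absolute value) or, failing that, END - POS.
#'
#' @param path VCF path (plain text).
#' @param samples sample-metadata tibble (`sample_id`, `group`, ...); the
#'   VCF's sample columns must match `sample_id` as a set.
#' @return tibble with `id`, `chrom`, `start`, `end` (0-based half-open
#'   anchor interval), `svtype`, `length`, and one `status_<sample>` column
#'   per sample plus a nested `status` list-column of named status vectors.
#' @export
parse_sv_vcf <- function(path, samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  vcf_samples <- colnames(gt)[-1]
  if (!setequal(vcf_samples, samples$sample_id)) {
    stop("VCF sample columns do not match metadata sample_ids")
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  if (any(is.na(svtype))) stop("variant without SVTYPE INFO key")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  endf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  pos <- as.numeric(fix$POS)
  len <- ifelse(!is.na(svlen), abs(svlen),
                ifelse(!is.na(endf), endf - pos, NA_real_))

  gt_codes <- apply(gt[, vcf_samples, drop = FALSE], 2, function(col) {
    g <- sub(":.*", "", col)
    # vcfR reads "./." as NA
    ifelse(is.na(g) | g %in% c("./.", ".|.", "."), "missing",
           ifelse(grepl("[1-9]", g), "present", "absent"))
  })
  gt_codes <- matrix(gt_codes, nrow = nrow(fix),
                     dimnames = list(NULL, vcf_samples))
  # status columns in metadata order
  gt_codes <- gt_codes[, samples$sample_id, drop = FALSE]

  out <- tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    start = pos - 1,
    end = ifelse(!is.na(endf), endf, pos),
    svtype = svtype,
    length = len
  )
  for (s in samples$sample_id) out[[paste0("status_", s)]] <- gt_codes[, s]
  out$status <- lapply(seq_len(nrow(out)), function(i) {
    stats::setNames(gt_codes[i, ], samples$sample_id)
  })
  out
}

#' Write structural variants as a minimal multi-sample VCF
#'
#' Emits a plain-text VCF 4.2 with SVTYPE/SVLEN/END INFO keys and GT-only
#' sample columns, sufficient for [parse_sv_vcf()] to round-trip the
#' per-sample status calls (`present` -> 0/1, `absent` -> 0/0,
#' `missing` -> ./.).
#'
#' @param variants tibble as returned by [parse_sv_vcf()] (or the
#'   simulator), with `status_<sample>` columns.
#' @param samples sample-metadata tibble giving the column order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(variants, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  ), con)
  gt_of <- c(present = "0/1", absent = "0/0", missing = "./.")
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", v$svtype,
                    as.integer(if (v$svtype == "DEL") -v$length else v$length),
                    as.integer(v$end))
    gts <- gt_of[unlist(v[paste0("status_", samples$sample_id)])]
    writeLines(paste(c(
      v$chrom, format(v$start + 1, scientific = FALSE), v$id, "N",
      paste0("<", v$svtype, ">"), ".", "PASS", info, "GT", gts
    ), collapse = "\t"), con)
  }
  invisible(path)
}
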
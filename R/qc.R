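flat_segments <- function(read_sets) {
  if ("segments" %in% names(read_sets)) {
    tidyr::unnest(dplyr::select(read_sets, "read_id", "segments"),
                  cols = "segments", names_repair = "minimal")
  } else {
    read_sets
  }
}

#' Count reads overlapping and fully covering each region of interest
#'
#' A read "fully covers" an ROI when the union of its aligned segments on the
#' ROI chromosome contains the whole interval; it "overlaps" when the
#' intersection is non-empty. Both are reported, together with mean
#' alignment-span depth over the ROI.
#'
#' @param read_sets tibble from [group_by_read()] (or a flat alignment
#'   tibble).
#' @param rois tibble of intervals (name, chrom, start, end), e.g. the
#'   genome's ROI features or [read_bed()] output.
#' @return tibble (name, chrom, start, end, n_overlapping, n_fully_covering,
#'   mean_depth).
#' @export
count_on_target <- function(read_sets, rois) {
  if (any(rois$end <= rois$start)) abort("empty ROI interval")
  segs <- flat_segments(read_sets)
  purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    s <- dplyr::filter(segs, .data$chrom == roi$chrom,
                       .data$rstart < roi$end, .data$rend > roi$start)
    if (nrow(s) == 0L) {
      return(tibble(name = roi$name, chrom = roi$chrom, start = roi$start,
                    end = roi$end, n_overlapping = 0L, n_fully_covering = 0L,
                    mean_depth = 0))
    }
    full <- s |>
      group_by(.data$read_id) |>
      summarise(covers = {
        ir <- IRanges::reduce(IRanges::IRanges(start = .data$rstart + 1L,
                                               end = .data$rend))
        any(IRanges::start(ir) <= roi$start + 1L & IRanges::end(ir) >= roi$end)
      }, .groups = "drop")
    clipped <- pmin(s$rend, roi$end) - pmax(s$rstart, roi$start)
    tibble(name = roi$name, chrom = roi$chrom, start = roi$start,
           end = roi$end,
           n_overlapping = dplyr::n_distinct(s$read_id),
           n_fully_covering = sum(full$covers),
           mean_depth = sum(clipped) / (roi$end - roi$start))
  })
}

#' Per-base alignment-span depth over an interval
#'
#' Depth at a position is the number of segments whose reference interval
#' contains it; deletions inside a segment still count (the convention of
#' standard depth tools).
#'
#' @param aln alignment tibble (or nested read sets).
#' @param region one-row data frame or list with chrom/start/end.
#' @return tibble (chrom, pos, depth), one row per position of the interval.
#' @export
coverage_track <- function(aln, region) {
  region <- as_region(region)
  segs <- dplyr::filter(flat_segments(aln), .data$chrom == region$chrom)
  cov <- IRanges::coverage(IRanges::IRanges(start = segs$rstart + 1L,
                                            end = segs$rend),
                           width = max(region$end, if (nrow(segs)) max(segs$rend) else 0L))
  depth <- as.integer(cov[(region$start + 1L):region$end])
  tibble(chrom = region$chrom, pos = seq.int(region$start, region$end - 1L),
         depth = depth)
}

#' Check the PAM motif of each crRNA against the genome
#'
#' Extracts the 3-mer under the PAM interval on the protospacer strand and
#' tests it against N-G-G, the SpCas9 motif.
#'
#' @param genome a `toy_genome`.
#' @param crrnas crRNA tibble (defaults to the genome's).
#' @return tibble (name, strand, observed_pam, pam_ok).
#' @export
pam_check <- function(genome, crrnas = NULL) {
  cr <- crrnas %||% genome$crrnas
  obs <- vapply(seq_len(nrow(cr)), function(i) {
    g <- cr[i, ]
    len <- nchar(genome$chromosomes[[g$chrom]])
    if (g$pam_start < 0 || g$pam_end > len) abort("PAM interval out of bounds")
    s <- subseq0(genome$chromosomes[[g$chrom]], g$pam_start, g$pam_end)
    if (g$strand == "-") revcomp(s) else s
  }, character(1))
  tibble(name = cr$name, strand = cr$strand, observed_pam = obs,
         pam_ok = grepl("^[ACGTN]GG$", obs))
}

#' Profile read ends against expected Cas9 cut sites
#'
#' For each read, finds the segment end facing the cut (segment start for
#' guides whose fragment extends rightwards, segment end boundary for
#' leftward guides) that falls within `window` bp of a crRNA's expected blunt
#' cut, and records the signed offset `observed - expected`. Reads matching
#' no cut site are tallied as off-signature.
#'
#' @param read_sets tibble from [group_by_read()] (or flat alignments).
#' @param genome a `toy_genome` (for crRNA geometry and PAM checks).
#' @param window matching half-width in bp (default 20).
#' @return a `cut_site_profile` object: list with `hits` (tibble: crrna,
#'   read_id, observed, offset, pam_ok), `histogram` (crrna, offset, n),
#'   `n_off_signature` and `window`.
#' @export
cut_site_profile <- function(read_sets, genome, window = 20L) {
  stopifnot(window >= 0)
  segs <- flat_segments(read_sets)
  cr <- genome$crrnas
  pam <- pam_check(genome, cr)
  cand <- purrr::map_dfr(seq_len(nrow(cr)), function(i) {
    g <- cr[i, ]
    s <- dplyr::filter(segs, .data$chrom == g$chrom)
    if (nrow(s) == 0L) return(NULL)
    obs <- if (g$direction > 0) s$rstart else s$rend
    tibble(crrna = g$name, read_id = s$read_id, observed = obs,
           offset = obs - g$expected_cut,
           pam_ok = pam$pam_ok[i])
  })
  hits <- cand |>
    filter(abs(.data$offset) <= window) |>
    group_by(.data$read_id) |>
    dplyr::slice_min(abs(.data$offset), n = 1, with_ties = FALSE) |>
    ungroup()
  all_reads <- unique(segs$read_id)
  structure(list(
    hits = dplyr::select(hits, "crrna", "read_id", "observed", "offset",
                         "pam_ok"),
    histogram = dplyr::count(hits, .data$crrna, .data$offset, name = "n"),
    n_off_signature = length(setdiff(all_reads, hits$read_id)),
    window = window
  ), class = "cut_site_profile")
}

#' @export
print.cut_site_profile <- function(x, ...) {
  cat("<cut_site_profile> ", nrow(x$hits), " cut-site hits, ",
      x$n_off_signature, " off-signature reads (window ±", x$window,
      " bp)\n", sep = "")
  print(x$histogram, n = 20)
  invisible(x)
}

#' Read / write BED intervals
#'
#' Minimal BED3+ support: 0-based half-open intervals with an optional name
#' column, the convention this package uses for ROIs.
#'
#' @param path file path.
#' @param x tibble with chrom, start, end and optionally name.
#' @return tibble (name, chrom, start, end) (reader); `path` (writer).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  names(df)[1:3] <- c("chrom", "start", "end")
  df$name <- if (ncol(df) >= 4L) as.character(df[[4]]) else
    paste0("region", seq_len(nrow(df)))
  dplyr::select(as_tibble(df), "name", "chrom", "start", "end")
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  nm <- if ("name" %in% names(x)) x$name else paste0("region", seq_len(nrow(x)))
  readr::write_tsv(tibble(x$chrom, x$start, x$end, nm), path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a depth track as bedGraph
#' @param track tibble from [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  r <- rle(track$depth)
  ends <- track$pos[cumsum(r$lengths)] + 1L
  starts <- c(track$pos[1], head(ends, -1))
  readr::write_tsv(tibble(track$chrom[1], starts, ends, r$values), path,
                   col_names = FALSE)
  invisible(path)
}
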
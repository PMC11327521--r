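#' Aggregate per-read CpG calls into per-site methylation frequencies
#'
#' @param calls tibble from [read_meth_tags()] (one row per informative
#'   (read, site) pair, binary `call`).
#' @param min_depth sites with fewer informative reads are flagged
#'   low-confidence but retained (default 5).
#' @return tibble (chrom, pos, n_meth, n_total, freq, low_confidence),
#'   sorted by position.
#' @export
aggregate_sites <- function(calls, min_depth = 5L) {
  calls |>
    group_by(.data$chrom, .data$pos) |>
    summarise(n_meth = sum(.data$call), n_total = dplyr::n(),
              .groups = "drop") |>
    mutate(freq = .data$n_meth / .data$n_total,
           low_confidence = .data$n_total < min_depth) |>
    arrange(.data$chrom, .data$pos)
}

#' Segment a methylation profile into hypo/hyper/intermediate regions
#'
#' Sites are labelled hypo (`freq < hypo_threshold`), hyper
#' (`freq > hyper_threshold`) or intermediate; maximal runs of at least
#' `min_run` same-label sites become regions, and shorter runs are merged
#' into the flanking run whose mean frequency is nearer.
#'
#' @param sites tibble from [aggregate_sites()] (single chromosome).
#' @param hypo_threshold,hyper_threshold label thresholds (defaults 0.3/0.7).
#' @param min_run minimum sites per region (default 3).
#' @return tibble (region_id, chrom, start, end, n_sites, mean_freq, label)
#'   with `[start, end)` spanning the first to last CpG of the region.
#' @export
segment_pattern <- function(sites, hypo_threshold = 0.3, hyper_threshold = 0.7,
                            min_run = 3L) {
  stopifnot(hypo_threshold < hyper_threshold)
  if (nrow(sites) == 0L) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  mean_freq = double(), label = character()))
  }
  sites <- arrange(sites, .data$pos)
  lab <- ifelse(sites$freq < hypo_threshold, "hypo",
                ifelse(sites$freq > hyper_threshold, "hyper", "intermediate"))
  ## absorb short runs into the nearer-mean flanking run
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_run)
    if (length(short) == 0L) break
    k <- short[1]
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    run_mean <- mean(sites$freq[starts[k]:ends[k]])
    left_d <- if (k > 1L)
      abs(run_mean - mean(sites$freq[starts[k - 1L]:ends[k - 1L]])) else Inf
    right_d <- if (k < length(r$lengths))
      abs(run_mean - mean(sites$freq[starts[k + 1L]:ends[k + 1L]])) else Inf
    take <- if (left_d <= right_d) r$values[k - 1L] else r$values[k + 1L]
    lab[starts[k]:ends[k]] <- take
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  purrr::map_dfr(seq_along(r$lengths), function(k) {
    idx <- starts[k]:ends[k]
    tibble(region_id = sprintf("region%d", k), chrom = sites$chrom[1],
           start = sites$pos[starts[k]], end = sites$pos[ends[k]] + 1L,
           n_sites = length(idx), mean_freq = mean(sites$freq[idx]),
           label = r$values[k])
  })
}

#' Unweighted mean methylation per fixed region
#'
#' @param sites tibble from [aggregate_sites()].
#' @param regions tibble (region_id, chrom, start, end).
#' @return tibble (region_id, chrom, start, end, n_sites, mean_freq); regions
#'   without sites get `n_sites = 0` and `NA` mean.
#' @export
region_means <- function(sites, regions) {
  if (nrow(regions) == 0L) abort("regions must be non-empty")
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    s <- dplyr::filter(sites, .data$chrom == rg$chrom, .data$pos >= rg$start,
                       .data$pos < rg$end)
    tibble(region_id = rg$region_id, chrom = rg$chrom, start = rg$start,
           end = rg$end, n_sites = nrow(s),
           mean_freq = if (nrow(s)) mean(s$freq) else NA_real_)
  })
}

#' Per-site methylation frequencies from bisulfite-amplicon counts
#'
#' Retained (unconverted) cytosines are read as methylated:
#' `freq = n_retained / (n_retained + n_converted)`. With conversion
#' efficiency `c < 1` the corrected frequency
#' `clamp((raw - (1 - c)) / c, 0, 1)` removes the expected unconverted
#' background. Zero-total records are dropped with a warning.
#'
#' @param bsas tibble with region_id, chrom, pos, n_retained, n_converted.
#' @param conversion bisulfite conversion efficiency in (0, 1].
#' @return tibble (region_id, chrom, pos, n_meth, n_total, freq).
#' @export
bsas_call <- function(bsas, conversion = 1) {
  stopifnot(conversion > 0, conversion <= 1)
  total <- bsas$n_retained + bsas$n_converted
  if (any(total == 0L)) {
    warn(sprintf("dropping %d zero-coverage BSAS records", sum(total == 0L)))
    bsas <- bsas[total > 0L, , drop = FALSE]
    total <- total[total > 0L]
  }
  raw <- bsas$n_retained / total
  freq <- pmin(1, pmax(0, (raw - (1 - conversion)) / conversion))
  tibble(region_id = bsas$region_id, chrom = bsas$chrom, pos = bsas$pos,
         n_meth = bsas$n_retained, n_total = total, freq = freq)
}

#' Concordance between long-read and bisulfite-amplicon methylation
#'
#' Inner-joins the two per-site tables on `(chrom, pos)` (both on the
#' plus-strand CpG C convention), keeps sites with depth at least `min_depth`
#' in both assays, and reports the Pearson correlation and mean absolute
#' difference of the matched frequencies.
#'
#' @param ncats tibble from [aggregate_sites()].
#' @param bsas tibble from [bsas_call()].
#' @param min_depth per-assay depth floor (default 5).
#' @return a `meth_concordance` object: list with `pairs` (matched tibble),
#'   `n`, `r`, `mean_abs_diff` and `reason` (NA unless r is undefined).
#' @export
meth_concordance <- function(ncats, bsas, min_depth = 5L) {
  pairs <- inner_join(
    dplyr::select(dplyr::filter(ncats, .data$n_total >= min_depth),
                  "chrom", "pos", ncats_freq = "freq", ncats_depth = "n_total"),
    dplyr::select(dplyr::filter(bsas, .data$n_total >= min_depth),
                  "chrom", "pos", bsas_freq = "freq", bsas_depth = "n_total"),
    by = c("chrom", "pos")
  )
  n <- nrow(pairs)
  r <- NA_real_; reason <- NA_character_
  if (n < 3L) {
    reason <- "fewer than 3 matched sites"
  } else if (stats::sd(pairs$ncats_freq) == 0 || stats::sd(pairs$bsas_freq) == 0) {
    reason <- "zero variance"
  } else {
    r <- cor(pairs$ncats_freq, pairs$bsas_freq)
  }
  structure(list(pairs = pairs, n = n, r = r,
                 mean_abs_diff = if (n) mean(abs(pairs$ncats_freq -
                                                   pairs$bsas_freq)) else NA_real_,
                 reason = reason),
            class = "meth_concordance")
}

#' @export
print.meth_concordance <- function(x, ...) {
  cat("<meth_concordance> ", x$n, " matched CpG sites; Pearson r = ",
      ifelse(is.na(x$r), paste0("NA (", x$reason, ")"),
             format(x$r, digits = 4)),
      "; mean |diff| = ", format(x$mean_abs_diff, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write per-site methylation as a bedMethyl-style TSV
#' @param sites tibble from [aggregate_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(sites, path) {
  readr::write_tsv(tibble(chrom = sites$chrom, start = sites$pos,
                          end = sites$pos + 1L, freq = sites$freq,
                          n_total = sites$n_total), path)
  invisible(path)
}
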
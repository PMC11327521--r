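#' Variant keys for set operations
#' @param calls call tibble with chrom, pos, ref, alt.
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Intersect named callsets into disjoint combination cells
#'
#' Computes UpSet-style exact disjoint cells over all non-empty caller
#' combinations using `(chrom, pos, ref, alt)` identity, so the cells
#' partition the union. An optional allowlist of variant keys restricts the
#' comparison (the stand-in for an rsID-annotated subset).
#'
#' @param callsets named list (>= 2) of call tibbles or character key vectors.
#' @param allowlist optional character vector of variant keys to keep.
#' @return a `caller_comparison` object: list with `membership` (tibble: key
#'   plus one logical column per caller), `cells` (tibble: combination,
#'   n_callers, n) and `callers`.
#' @export
intersect_callsets <- function(callsets, allowlist = NULL) {
  if (length(callsets) < 2L) abort("need at least two callsets")
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    abort("callsets must be named")
  }
  keys <- lapply(callsets, function(x) {
    unique(if (is.character(x)) x else variant_key(x))
  })
  if (!is.null(allowlist)) keys <- lapply(keys, intersect, y = allowlist)
  union_keys <- sort(unique(unlist(keys)))
  membership <- tibble(key = union_keys)
  for (nm in names(keys)) membership[[nm]] <- union_keys %in% keys[[nm]]
  combo <- apply(as.matrix(membership[names(keys)]), 1L, function(r) {
    paste(names(keys)[r], collapse = "&")
  })
  cells <- tibble(key = union_keys, combination = combo) |>
    dplyr::count(.data$combination, name = "n") |>
    mutate(n_callers = stringr::str_count(.data$combination, "&") + 1L) |>
    arrange(desc(.data$n_callers), .data$combination) |>
    dplyr::relocate("combination", "n_callers", "n")
  structure(list(membership = membership, cells = cells,
                 callers = names(keys)),
            class = "caller_comparison")
}

#' @export
print.caller_comparison <- function(x, ...) {
  cat("<caller_comparison> ", length(x$callers), " callers, ",
      nrow(x$membership), " variants in union\n", sep = "")
  print(x$cells)
  invisible(x)
}

#' Sequencing-depth summaries per caller combination
#'
#' Summarises per-variant depth within each disjoint combination cell
#' (n, median, interquartile range) and reports the point-biserial
#' correlation between depth and the detected-by-all-callers indicator
#' (defined as 0 when either variable has zero variance).
#'
#' @param comparison a `caller_comparison`.
#' @param depths tibble with `key` and `depth` columns (or a named numeric
#'   vector keyed by variant key).
#' @return tibble (combination, n, median_depth, iqr_depth) with attribute
#'   `point_biserial`.
#' @export
depth_effect <- function(comparison, depths) {
  if (!is.data.frame(depths)) {
    depths <- tibble(key = names(depths), depth = as.numeric(depths))
  }
  m <- comparison$membership |>
    left_join(depths, by = "key")
  if (anyNA(m$depth)) abort("every variant needs a depth")
  combo <- apply(as.matrix(m[comparison$callers]), 1L, function(r) {
    paste(comparison$callers[r], collapse = "&")
  })
  all_ind <- as.integer(rowSums(as.matrix(m[comparison$callers])) ==
                          length(comparison$callers))
  pb <- if (stats::sd(m$depth) == 0 || stats::sd(all_ind) == 0) 0 else
    cor(m$depth, all_ind)
  out <- tibble(combination = combo, depth = m$depth) |>
    group_by(.data$combination) |>
    summarise(n = dplyr::n(), median_depth = median(.data$depth),
              iqr_depth = stats::IQR(.data$depth), .groups = "drop")
  attr(out, "point_biserial") <- pb
  out
}

#' Pearson correlation between QUAL and sequencing depth
#'
#' The per-caller depth/confidence association the multi-caller comparison
#' inspects. Undefined when fewer than 3 variants or either variable has
#' zero variance; then `r` is NA with a reason.
#'
#' @param calls call tibble with `qual` and `depth` columns.
#' @return one-row tibble (n, r, reason).
#' @export
qual_depth_correlation <- function(calls) {
  n <- sum(stats::complete.cases(calls$qual, calls$depth))
  if (n < 3L) {
    return(tibble(n = n, r = NA_real_, reason = "fewer than 3 variants"))
  }
  ok <- stats::complete.cases(calls$qual, calls$depth)
  if (stats::sd(calls$qual[ok]) == 0 || stats::sd(calls$depth[ok]) == 0) {
    return(tibble(n = n, r = NA_real_, reason = "zero variance"))
  }
  tibble(n = n, r = cor(calls$qual[ok], calls$depth[ok]),
         reason = NA_character_)
}
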
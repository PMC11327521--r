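#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidiers
#' @name tidiers
#' @title Broom-style tidiers for ncatsr result objects
#' @description `tidy()` returns the per-record table of a result object;
#'   `glance()` returns a one-row summary.
#' @param x a result object.
#' @param ... unused.
NULL

#' @rdname tidiers
#' @export
tidy.fusion_calls <- function(x, ...) {
  dplyr::select(as_tibble(x), -dplyr::any_of("read_ids"))
}

#' @rdname tidiers
#' @export
glance.fusion_calls <- function(x, ...) {
  tibble(n_calls = nrow(x),
         total_support = sum(x$n_supporting_reads),
         max_mad = if (nrow(x)) max(x$mad) else NA_real_,
         n_dropped_observations = attr(x, "n_dropped_observations") %||% 0L)
}

#' @rdname tidiers
#' @export
tidy.caller_comparison <- function(x, ...) x$cells

#' @rdname tidiers
#' @export
glance.caller_comparison <- function(x, ...) {
  tibble(n_callers = length(x$callers), n_union = nrow(x$membership),
         n_all_callers = sum(rowSums(as.matrix(x$membership[x$callers])) ==
                               length(x$callers)))
}

#' @rdname tidiers
#' @export
tidy.meth_concordance <- function(x, ...) x$pairs

#' @rdname tidiers
#' @export
glance.meth_concordance <- function(x, ...) {
  tibble(n = x$n, r = x$r, mean_abs_diff = x$mean_abs_diff,
         reason = x$reason)
}

#' @rdname tidiers
#' @export
tidy.cut_site_profile <- function(x, ...) x$hits

#' @rdname tidiers
#' @export
glance.cut_site_profile <- function(x, ...) {
  tibble(n_hits = nrow(x$hits),
         n_off_signature = x$n_off_signature,
         frac_offset_zero = if (nrow(x$hits)) mean(x$hits$offset == 0L) else NA_real_,
         all_pam_ok = if (nrow(x$hits)) all(x$hits$pam_ok) else NA)
}

#' @rdname tidiers
#' @export
tidy.snv_calls <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.snv_calls <- function(x, ...) {
  tibble(n_calls = nrow(x), n_het = sum(x$genotype == "het"),
         n_hom_alt = sum(x$genotype == "hom_alt"),
         median_depth = if (nrow(x)) median(x$depth) else NA_real_,
         median_qual = if (nrow(x)) median(x$qual) else NA_real_)
}
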
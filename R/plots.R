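#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_abline facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a per-base coverage track
#' @param track tibble from [coverage_track()].
#' @param rois optional ROI tibble to shade.
#' @return a ggplot.
#' @export
plot_coverage <- function(track, rois = NULL) {
  p <- ggplot(track, aes(x = .data$pos, y = .data$depth)) +
    geom_line(linewidth = 0.3) +
    labs(x = paste0("position on ", track$chrom[1]), y = "depth") +
    theme_minimal()
  if (!is.null(rois)) {
    rois <- dplyr::filter(rois, .data$chrom == track$chrom[1])
    p <- p + ggplot2::geom_rect(
      data = rois,
      aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.12, fill = "steelblue")
  }
  p
}

#' @export
autoplot.cut_site_profile <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$offset, y = .data$n)) +
    geom_col(width = 0.8) +
    facet_wrap(~crrna, scales = "free_y") +
    labs(x = "read-end offset from expected cut (bp)", y = "reads",
         title = sprintf("cut-site signature (window ±%d bp)",
                         object$window)) +
    theme_minimal()
}

#' @export
autoplot.fusion_calls <- function(object, ...) {
  df <- tidy(object)
  df$junction <- paste0(df$chromA, ":", df$posA + 1L, " | ",
                        df$chromB, ":", df$posB + 1L)
  ggplot(df, aes(x = .data$junction, y = .data$n_supporting_reads)) +
    geom_col() +
    labs(x = NULL, y = "supporting reads",
         title = "consensus fusion junctions") +
    theme_minimal()
}

#' @export
autoplot.caller_comparison <- function(object, ...) {
  ggplot(object$cells,
         aes(x = stats::reorder(.data$combination, -.data$n), y = .data$n)) +
    geom_col() +
    labs(x = "caller combination (disjoint cells)", y = "variants",
         title = "callset intersections") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.meth_concordance <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$bsas_freq, y = .data$ncats_freq)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.7) +
    labs(x = "bisulfite-amplicon methylation", y = "nCATS methylation",
         title = if (is.na(object$r)) "methylation concordance" else
           sprintf("methylation concordance (Pearson r = %.3f, n = %d)",
                   object$r, object$n)) +
    theme_minimal()
}

#' Plot per-site methylation frequencies with optional pattern regions
#' @param sites tibble from [aggregate_sites()].
#' @param regions optional tibble from [segment_pattern()].
#' @return a ggplot.
#' @export
plot_methylation <- function(sites, regions = NULL) {
  p <- ggplot(sites, aes(x = .data$pos, y = .data$freq)) +
    geom_point(size = 0.8, alpha = 0.8) +
    labs(x = paste0("CpG position on ", sites$chrom[1]),
         y = "methylation frequency") +
    ggplot2::ylim(0, 1) +
    theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      aes(xmin = .data$start, xmax = .data$end, ymin = -Inf, ymax = Inf,
          fill = .data$label),
      inherit.aes = FALSE, alpha = 0.15)
  }
  p
}
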
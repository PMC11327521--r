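#' Find chimeric (split-read) junction observations
#'
#' Walks each read's segments in query order and emits one junction
#' observation per pair of query-adjacent segments that are both long enough,
#' separated by at most `max_query_gap` on the read, and map to different
#' chromosomes (or to loci at least `min_intra_distance` apart). The junction
#' coordinate convention is: `posA` = reference position of the query-5'
#' segment's last aligned base, `posB` = reference position of the query-3'
#' segment's first aligned base, both strand-aware and 0-based.
#'
#' Observations are canonicalised so that `(chromA, posA) <= (chromB, posB)`,
#' complementing the strand pair on a flip, so reads sequenced in either
#' direction across the same junction yield one orientation class.
#'
#' @param read_sets tibble from [group_by_read()].
#' @param min_segment minimum aligned query length per partner segment (bp).
#' @param max_query_gap maximum unaligned read bases between partners (bp).
#' @param overlap_tol maximum query overlap tolerated between partners (bp).
#' @param min_intra_distance minimum reference distance for an
#'   intra-chromosomal junction (bp).
#' @return tibble (read_id, chromA, posA, strandA, chromB, posB, strandB,
#'   orientation, query_gap).
#' @export
find_chimeric_junctions <- function(read_sets, min_segment = 200L,
                                    max_query_gap = 100L, overlap_tol = 20L,
                                    min_intra_distance = 10000L) {
  obs <- list()
  for (i in seq_len(nrow(read_sets))) {
    s <- read_sets$segments[[i]]
    if (nrow(s) < 2L) next
    for (k in seq_len(nrow(s) - 1L)) {
      a <- s[k, ]; b <- s[k + 1L, ]
      if (a$qend - a$qstart < min_segment || b$qend - b$qstart < min_segment) next
      gap <- b$qstart - a$qend
      if (gap > max_query_gap || gap < -overlap_tol) next
      posA <- if (a$strand == "+") a$rend - 1L else a$rstart
      posB <- if (b$strand == "+") b$rstart else b$rend - 1L
      if (a$chrom == b$chrom && abs(posA - posB) <= min_intra_distance) next
      sA <- a$strand; sB <- b$strand
      cA <- a$chrom; cB <- b$chrom
      if (cB < cA || (cB == cA && posB < posA)) {
        ## canonical flip: swap partners, complement strands
        tmp <- list(cA, posA, sA)
        cA <- cB; posA <- posB; sA <- if (sB == "+") "-" else "+"
        cB <- tmp[[1]]; posB <- tmp[[2]]
        sB <- if (tmp[[3]] == "+") "-" else "+"
      }
      obs[[length(obs) + 1L]] <- tibble(
        read_id = read_sets$read_id[i], chromA = cA, posA = posA, strandA = sA,
        chromB = cB, posB = posB, strandB = sB,
        orientation = paste0(sA, sB), query_gap = gap
      )
    }
  }
  if (length(obs) == 0L) {
    return(tibble(read_id = character(), chromA = character(), posA = integer(),
                  strandA = character(), chromB = character(), posB = integer(),
                  strandB = character(), orientation = character(),
                  query_gap = integer()))
  }
  dplyr::bind_rows(obs)
}

## lower-middle median: deterministic consensus for even n
median_low <- function(x) {
  sort(x)[(length(x) + 1L) %/% 2L]
}

#' Cluster junction observations into consensus fusion calls
#'
#' Observations sharing `(chromA, chromB, orientation)` are linked whenever
#' both coordinates agree within `tolerance` (single linkage); each connected
#' component becomes one call with the coordinate-wise median (lower of two
#' middles) as consensus. Components with fewer than `min_support` reads are
#' dropped but tallied, so supports plus dropped observations conserve the
#' input count.
#'
#' @param obs tibble from [find_chimeric_junctions()].
#' @param tolerance per-coordinate linking tolerance in bp.
#' @param min_support minimum supporting reads per call.
#' @return a `fusion_calls` tibble (chromA, posA, chromB, posB, orientation,
#'   n_supporting_reads, read_ids list-column, mad) with attribute
#'   `n_dropped_observations`.
#' @export
cluster_junctions <- function(obs, tolerance = 50L, min_support = 3L) {
  stopifnot(tolerance >= 0, min_support >= 1)
  calls <- list(); n_dropped <- 0L
  groups <- dplyr::group_split(dplyr::group_by(
    obs, .data$chromA, .data$chromB, .data$orientation))
  for (g in groups) {
    n <- nrow(g)
    ## single-linkage connected components under the Chebyshev-like criterion
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        link <- abs(g$posA - g$posA[i]) <= tolerance &
          abs(g$posB - g$posB[i]) <= tolerance
        m <- min(comp[link])
        if (any(comp[link] != m)) {
          comp[comp %in% comp[link]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in unique(comp)) {
      mem <- g[comp == cid, ]
      if (nrow(mem) < min_support) {
        n_dropped <- n_dropped + nrow(mem)
        next
      }
      cA <- median_low(mem$posA); cB <- median_low(mem$posB)
      calls[[length(calls) + 1L]] <- tibble(
        chromA = mem$chromA[1], posA = cA,
        chromB = mem$chromB[1], posB = cB,
        orientation = mem$orientation[1],
        n_supporting_reads = nrow(mem),
        read_ids = list(mem$read_id),
        mad = stats::median(pmax(abs(mem$posA - cA), abs(mem$posB - cB)))
      )
    }
  }
  out <- if (length(calls)) dplyr::bind_rows(calls) else {
    tibble(chromA = character(), posA = integer(), chromB = character(),
           posB = integer(), orientation = character(),
           n_supporting_reads = integer(), read_ids = list(), mad = double())
  }
  out <- arrange(out, .data$chromA, .data$posA, .data$chromB, .data$posB)
  attr(out, "n_dropped_observations") <- n_dropped
  class(out) <- c("fusion_calls", class(out))
  out
}

default_fusion_table <- function() {
  tibble::tribble(
    ~intronA,        ~intronB,       ~label,
    "BCR_intron13",  "ABL1_intron1", "b2a2",
    "BCR_intron14",  "ABL1_intron1", "b3a2"
  )
}

#' Classify fusion calls by annotated intron context
#'
#' Maps the pair (intron containing `posA`, intron containing `posB`) to a
#' transcript label through a configurable table; the default encodes the
#' BCR-ABL1 major-breakpoint nomenclature (BCR intron 13 -> b2a2, intron 14
#' -> b3a2, joined to ABL1 intron 1). Calls with either breakpoint outside an
#' annotated intron are labelled "unclassified".
#'
#' @param calls a `fusion_calls` tibble.
#' @param features feature tibble with role == "intron" rows (e.g.
#'   `genome$features`).
#' @param table mapping tibble (intronA, intronB, label).
#' @return `calls` with added columns intronA, intronB, label.
#' @export
classify_fusion <- function(calls, features, table = default_fusion_table()) {
  introns <- dplyr::filter(features, .data$role == "intron")
  if (nrow(introns) == 0L) abort("annotation contains no introns")
  locate <- function(chrom, pos) {
    hit <- introns$name[introns$chrom == chrom & introns$start <= pos &
                          pos < introns$end]
    if (length(hit)) hit[1] else NA_character_
  }
  calls$intronA <- purrr::map2_chr(calls$chromA, calls$posA, locate)
  calls$intronB <- purrr::map2_chr(calls$chromB, calls$posB, locate)
  lab <- dplyr::left_join(
    tibble(intronA = calls$intronA, intronB = calls$intronB),
    table, by = c("intronA", "intronB"))$label
  calls$label <- ifelse(is.na(lab), "unclassified", lab)
  calls
}

#' Write fusion calls as BEDPE
#'
#' One line per call with 0-based half-open single-base intervals at each
#' breakpoint, the support as score, and the strand pair.
#'
#' @param calls a `fusion_calls` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  df <- tibble(
    chrom1 = calls$chromA, start1 = calls$posA, end1 = calls$posA + 1L,
    chrom2 = calls$chromB, start2 = calls$posB, end2 = calls$posB + 1L,
    name = paste0("fusion", seq_len(nrow(calls))),
    score = calls$n_supporting_reads,
    strand1 = substr(calls$orientation, 1, 1),
    strand2 = substr(calls$orientation, 2, 2)
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read BEDPE fusion calls back into a tibble
#' @param path BEDPE file.
#' @return tibble (chromA, posA, chromB, posB, orientation,
#'   n_supporting_reads).
#' @export
read_bedpe <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0L) {
    return(tibble(chromA = character(), posA = integer(), chromB = character(),
                  posB = integer(), orientation = character(),
                  n_supporting_reads = integer()))
  }
  tibble(chromA = as.character(df[[1]]), posA = as.integer(df[[2]]),
         chromB = as.character(df[[4]]), posB = as.integer(df[[5]]),
         orientation = paste0(df[[9]], df[[10]]),
         n_supporting_reads = as.integer(df[[8]]))
}

#' Write fusion calls as VCF 4.2 breakend (BND) records
#'
#' Emits one mate pair per call with 1-based positions and bracket notation
#' matching the call's strand pair; mates cross-reference through MATEID.
#'
#' @param calls a `fusion_calls` tibble.
#' @param seqlengths named vector of reference lengths for contig headers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bnd_vcf <- function(calls, seqlengths, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ncatsr",
    sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
            as.integer(seqlengths)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend ID\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    sideA <- if (substr(cl$orientation, 1, 1) == "+") "right" else "left"
    sideB <- if (substr(cl$orientation, 2, 2) == "+") "left" else "right"
    posA1 <- cl$posA + 1L; posB1 <- cl$posB + 1L
    mateB <- paste0(cl$chromB, ":", posB1)
    mateA <- paste0(cl$chromA, ":", posA1)
    altA <- switch(paste(sideA, sideB),
                   "right left" = paste0("N[", mateB, "["),
                   "right right" = paste0("N]", mateB, "]"),
                   "left left" = paste0("[", mateB, "[N"),
                   "left right" = paste0("]", mateB, "]N"))
    altB <- switch(paste(sideA, sideB),
                   "right left" = paste0("]", mateA, "]N"),
                   "right right" = paste0("N]", mateA, "]"),
                   "left left" = paste0("[", mateA, "[N"),
                   "left right" = paste0("N[", mateA, "["))
    idA <- sprintf("bnd_%da", i); idB <- sprintf("bnd_%db", i)
    info <- sprintf("SVTYPE=BND;MATEID=%%s;SUPPORT=%d", cl$n_supporting_reads)
    lines <- c(lines,
               sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s", cl$chromA, posA1,
                       idA, altA, sprintf(info, idB)),
               sprintf("%s\t%d\t%s\tN\t%s\t.\tPASS\t%s", cl$chromB, posB1,
                       idB, altB, sprintf(info, idA)))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Report fusion calls to BEDPE, VCF and TSV
#' @param calls a `fusion_calls` tibble (ideally after [classify_fusion()]).
#' @param seqlengths named reference lengths.
#' @param dir output directory.
#' @return named vector of written paths, invisibly.
#' @export
report_fusions <- function(calls, seqlengths, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(bedpe = file.path(dir, "fusions.bedpe"),
             vcf = file.path(dir, "fusions.vcf"),
             tsv = file.path(dir, "fusions.tsv"))
  write_bedpe(calls, paths[["bedpe"]])
  write_bnd_vcf(calls, seqlengths, paths[["vcf"]])
  tsv <- dplyr::select(as_tibble(calls), -dplyr::any_of("read_ids"))
  readr::write_tsv(tsv, paths[["tsv"]])
  invisible(paths)
}
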
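#' Build a CIGAR-aware pileup over a region
#'
#' Walks every aligned segment overlapping the region and tallies per-column
#' base counts (A/C/G/T), spanning deletions, anchored insertions, and summed
#' base qualities. Bases below the quality floor are masked (excluded from
#' counts and depth). Only covered columns are emitted.
#'
#' @param aln alignment tibble from [read_alignments()].
#' @param genome a `toy_genome` (for the reference base per column).
#' @param region one-row data frame or list with chrom/start/end.
#' @param min_base_qual Phred floor below which bases are masked (default 7).
#' @return tibble (chrom, pos, ref, A, C, G, T, del, ins, depth, mean_qual)
#'   where `depth = A + C + G + T + del` and `mean_qual` averages the counted
#'   bases' qualities.
#' @export
build_pileup <- function(aln, genome, region, min_base_qual = 7L) {
  region <- as_region(region)
  if (!region$chrom %in% names(genome$chromosomes)) {
    abort("region chromosome absent from genome")
  }
  segs <- dplyr::filter(aln, .data$chrom == region$chrom,
                        .data$rstart < region$end, .data$rend > region$start)
  pos_l <- list(); base_l <- list(); qual_l <- list()
  del_l <- list(); ins_l <- list()
  for (i in seq_len(nrow(segs))) {
    cigar <- segs$cigar[i]
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
    qcons <- ifelse(ops %in% c("M", "I", "S", "=", "X"), lens, 0L)
    rcons <- ifelse(ops %in% c("M", "D", "N", "=", "X"), lens, 0L)
    qoff <- cumsum(qcons) - qcons
    roff <- segs$rstart[i] + cumsum(rcons) - rcons
    quals <- as.integer(charToRaw(segs$qual[i])) - 33L
    for (k in seq_along(ops)) {
      if (ops[k] %in% c("M", "=", "X")) {
        r0 <- max(roff[k], region$start); r1 <- min(roff[k] + lens[k], region$end)
        if (r1 <= r0) next
        rpos <- seq.int(r0, r1 - 1L)
        qpos <- qoff[k] + (rpos - roff[k])
        pos_l[[length(pos_l) + 1L]] <- rpos
        base_l[[length(base_l) + 1L]] <-
          strsplit(substr(segs$seq[i], qpos[1] + 1L,
                          qpos[length(qpos)] + 1L), "", fixed = TRUE)[[1]]
        qual_l[[length(qual_l) + 1L]] <- quals[qpos + 1L]
      } else if (ops[k] == "D") {
        r0 <- max(roff[k], region$start); r1 <- min(roff[k] + lens[k], region$end)
        if (r1 > r0) del_l[[length(del_l) + 1L]] <- seq.int(r0, r1 - 1L)
      } else if (ops[k] == "I") {
        anchor <- roff[k] - 1L
        if (anchor >= region$start && anchor < region$end) {
          ins_l[[length(ins_l) + 1L]] <- anchor
        }
      }
    }
  }
  pos <- unlist(pos_l); base <- unlist(base_l); qual <- unlist(qual_l)
  keep <- qual >= min_base_qual & base %in% DNA_BASES
  pos <- pos[keep]; base <- base[keep]; qual <- qual[keep]
  dels <- unlist(del_l); inss <- unlist(ins_l)
  if (length(pos) == 0L && length(dels) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  del = integer(), ins = integer(), depth = integer(),
                  mean_qual = double()))
  }
  counts <- tibble(pos = pos, base = base, qual = qual) |>
    group_by(.data$pos, .data$base) |>
    summarise(n = dplyr::n(), qsum = sum(.data$qual), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "base", values_from = c("n", "qsum"),
                       values_fill = 0L)
  for (b in DNA_BASES) {
    if (!paste0("n_", b) %in% names(counts)) counts[[paste0("n_", b)]] <- 0L
    if (!paste0("qsum_", b) %in% names(counts)) counts[[paste0("qsum_", b)]] <- 0L
  }
  all_pos <- sort(unique(c(counts$pos, dels)))
  out <- tibble(pos = all_pos) |>
    left_join(counts, by = "pos") |>
    mutate(across(dplyr::starts_with(c("n_", "qsum_")),
                  ~ tidyr::replace_na(.x, 0L)))
  dtab <- table(factor(dels, levels = all_pos))
  itab <- table(factor(inss, levels = all_pos))
  refchars <- strsplit(subseq0(genome$chromosomes[[region$chrom]],
                               region$start, region$end), "", fixed = TRUE)[[1]]
  tibble(
    chrom = region$chrom, pos = out$pos,
    ref = refchars[out$pos - region$start + 1L],
    A = out$n_A, C = out$n_C, G = out$n_G, T = out$n_T,
    del = as.integer(dtab), ins = as.integer(itab),
    depth = out$n_A + out$n_C + out$n_G + out$n_T + as.integer(dtab),
    mean_qual = ifelse(out$n_A + out$n_C + out$n_G + out$n_T > 0,
                       (out$qsum_A + out$qsum_C + out$qsum_G + out$qsum_T) /
                         (out$n_A + out$n_C + out$n_G + out$n_T), NA_real_)
  )
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Call SNVs from a pileup with an explicit genotype-likelihood model
#'
#' Per column, computes binomial likelihoods of the alternate-base count under
#' three genotypes - homozygous reference (alt fraction `e`), heterozygous
#' (0.5) and homozygous alternate (`1 - e`) - where `e` is the column's mean
#' base-error probability derived from base qualities and floored at
#' `error_floor`. With a flat prior, `QUAL = -10 log10 P(RR | data)`. Columns
#' passing all thresholds emit the maximum a-posteriori non-reference
#' genotype; the alternate is the highest-count non-reference base, and
#' columns where a second non-reference base also passes `min_alt_count` are
#' flagged multi-allelic.
#'
#' @param pileup tibble from [build_pileup()].
#' @param min_depth,min_alt_count,min_alt_fraction,min_qual call thresholds
#'   (defaults 10, 4, 0.2, 20).
#' @param error_floor lower bound on the per-base error probability.
#' @return a `snv_calls` tibble (chrom, pos, ref, alt, genotype, depth,
#'   alt_count, af, qual, p_rr, p_ra, p_aa, multiallelic).
#' @export
call_snvs <- function(pileup, min_depth = 10L, min_alt_count = 4L,
                      min_alt_fraction = 0.2, min_qual = 20,
                      error_floor = 0.001) {
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(), depth = integer(),
                  alt_count = integer(), af = double(), qual = double(),
                  p_rr = double(), p_ra = double(), p_aa = double(),
                  multiallelic = logical())
  if (nrow(pileup) == 0L) return(structure(empty, class = c("snv_calls", class(empty))))
  calls <- list()
  for (i in seq_len(nrow(pileup))) {
    col <- pileup[i, ]
    if (!col$ref %in% DNA_BASES) next
    cnt <- c(A = col$A, C = col$C, G = col$G, T = col$T)
    alts <- sort(cnt[setdiff(DNA_BASES, col$ref)], decreasing = TRUE)
    alt <- names(alts)[1]; k <- alts[[1]]
    if (col$depth < min_depth || k < min_alt_count) next
    af <- k / col$depth
    if (af < min_alt_fraction) next
    e <- max(10^(-col$mean_qual / 10), error_floor)
    ll <- c(rr = dbinom(k, col$depth, e, log = TRUE),
            ra = dbinom(k, col$depth, 0.5, log = TRUE),
            aa = dbinom(k, col$depth, 1 - e, log = TRUE))
    lz <- logsumexp(ll)
    post <- exp(ll - lz)
    qual <- min(-10 * (ll[["rr"]] - lz) / log(10), 1e5)
    if (qual < min_qual) next
    genotype <- if (post[["aa"]] > post[["ra"]]) "hom_alt" else "het"
    calls[[length(calls) + 1L]] <- tibble(
      chrom = col$chrom, pos = col$pos, ref = col$ref, alt = alt,
      genotype = genotype, depth = col$depth, alt_count = as.integer(k),
      af = af, qual = qual, p_rr = post[["rr"]], p_ra = post[["ra"]],
      p_aa = post[["aa"]],
      multiallelic = length(alts) > 1L && alts[[2]] >= min_alt_count
    )
  }
  out <- if (length(calls)) dplyr::bind_rows(calls) else empty
  structure(out, class = c("snv_calls", class(out)))
}

#' Write SNV calls as VCF 4.2
#'
#' 1-based POS, QUAL column populated, INFO carrying depth and allele
#' fraction, and a single-sample GT column. Unsorted input is sorted on
#' write with a message.
#'
#' @param calls an `snv_calls` tibble.
#' @param seqlengths named reference lengths for contig headers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, seqlengths, path) {
  srt <- arrange(as_tibble(calls), .data$chrom, .data$pos)
  if (!identical(srt$pos, calls$pos) || !identical(srt$chrom, calls$chrom)) {
    message("unsorted SNV calls; sorting on write")
    calls <- srt
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ncatsr",
    sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
            as.integer(seqlengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d;AF=%.6g\tGT\t%s",
                  calls$chrom, calls$pos + 1L, calls$ref, calls$alt,
                  calls$qual, calls$depth, calls$af,
                  ifelse(calls$genotype == "hom_alt", "1/1", "0/1"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF of SNVs into a call tibble
#'
#' Accepts this package's VCFs and external callers' single-sample VCFs;
#' indel records are dropped. Positions are converted to the package's
#' 0-based convention.
#'
#' @param path VCF file.
#' @return tibble (chrom, pos, ref, alt, genotype, depth, af, qual).
#' @export
read_snv_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), genotype = character(), depth = integer(),
                  af = double(), qual = double()))
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  gt <- tryCatch(vcfR::extract.gt(v)[, 1], error = function(e) rep(NA, nrow(fix)))
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT,
    genotype = dplyr::case_when(gt %in% c("1/1", "1|1") ~ "hom_alt",
                                is.na(gt) ~ NA_character_,
                                TRUE ~ "het"),
    depth = dp, af = af,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  dplyr::filter(out, nchar(.data$ref) == 1L, nchar(.data$alt) == 1L)
}
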
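#' Read SAM/BAM alignments into a per-segment tibble
#'
#' Parses every mapped record (primary and supplementary) into one row of a
#' segment table. Soft/hard clips are converted into query-interval offsets
#' and reverse-strand query intervals are re-expressed in the original read
#' orientation, so `[qstart, qend)` always indexes the read as sequenced.
#' Unmapped records are skipped and counted in the `n_unmapped` attribute.
#' All coordinates are 0-based half-open.
#'
#' @param path a SAM or BAM file. SAM input is converted with
#'   [Rsamtools::asBam()] first.
#' @return tibble with one row per mapped record: read_id, flag, chrom,
#'   rstart, rend, strand, mapq, cigar, is_primary, qstart, qend,
#'   read_length, seq, qual, mm, ml (list), crrna, allele, hap.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("MM", "ML", "XC", "XA", "XH")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  mapped <- !bitwAnd(flag, 4L)
  n_unmapped <- sum(!mapped)

  cigar <- res$cigar[mapped]
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  lead_clip <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    k <- which(!o %in% c("S", "H"))[1]
    if (is.na(k) || k == 1L) 0L else sum(l[seq_len(k - 1L)][o[seq_len(k - 1L)] %in% c("S", "H")])
  }, integer(1))
  aq <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar, after.soft.clipping = TRUE)
  total <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar, before.hard.clipping = TRUE)
  rwidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  rev <- bitwAnd(res$flag[mapped], 16L) > 0L

  ml <- res$tag$ML[mapped]
  if (is.null(ml)) ml <- rep(list(integer(0)), sum(mapped))
  ml <- lapply(ml, function(v) if (is.null(v)) integer(0) else as.integer(v))
  tagchr <- function(tag) {
    v <- res$tag[[tag]]
    if (is.null(v)) rep(NA_character_, sum(mapped)) else as.character(v[mapped])
  }
  xh <- res$tag$XH
  out <- tibble(
    read_id = res$qname[mapped],
    flag = res$flag[mapped],
    chrom = as.character(res$rname[mapped]),
    rstart = res$pos[mapped] - 1L,
    rend = res$pos[mapped] - 1L + rwidth,
    strand = ifelse(rev, "-", "+"),
    mapq = res$mapq[mapped],
    cigar = cigar,
    is_primary = bitwAnd(res$flag[mapped], 2304L) == 0L,
    qstart = ifelse(rev, total - lead_clip - aq, lead_clip),
    qend = ifelse(rev, total - lead_clip, lead_clip + aq),
    read_length = total,
    seq = as.character(res$seq[mapped]),
    qual = as.character(res$qual[mapped]),
    mm = tagchr("MM"),
    ml = ml,
    crrna = gsub("_", " ", tagchr("XC")),
    allele = tagchr("XA"),
    hap = if (is.null(xh)) rep(NA_integer_, sum(mapped)) else as.integer(xh[mapped])
  )
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write a segment-alignment tibble as SAM
#'
#' Inverse of [read_alignments()] on modeled fields: one SAM line per row,
#' 1-based POS, optional MM/ML and XC/XA/XH tags.
#'
#' @param aln alignment tibble (columns read_id, flag, chrom, rstart, mapq,
#'   cigar, seq, qual; optional mm, ml, crrna, allele, hap).
#' @param seqlengths named vector of reference lengths for `@SQ` lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seqlengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  has <- function(col) col %in% names(aln)
  tags <- vapply(seq_len(nrow(aln)), function(i) {
    t <- character(0)
    if (has("crrna") && !is.na(aln$crrna[i])) {
      t <- c(t, sprintf("XC:Z:%s", gsub("[ \t]", "_", aln$crrna[i])))
    }
    if (has("allele") && !is.na(aln$allele[i])) {
      t <- c(t, sprintf("XA:Z:%s", aln$allele[i]))
    }
    if (has("hap") && !is.na(aln$hap[i])) t <- c(t, sprintf("XH:i:%d", aln$hap[i]))
    if (has("mm") && !is.na(aln$mm[i])) {
      t <- c(t, paste0("MM:Z:", aln$mm[i]),
             paste0("ML:B:C,", paste(aln$ml[[i]], collapse = ",")))
    }
    paste(t, collapse = "\t")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  aln$read_id, aln$flag, aln$chrom, aln$rstart + 1L, aln$mapq,
                  aln$cigar, aln$seq, aln$qual)
  body <- ifelse(nzchar(tags), paste(body, tags, sep = "\t"), body)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Group alignment segments by read
#'
#' @param aln tibble from [read_alignments()].
#' @return nested tibble (read_id, n_segments, read_length, segments), with
#'   each read's segments ordered by query start (ties broken by chrom then
#'   reference start).
#' @export
group_by_read <- function(aln) {
  if (nrow(aln) == 0L) {
    return(tibble(read_id = character(), n_segments = integer(),
                  read_length = integer(), segments = list()))
  }
  aln |>
    arrange(.data$read_id, .data$qstart, .data$chrom, .data$rstart) |>
    tidyr::nest(segments = -"read_id") |>
    mutate(n_segments = vapply(.data$segments, nrow, integer(1)),
           read_length = vapply(.data$segments,
                                function(s) max(s$read_length), integer(1))) |>
    dplyr::relocate("read_id", "n_segments", "read_length")
}

## map SEQ-space 0-based query indices to reference positions through a CIGAR;
## indices falling in clips, insertions or deletions map to NA
query_to_ref <- function(cigar, rstart, qidx) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qcons <- ifelse(ops %in% c("M", "I", "S", "=", "X"), lens, 0L)
  rcons <- ifelse(ops %in% c("M", "D", "N", "=", "X"), lens, 0L)
  qend <- cumsum(qcons); qstart <- qend - qcons
  rend <- rstart + cumsum(rcons); rops_start <- rend - rcons
  op_i <- findInterval(qidx, qstart, left.open = FALSE)
  ## findInterval with duplicated starts (non-consuming ops): step to the op
  ## actually containing the index
  out <- rep(NA_integer_, length(qidx))
  for (j in seq_along(qidx)) {
    i <- op_i[j]
    while (i >= 1L && qcons[i] == 0L) i <- i - 1L
    if (i < 1L || qidx[j] >= qend[i]) next
    if (ops[i] %in% c("M", "=", "X")) {
      out[j] <- rops_start[i] + (qidx[j] - qstart[i])
    }
  }
  out
}

#' Decode per-read CpG methylation calls from MM/ML tags
#'
#' Follows the SAM base-modification convention for 5mC at CpG (`C+m`): MM
#' deltas count skipped cytosines in the original read orientation; ML holds
#' the 0-255 modification probability. Calls are binarised at `threshold`
#' (ties count as methylated) and projected through the CIGAR onto reference
#' coordinates. Evidence on reverse-strand records lands on the G of the CpG
#' and is projected to the plus-strand C coordinate (symmetric-CpG
#' assumption). Sites whose tagged base is inconsistent with the record
#' (non-C in read space, or falling in a clip/insertion/deletion) are dropped
#' and tallied in the `n_skipped` attribute.
#'
#' @param aln tibble from [read_alignments()] with `mm`/`ml` columns.
#' @param threshold call threshold on the probability scale (default 0.5).
#' @return tibble (read_id, chrom, pos, prob, call) with `pos` the plus-strand
#'   C of the CpG; one row per informative (read, site) pair.
#' @export
read_meth_tags <- function(aln, threshold = 0.5) {
  out <- list()
  n_skipped <- 0L
  tagged <- which(!is.na(aln$mm) & lengths(aln$ml) > 0L)
  for (i in tagged) {
    mm <- aln$mm[i]
    if (!startsWith(mm, "C+m")) next
    deltas <- suppressWarnings(as.integer(strsplit(
      sub("^C\\+m\\??,", "", sub(";$", "", mm)), ",", fixed = TRUE)[[1]]))
    if (anyNA(deltas)) { n_skipped <- n_skipped + length(deltas); next }
    probs <- (aln$ml[[i]] + 0.5) / 256
    rev <- aln$strand[i] == "-"
    oseq <- if (rev) revcomp(aln$seq[i]) else aln$seq[i]
    cpos <- which(strsplit(oseq, "", fixed = TRUE)[[1]] == "C") - 1L
    ranks <- cumsum(deltas + 1L)
    if (length(ranks) != length(probs) || any(ranks > length(cpos))) {
      n_skipped <- n_skipped + length(ranks)
      next
    }
    o_idx <- cpos[ranks]
    n <- nchar(aln$seq[i])
    seq_idx <- if (rev) n - 1L - o_idx else o_idx
    refpos <- query_to_ref(aln$cigar[i], aln$rstart[i], seq_idx)
    ok <- !is.na(refpos)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    pos <- refpos[ok]
    if (rev) pos <- pos - 1L  # CpG G -> plus-strand C
    out[[length(out) + 1L]] <- tibble(
      read_id = aln$read_id[i], chrom = aln$chrom[i], pos = pos,
      prob = probs[ok], call = as.integer(probs[ok] >= threshold)
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else {
    tibble(read_id = character(), chrom = character(), pos = integer(),
           prob = double(), call = integer())
  }
  attr(res, "n_skipped") <- n_skipped
  res
}
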
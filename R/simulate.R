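## Read simulation happens in "molecule space": the fragment in reference
## orientation. A read sequenced leftwards from a cut (crRNA direction -1) is
## the reverse complement of its molecule; its SAM records carry the
## molecule-orientation SEQ with FLAG 16, as an aligner would emit.

ML_METH <- 230L   # ~0.90 on the 0-255 modification-probability scale
ML_UNMETH <- 25L  # ~0.10

other_base <- function(bases) {
  idx <- match(bases, DNA_BASES)
  shift <- sample.int(3L, length(bases), replace = TRUE)
  DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
}

## allele coordinate offsets of each segment, and the cut sites present
allele_cuts <- function(allele, crrnas) {
  segs <- allele$segments
  offs <- cumsum(c(0L, segs$end - segs$start))
  out <- list()
  for (i in seq_len(nrow(crrnas))) {
    g <- crrnas[i, ]
    k <- which(segs$chrom == g$chrom & segs$start < g$expected_cut &
                 g$expected_cut < segs$end)
    if (length(k) == 1L) {
      out[[length(out) + 1L]] <- tibble(
        crrna = g$name, direction = g$direction,
        cut_allele = offs[k] + (g$expected_cut - segs$start[k])
      )
    }
  }
  dplyr::bind_rows(out)
}

## map an allele interval [astart, aend) to its reference parts, in order
allele_parts <- function(allele, astart, aend) {
  segs <- allele$segments
  offs <- cumsum(c(0L, segs$end - segs$start))
  parts <- list()
  for (k in seq_len(nrow(segs))) {
    lo <- max(astart, offs[k]); hi <- min(aend, offs[k + 1L])
    if (hi > lo) {
      parts[[length(parts) + 1L]] <- tibble(
        chrom = segs$chrom[k],
        rstart = segs$start[k] + (lo - offs[k]),
        rend = segs$start[k] + (hi - offs[k])
      )
    }
  }
  dplyr::bind_rows(parts)
}

#' Simulate Cas9-targeted nanopore reads with truth alignments
#'
#' Generates reads whose ends coincide (up to `jitter`) with the blunt Cas9
#' cut of each crRNA present on each allele, extending towards the enriched
#' fragment side. Planted SNVs are applied per read by a haplotype coin with
#' probability `vaf`; per-read CpG methylation states are drawn
#' Bernoulli(profile) and encoded as SAM MM/ML base-modification tags
#' (5mC at CpG); substitution and indel errors are then injected and the truth
#' CIGARs reflect them. Reads from a fusion allele that span the junction get
#' one primary plus one supplementary truth record on different chromosomes.
#'
#' @param genome a `toy_genome`.
#' @param alleles an `allele` or list of alleles (see [chromosome_allele()],
#'   [make_fusion_allele()]).
#' @param truth a `truth_set` (SNVs + methylation profile); NULL for none.
#' @param n_reads reads per cut site, scalar or named by allele.
#' @param sub_rate,ins_rate,del_rate per-base error rates in `[0, 1)`.
#' @param jitter maximum absolute cut-end offset (discrete uniform on
#'   `-jitter:jitter`).
#' @param read_length `c(mean, sd)` of a truncated normal length model.
#' @param length_range `c(min, max)` truncation bounds.
#' @param meth_call_error probability a per-read CpG call is flipped relative
#'   to its drawn state (emulates caller error).
#' @param qual constant per-base Phred quality.
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a `sim_reads` object: list with `reads` (tibble: read_id, sequence,
#'   qual, crrna, allele, direction, hap), `alignments` (truth SAM records as
#'   a tibble), `meth_truth` (tibble: read_id, chrom, pos, state, called)
#'   and `params`.
#' @export
simulate_reads <- function(genome, alleles, truth = NULL, n_reads = 500,
                           sub_rate = 0.01, ins_rate = 0.0025,
                           del_rate = 0.0025, jitter = 2L,
                           read_length = c(8000, 1000),
                           length_range = c(6000, 12000),
                           meth_call_error = 0.01, qual = 20L, seed = 1) {
  if (inherits(alleles, "allele")) alleles <- list(alleles)
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  stopifnot(all(c(sub_rate, ins_rate, del_rate) >= 0),
            all(c(sub_rate, ins_rate, del_rate) < 1), jitter >= 0)
  check_seed(seed)
  snvs <- if (!is.null(truth)) truth$snvs else NULL
  profile <- if (!is.null(truth)) truth$profile else NULL

  reads_acc <- list(); aln_acc <- list(); meth_acc <- list()
  for (al in alleles) {
    cuts <- allele_cuts(al, genome$crrnas)
    if (nrow(cuts) == 0L) {
      warn(paste0("allele ", al$name, " carries no crRNA cut site; no reads"))
      next
    }
    n_al <- if (length(n_reads) > 1L) n_reads[[al$name]] else n_reads
    for (ci in seq_len(nrow(cuts))) {
      for (ri in seq_len(n_al)) {
        read_id <- sprintf("%s_c%d_r%04d", al$name, ci, ri)
        r <- simulate_one_read(al, cuts[ci, ], read_id, snvs, profile,
                               sub_rate, ins_rate, del_rate, jitter,
                               read_length, length_range, meth_call_error,
                               qual)
        if (is.null(r)) next
        reads_acc[[length(reads_acc) + 1L]] <- r$read
        aln_acc[[length(aln_acc) + 1L]] <- r$aln
        if (!is.null(r$meth)) meth_acc[[length(meth_acc) + 1L]] <- r$meth
      }
    }
  }
  structure(list(
    reads = dplyr::bind_rows(reads_acc),
    alignments = dplyr::bind_rows(aln_acc),
    meth_truth = dplyr::bind_rows(meth_acc),
    params = list(n_reads = n_reads, sub_rate = sub_rate, ins_rate = ins_rate,
                  del_rate = del_rate, jitter = jitter,
                  read_length = read_length, length_range = length_range,
                  meth_call_error = meth_call_error, qual = qual, seed = seed)
  ), class = "sim_reads")
}

simulate_one_read <- function(al, cut, read_id, snvs, profile,
                              sub_rate, ins_rate, del_rate, jitter,
                              read_length, length_range, meth_call_error,
                              qual) {
  alen <- nchar(al$sequence)
  jit <- if (jitter > 0) sample(seq(-jitter, jitter), 1L) else 0L
  L <- round(rnorm(1L, read_length[1], read_length[2]))
  L <- max(length_range[1], min(length_range[2], L))
  if (cut$direction > 0) {
    astart <- max(0L, cut$cut_allele + jit); aend <- min(alen, astart + L)
  } else {
    aend <- min(alen, cut$cut_allele + jit); astart <- max(0L, aend - L)
  }
  if (aend - astart < 50L) return(NULL)

  parts <- allele_parts(al, astart, aend)
  mol <- strsplit(subseq0(al$sequence, astart, aend), "", fixed = TRUE)[[1]]
  n <- length(mol)
  part_id <- rep.int(seq_len(nrow(parts)), parts$rend - parts$rstart)
  refpos <- unlist(lapply(seq_len(nrow(parts)), function(k) {
    seq.int(parts$rstart[k], parts$rend[k] - 1L)
  }), use.names = FALSE)
  refchrom <- parts$chrom[part_id]

  ## haplotype coin: alt-bearing molecule with probability vaf (phased SNVs)
  hap <- 0L
  if (!is.null(snvs) && nrow(snvs)) {
    hap <- as.integer(runif(1L) < snvs$vaf[1])
    if (hap == 1L) {
      hit <- match(paste(snvs$chrom, snvs$pos), paste(refchrom, refpos))
      ok <- !is.na(hit)
      mol[hit[ok]] <- snvs$alt[ok]
    }
  }

  ## per-read CpG states, drawn before error injection
  meth <- NULL
  site_idx <- integer(0)
  if (!is.null(profile) && nrow(profile)) {
    hit <- match(paste(profile$chrom, profile$pos), paste(refchrom, refpos))
    need <- if (cut$direction > 0) profile$pos else profile$pos + 1L
    hit2 <- match(paste(profile$chrom, need), paste(refchrom, refpos))
    ok <- !is.na(hit) & !is.na(hit2)
    if (any(ok)) {
      p <- profile$p[ok]
      state <- as.integer(runif(sum(ok)) < p)
      called <- ifelse(runif(sum(ok)) < meth_call_error, 1L - state, state)
      meth <- tibble(read_id = read_id, chrom = profile$chrom[ok],
                     pos = profile$pos[ok], state = state, called = called)
      site_idx <- hit2[ok]  # molecule index of the tagged base (C or the CpG G)
    }
  }

  ## error injection
  del <- runif(n) < del_rate
  sub <- runif(n) < sub_rate & !del
  if (any(sub)) mol[sub] <- other_base(mol[sub])
  ins <- runif(n) < ins_rate

  ## item list in molecule order: M/D per reference base, I after flagged bases
  n_ins <- sum(ins)
  key <- c(seq_len(n), which(ins) + 0.5)
  type <- c(ifelse(del, "D", "M"), rep("I", n_ins))
  qbase <- c(ifelse(del, NA_character_, mol),
             if (n_ins) sample(DNA_BASES, n_ins, replace = TRUE) else character(0))
  irefpos <- c(refpos, rep(NA_integer_, n_ins))
  ipart <- c(part_id, part_id[ins])
  ord <- order(key)
  type <- type[ord]; qbase <- qbase[ord]; irefpos <- irefpos[ord]; ipart <- ipart[ord]
  ## molecule index of surviving tagged bases (M items only, base unchanged)
  mol_item_of <- match(seq_len(n), floor(key[ord]))  # item index of ref base i

  consumes_q <- type != "D"
  qidx <- cumsum(consumes_q) - 1L  # 0-based query position per item (valid when consumes_q)
  qseq <- paste(qbase[consumes_q], collapse = "")
  total_q <- sum(consumes_q)

  ## per-part SAM records
  recs <- list()
  for (k in seq_len(nrow(parts))) {
    sel <- which(ipart == k)
    m <- sel[type[sel] == "M"]
    if (length(m) == 0L) next
    block <- seq.int(min(m), max(m))
    block <- block[ipart[block] == k]
    ops <- rle(type[block])
    cigar_core <- paste0(ops$lengths, ops$values, collapse = "")
    q0 <- qidx[min(m)]; q1 <- qidx[max(m)] + 1L
    lead <- q0; trail <- total_q - q1
    cigar <- paste0(if (lead) paste0(lead, "S") else "", cigar_core,
                    if (trail) paste0(trail, "S") else "")
    recs[[length(recs) + 1L]] <- tibble(
      read_id = read_id, chrom = parts$chrom[k],
      rstart = irefpos[min(m)], rend = irefpos[max(m)] + 1L,
      cigar = cigar, qstart_mol = q0, qend_mol = q1
    )
  }
  if (length(recs) == 0L) return(NULL)
  recs <- dplyr::bind_rows(recs)
  recs$is_primary <- seq_len(nrow(recs)) == which.max(recs$qend_mol - recs$qstart_mol)
  recs$flag <- ifelse(recs$is_primary, 0L, 2048L) +
    ifelse(cut$direction > 0, 0L, 16L)
  recs$strand <- if (cut$direction > 0) "+" else "-"
  recs$mapq <- 60L
  recs$seq <- qseq
  recs$qual <- phred_string(qual, total_q)
  recs$crrna <- cut$crrna
  recs$allele <- al$name
  recs$hap <- hap

  ## MM/ML tags: original-read-orientation positions of surviving tagged C's
  mm <- NA_character_; ml <- list(integer(0))
  if (length(site_idx)) {
    item <- mol_item_of[site_idx]
    want <- if (cut$direction > 0) "C" else "G"
    live <- !is.na(item) & type[item] == "M" & qbase[item] == want
    if (any(live)) {
      q_mol <- qidx[item[live]]
      o_idx <- if (cut$direction > 0) q_mol else total_q - 1L - q_mol
      oseq <- if (cut$direction > 0) qseq else revcomp(qseq)
      cpos <- which(strsplit(oseq, "", fixed = TRUE)[[1]] == "C") - 1L
      r <- match(o_idx, cpos)
      keep <- !is.na(r)            # defensive; all should be C in read space
      ordc <- order(r[keep])
      ranks <- r[keep][ordc]
      deltas <- diff(c(0L, ranks)) - 1L
      states <- meth$called[live][keep][ordc]
      mm <- paste0("C+m?,", paste(deltas, collapse = ","), ";")
      ml <- list(ifelse(states == 1L, ML_METH, ML_UNMETH))
    }
  }
  recs$mm <- mm
  recs$ml <- rep(ml, nrow(recs))

  read_seq <- if (cut$direction > 0) qseq else revcomp(qseq)
  list(
    read = tibble(read_id = read_id, sequence = read_seq,
                  qual = phred_string(qual, total_q), crrna = cut$crrna,
                  allele = al$name, direction = cut$direction, hap = hap,
                  n_segments = nrow(recs)),
    aln = recs,
    meth = meth
  )
}

#' Write simulated reads as FASTQ
#' @param sim a `sim_reads` object (or its `reads` tibble).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "sim_reads")) sim$reads else sim
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Write the simulator's truth alignments as SAM
#'
#' Emits one record per truth segment with CIGARs reflecting injected errors,
#' MM/ML 5mC tags, and custom tags `XC` (originating crRNA), `XA` (allele) and
#' `XH` (haplotype). Coordinates are converted to SAM's 1-based convention.
#'
#' @param sim a `sim_reads` object.
#' @param genome the `toy_genome` (for `@SQ` header lines).
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(sim, genome, path) {
  aln <- sim$alignments
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                      nchar(genome$chromosomes)))
  tags <- vapply(seq_len(nrow(aln)), function(i) {
    t <- c(sprintf("XC:Z:%s", gsub("[ \t]", "_", aln$crrna[i])),
           sprintf("XA:Z:%s", aln$allele[i]),
           sprintf("XH:i:%d", aln$hap[i]))
    if (!is.na(aln$mm[i])) {
      t <- c(t, paste0("MM:Z:", aln$mm[i]),
             paste0("ML:B:C,", paste(aln$ml[[i]], collapse = ",")))
    }
    paste(t, collapse = "\t")
  }, character(1))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
                  aln$read_id, aln$flag, aln$chrom, aln$rstart + 1L, aln$mapq,
                  aln$cigar, aln$seq, aln$qual, tags)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate bisulfite-amplicon counts from a methylation profile
#'
#' For every CpG site of `profile` falling in one of `regions`, draws
#' `n_retained ~ Binomial(depth, p + (1 - conversion) * (1 - p))`: retained
#' (unconverted) cytosines are read as methylated, and incomplete bisulfite
#' conversion inflates the retained fraction at unmethylated sites.
#'
#' @param profile tibble from [methylation_profile()].
#' @param regions tibble (region_id, chrom, start, end), e.g.
#'   [default_bsas_regions()].
#' @param depth reads per site (>= 1).
#' @param conversion bisulfite conversion efficiency in (0, 1].
#' @param seed integer seed.
#' @return tibble (region_id, chrom, pos, n_retained, n_converted, freq).
#' @export
simulate_bsas <- function(profile, regions, depth = 100L, conversion = 1,
                          seed = 1) {
  stopifnot(depth >= 1, conversion > 0, conversion <= 1)
  check_seed(seed)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    sites <- dplyr::filter(profile, .data$chrom == rg$chrom,
                           .data$pos >= rg$start, .data$pos < rg$end)
    if (nrow(sites) == 0L) {
      warn(paste0("BSAS region ", rg$region_id, " contains no CpG sites"))
      next
    }
    p_obs <- sites$p + (1 - conversion) * (1 - sites$p)
    n_ret <- rbinom(nrow(sites), depth, p_obs)
    out[[length(out) + 1L]] <- tibble(
      region_id = rg$region_id, chrom = sites$chrom, pos = sites$pos,
      n_retained = n_ret, n_converted = depth - n_ret,
      freq = n_ret / depth
    )
  }
  dplyr::bind_rows(out)
}

#' Write / read BSAS counts as TSV
#' @param bsas tibble from [simulate_bsas()] (or matching columns).
#' @param path file path.
#' @return `path` invisibly (writer); tibble (reader).
#' @export
write_bsas_tsv <- function(bsas, path) {
  readr::write_tsv(bsas, path)
  invisible(path)
}

#' @rdname write_bsas_tsv
#' @export
read_bsas_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
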
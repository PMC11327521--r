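pileup_row <- function(ref = "A", alt = "C", depth = 100L, alt_count = 50L,
                       mean_qual = 20) {
  counts <- stats::setNames(rep(0L, 4), c("A", "C", "G", "T"))
  counts[ref] <- depth - alt_count
  counts[alt] <- alt_count
  tibble::tibble(chrom = "toy", pos = 500L, ref = ref, A = counts[["A"]],
                 C = counts[["C"]], G = counts[["G"]], T = counts[["T"]],
                 del = 0L, ins = 0L, depth = depth, mean_qual = mean_qual)
}

test_that("pileup columns count bases, deletions and anchored insertions", {
  seqs <- c(toy = 2000L)
  mk <- function(id, cigar, seq) {
    paste0(id, "\t0\ttoy\t101\t60\t", cigar, "\t*\t0\t0\t", seq, "\t",
           strrep("5", nchar(seq)))
  }
  ref20 <- substr(tg$chromosomes[["toy22"]], 101, 120)
  g <- structure(list(chromosomes = list(toy = tg$chromosomes[["toy22"]])),
                 class = "toy_genome")
  lines <- c(vapply(1:10, function(i) mk(paste0("r", i), "20M", ref20),
                    character(1)),
             mk("del", "5M3D12M", paste0(substr(ref20, 1, 5),
                                         substr(ref20, 9, 20))),
             mk("ins", "5M2I15M", paste0(substr(ref20, 1, 5), "TT",
                                         substr(ref20, 6, 20))))
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:toy\tLN:2000", lines), path)
  aln <- read_alignments(path)
  pile <- build_pileup(aln, g, list(chrom = "toy", start = 100L, end = 120L))
  expect_identical(nrow(pile), 20L)
  first <- pile[pile$pos == 100L, ]
  expect_identical(first$depth, 12L)
  expect_identical(first[[first$ref]], 12L)
  delcol <- pile[pile$pos == 105L, ]  # inside the 3 bp deletion
  expect_identical(delcol$del, 1L)
  expect_identical(delcol$depth, 12L)   # deletion still consumes depth
  inscol <- pile[pile$pos == 104L, ]  # insertion anchored after 5th base
  expect_identical(inscol$ins, 1L)
  # error-free simulated reads reproduce reference-only columns
  expect_true(all(pile$A + pile$C + pile$G + pile$T + pile$del ==
                    pile$depth))
})

test_that("pileup counts on simulated data match truth-derived expectations", {
  # noiseless reads + planted het SNVs: alt fraction equals the haplotype mix
  aln <- dplyr::filter(sim_clean_aln, chrom == "toy9")
  region <- feature_region(tg, "ROI_ABL1_KD")
  pile <- build_pileup(aln, tg, region)
  haps <- dplyr::distinct(
    dplyr::filter(sim_clean_aln, chrom == "toy9", rend > region$start,
                  rstart < region$end),
    read_id, hap)
  n_alt <- sum(haps$hap)
  snv_cols <- dplyr::inner_join(pile, tg_snvs, by = c("chrom", "pos"))
  expect_identical(nrow(snv_cols), nrow(tg_snvs))
  for (i in seq_len(nrow(snv_cols))) {
    expect_identical(snv_cols[[snv_cols$alt[i]]][i], n_alt)
  }
  # non-variant columns are pure reference
  pure <- dplyr::anti_join(pile, tg_snvs, by = c("chrom", "pos"))
  ref_count <- vapply(seq_len(nrow(pure)), function(i) pure[[pure$ref[i]]][i],
                      integer(1))
  expect_true(all(ref_count == pure$depth))
})

test_that("genotype posteriors match a brute-force Bayes oracle", {
  # oracle: enumerate the three genotypes directly on the binomial likelihood
  oracle <- function(k, n, e) {
    lik <- c(rr = dbinom(k, n, e), ra = dbinom(k, n, 0.5),
             aa = dbinom(k, n, 1 - e))
    lik / sum(lik)
  }
  for (case in list(c(100L, 50L), c(200L, 120L), c(60L, 58L), c(30L, 10L))) {
    depth <- case[1]; altc <- case[2]
    calls <- call_snvs(pileup_row(depth = depth, alt_count = altc),
                       min_qual = 0, min_alt_fraction = 0)
    expect_identical(nrow(calls), 1L)
    post <- oracle(altc, depth, max(10^(-20 / 10), 0.001))
    expect_equal(calls$p_rr, post[["rr"]], tolerance = 1e-10)
    expect_equal(calls$p_ra, post[["ra"]], tolerance = 1e-10)
    expect_equal(calls$p_aa, post[["aa"]], tolerance = 1e-10)
    expect_equal(calls$qual, -10 * log10(post[["rr"]]), tolerance = 1e-6)
  }
  het <- call_snvs(pileup_row(depth = 100L, alt_count = 50L))
  expect_identical(het$genotype, "het")
  hom <- call_snvs(pileup_row(depth = 100L, alt_count = 99L))
  expect_identical(hom$genotype, "hom_alt")
})

test_that("call thresholds gate low-evidence columns", {
  expect_identical(nrow(call_snvs(pileup_row(depth = 100L, alt_count = 1L))),
                   0L)
  expect_identical(nrow(call_snvs(pileup_row(depth = 8L, alt_count = 8L))),
                   0L)
  expect_identical(nrow(call_snvs(pileup_row(depth = 100L, alt_count = 10L))),
                   0L)  # below min_alt_fraction
  expect_identical(nrow(call_snvs(pileup_row()[0, ])), 0L)
})

test_that("QUAL is non-decreasing in depth at fixed allele fraction", {
  quals <- vapply(seq(20L, 400L, by = 20L), function(d) {
    call_snvs(pileup_row(depth = d, alt_count = d %/% 2L),
              min_qual = 0)$qual
  }, numeric(1))
  expect_true(all(diff(quals) >= -1e-9))
})

test_that("callset intersection cells partition the union", {
  cmp <- intersect_callsets(list(A = c("v1", "v2"), B = c("v2", "v3")))
  cells <- cmp$cells
  expect_identical(cells$n[cells$combination == "A"], 1L)
  expect_identical(cells$n[cells$combination == "B"], 1L)
  expect_identical(cells$n[cells$combination == "A&B"], 1L)

  same <- replicate(3, paste0("v", 1:10), simplify = FALSE)
  names(same) <- c("x", "y", "z")
  cmp3 <- intersect_callsets(same)
  expect_identical(cmp3$cells$combination, "x&y&z")
  expect_identical(cmp3$cells$n, 10L)

  # brute-force oracle: count each union member's membership pattern directly
  set.seed(7)
  for (rep in 1:5) {
    sets <- lapply(1:3, function(i) sample(paste0("v", 1:20),
                                           sample(3:15, 1)))
    names(sets) <- c("a", "b", "c")
    cmp <- intersect_callsets(sets)
    u <- unique(unlist(sets))
    patt <- vapply(u, function(v) {
      paste(names(sets)[vapply(sets, function(s) v %in% s, logical(1))],
            collapse = "&")
    }, character(1))
    brute <- table(patt)
    for (comb in names(brute)) {
      expect_identical(cmp$cells$n[cmp$cells$combination == comb],
                       as.integer(brute[[comb]]))
    }
    expect_identical(sum(cmp$cells$n), length(u))
  }
  expect_error(intersect_callsets(list(A = "v1")), "at least two")
})

test_that("allowlist restricts the comparison like an annotation filter", {
  cmp <- intersect_callsets(list(A = c("v1", "v2", "v9"), B = c("v2", "v9")),
                            allowlist = c("v1", "v2"))
  expect_identical(sum(cmp$cells$n), 2L)
  expect_false("v9" %in% cmp$membership$key)
})

test_that("depth summaries and point-biserial correlation behave on edge cases", {
  cmp <- intersect_callsets(list(A = c("v1", "v2"), B = c("v2", "v3")))
  de_flat <- depth_effect(cmp, c(v1 = 30, v2 = 30, v3 = 30))
  expect_true(all(de_flat$median_depth == 30))
  expect_identical(attr(de_flat, "point_biserial"), 0)

  cmp2 <- intersect_callsets(list(A = paste0("v", 1:3), B = paste0("v", 1:3)))
  de2 <- depth_effect(cmp2, c(v1 = 10, v2 = 20, v3 = 30))
  expect_identical(de2$median_depth, 20)

  # deep variants all-caller, shallow single-caller -> positive correlation
  cmp3 <- intersect_callsets(list(A = c("d1", "d2", "s1", "s2"),
                                  B = c("d1", "d2")))
  de3 <- depth_effect(cmp3, c(d1 = 100, d2 = 110, s1 = 10, s2 = 12))
  expect_gt(attr(de3, "point_biserial"), 0.9)
  expect_error(depth_effect(cmp3, c(d1 = 100)), "depth")
})

test_that("QUAL-depth Pearson matches hand-computed values", {
  lin <- tibble::tibble(qual = 2 * c(10, 20, 30, 40), depth = c(10, 20, 30, 40))
  expect_equal(qual_depth_correlation(lin)$r, 1.0)
  const <- tibble::tibble(qual = rep(5, 4), depth = c(10, 20, 30, 40))
  res <- qual_depth_correlation(const)
  expect_true(is.na(res$r))
  expect_identical(res$reason, "zero variance")
  worked <- tibble::tibble(qual = c(1, 3, 2, 4), depth = c(1, 2, 3, 4))
  expect_equal(qual_depth_correlation(worked)$r, 0.8)
  expect_true(is.na(qual_depth_correlation(lin[1:2, ])$r))
})

test_that("SNV VCF emission is 1-based and a write-read-write fixpoint", {
  skip_if_not_installed("vcfR")
  calls <- call_snvs(pileup_row(depth = 100L, alt_count = 50L))
  calls$pos <- 999L; calls$chrom <- "toy22"
  p1 <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls, c(toy22 = 60000L), p1)
  line <- grep("^[^#]", readLines(p1), value = TRUE)
  expect_identical(as.integer(strsplit(line, "\t")[[1]][2]), 1000L)

  back <- read_snv_vcf(p1)
  expect_identical(back$pos, 999L)
  expect_identical(back$ref, calls$ref)
  expect_identical(back$alt, calls$alt)
  expect_identical(back$genotype, "het")
  expect_equal(back$af, calls$af, tolerance = 1e-6)
  p2 <- tempfile(fileext = ".vcf")
  write_snv_vcf(back, c(toy22 = 60000L), p2)
  expect_identical(readLines(p1), readLines(p2))

  pe <- tempfile(fileext = ".vcf")
  write_snv_vcf(calls[0, ], c(toy22 = 60000L), pe)
  expect_identical(grep("^[^#]", readLines(pe)), integer(0))
})
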
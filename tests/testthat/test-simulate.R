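test_that("noiseless reads start exactly at the expected cut and match the reference", {
  aln <- sim_clean$alignments
  cr <- tg$crrnas
  for (i in seq_len(nrow(cr))) {
    g <- cr[i, ]
    recs <- dplyr::filter(aln, crrna == g$name, allele == g$chrom)
    expect_gt(nrow(recs), 0)
    if (g$direction > 0) {
      expect_true(all(recs$rstart == g$expected_cut))
    } else {
      expect_true(all(recs$rend == g$expected_cut))
    }
    # sequence equals the reference substring (molecule orientation);
    # haplotype-0 reads only, since alt-bearing reads differ at planted SNVs
    clean <- dplyr::filter(recs, hap == 0L)
    for (j in seq_len(min(2, nrow(clean)))) {
      r <- clean[j, ]
      expect_identical(r$seq, substr(tg$chromosomes[[r$chrom]], r$rstart + 1,
                                     r$rend))
    }
  }
  # reads sequenced leftwards are reverse complements of their molecule
  rev_reads <- dplyr::filter(sim_clean$reads, direction == -1)
  rec <- dplyr::filter(aln, read_id == rev_reads$read_id[1])
  expect_identical(rev_reads$sequence[1], revcomp(rec$seq[1]))
})

test_that("fusion-spanning reads get two query-adjacent truth segments on different chromosomes", {
  spanning <- sim_clean$alignments |>
    dplyr::filter(allele == "fusion", crrna == "BCR-16000 crRNA+")
  expect_true(all(table(spanning$read_id) == 2L))
  one <- dplyr::filter(spanning, read_id == spanning$read_id[1]) |>
    dplyr::arrange(rstart)
  expect_setequal(one$chrom, c("toy22", "toy9"))
  # adjacency in query coordinates: no gap between the two segments
  a <- dplyr::filter(one, chrom == "toy22")
  b <- dplyr::filter(one, chrom == "toy9")
  expect_identical(a$qend_mol, b$qstart_mol)
  expect_identical(a$rend, 19000L)
  expect_identical(b$rstart, 8000L)
})

test_that("substitution errors appear at the configured rate", {
  sim <- simulate_reads(tg, chromosome_allele(tg, "toy22"), NULL, n_reads = 2,
                        sub_rate = 0.05, ins_rate = 0, del_rate = 0,
                        jitter = 0, seed = 21)
  n_mismatch <- 0L; n_bases <- 0L
  for (i in seq_len(nrow(sim$alignments))) {
    r <- sim$alignments[i, ]
    ref <- substr(tg$chromosomes[[r$chrom]], r$rstart + 1, r$rend)
    n_bases <- n_bases + nchar(ref)
    n_mismatch <- n_mismatch +
      sum(strsplit(r$seq, "")[[1]] != strsplit(ref, "")[[1]])
  }
  expect_gt(n_bases, 10000)
  p_hat <- n_mismatch / n_bases
  sd3 <- 3 * sqrt(0.05 * 0.95 / n_bases)
  expect_lt(abs(p_hat - 0.05), sd3)
})

test_that("simulation is deterministic and warns on cut-free alleles", {
  s1 <- simulate_reads(tg, tg_alleles, tg_truth, n_reads = 3, seed = 5)
  s2 <- simulate_reads(tg, tg_alleles, tg_truth, n_reads = 3, seed = 5)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$meth_truth, s2$meth_truth)
  bare <- structure(list(name = "bare", sequence = strrep("A", 1000),
                         segments = tibble::tibble(chrom = "bare", start = 0L,
                                                   end = 1000L)),
                    class = "allele")
  expect_warning(simulate_reads(tg, bare, NULL, n_reads = 2, seed = 1),
                 "no crRNA cut site")
})

test_that("every simulated base is attributable to a truth segment or insertion", {
  # query intervals of a read's records partition [0, read length)
  aln <- sim_noisy_aln |> dplyr::arrange(read_id, qstart)
  for (rid in unique(aln$read_id)[1:20]) {
    segs <- dplyr::filter(aln, read_id == rid)
    expect_true(all(segs$qend <= segs$read_length[1]))
    if (nrow(segs) > 1L) {
      expect_true(all(segs$qend[-nrow(segs)] <= segs$qstart[-1]))
    }
  }
})

test_that("BSAS simulation follows the retained-count binomial", {
  regions <- default_bsas_regions(tg)
  prof1 <- dplyr::mutate(tg_profile, p = 1)
  b1 <- simulate_bsas(prof1, regions, depth = 50, conversion = 1, seed = 3)
  expect_true(all(b1$freq == 1))
  prof0 <- dplyr::mutate(tg_profile, p = 0)
  b0 <- simulate_bsas(prof0, regions, depth = 100, conversion = 1, seed = 3)
  expect_true(all(b0$n_retained == 0L))
  # incomplete conversion leaves ~(1 - c) retained background
  bc <- simulate_bsas(prof0, regions, depth = 2000, conversion = 0.95,
                      seed = 4)
  n_trials <- 2000 * nrow(bc)
  pooled <- sum(bc$n_retained) / n_trials
  sd3 <- 3 * sqrt(0.05 * 0.95 / n_trials)
  expect_lt(abs(pooled - 0.05), sd3)
  # region without CpGs warns and contributes nothing
  empty_rg <- tibble::tibble(region_id = "none", chrom = "toy22",
                             start = 0L, end = 10L)
  expect_warning(out <- simulate_bsas(tg_profile, empty_rg, depth = 10,
                                      seed = 1), "no CpG")
  expect_identical(nrow(out), 0L)
  expect_identical(simulate_bsas(tg_profile, regions, depth = 30, seed = 9),
                   simulate_bsas(tg_profile, regions, depth = 30, seed = 9))
})

test_that("FASTQ output holds one 4-line block per read", {
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim_clean, path)
  lines <- readLines(path)
  expect_identical(length(lines), 4L * nrow(sim_clean$reads))
  expect_identical(sub("^@", "", lines[1]), sim_clean$reads$read_id[1])
  expect_identical(lines[2], sim_clean$reads$sequence[1])
  expect_identical(nchar(lines[2]), nchar(lines[4]))
})
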
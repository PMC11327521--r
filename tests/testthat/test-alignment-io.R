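min_sam <- function(lines, seqs = c(toy = 1000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), seqs),
               lines), path)
  path
}

test_that("CIGAR arithmetic places query and reference intervals correctly", {
  # 10S90M at 1-based POS 101: query [10,100), ref [100,190)
  p <- min_sam(paste0("r1\t0\ttoy\t101\t60\t10S90M\t*\t0\t0\t",
                      strrep("A", 100), "\t", strrep("I", 100)))
  a <- read_alignments(p)
  expect_identical(a$qstart, 10L)
  expect_identical(a$qend, 100L)
  expect_identical(a$rstart, 100L)
  expect_identical(a$rend, 190L)
  expect_identical(a$read_length, 100L)

  p2 <- min_sam(paste0("r2\t0\ttoy\t1\t60\t100M\t*\t0\t0\t",
                       strrep("A", 100), "\t", strrep("I", 100)))
  a2 <- read_alignments(p2)
  expect_identical(a2$qend - a2$qstart, a2$rend - a2$rstart)
  expect_identical(a2$qend - a2$qstart, 100L)

  # reverse-strand record: clips are re-expressed in read orientation
  p3 <- min_sam(paste0("r3\t16\ttoy\t101\t60\t10S90M\t*\t0\t0\t",
                       strrep("A", 100), "\t", strrep("I", 100)))
  a3 <- read_alignments(p3)
  expect_identical(a3$qstart, 0L)
  expect_identical(a3$qend, 90L)
  expect_identical(a3$strand, "-")
})

test_that("unmapped records are skipped with a counter", {
  p <- min_sam(c(paste0("r1\t0\ttoy\t1\t60\t10M\t*\t0\t0\t", strrep("A", 10),
                        "\t", strrep("I", 10)),
                 paste0("r2\t4\t*\t0\t0\t*\t*\t0\t0\t", strrep("A", 10),
                        "\t", strrep("I", 10))))
  a <- read_alignments(p)
  expect_identical(nrow(a), 1L)
  expect_identical(attr(a, "n_unmapped"), 1L)
})

test_that("truth SAM round-trips to the simulator's segment model", {
  a <- sim_noisy$alignments |>
    dplyr::arrange(read_id, chrom, rstart)
  b <- sim_noisy_aln |>
    dplyr::arrange(read_id, chrom, rstart)
  for (col in c("read_id", "flag", "chrom", "rstart", "rend", "cigar", "seq",
                "qual", "mm", "crrna", "allele", "hap")) {
    expect_identical(as.vector(b[[col]]), as.vector(a[[col]]), label = col)
  }
  expect_identical(b$ml, a$ml)
  # and write_sam(read_alignments(x)) is a fixpoint on the file
  p2 <- tempfile(fileext = ".sam")
  write_sam(b, nchar(tg$chromosomes), p2)
  c2 <- read_alignments(p2)
  expect_identical(dplyr::select(c2, -dplyr::any_of("mapq")),
                   dplyr::select(b, -dplyr::any_of("mapq")))
})

test_that("group_by_read orders segments by query start, invariant to input order", {
  rs <- group_by_read(sim_noisy_aln)
  two <- rs[rs$n_segments == 2L, ]
  expect_gt(nrow(two), 0)
  s <- two$segments[[1]]
  expect_true(s$qstart[1] <= s$qstart[2])
  shuffled <- sim_noisy_aln[sample.int(nrow(sim_noisy_aln)), ]
  rs2 <- group_by_read(shuffled)
  expect_identical(rs$read_id, rs2$read_id)
  expect_identical(rs$segments, rs2$segments)
  empty <- group_by_read(sim_noisy_aln[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("MM/ML decoding recovers the per-read truth CpG states exactly on clean reads", {
  calls <- read_meth_tags(sim_clean_aln)
  truth <- sim_clean$meth_truth
  expect_gt(nrow(truth), 100)
  j <- dplyr::full_join(calls, truth, by = c("read_id", "chrom", "pos"))
  # noiseless simulation: every truth state recovered, nothing extra
  expect_identical(nrow(j), nrow(truth))
  expect_identical(j$call, j$state)
  expect_identical(attr(calls, "n_skipped"), 0L)
})

test_that("reverse-strand records project CpG evidence onto the plus-strand C", {
  # add a leftward guide downstream of the island so reverse-complemented
  # reads carry 5mC tags on the CpG G
  layout <- toy_genome_layout()
  layout$crrnas <- dplyr::bind_rows(
    layout$crrnas[1, ],
    tibble::tibble(name = "BCR-9000 crRNA-", chrom = "toy22", cut = 9000L,
                   direction = -1L))
  g2 <- make_toy_genome(layout, seed = 1)
  prof2 <- methylation_profile(g2)
  truth2 <- make_truth_set(g2, profile = prof2, jitter = 0, seed = 1)
  sim2 <- simulate_reads(g2, chromosome_allele(g2, "toy22"), truth2,
                         n_reads = 4, sub_rate = 0, ins_rate = 0,
                         del_rate = 0, jitter = 0, meth_call_error = 0,
                         seed = 41)
  expect_setequal(unique(sim2$reads$direction), c(1L, -1L))
  aln2 <- read_alignments(sam_path_for(sim2, g2))
  calls2 <- read_meth_tags(aln2)
  truth <- sim2$meth_truth
  j <- dplyr::full_join(calls2, truth, by = c("read_id", "chrom", "pos"))
  expect_identical(nrow(j), nrow(truth))
  expect_identical(j$call, j$state)
  rev_ids <- sim2$reads$read_id[sim2$reads$direction == -1L]
  expect_gt(sum(calls2$read_id %in% rev_ids), 100)
})

test_that("records without tags yield no methylation calls", {
  untagged <- dplyr::filter(sim_clean_aln, is.na(mm))
  expect_gt(nrow(untagged), 0)
  out <- read_meth_tags(untagged)
  expect_identical(nrow(out), 0L)
})

test_that("bases lost to errors drop their sites rather than miscall", {
  # heavy deletion load: decoded calls are a subset of the drawn truth
  sim_del <- simulate_reads(tg, chromosome_allele(tg, "toy22"), tg_truth,
                            n_reads = 3, sub_rate = 0, ins_rate = 0,
                            del_rate = 0.05, jitter = 0,
                            meth_call_error = 0, seed = 31)
  aln <- read_alignments(sam_path_for(sim_del))
  calls <- read_meth_tags(aln)
  truth <- sim_del$meth_truth
  expect_lt(nrow(calls), nrow(truth))
  j <- dplyr::inner_join(calls, truth, by = c("read_id", "chrom", "pos"))
  expect_identical(nrow(j), nrow(calls))
  expect_identical(j$call, j$state)
})
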
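test_that("noiseless fusion reads give the stated junction convention", {
  rs <- group_by_read(sim_clean_aln)
  obs <- find_chimeric_junctions(rs)
  expect_gt(nrow(obs), 0)
  # truth boundaries (bpA, bpB) = (19000, 8000): last base / first base
  expect_true(all(obs$chromA == "toy22" & obs$posA == 18999L))
  expect_true(all(obs$chromB == "toy9" & obs$posB == 8000L))
  expect_true(all(obs$orientation == "++"))
  # single-segment reads contribute nothing
  single <- rs[rs$n_segments == 1L, ]
  expect_identical(nrow(find_chimeric_junctions(single)), 0L)
})

test_that("segment-length and query-gap filters drop non-junction pairs", {
  short <- dplyr::bind_rows(
    make_segments("r", "toy22", 1000, 1100, qstart = 0, qend = 100,
                  read_length = 600),
    make_segments("r", "toy9", 5000, 5500, qstart = 100, qend = 600,
                  read_length = 600))
  expect_identical(nrow(find_chimeric_junctions(group_by_read(short))), 0L)
  gapped <- dplyr::bind_rows(
    make_segments("r", "toy22", 1000, 1300, qstart = 0, qend = 300,
                  read_length = 1000),
    make_segments("r", "toy9", 5000, 5500, qstart = 500, qend = 1000,
                  read_length = 1000))
  expect_identical(nrow(find_chimeric_junctions(group_by_read(gapped),
                                                max_query_gap = 100)), 0L)
  expect_identical(nrow(find_chimeric_junctions(group_by_read(gapped),
                                                max_query_gap = 300)), 1L)
})

test_that("clustering takes the coordinate-wise lower median and respects support", {
  obs <- tibble::tibble(read_id = paste0("r", 1:3),
                        chromA = "toy22", posA = c(999L, 1000L, 1001L),
                        strandA = "+", chromB = "toy9",
                        posB = c(5000L, 5000L, 5001L), strandB = "+",
                        orientation = "++", query_gap = 0L)
  calls <- cluster_junctions(obs, tolerance = 50, min_support = 1)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$posA, 1000L)
  expect_identical(calls$posB, 5000L)
  expect_identical(calls$n_supporting_reads, 3L)

  one <- cluster_junctions(obs[1, ], tolerance = 50, min_support = 1)
  expect_identical(one$posA, obs$posA[1])
  expect_identical(one$posB, obs$posB[1])

  # groups 10 kb apart stay separate
  two_grp <- dplyr::bind_rows(obs, dplyr::mutate(obs, posA = posA + 10000L,
                                                 read_id = paste0("s", 1:3)))
  calls2 <- cluster_junctions(two_grp, tolerance = 50, min_support = 1)
  expect_identical(nrow(calls2), 2L)

  # below min_support drops the call but conserves observations
  dropped <- cluster_junctions(obs, tolerance = 50, min_support = 5)
  expect_identical(nrow(dropped), 0L)
  expect_identical(attr(dropped, "n_dropped_observations"), 3L)
})

test_that("clustering matches brute-force single-linkage on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    centers <- sample(c(1000L, 5000L, 50000L), n, replace = TRUE)
    obs <- tibble::tibble(
      read_id = paste0("r", seq_len(n)), chromA = "cA",
      posA = centers + sample(-30:30, n, replace = TRUE), strandA = "+",
      chromB = "cB", posB = 7000L + sample(-30:30, n, replace = TRUE),
      strandB = "+", orientation = "++", query_gap = 0L)
    calls <- cluster_junctions(obs, tolerance = 50, min_support = 1)
    comp <- brute_components(obs$posA, obs$posB, 50L)
    expect_identical(nrow(calls), length(unique(comp)))
    expect_identical(sort(calls$n_supporting_reads),
                     sort(unname(as.integer(table(comp)))))
    # permutation invariance and idempotence
    perm <- cluster_junctions(obs[sample.int(n), ], tolerance = 50,
                              min_support = 1)
    expect_identical(tidy(calls), tidy(perm))
    again <- cluster_junctions(
      dplyr::mutate(tidy(calls), read_id = paste0("c", dplyr::row_number()),
                    strandA = "+", strandB = "+", query_gap = 0L),
      tolerance = 50, min_support = 1)
    expect_identical(again$posA, calls$posA)
    expect_identical(again$posB, calls$posB)
  }
})

test_that("intron context maps to the transcript label table", {
  mk_call <- function(posA, posB) {
    structure(tibble::tibble(chromA = "toy22", posA = as.integer(posA),
                             chromB = "toy9", posB = as.integer(posB),
                             orientation = "++", n_supporting_reads = 5L,
                             read_ids = list("r"), mad = 0),
              class = c("fusion_calls", "tbl_df", "tbl", "data.frame"))
  }
  expect_identical(classify_fusion(mk_call(19000, 8000), tg$features)$label,
                   "b3a2")
  expect_identical(classify_fusion(mk_call(13000, 8000), tg$features)$label,
                   "b2a2")
  expect_identical(classify_fusion(mk_call(14950, 8000), tg$features)$label,
                   "unclassified")  # exon breakpoint
  expect_error(classify_fusion(mk_call(19000, 8000),
                               tg$features[tg$features$role != "intron", ]),
               "intron")
})

test_that("BND VCF uses 1-based positions with cross-referencing mates", {
  call <- structure(tibble::tibble(chromA = "toy22", posA = 29999L,
                                   chromB = "toy9", posB = 10000L,
                                   orientation = "++",
                                   n_supporting_reads = 7L,
                                   read_ids = list("r"), mad = 0),
                    class = c("fusion_calls", "tbl_df", "tbl", "data.frame"))
  p <- tempfile(fileext = ".vcf")
  write_bnd_vcf(call, c(toy22 = 60000L, toy9 = 60000L), p)
  lines <- grep("^[^#]", readLines(p), value = TRUE)
  expect_identical(length(lines), 2L)
  f1 <- strsplit(lines[1], "\t")[[1]]; f2 <- strsplit(lines[2], "\t")[[1]]
  expect_identical(as.integer(f1[2]), 30000L)
  expect_identical(as.integer(f2[2]), 10001L)
  expect_identical(f1[5], "N[toy9:10001[")
  expect_identical(f2[5], "]toy22:30000]N")
  expect_match(f1[8], "MATEID=bnd_1b")
  expect_match(f2[8], "MATEID=bnd_1a")

  # empty call set -> header-only outputs
  empty <- cluster_junctions(find_chimeric_junctions(
    group_by_read(sim_clean_aln)[0, ]), min_support = 1)
  p2 <- tempfile(fileext = ".vcf")
  write_bnd_vcf(empty, c(toy22 = 60000L), p2)
  expect_identical(grep("^[^#]", readLines(p2)), integer(0))
})

test_that("BEDPE round-trips the modeled call fields", {
  rs <- group_by_read(sim_clean_aln)
  calls <- cluster_junctions(find_chimeric_junctions(rs), min_support = 2)
  p <- tempfile(fileext = ".bedpe")
  write_bedpe(calls, p)
  back <- read_bedpe(p)
  expect_identical(back$posA, calls$posA)
  expect_identical(back$posB, calls$posB)
  expect_identical(back$orientation, calls$orientation)
  expect_identical(back$n_supporting_reads, calls$n_supporting_reads)
})
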
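# Shared desk-scale fixtures, built once per test run.

tg <- make_toy_genome(seed = 1)
tg_fusion <- make_fusion_allele(tg, 19000, 8000)
tg_snvs <- plant_snvs(tg, feature_region(tg, "ROI_ABL1_KD"), n = 10,
                      vaf = 0.5, seed = 2)
tg_profile <- methylation_profile(tg)
tg_truth <- make_truth_set(tg, tg_fusion, tg_snvs, tg_profile,
                           jitter = 2, seed = 1)

tg_alleles <- list(chromosome_allele(tg, "toy22"),
                   chromosome_allele(tg, "toy9"),
                   tg_fusion)

# noiseless: no errors, no jitter, no methylation-call error
sim_clean <- simulate_reads(tg, tg_alleles, tg_truth, n_reads = 4,
                            sub_rate = 0, ins_rate = 0, del_rate = 0,
                            jitter = 0, meth_call_error = 0, seed = 11)

# default noise model, small depth
sim_noisy <- simulate_reads(tg, tg_alleles, tg_truth, n_reads = 10,
                            jitter = 2, seed = 12)

sam_path_for <- function(sim, genome = tg) {
  path <- tempfile(fileext = ".sam")
  write_truth_sam(sim, genome, path)
  path
}

sim_clean_aln <- read_alignments(sam_path_for(sim_clean))
sim_noisy_aln <- read_alignments(sam_path_for(sim_noisy))

# independent oracle: brute-force single-linkage components via BFS over the
# pairwise link matrix
brute_components <- function(posA, posB, tol) {
  n <- length(posA)
  link <- outer(posA, posA, function(a, b) abs(a - b) <= tol) &
    outer(posB, posB, function(a, b) abs(a - b) <= tol)
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(link[v, ] & is.na(comp)))
    }
  }
  comp
}

# minimal hand-built segment tibble for constructed-fixture tests
make_segments <- function(read_id, chrom, rstart, rend, strand = "+",
                          qstart = 0L, qend = rend - rstart,
                          read_length = max(qend)) {
  tibble::tibble(
    read_id = read_id, flag = 0L, chrom = chrom,
    rstart = as.integer(rstart), rend = as.integer(rend), strand = strand,
    mapq = 60L, cigar = paste0(rend - rstart, "M"), is_primary = TRUE,
    qstart = as.integer(qstart), qend = as.integer(qend),
    read_length = as.integer(read_length),
    seq = strrep("A", max(qend)), qual = strrep("5", max(qend)),
    mm = NA_character_, ml = list(integer(0)), crrna = NA_character_,
    allele = NA_character_, hap = NA_integer_
  )
}
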
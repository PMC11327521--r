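#' Default pipeline configuration
#'
#' One nested list drives every stage; unknown keys are rejected at
#' validation. `paths` entries left NULL are resolved from the `simulate`
#' stage's outputs, so the default configuration runs end-to-end with no
#' external files; point them at your own BAM/FASTA/TSV to analyse real data.
#'
#' @param out_dir output directory (each stage writes only under its own
#'   subdirectory).
#' @param seed global seed; per-stage seeds are derived as
#'   `(seed + sum of UTF-8 codes of the stage name) mod (2^31 - 1)` and
#'   logged in each stage manifest.
#' @return a config list.
#' @export
default_config <- function(out_dir = "ncats_out", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    paths = list(genome_dir = NULL, alignments = NULL, bsas = NULL),
    simulate = list(
      n_reads = 250L,        # per cut per allele; two alleles per locus ~ 500x
      bpA = 19000L, bpB = 8000L,
      n_snvs = 10L, vaf = 0.5,
      p_high = 0.9, p_low = 0.1,
      sub_rate = 0.01, ins_rate = 0.0025, del_rate = 0.0025,
      jitter = 2L, meth_call_error = 0.01,
      bsas_depth = 100L, conversion = 1.0
    ),
    qc = list(window = 20L),
    fusion = list(min_segment = 200L, max_query_gap = 100L,
                  tolerance = 50L, min_support = 3L),
    snv = list(region = "ROI_ABL1_KD", min_depth = 10L, min_alt_count = 4L,
               min_alt_fraction = 0.2, min_qual = 20, min_base_qual = 7L),
    compare = list(callsets = list()),
    meth = list(threshold = 0.5, min_depth = 5L, hypo_threshold = 0.3,
                hyper_threshold = 0.7, min_run = 3L, conversion = 1.0)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every key against the schema of [default_config()]; unknown keys
#' are an error, and referenced input paths must exist.
#'
#' @param config a config list.
#' @return the config, invisibly, with defaults filled in.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  for (blk in setdiff(names(def), c("out_dir", "seed"))) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad)) {
        abort(paste0("unknown config keys in '", blk, "': ",
                     paste(bad, collapse = ", ")))
      }
      def[[blk]] <- utils::modifyList(def[[blk]], config[[blk]])
    }
  }
  def$out_dir <- config$out_dir %||% def$out_dir
  def$seed <- as.integer(config$seed %||% def$seed)
  for (p in c("alignments", "bsas")) {
    pth <- def$paths[[p]]
    if (!is.null(pth) && !file.exists(pth)) {
      abort(paste0("configured input does not exist: ", p, " = ", pth))
    }
  }
  invisible(def)
}

#' Read a YAML pipeline configuration
#' @param path YAML file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname default_config
#' @param stage stage name.
#' @export
stage_seed <- function(seed, stage) {
  (as.integer(seed) + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

## --- genome file round-trip (FASTA + feature/crRNA TSV) -------------------

#' Write / load a toy genome as FASTA plus feature and crRNA tables
#' @param genome a `toy_genome`.
#' @param dir directory to hold genome.fasta, features.tsv, crrnas.tsv.
#' @return `dir` invisibly (writer); a `toy_genome` (loader).
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes),
    file.path(dir, "genome.fasta"))
  readr::write_tsv(genome$features, file.path(dir, "features.tsv"))
  readr::write_tsv(genome$crrnas, file.path(dir, "crrnas.tsv"))
  invisible(dir)
}

#' @rdname write_genome_files
#' @export
load_genome_files <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "genome.fasta"))
  chroms <- setNames(as.character(seqs), names(seqs))
  structure(list(
    chromosomes = chroms,
    features = readr::read_tsv(file.path(dir, "features.tsv"),
                               show_col_types = FALSE),
    crrnas = readr::read_tsv(file.path(dir, "crrnas.tsv"),
                             show_col_types = FALSE)
  ), class = "toy_genome")
}

stage_dir <- function(config, stage) {
  d <- file.path(config$out_dir, sub("-", "_", stage))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

resolve_genome <- function(config) {
  dir <- config$paths$genome_dir %||% file.path(config$out_dir, "simulate")
  if (!file.exists(file.path(dir, "genome.fasta"))) {
    abort(paste0("missing input: genome files under ", dir,
                 " (run the simulate stage or set paths$genome_dir)"))
  }
  load_genome_files(dir)
}

resolve_alignments <- function(config) {
  pth <- config$paths$alignments %||%
    file.path(config$out_dir, "simulate", "truth.sam")
  if (!file.exists(pth)) {
    abort(paste0("missing input: alignments at ", pth))
  }
  read_alignments(pth)
}

write_manifest <- function(config, stage, params, inputs, outputs) {
  manifest <- list(
    stage = stage, seed = config$seed,
    stage_seed = stage_seed(config$seed, stage),
    params = params, inputs = inputs,
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(stage_dir(config, stage),
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Stages communicate only through files in standard formats under
#' `out_dir/<stage>/`, so any stage's inputs can be swapped for an external
#' tool's output (e.g. a real caller's VCF into `compare-callers`). Each run
#' writes a manifest recording parameters, the derived stage seed, inputs and
#' output MD5 hashes; deterministic stages reproduce identical outputs for an
#' identical config.
#'
#' @param stage one of `"simulate"`, `"qc"`, `"fusion"`, `"snv"`,
#'   `"compare-callers"`, `"meth"`, `"report"`.
#' @param config config list (validated with [validate_config()]).
#' @return named list of the stage's main results, invisibly.
#' @export
run_stage <- function(stage, config) {
  config <- validate_config(config)
  stages <- c("simulate", "qc", "fusion", "snv", "compare-callers", "meth",
              "report")
  if (!stage %in% stages) {
    abort(paste0("unknown stage '", stage, "'; expected one of ",
                 paste(stages, collapse = ", ")))
  }
  fn <- switch(stage,
               "simulate" = stage_simulate, "qc" = stage_qc,
               "fusion" = stage_fusion, "snv" = stage_snv,
               "compare-callers" = stage_compare, "meth" = stage_meth,
               "report" = function(cfg) make_report(cfg))
  fn(config)
}

#' Run several stages in order
#' @param config config list.
#' @param stages character vector of stage names.
#' @return invisibly, the last stage's result.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "qc", "fusion", "snv",
                                    "compare-callers", "meth", "report")) {
  res <- NULL
  for (s in stages) res <- run_stage(s, config)
  invisible(res)
}

stage_simulate <- function(config) {
  p <- config$simulate
  sseed <- stage_seed(config$seed, "simulate")
  d <- stage_dir(config, "simulate")
  genome <- make_toy_genome(toy_genome_layout(), seed = sseed)
  fusion <- make_fusion_allele(genome, p$bpA, p$bpB)
  snvs <- plant_snvs(genome, feature_region(genome, "ROI_ABL1_KD"),
                     n = p$n_snvs, vaf = p$vaf, seed = sseed + 1L)
  profile <- methylation_profile(genome, p_high = p$p_high, p_low = p$p_low)
  truth <- make_truth_set(genome, fusion, snvs, profile, jitter = p$jitter,
                          seed = sseed)
  alleles <- list(chromosome_allele(genome, "toy22"),
                  chromosome_allele(genome, "toy9"), fusion)
  sim <- simulate_reads(genome, alleles, truth, n_reads = p$n_reads,
                        sub_rate = p$sub_rate, ins_rate = p$ins_rate,
                        del_rate = p$del_rate, jitter = p$jitter,
                        meth_call_error = p$meth_call_error, seed = sseed + 2L)
  bsas <- simulate_bsas(profile, default_bsas_regions(genome),
                        depth = p$bsas_depth, conversion = p$conversion,
                        seed = sseed + 3L)
  write_genome_files(genome, d)
  write_fastq(sim, file.path(d, "reads.fastq"))
  write_truth_sam(sim, genome, file.path(d, "truth.sam"))
  write_truth_json(truth, file.path(d, "truth.json"))
  write_bsas_tsv(bsas, file.path(d, "bsas.tsv"))
  write_bed(dplyr::filter(genome$features, .data$role == "ROI"),
            file.path(d, "rois.bed"))
  if (nrow(snvs)) {
    tv <- mutate(snvs, genotype = ifelse(.data$vaf >= 1, "hom_alt", "het"),
                 depth = 0L, af = .data$vaf, qual = 100)
    write_snv_vcf(tv, nchar(genome$chromosomes), file.path(d, "truth.vcf"))
  }
  outs <- file.path(d, c("genome.fasta", "features.tsv", "crrnas.tsv",
                         "reads.fastq", "truth.sam", "truth.json", "bsas.tsv",
                         "rois.bed"))
  write_manifest(config, "simulate", p, character(0), outs)
  invisible(list(genome = genome, truth = truth, sim = sim, bsas = bsas))
}

stage_qc <- function(config) {
  d <- stage_dir(config, "qc")
  genome <- resolve_genome(config)
  aln <- resolve_alignments(config)
  rs <- group_by_read(aln)
  rois <- dplyr::filter(genome$features, .data$role == "ROI")
  roi_report <- count_on_target(rs, rois)
  prof <- cut_site_profile(rs, genome, window = config$qc$window)
  pam <- pam_check(genome)
  readr::write_tsv(roi_report, file.path(d, "roi_report.tsv"))
  readr::write_tsv(prof$hits, file.path(d, "cutsite_hits.tsv"))
  readr::write_tsv(prof$histogram, file.path(d, "cutsite_histogram.tsv"))
  readr::write_tsv(pam, file.path(d, "pam_check.tsv"))
  for (i in seq_len(nrow(rois))) {
    trk <- coverage_track(aln, rois[i, ])
    write_bedgraph(trk, file.path(d, paste0("coverage_", rois$name[i],
                                            ".bedGraph")))
  }
  outs <- file.path(d, c("roi_report.tsv", "cutsite_hits.tsv",
                         "cutsite_histogram.tsv", "pam_check.tsv"))
  write_manifest(config, "qc", config$qc,
                 config$paths$alignments %||% "simulate/truth.sam", outs)
  invisible(list(roi_report = roi_report, cut_sites = prof, pam = pam))
}

stage_fusion <- function(config) {
  d <- stage_dir(config, "fusion")
  genome <- resolve_genome(config)
  p <- config$fusion
  rs <- group_by_read(resolve_alignments(config))
  obs <- find_chimeric_junctions(rs, min_segment = p$min_segment,
                                 max_query_gap = p$max_query_gap)
  calls <- cluster_junctions(obs, tolerance = p$tolerance,
                             min_support = p$min_support)
  calls <- classify_fusion(calls, genome$features)
  report_fusions(calls, nchar(genome$chromosomes), d)
  readr::write_tsv(obs, file.path(d, "junction_observations.tsv"))
  outs <- file.path(d, c("fusions.bedpe", "fusions.vcf", "fusions.tsv",
                         "junction_observations.tsv"))
  write_manifest(config, "fusion", p, character(0), outs)
  invisible(list(observations = obs, calls = calls))
}

snv_region <- function(config, genome) {
  r <- config$snv$region
  if (is.character(r) && length(r) == 1L && !grepl(":", r)) {
    return(feature_region(genome, r))
  }
  if (is.character(r)) {  # samtools-style 1-based inclusive "chrom:start-end"
    m <- regmatches(r, regexec("^([^:]+):([0-9]+)-([0-9]+)$", r))[[1]]
    if (length(m) != 4L) abort("cannot parse snv region")
    return(list(chrom = m[2], start = as.integer(m[3]) - 1L,
                end = as.integer(m[4])))
  }
  as_region(r)
}

stage_snv <- function(config) {
  d <- stage_dir(config, "snv")
  genome <- resolve_genome(config)
  p <- config$snv
  aln <- resolve_alignments(config)
  region <- snv_region(config, genome)
  pile <- build_pileup(aln, genome, region, min_base_qual = p$min_base_qual)
  calls <- call_snvs(pile, min_depth = p$min_depth,
                     min_alt_count = p$min_alt_count,
                     min_alt_fraction = p$min_alt_fraction,
                     min_qual = p$min_qual)
  write_snv_vcf(calls, nchar(genome$chromosomes), file.path(d, "calls.vcf"))
  readr::write_tsv(as_tibble(calls), file.path(d, "calls.tsv"))
  outs <- file.path(d, c("calls.vcf", "calls.tsv"))
  write_manifest(config, "snv", p, character(0), outs)
  invisible(list(pileup = pile, calls = calls))
}

stage_compare <- function(config) {
  d <- stage_dir(config, "compare_callers")
  own <- file.path(config$out_dir, "snv", "calls.vcf")
  sets <- list()
  if (file.exists(own)) sets$ncatsr <- read_snv_vcf(own)
  truth_vcf <- file.path(config$out_dir, "simulate", "truth.vcf")
  if (file.exists(truth_vcf)) sets$truth <- read_snv_vcf(truth_vcf)
  for (nm in names(config$compare$callsets)) {
    sets[[nm]] <- read_snv_vcf(config$compare$callsets[[nm]])
  }
  if (length(sets) < 2L) {
    abort("compare-callers needs at least two callsets (run snv + simulate, or configure compare$callsets)")
  }
  cmp <- intersect_callsets(sets)
  ## depths: prefer the transparent caller's observed depth, else 0
  depth_src <- if (!is.null(sets$ncatsr)) sets$ncatsr else sets[[1]]
  depths <- tibble(key = cmp$membership$key) |>
    left_join(tibble(key = variant_key(depth_src), depth = depth_src$depth),
              by = "key") |>
    mutate(depth = ifelse(is.na(.data$depth), 0, .data$depth))
  de <- depth_effect(cmp, depths)
  qd <- purrr::map_dfr(names(sets), function(nm) {
    dplyr::bind_cols(tibble(caller = nm), qual_depth_correlation(sets[[nm]]))
  })
  readr::write_tsv(cmp$cells, file.path(d, "intersection_cells.tsv"))
  readr::write_tsv(cmp$membership, file.path(d, "membership.tsv"))
  readr::write_tsv(de, file.path(d, "depth_by_combination.tsv"))
  readr::write_tsv(qd, file.path(d, "qual_depth_correlation.tsv"))
  outs <- file.path(d, c("intersection_cells.tsv", "membership.tsv",
                         "depth_by_combination.tsv",
                         "qual_depth_correlation.tsv"))
  write_manifest(config, "compare-callers",
                 list(callsets = names(sets)), character(0), outs)
  invisible(list(comparison = cmp, depth_effect = de, qual_depth = qd))
}

stage_meth <- function(config) {
  d <- stage_dir(config, "meth")
  p <- config$meth
  aln <- resolve_alignments(config)
  calls <- read_meth_tags(aln, threshold = p$threshold)
  sites <- aggregate_sites(calls, min_depth = p$min_depth)
  segs <- segment_pattern(sites, hypo_threshold = p$hypo_threshold,
                          hyper_threshold = p$hyper_threshold,
                          min_run = p$min_run)
  bsas_path <- config$paths$bsas %||%
    file.path(config$out_dir, "simulate", "bsas.tsv")
  conc <- NULL; bsites <- NULL; bsp_means <- NULL
  if (file.exists(bsas_path)) {
    bsites <- bsas_call(read_bsas_tsv(bsas_path), conversion = p$conversion)
    regions <- bsites |>
      group_by(.data$region_id, .data$chrom) |>
      summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
                .groups = "drop")
    bsp_means <- region_means(sites, regions)
    conc <- meth_concordance(sites, bsites, min_depth = p$min_depth)
    readr::write_tsv(bsites, file.path(d, "bsas_sites.tsv"))
    readr::write_tsv(bsp_means, file.path(d, "bsp_region_means.tsv"))
    jsonlite::write_json(list(n = conc$n, r = conc$r,
                              mean_abs_diff = conc$mean_abs_diff,
                              reason = conc$reason),
                         file.path(d, "concordance.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  write_bedmethyl(sites, file.path(d, "sites.tsv"))
  readr::write_tsv(segs, file.path(d, "pattern_regions.tsv"))
  outs <- file.path(d, c("sites.tsv", "pattern_regions.tsv"))
  write_manifest(config, "meth", p, bsas_path, outs)
  invisible(list(sites = sites, regions = segs, bsas = bsites,
                 concordance = conc))
}

#' Consolidate stage outputs into one machine-readable report
#'
#' Aggregates whatever stages have run (QC counts, fusion calls, SNV calls
#' and comparison cells, methylation regions and concordance) into a
#' schema-versioned JSON plus a long-format TSV summary; absent stages are
#' marked as such.
#'
#' @param config config list.
#' @return the report list, invisibly.
#' @export
make_report <- function(config) {
  config <- validate_config(config)
  d <- stage_dir(config, "report")
  rd <- function(stage, file) {
    pth <- file.path(config$out_dir, stage, file)
    if (file.exists(pth)) readr::read_tsv(pth, show_col_types = FALSE) else NULL
  }
  qc <- rd("qc", "roi_report.tsv")
  fus <- rd("fusion", "fusions.tsv")
  snv <- rd("snv", "calls.tsv")
  cells <- rd("compare_callers", "intersection_cells.tsv")
  meth <- rd("meth", "pattern_regions.tsv")
  conc_path <- file.path(config$out_dir, "meth", "concordance.json")
  conc <- if (file.exists(conc_path)) jsonlite::read_json(conc_path) else NULL
  present <- !vapply(list(qc, fus, snv, meth), is.null, logical(1))
  if (!any(present) && is.null(cells)) abort("no stage outputs to report")
  report <- list(
    schema_version = "1.0",
    qc = if (is.null(qc)) "absent" else qc,
    fusion = if (is.null(fus)) "absent" else fus,
    snv = if (is.null(snv)) "absent" else snv,
    comparison = if (is.null(cells)) "absent" else cells,
    methylation = if (is.null(meth)) "absent" else
      list(regions = meth, concordance = conc)
  )
  jsonlite::write_json(report, file.path(d, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  summary <- dplyr::bind_rows(
    if (!is.null(qc)) tibble(stage = "qc", metric = paste0("reads_covering_", qc$name),
                             value = as.numeric(qc$n_fully_covering)),
    if (!is.null(fus)) tibble(stage = "fusion", metric = "n_calls",
                              value = as.numeric(nrow(fus))),
    if (!is.null(snv)) tibble(stage = "snv", metric = "n_calls",
                              value = as.numeric(nrow(snv))),
    if (!is.null(conc) && !is.null(conc$r))
      tibble(stage = "meth", metric = "bsas_pearson_r",
             value = as.numeric(conc$r))
  )
  readr::write_tsv(summary, file.path(d, "summary.tsv"))
  write_manifest(config, "report", list(), character(0),
                 file.path(d, c("report.json", "summary.tsv")))
  invisible(report)
}
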
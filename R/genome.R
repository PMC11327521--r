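#' Default layout for the two-chromosome toy genome
#'
#' Describes a desk-scale genome that mirrors the geometry of a Cas9-targeted
#' fusion-gene experiment: `toy22` carries a promoter, a CpG island and a
#' major-breakpoint-cluster-like intron; `toy9` carries an intron-1 analog and
#' a kinase-domain-like region of interest. Four guide RNAs flank/cover three
#' ROIs. All coordinates are 0-based half-open.
#'
#' The crRNA table specifies each guide by its blunt-cut boundary (`cut`) and
#' the side of the cut the enriched fragment lies on (`direction`: `+1` reads
#' extend towards increasing coordinates, `-1` decreasing). The protospacer is
#' placed on the strand that puts the PAM on the opposite side of the cut from
#' the enriched fragment, so reads run away from the PAM, and the cut sits 3 nt
#' PAM-proximal as for SpCas9. The `+`/`-` suffix in the guide name records the
#' fragment direction.
#'
#' @return a list with `chrom_sizes`, `features` (tibble: name, chrom, start,
#'   end, role) and `crrnas` (tibble: name, chrom, cut, direction).
#' @export
toy_genome_layout <- function() {
  list(
    chrom_sizes = c(toy22 = 60000L, toy9 = 60000L),
    cpg_spacing = 20L,
    features = tibble::tribble(
      ~name,                 ~chrom,  ~start,  ~end,    ~role,
      "BCR_promoter",        "toy22", 3600L,   4800L,   "promoter",
      "BCR_CpG_island",      "toy22", 4800L,   6800L,   "CpG_island",
      "ROI_promoter_island", "toy22", 3400L,   7000L,   "ROI",
      "BCR_exon13",          "toy22", 11800L,  12000L,  "exon",
      "BCR_intron13",        "toy22", 12000L,  14900L,  "intron",
      "BCR_exon14",          "toy22", 14900L,  15000L,  "exon",
      "BCR_intron14",        "toy22", 15000L,  21000L,  "intron",
      "ROI_Mbcr",            "toy22", 16100L,  17900L,  "ROI",
      "ABL1_exon1",          "toy9",  3800L,   4000L,   "exon",
      "ABL1_intron1",        "toy9",  4000L,   12000L,  "intron",
      "ROI_ABL1_KD",         "toy9",  34500L,  39800L,  "ROI"
    ),
    crrnas = tibble::tribble(
      ~name,               ~chrom,  ~cut,    ~direction,
      "BCR-3000 crRNA+",   "toy22", 3000L,   1L,
      "BCR-16000 crRNA+",  "toy22", 16000L,  1L,
      "BCR-18000 crRNA+",  "toy22", 18000L,  1L,
      "ABL1-40000 crRNA-", "toy9",  40000L, -1L
    )
  )
}

#' Generate a seeded toy genome with planted PAM sites and a CpG island
#'
#' Draws random uniform DNA for each chromosome, plants a CpG dinucleotide
#' every `cpg_spacing` bases across every CpG-island feature, then plants an
#' NGG PAM (on the protospacer strand) for every configured crRNA and records
#' the resulting 20-nt spacer sequence and expected blunt-cut boundary.
#' Deterministic for a given `(config, seed)`.
#'
#' @param config layout list as returned by [toy_genome_layout()].
#' @param seed integer seed for the sequence draw.
#' @return an object of class `toy_genome`: list with `chromosomes` (named
#'   character vector), `features` (tibble) and `crrnas` (tibble with columns
#'   name, chrom, spacer_seq, strand, pam_start, pam_end, expected_cut,
#'   direction).
#' @export
make_toy_genome <- function(config = toy_genome_layout(), seed = 1) {
  check_seed(seed)
  sizes <- config$chrom_sizes
  feats <- as_tibble(config$features)
  bad <- feats$end > sizes[feats$chrom] | feats$start < 0 | feats$start >= feats$end
  if (any(bad)) {
    abort(paste0("feature layout exceeds chromosome bounds: ",
                 paste(feats$name[bad], collapse = ", ")))
  }
  if (any(sizes < 10000L)) abort("chromosome sizes must be >= 10 kb")

  chroms <- vapply(sizes, random_dna, character(1))

  ## plant CpGs across island features so the methylation substrate is dense
  spacing <- config$cpg_spacing %||% 20L
  islands <- dplyr::filter(feats, .data$role == "CpG_island")
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    pos <- seq(isl$start + 5L, isl$end - 2L, by = spacing)
    chroms[[isl$chrom]] <- replace_bases(
      chroms[[isl$chrom]],
      c(rbind(pos, pos + 1L)),
      rep(c("C", "G"), times = length(pos))
    )
  }

  ## place PAMs and derive spacer/cut geometry for each crRNA
  cr <- as_tibble(config$crrnas)
  cr$strand <- ifelse(cr$direction > 0, "-", "+")
  cr$pam_start <- ifelse(cr$direction > 0, cr$cut - 6L, cr$cut + 3L)
  cr$pam_end <- cr$pam_start + 3L
  cr$expected_cut <- cr$cut
  for (i in seq_len(nrow(cr))) {
    g <- cr[i, ]
    if (g$pam_start < 0 || g$pam_end > sizes[g$chrom]) {
      abort(paste0("PAM interval out of bounds for ", g$name))
    }
    ## NGG on the spacer strand: plus-strand genome shows NGG (+) or CCN (-)
    if (g$strand == "+") {
      chroms[[g$chrom]] <- replace_bases(chroms[[g$chrom]],
                                         c(g$pam_start + 1L, g$pam_start + 2L),
                                         c("G", "G"))
    } else {
      chroms[[g$chrom]] <- replace_bases(chroms[[g$chrom]],
                                         c(g$pam_start, g$pam_start + 1L),
                                         c("C", "C"))
    }
  }
  cr$spacer_seq <- vapply(seq_len(nrow(cr)), function(i) {
    g <- cr[i, ]
    if (g$strand == "+") {
      subseq0(chroms[[g$chrom]], g$pam_start - 20L, g$pam_start)
    } else {
      revcomp(subseq0(chroms[[g$chrom]], g$pam_end, g$pam_end + 20L))
    }
  }, character(1))

  genome <- structure(
    list(chromosomes = chroms,
         features = feats,
         crrnas = dplyr::select(cr, "name", "chrom", "spacer_seq", "strand",
                                "pam_start", "pam_end", "expected_cut",
                                "direction")),
    class = "toy_genome"
  )
  ## invariant: each island really is CpG-dense
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    ncpg <- length(cpg_positions(chroms[[isl$chrom]], isl$start, isl$end))
    if (ncpg < 20L) abort("CpG island ended up with fewer than 20 CpGs")
  }
  genome
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("<toy_genome> ", length(x$chromosomes), " chromosomes (",
      paste(sprintf("%s: %d bp", names(x$chromosomes),
                    nchar(x$chromosomes)), collapse = ", "),
      ")\n", sep = "")
  cat(nrow(x$features), "features,", nrow(x$crrnas), "crRNAs\n")
  invisible(x)
}

#' Look up a named feature interval
#' @param genome a `toy_genome`.
#' @param name feature name.
#' @return one-row tibble (chrom, start, end).
#' @export
feature_region <- function(genome, name) {
  f <- dplyr::filter(genome$features, .data$name == !!name)
  if (nrow(f) == 0L) abort(paste0("no feature named ", name))
  dplyr::select(f[1, ], "chrom", "start", "end")
}

#' Construct an allele from whole reference chromosomes
#' @param genome a `toy_genome`.
#' @param chrom chromosome name.
#' @param name allele name (defaults to the chromosome name).
#' @return an `allele` object: list(name, sequence, segments tibble).
#' @export
chromosome_allele <- function(genome, chrom, name = chrom) {
  seq <- genome$chromosomes[[chrom]]
  structure(list(
    name = name,
    sequence = seq,
    segments = tibble(chrom = chrom, start = 0L, end = nchar(seq))
  ), class = "allele")
}

#' Build a fusion allele by joining two chromosomes at breakpoint boundaries
#'
#' The allele is `chromA[0, bpA)` followed by `chromB[bpB, end)`, the standard
#' head-to-tail geometry of a reciprocal-translocation derivative chromosome.
#' Breakpoints are 0-based inter-base boundaries.
#'
#' @param genome a `toy_genome`.
#' @param bpA,bpB breakpoint boundaries on `chromA` / `chromB`.
#' @param chromA,chromB partner chromosomes (defaults toy22 / toy9).
#' @param name allele name.
#' @return an `allele` with a two-segment map and a `junction` attribute
#'   recording `(chromA, bpA, chromB, bpB)`.
#' @export
make_fusion_allele <- function(genome, bpA, bpB, chromA = "toy22",
                               chromB = "toy9", name = "fusion") {
  lenA <- nchar(genome$chromosomes[[chromA]])
  lenB <- nchar(genome$chromosomes[[chromB]])
  if (bpA < 0 || bpA > lenA || bpB < 0 || bpB > lenB) {
    abort("breakpoint boundary outside chromosome")
  }
  seq <- paste0(subseq0(genome$chromosomes[[chromA]], 0L, bpA),
                subseq0(genome$chromosomes[[chromB]], bpB, lenB))
  segs <- tibble(chrom = c(chromA, chromB),
                 start = c(0L, as.integer(bpB)),
                 end = c(as.integer(bpA), lenB))
  segs <- segs[segs$end > segs$start, , drop = FALSE]
  structure(list(name = name, sequence = seq, segments = segs,
                 junction = tibble(chromA = chromA, bpA = as.integer(bpA),
                                   chromB = chromB, bpB = as.integer(bpB))),
            class = "allele")
}

#' Plant heterozygous/homozygous SNVs in a region
#'
#' Chooses `n` distinct positions uniformly in `region` and assigns each a
#' non-reference alternate base and an allele fraction (0.5 = heterozygous).
#'
#' @param genome a `toy_genome`.
#' @param region one-row data frame or list with chrom/start/end.
#' @param n number of SNVs.
#' @param vaf allele fraction in (0, 1].
#' @param seed integer seed.
#' @return tibble (chrom, pos, ref, alt, vaf), sorted by position.
#' @export
plant_snvs <- function(genome, region, n, vaf = 0.5, seed = 1) {
  region <- as_region(region)
  check_seed(seed)
  stopifnot(vaf > 0, vaf <= 1, n >= 0)
  width <- region$end - region$start
  if (n > width) abort("more SNVs requested than positions in region")
  if (n == 0L) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character(), vaf = double()))
  }
  pos <- sort(sample.int(width, n) - 1L + region$start)
  ref <- strsplit(subseq0(genome$chromosomes[[region$chrom]],
                          region$start, region$end), "")[[1]][pos - region$start + 1L]
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  tibble(chrom = region$chrom, pos = pos, ref = ref, alt = unname(alt), vaf = vaf)
}

#' Per-CpG-site methylation probabilities with a high-low-high pattern
#'
#' Scans the CpG island for CpG dinucleotides (plus-strand C coordinate) and
#' assigns each site the Bernoulli methylation probability of its run:
#' `p_high` in the two flanking runs and `p_low` in the middle run, the
#' hyper/hypo/hyper geometry typical of a partially methylated CpG island.
#'
#' @param genome a `toy_genome`.
#' @param island one-row data frame or list with chrom/start/end; defaults to
#'   the genome's CpG-island feature.
#' @param p_high,p_low run probabilities, `0 <= p_low < p_high <= 1` (equality
#'   permitted for a flat profile).
#' @param boundaries two interior boundaries splitting the island into three
#'   runs; defaults to thirds.
#' @return tibble (chrom, pos, p, run) with run in `c("high","low","high")`.
#' @export
methylation_profile <- function(genome, island = NULL, p_high = 0.9,
                                p_low = 0.1, boundaries = NULL) {
  island <- as_region(island %||% dplyr::filter(genome$features,
                                                .data$role == "CpG_island")[1, ])
  stopifnot(p_low >= 0, p_high <= 1, p_low <= p_high)
  if (is.null(boundaries)) {
    third <- (island$end - island$start) / 3
    boundaries <- round(island$start + c(third, 2 * third))
  }
  boundaries <- as.integer(boundaries)
  if (length(boundaries) != 2L || any(boundaries <= island$start) ||
      any(boundaries >= island$end) || boundaries[1] >= boundaries[2]) {
    abort("boundaries must lie strictly inside the island, in order")
  }
  pos <- cpg_positions(genome$chromosomes[[island$chrom]], island$start, island$end)
  run <- ifelse(pos < boundaries[1], "high",
                ifelse(pos < boundaries[2], "low", "high"))
  tibble(chrom = island$chrom, pos = pos,
         p = ifelse(run == "high", p_high, p_low), run = run)
}

#' Default ~200 bp bisulfite-amplicon regions, one per methylation run
#' @param genome a `toy_genome`.
#' @return tibble (region_id, chrom, start, end).
#' @export
default_bsas_regions <- function(genome) {
  isl <- as_region(dplyr::filter(genome$features, .data$role == "CpG_island")[1, ])
  third <- (isl$end - isl$start) / 3
  mids <- round(isl$start + third * (c(1, 2, 3) - 0.5))
  tibble(region_id = paste0("BSP", 1:3), chrom = isl$chrom,
         start = as.integer(mids - 100L), end = as.integer(mids + 100L))
}

#' Bundle simulation ground truth
#'
#' @param genome a `toy_genome`.
#' @param fusion a fusion `allele` (or NULL).
#' @param snvs tibble from [plant_snvs()].
#' @param profile tibble from [methylation_profile()].
#' @param jitter maximum cut-end offset in bp.
#' @param seed the master seed.
#' @return a `truth_set` list.
#' @export
make_truth_set <- function(genome, fusion = NULL, snvs = NULL, profile = NULL,
                           jitter = 2L, seed = 1L) {
  if (!is.null(snvs) && nrow(snvs)) {
    refs <- vapply(seq_len(nrow(snvs)), function(i) {
      subseq0(genome$chromosomes[[snvs$chrom[i]]], snvs$pos[i], snvs$pos[i] + 1L)
    }, character(1))
    if (!all(refs == snvs$ref)) abort("SNV ref base does not match genome")
  }
  if (!is.null(profile) && any(profile$p < 0 | profile$p > 1)) {
    abort("methylation probabilities must lie in [0, 1]")
  }
  structure(list(
    fusion = if (!is.null(fusion)) fusion$junction else NULL,
    snvs = snvs %||% tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(), vaf = double()),
    profile = profile %||% tibble(chrom = character(), pos = integer(),
                                  p = double(), run = character()),
    jitter = as.integer(jitter), seed = as.integer(seed)
  ), class = "truth_set")
}

#' Write / read a truth set as JSON
#' @param truth a `truth_set`.
#' @param path output path.
#' @return `path`, invisibly (writer); a `truth_set` (reader).
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$snvs <- as_tibble(x$snvs)
  x$profile <- as_tibble(x$profile)
  if (!is.null(x$fusion)) x$fusion <- as_tibble(x$fusion)
  structure(x, class = "truth_set")
}
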
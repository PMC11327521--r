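---
title: "Methods: simulating and analysing Cas9-targeted nanopore sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Cas9-targeted nanopore sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncatsr)
library(dplyr)
```

## The assay and what the package computes

Nanopore Cas9-targeted sequencing (nCATS) enriches native DNA without
amplification: guide RNAs direct Cas9 to blunt-cut the genome at chosen sites,
sequencing adaptors ligate preferentially to the fresh cut ends, and the
flanked fragments dominate the resulting long-read library. Because the DNA is
native, a single run supports three read-outs at once:

* **structural variation** — a fusion junction shows up as chimeric (split)
  alignments: consecutive parts of one read mapping to two loci;
* **small variants** — SNVs in a kinase-domain-like region called from a
  pileup;
* **epigenetics** — 5-methylcytosine at CpG sites, carried per read in SAM
  MM/ML base-modification tags and aggregated into per-site frequencies.

`ncatsr` implements the full analysis path for such data plus a seeded
simulator of the assay, so that every stage is testable on a desk without any
download. All functions take and return tibbles; coordinates are 0-based
half-open internally and only become 1-based at SAM/VCF emission.

## The toy genome and guide geometry

`make_toy_genome()` draws two uniform-random chromosomes (`toy22`, `toy9`,
60 kb each by default) and plants the features the assay needs: a promoter and
a 2 kb CpG island on `toy22` (a CpG dinucleotide every 20 bp, plus whatever
CpGs occur by chance), intron/exon annotation mimicking a major breakpoint
cluster region, a kinase-domain-like ROI on `toy9`, and an NGG PAM for every
configured guide.

Guides are specified by their blunt-cut boundary and the side of the cut the
enriched fragment lies on (the `+`/`-` suffix in names such as
`BCR-3000 crRNA+`). The protospacer is placed on whichever strand puts the PAM
on the *opposite* side of the cut from the enriched fragment, and the cut sits
3 nt PAM-proximal, the SpCas9 rule. Reads therefore run *away from* the PAM
into the region of interest — the geometry that makes cut-site QC informative:
an on-target read's first (or last) aligned base should coincide with the
expected cut up to end jitter.

## The read simulator

`simulate_reads()` works per allele. An allele is a sequence plus an ordered
segment map back to reference chromosomes; `make_fusion_allele(genome, bpA,
bpB)` builds the derivative-chromosome allele `toy22[0, bpA) + toy9[bpB, end)`
so fusion-spanning reads acquire two truth segments on different chromosomes.
For every guide cut present on an allele it generates `n_reads` reads:

* **start** at the cut plus a discrete-uniform jitter on `-jitter:jitter`
  (default ±2 bp; the end-offset distribution of real Cas9 cuts is not
  standardised, so a small symmetric window is used);
* **length** from a truncated normal (mean 8 kb, sd 1 kb, bounds 6–12 kb),
  long enough that every ROI is fully contained by its guide's reads;
* **haplotype** by a fair coin at the configured allele fraction (0.5 =
  heterozygous); alt-bearing reads carry all planted SNVs (phased);
* **methylation** per CpG site as Bernoulli(profile probability), flipped
  with probability `meth_call_error` (default 1%) to emulate caller error,
  then encoded as `C+m?` MM/ML tags;
* **errors** injected per base — substitutions (default 1%) and single-base
  insertions/deletions (default 0.25% each, i.e. 0.5% indel total) — with the
  truth CIGAR updated accordingly, so the truth SAM behaves like a real
  aligner's output including end erosion by indels.

Reads whose fragment extends leftwards are emitted as the reverse complement
of their molecule; their SAM records keep molecule-orientation SEQ with FLAG
16, and their methylation tags mark the complementary-strand cytosine (the G
of the CpG in molecule space), which the decoder projects back to the
plus-strand C under the symmetric-CpG assumption. This exercises the same
strand bookkeeping a real base-modification pipeline requires.

Per-base qualities are constant (default Q20) and errors are injected
independently of them: the simplest model that still drives quality-aware code
paths. The per-column error rate the SNV caller derives from qualities
(`10^(-Q/10)` = 0.01 at Q20) therefore matches the injected substitution rate
by construction — a deliberate coherence, not a calibration.

The defaults (250 reads per cut per allele in the pipeline's diploid-like
scenario, hence ~500 reads per ROI; 1% substitutions; ±2 bp jitter;
high–low–high island profile at 0.9/0.1/0.9) are the study-like conditions the
acceptance checks run under.

## Fusion detection

`find_chimeric_junctions()` scans each read's segments in query order and
emits an observation for every adjacent pair that passes three filters:
both segments at least `min_segment` = 200 bp (shorter nanopore fragments
align promiscuously), query gap at most `max_query_gap` = 100 bp (a real
junction leaves few unaligned bases), and different chromosomes or loci more
than 10 kb apart. The junction coordinate convention is *last aligned base of
the query-5′ partner / first aligned base of the query-3′ partner*,
strand-aware. Observations are canonicalised so the lexicographically smaller
breakpoint is partner A, complementing the strand pair on a flip — otherwise
reads sequenced in the two directions across one junction would form two
orientation-split clusters.

`cluster_junctions()` links observations sharing `(chromA, chromB,
orientation)` whenever both coordinates agree within `tolerance` = 50 bp
(single linkage, exact pairwise), takes the coordinate-wise median as the
consensus — lower of the two middles for even cluster sizes, a deterministic
tie-break robust to outlier split points — and drops clusters below
`min_support` = 3 reads. Dropped observations are counted so support is
conserved. `classify_fusion()` maps the intron containing each consensus
coordinate through a configurable table (intron 13 → b2a2, intron 14 → b3a2
against an intron-1 partner), labelling anything else `unclassified`.

With 1% substitution and 0.5% indel error, only an indel landing exactly on a
junction-adjacent base can shift one read's observed breakpoint, so the median
of even a handful of spanning reads recovers the truth boundary exactly; at
~8% total error the consensus stays within a few bases.

## SNV calling and caller-comparison analytics

`build_pileup()` walks CIGARs to tally per-column base counts, spanning
deletions (which still consume depth, the convention of standard depth tools),
anchored insertions and summed base qualities; bases under the Q7 floor are
masked. `call_snvs()` evaluates three genotypes per column — homozygous
reference, heterozygous, homozygous alternate — as binomial likelihoods of the
alternate count at alt fractions `e`, 0.5 and `1 − e`, where `e` is the
column's mean base-error probability floored at 0.001. With a flat prior,
`QUAL = −10·log10 P(RR | data)`. Thresholds (depth ≥ 10, alt count ≥ 4, alt
fraction ≥ 0.2, QUAL ≥ 20) gate the emitted maximum-a-posteriori
non-reference genotype. The model is deliberately transparent: unit tests
check its posteriors against a brute-force enumeration, and its QUAL is
provably non-decreasing in depth at fixed allele fraction.

The comparison analytics are caller-agnostic set operations on
`(chrom, pos, ref, alt)` keys: `intersect_callsets()` computes exact disjoint
UpSet-style cells (with an optional key allowlist standing in for an
annotation filter), `depth_effect()` summarises depth per cell and reports a
point-biserial correlation with the detected-by-all indicator (defined as 0
under zero variance), and `qual_depth_correlation()` is a per-caller Pearson
correlation — per caller only, since QUAL scales are not comparable across
callers. External VCFs enter through `read_snv_vcf()`.

## Methylation aggregation and bisulfite concordance

`read_meth_tags()` binarises ML probabilities at 0.5 (ties methylated) and
projects tag positions through the CIGAR; sites lost to deletions or
substitutions simply provide no evidence. `aggregate_sites()` sums the binary
calls per plus-strand CpG coordinate, flagging sites under 5 informative
reads. `segment_pattern()` labels sites hypo (< 0.3) / hyper (> 0.7) /
intermediate and merges runs shorter than `min_run` = 3 into the flanking run
with the nearer mean, yielding the region-level hypo/hyper architecture.
`bsas_call()` turns bisulfite-amplicon retained/converted counts into
frequencies, with an optional conversion-efficiency correction
`(raw − (1 − c)) / c` clamped to [0, 1]; the default `c = 1` applies no
correction. `meth_concordance()` inner-joins the two assays on site identity
(depth ≥ 5 in both) and reports Pearson's r with the mean absolute
difference, declining to report r for fewer than 3 pairs or zero variance.

Region means are unweighted across sites: weighting by depth would let a few
deep sites dominate a ~200 bp amplicon summary.

## Pipeline, configuration and determinism

Stages (`simulate`, `qc`, `fusion`, `snv`, `compare-callers`, `meth`,
`report`) communicate only through files in standard formats (FASTA, FASTQ,
SAM, VCF, BED/bedGraph/BEDPE, TSV, JSON) under `out_dir/<stage>/`, so any
input can be swapped for an external tool's output — a real BAM into `qc`, a
real caller's VCF into `compare-callers`. One YAML config drives everything;
unknown keys are rejected before any write. Every stage writes a manifest
with its parameters, derived seed and output MD5 hashes, and each per-stage
seed is `(global seed + sum of UTF-8 codes of the stage name) mod (2^31 − 1)`,
so stages are decoupled yet fully reproducible. `inst/cli/ncats.R` is a thin
Rscript wrapper over `run_stage()`.

## What the simulator does and does not establish

The simulator emulates cut-anchored read starts, chimeric fusion reads,
haplotyped SNVs, Bernoulli per-read methylation with MM/ML encoding, and
uniform substitution/indel noise. It does **not** model basecaller-specific
artefacts (homopolymer compression, context-dependent error, miscalibrated
modification probabilities), alignment ambiguity around junctions, mapping
bias, or off-target Cas9 activity. Green tests therefore demonstrate that the
*analysis logic* is correct under controlled noise — conventions, arithmetic,
clustering, likelihoods, joins — not that real-data performance will match;
real alignments and real caller VCFs should be run through the same stages
for that (see `scripts/validate_real_data.R`).

Problem sizes were chosen for desk-scale runs: 60 kb chromosomes, 6–12 kb
reads, up to ~500× ROI depth in the acceptance scenario and 10–30 reads per
cut in unit tests.

## Numerical and edge-case choices

* Median consensus uses the lower middle for even n (deterministic).
* Genotype posteriors are computed in log space with a log-sum-exp
  normalisation; QUAL is capped at 10^5.
* Zero-variance correlations are reported as absent with a reason (Pearson)
  or defined as 0 (point-biserial), each stated in the function docs.
* Empty inputs produce typed empty tibbles or header-only files, never
  errors, except where the contract requires inputs (e.g. regions must be
  non-empty for `region_means()`).
* Leading/trailing deletions at a truth-segment edge are trimmed from the
  CIGAR and the reference interval shifted, as an aligner would report.
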
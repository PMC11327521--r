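#!/usr/bin/env Rscript

## Optional real-data validation (not run in CI): given a BAM of nCATS reads
## aligned to hg38 with minimap2 and a features TSV annotating BCR/ABL1
## introns, runs the split-read fusion stage and prints the consensus
## breakpoints for comparison with the published K562 coordinates
## (Chr22:23290555 / Chr9:130731760, b3a2).
##
##   Rscript scripts/validate_real_data.R <alignments.bam> <features.tsv>

suppressPackageStartupMessages(library(ncatsr))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: validate_real_data.R <alignments.bam> [features.tsv]")
}
aln <- read_alignments(args[1])
calls <- cluster_junctions(find_chimeric_junctions(group_by_read(aln)))
if (length(args) >= 2L) {
  features <- readr::read_tsv(args[2], show_col_types = FALSE)
  calls <- classify_fusion(calls, features)
}
print(tidy(calls))
cat("\n(1-based breakpoint coordinates:)\n")
for (i in seq_len(nrow(calls))) {
  cat(sprintf("  %s:%d | %s:%d  support=%d\n", calls$chromA[i],
              calls$posA[i] + 1L, calls$chromB[i], calls$posB[i] + 1L,
              calls$n_supporting_reads[i]))
}
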
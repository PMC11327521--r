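#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join inner_join n row_number across all_of desc
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rnorm runif median quantile cor setNames dbinom
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement (A<->T, C<->G); IUPAC ambiguity codes
#' other than N are not expected in this package's synthetic sequences.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## substring on 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

## replace bases at 0-based positions
replace_bases <- function(seq, pos0, bases) {
  if (length(pos0) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos0 + 1L] <- bases
  paste(ch, collapse = "")
}

## all 0-based positions of the C of CpG dinucleotides in [start, end)
cpg_positions <- function(seq, start = 0L, end = nchar(seq)) {
  sub <- subseq0(seq, start, end)
  hits <- gregexpr("CG", sub, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L + start
}

phred_string <- function(q, len) {
  strrep(rawToChar(as.raw(q + 33L)), len)
}

## region argument: accept a one-row data frame (chrom/start/end) or a
## list/vector with named elements
as_region <- function(region) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- as.list(region)
  }
  if (is.null(region$chrom) || is.null(region$start) || is.null(region$end)) {
    abort("region must provide chrom, start and end (0-based half-open)")
  }
  list(chrom = as.character(region$chrom),
       start = as.integer(region$start),
       end = as.integer(region$end))
}

check_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    set.seed(as.integer(seed))
  }
  invisible(seed)
}
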
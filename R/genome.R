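#' Canonical SBS-96 trinucleotide context labels
#'
#' Returns the 96 single-base-substitution categories in the fixed order used
#' throughout the package: the six pyrimidine substitutions (C>A, C>G, C>T,
#' T>A, T>C, T>G), each expanded over the 16 flanking-base combinations, as
#' labels of the form `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs_contexts <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (f5 in bases)
      for (f3 in bases)
        out <- c(out, paste0(f5, "[", s, "]", f3))
  out
}

#' Miniature genome arm definitions
#'
#' A 22-arm toy genome (11 chromosomes, p and q arms) totalling ~2.85 Mb,
#' used by the synthetic-cohort generator and as the default arm table for
#' copy-number scoring. Coordinates are 1-based inclusive; arms tile each
#' chromosome without overlap. Chromosome names follow a subset of the human
#' karyotype so that the planted deletion arm can be called "16q".
#'
#' @return A data.frame with columns `arm`, `chrom`, `start`, `end`.
#' @export
default_arm_table <- function() {
  chroms <- c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6",
              "chr7", "chr8", "chr16", "chr17", "chr20")
  p_kb <- c(200, 180, 150, 140, 130, 120, 110, 90, 70, 60, 50)
  q_kb <- c(220, 200, 170, 160, 150, 140, 130, 150, 90, 80, 60)
  arms <- data.frame(
    arm = character(0), chrom = character(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(chroms)) {
    p_len <- p_kb[i] * 1000L
    q_len <- q_kb[i] * 1000L
    nm <- sub("^chr", "", chroms[i])
    arms <- rbind(arms, data.frame(
      arm = paste0(nm, c("p", "q")),
      chrom = chroms[i],
      start = c(1L, p_len + 1L),
      end = c(p_len, p_len + q_len),
      stringsAsFactors = FALSE))
  }
  arms
}

#' Read an arm-definition table
#'
#' @param path TSV with columns `arm`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @return data.frame as [default_arm_table()].
#' @export
read_arm_table <- function(path) {
  arms <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(arms, c("arm", "chrom", "start", "end"), "arm table")
  if (any(arms$end < arms$start)) stop("arm table has end < start")
  arms
}
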
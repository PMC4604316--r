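#' Majority-rule consensus of an alignment
#'
#' Per column, the most frequent base among `A`, `C`, `G`, `T`; gaps and `N`
#' are not nucleotides and are excluded from the vote. Ties are broken toward
#' the lexicographically smallest base (A < C < G < T) so the result is
#' deterministic. A column with no informative base (all gap/N) yields `-`.
#'
#' @param aln an [alignment()].
#' @return single consensus sequence string.
#' @export
build_consensus <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  m <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(m == b),
                   numeric(ncol(m)))           # columns x 4
  counts <- matrix(counts, ncol = 4, dimnames = list(NULL, bases))
  pick <- bases[max.col(counts, ties.method = "first")]
  pick[rowSums(counts) == 0] <- "-"
  paste(pick, collapse = "")
}

#' Percent similarity of an aligned sequence to a consensus
#'
#' Compared over the columns where both sequences carry a real nucleotide
#' (`A/C/G/T`); gap and `N` columns contribute to neither the difference count
#' nor the denominator. Similarity = 100 * (1 - differences / compared),
#' reported to one decimal.
#'
#' @param seq aligned sequence string (same length as `consensus`).
#' @param consensus consensus sequence string.
#' @return similarity percent, rounded to 1 decimal.
#' @export
similarity_to_consensus <- function(seq, consensus) {
  seq <- toupper(seq); consensus <- toupper(consensus)
  if (nchar(seq) != nchar(consensus))
    stop("sequence and consensus must have equal aligned length")
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  acgt <- c("A", "C", "G", "T")
  comparable <- a %in% acgt & b %in% acgt
  n <- sum(comparable)
  if (n == 0L)
    stop("no comparable columns (similarity undefined)")
  round(100 * (1 - sum(a[comparable] != b[comparable]) / n), 1)
}

#' Per-strain similarity to the alignment consensus
#'
#' Builds the majority consensus and scores every sequence against it,
#' mirroring the 16S identity column of a genome-statistics table.
#'
#' @param aln an [alignment()].
#' @return data frame with columns `strain_id` and `similarity` (percent, 1
#'   decimal), in alignment order.
#' @export
consensus_similarity <- function(aln) {
  cons <- build_consensus(aln)
  data.frame(
    strain_id = names(aln),
    similarity = vapply(unclass(aln), similarity_to_consensus, numeric(1),
                        consensus = cons, USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}
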
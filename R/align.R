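# Pairwise protein alignment (the similarity oracle behind clustering and
# AAI) and seed-and-extend local nucleotide alignment used by the classical
# matchers, population clustering and dereplication.
#
# Protein alignment is ends-free global (overlap) under BLOSUM62 with
# affine gaps (open 11, extend 1).  Identity is matches over alignment
# columns between the outermost aligned residue pairs (terminal overhangs
# excluded); coverage is the aligned span of each sequence over its length.

#' Globally align two protein sequences
#'
#' @param a,b amino-acid strings (standard residues plus X).
#' @param gap_open,gap_ext affine gap penalties.
#' @return list with identity, cov_a, cov_b, score and the aligned spans.
#' @export
align_pair <- function(a, b, gap_open = 11, gap_ext = 1) {
  stopifnot(nchar(a) >= 1, nchar(b) >= 1)
  r <- .aa_align_pair_cpp(aa_codes(a), aa_codes(b), aa_submat(),
                          gap_open, gap_ext)
  list(identity = if (r$columns > 0) r$matches / r$columns else 0,
       cov_a = if (r$a_end > 0) (r$a_end - r$a_begin + 1) / nchar(a) else 0,
       cov_b = if (r$b_end > 0) (r$b_end - r$b_begin + 1) / nchar(b) else 0,
       score = r$score, matches = r$matches, columns = r$columns,
       a_begin = r$a_begin, a_end = r$a_end,
       b_begin = r$b_begin, b_end = r$b_end)
}

# align one coded query against a list of coded references; returns the
# matrix of (score, identity, cov_q, cov_r); rows of NA when the optional
# shared-word prefilter skipped the pair
#' @noRd
align_to_refs <- function(q_codes, ref_codes, gap_open = 11, gap_ext = 1,
                          prefilter_word = 0L) {
  .aa_align_many_cpp(q_codes, ref_codes, aa_submat(), gap_open, gap_ext,
                     as.integer(prefilter_word))
}

# Seed-and-extend best local nucleotide alignment.  Exact shared words
# seed candidate diagonals; each candidate band is aligned with a banded
# Smith-Waterman.  Both strands searched when both_strands is TRUE.
# Returns NULL when no seeds are found on either strand.
#' @noRd
nt_best_local <- function(a, b, word = 11, band = 64,
                          match = 1, mismatch = -2,
                          gap_open = 5, gap_ext = 2,
                          both_strands = TRUE, max_bands = 8) {
  best <- NULL
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    bs <- if (strand == "+") b else revcomp(b)
    hits <- .shared_kmers_cpp(a, bs, as.integer(word))
    if (nrow(hits) == 0) next
    d <- hits[, 2] - hits[, 1]
    # group seed diagonals into bands
    du <- sort(unique(d))
    grp <- cumsum(c(1L, diff(du) > band))
    cnt <- tapply(tabulate(match(d, du)), grp, sum)
    ord <- order(-cnt)
    for (g in head(names(cnt)[ord], max_bands)) {
      dg <- du[grp == as.integer(g)]
      lo <- min(dg) - band %/% 2
      hi <- max(dg) + band %/% 2
      if (hi - lo + 1 > 4 * band) { # cap band width
        mid <- dg[which.max(tabulate(match(d[d %in% dg], dg)))]
        lo <- mid - 2 * band
        hi <- mid + 2 * band
      }
      r <- .banded_local_nt_cpp(a, bs, as.integer(lo), as.integer(hi),
                                match, mismatch, gap_open, gap_ext)
      if (is.null(best) || r$score > best$score) {
        r$strand <- strand
        best <- r
      }
    }
  }
  if (is.null(best) || best$score <= 0) return(NULL)
  best$identity <- if (best$columns > 0) best$matches / best$columns else 0
  best$length <- best$columns
  best$qcov <- (best$a_end - best$a_begin + 1) / nchar(a)
  # bit score under the documented scoring (match=1 bit); expectation in
  # Karlin-Altschul form with calibration constant K
  best$bits <- best$score
  best$e_value <- karlin_evalue(best$bits, nchar(a), nchar(b))
  best
}
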
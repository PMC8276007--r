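# Shared residue coding, substitution scores, and small sequence helpers.

# standard 20 amino acids in BLOSUM order; code 20 = X
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
aa_submat <- function() {
  if (is.null(.hf_cache$submat)) {
    blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment())[1], envir = environment())
    keep <- c(AA20, "X")
    .hf_cache$submat <- unname(as.matrix(blosum[keep, keep]))
  }
  .hf_cache$submat
}

# integer codes 0..19 for standard residues, 20 for X; anything else errors
#' @noRd
aa_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(chars, AA20) - 1L
  codes[chars == "X"] <- 20L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("non-amino-acid symbols in sequence: ", paste(bad, collapse = ", "))
  }
  codes
}

#' @noRd
check_dna <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains symbols outside {A,C,G,T,N}")
  }
  invisible(seq)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# codon -> amino acid map (standard code); codons with N translate to X,
# and never act as start or stop because matching is exact
#' @noRd
codon_table <- function() {
  if (is.null(.hf_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- gsub("U", "T", names(gc))
    .hf_cache$codons <- gc
  }
  .hf_cache$codons
}

#' @noRd
translate_codons <- function(codons) {
  aa <- codon_table()[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Karlin-Altschul style expectation for a bit score
#' @noRd
karlin_evalue <- function(bits, m, n, K = 0.1) {
  K * m * n * 2^(-bits)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
new_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hostforest_error")))
}
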
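# FASTA readers/writers, the six-frame ORF extractor standing in for an
# external gene caller, and the profile-search hit-table interface.

#' Read a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are uppercased; in nucleotide mode U is converted to T.
#'
#' @param path FASTA file.
#' @param type "dna" or "protein".
#' @return data.frame with columns id, sequence, desc (full header line).
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      desc = character(), stringsAsFactors = FALSE))
  }
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (type == "dna") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  data.frame(id = ids, sequence = unname(seqs), desc = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids,seqs character vectors of equal length (or a data.frame with
#'   id/sequence columns passed as `ids`).
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(ids, seqs = NULL, path, width = 70) {
  if (is.data.frame(ids)) {
    df <- ids
    ids <- if ("desc" %in% names(df)) df$desc else df$id
    seqs <- df$sequence
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    s <- seqs[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(c(paste0(">", ids[i]),
                 substring(s, starts, pmin(starts + width - 1, nchar(s)))), con)
  }
  invisible(path)
}

#' Read viral/host genome records from FASTA
#'
#' Completeness (percent) may be encoded in the header as
#' `completeness=<value>`; absent values are unknown (NA).
#'
#' @param path FASTA file of nucleotide sequences.
#' @return data.frame: genome_id, sequence, source, completeness.
#' @export
read_genomes <- function(path) {
  fa <- read_fasta(path, "dna")
  comp <- rep(NA_real_, nrow(fa))
  hit <- regmatches(fa$desc, regexpr("completeness=[0-9.]+", fa$desc))
  has <- grepl("completeness=", fa$desc)
  comp[has] <- as.numeric(sub("completeness=", "", hit))
  data.frame(genome_id = fa$id, sequence = fa$sequence, source = fa$desc,
             completeness = comp, stringsAsFactors = FALSE)
}

#' Read protein records from FASTA
#'
#' Headers of the form `genomeid|ordinal begin end strand` carry the
#' coordinate metadata written by [write_proteins()]; other headers yield
#' records with unknown coordinates and the genome id taken from the part
#' of the id before the last `|` (or the whole id).
#'
#' @param path protein FASTA file.
#' @return data.frame: protein_id, genome_id, begin, end, strand, aa_sequence.
#' @export
read_proteins <- function(path) {
  fa <- read_fasta(path, "protein")
  parts <- strsplit(fa$desc, "\\s+")
  meta <- t(vapply(parts, function(p) {
    if (length(p) >= 4 && grepl("^[0-9]+$", p[2]) && grepl("^[0-9]+$", p[3])) {
      c(p[2], p[3], p[4])
    } else c(NA, NA, NA)
  }, character(3)))
  gid <- ifelse(grepl("|", fa$id, fixed = TRUE),
                sub("\\|[^|]*$", "", fa$id), fa$id)
  data.frame(protein_id = fa$id, genome_id = gid,
             begin = as.integer(meta[, 1]), end = as.integer(meta[, 2]),
             strand = meta[, 3], aa_sequence = fa$sequence,
             stringsAsFactors = FALSE)
}

#' @rdname read_proteins
#' @param proteins protein record data.frame.
#' @export
write_proteins <- function(proteins, path) {
  hdr <- paste(proteins$protein_id, proteins$begin, proteins$end,
               proteins$strand)
  hdr[is.na(proteins$begin)] <- proteins$protein_id[is.na(proteins$begin)]
  write_fasta(hdr, proteins$aa_sequence, path)
}

#' Extract open reading frames from a genome
#'
#' A deliberately simple six-frame caller: an ORF runs from an ATG to the
#' next in-frame stop (stop excluded from the translation) and must encode
#' at least `min_aa_len` residues.  Within one reading frame the first ATG
#' after the previous stop founds the (longest) ORF for that stop segment;
#' overlapping ORFs on different frames are all reported.  Coordinates are
#' 1-based inclusive on the forward strand and cover start through last
#' sense codon.  Codons containing N translate to X and never act as start
#' or stop.
#'
#' @param genome a single-row genome record data.frame (or list) with
#'   genome_id and sequence.
#' @param min_aa_len minimum protein length in residues (>= 20).
#' @return protein record data.frame (possibly empty), ordinals assigned in
#'   order of forward-strand begin coordinate.
#' @export
extract_orfs <- function(genome, min_aa_len = 60) {
  stopifnot(min_aa_len >= 20)
  gid <- genome$genome_id
  seq <- genome$sequence
  check_dna(seq, paste0("genome ", gid))
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      ncod <- (n - f) %/% 3
      if (ncod < 1) next
      pos <- seq(1 + f, by = 3, length.out = ncod)
      codons <- substring(s, pos, pos + 2)
      stop_idx <- which(codons %in% stops)
      seg_start <- 1L
      for (si in stop_idx) {
        rng <- seg_start:si
        starts <- rng[codons[rng] == "ATG"]
        starts <- starts[starts < si]
        if (length(starts)) {
          a <- starts[1]
          len <- si - a  # codons incl ATG, excl stop
          if (len >= min_aa_len) {
            aa <- paste(translate_codons(codons[a:(si - 1)]), collapse = "")
            b1 <- pos[a]
            b2 <- pos[si - 1] + 2
            if (strand == "+") {
              begin <- b1; end <- b2
            } else {
              begin <- n - b2 + 1; end <- n - b1 + 1
            }
            out[[length(out) + 1]] <- data.frame(
              genome_id = gid, begin = begin, end = end, strand = strand,
              aa_sequence = aa, stringsAsFactors = FALSE)
          }
        }
        seg_start <- si + 1L
      }
    }
  }
  if (!length(out)) {
    return(data.frame(protein_id = character(), genome_id = character(),
                      begin = integer(), end = integer(),
                      strand = character(), aa_sequence = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$begin, df$end, df$strand), , drop = FALSE]
  df <- data.frame(protein_id = paste0(gid, "|", seq_len(nrow(df))), df,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

HIT_COLS <- c("protein_id", "genome_id", "profile_id", "bit_score",
              "e_value", "q_span", "t_span")

#' Read / write a profile-search hit table
#'
#' Headered TSV with columns protein_id, genome_id, profile_id, bit_score,
#' e_value, q_span, t_span.  The interface lets production users substitute
#' an external profile-search program's tabular output for the built-in
#' scorer.
#'
#' @param path TSV file.
#' @return data.frame of typed hit rows.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(HIT_COLS, names(df))
  if (length(missing_cols)) {
    stop("hit table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[HIT_COLS]
  for (cn in c("bit_score", "e_value", "q_span", "t_span")) {
    df[[cn]] <- as.numeric(df[[cn]])
  }
  if (any(!is.finite(df$bit_score))) stop("non-finite bit_score in hit table")
  if (any(df$e_value < 0)) stop("negative e_value in hit table")
  if (any(df$q_span < 0 | df$q_span > 1 | df$t_span < 0 | df$t_span > 1)) {
    stop("spans must lie in [0,1]")
  }
  df
}

#' @rdname read_hit_table
#' @param rows hit row data.frame.
#' @export
write_hit_table <- function(rows, path) {
  out <- rows[HIT_COLS]
  for (cn in c("bit_score", "e_value", "q_span", "t_span")) {
    out[[cn]] <- formatC(out[[cn]], digits = 10, format = "g")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
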
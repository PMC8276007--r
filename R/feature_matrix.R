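# Score proteins against profile models, apply the hit filters
# (e-value <= 1e-5, >= 70% aligned span of both, score >= 50), assemble the
# genomes x protein-cluster best-bit-score matrix, and prune correlated
# clusters into superclusters (Pearson r >= 0.9, one representative kept).

#' Score one protein against a profile model
#'
#' Best local alignment of the protein against the profile columns with
#' affine gaps; the bit score is the alignment score in bits and the
#' expectation follows the Karlin-Altschul form
#' `K * m * (profile_length * db_factor) * 2^(-bits)`.
#'
#' @param profile a `profile_model`.
#' @param protein a protein record (list/row with protein_id, genome_id,
#'   aa_sequence) or a plain amino-acid string.
#' @param K calibration constant for the expectation.
#' @param db_factor effective database-size factor (number of profiles
#'   searched, for a full search).
#' @return a one-row hit data.frame, or NULL if the best score is <= 0.
#' @export
score_protein <- function(profile, protein, K = 0.1, db_factor = 1) {
  if (is.character(protein)) {
    protein <- list(protein_id = "query", genome_id = NA_character_,
                    aa_sequence = protein)
  }
  codes <- aa_codes(protein$aa_sequence)
  r <- .pssm_local_cpp(codes, profile$match_scores, profile$gap_open,
                       profile$gap_extend)
  if (r$score <= 0) return(NULL)
  m <- length(codes)
  data.frame(protein_id = protein$protein_id,
             genome_id = protein$genome_id %||% NA_character_,
             profile_id = profile$profile_id,
             bit_score = r$score,
             e_value = karlin_evalue(r$score, m, profile$length * db_factor, K),
             q_span = (r$q_end - r$q_begin + 1) / m,
             t_span = (r$t_end - r$t_begin + 1) / profile$length,
             stringsAsFactors = FALSE)
}

#' Score a protein set against all profiles
#'
#' @param proteins protein record data.frame.
#' @param profiles list of profile models.
#' @inheritParams score_protein
#' @return hit table data.frame (zero rows if nothing scores > 0).
#' @export
score_proteins <- function(proteins, profiles, K = 0.1,
                           db_factor = length(profiles)) {
  hits <- vector("list", nrow(proteins) * length(profiles))
  n <- 0L
  codes_list <- lapply(proteins$aa_sequence, aa_codes)
  for (i in seq_len(nrow(proteins))) {
    codes <- codes_list[[i]]
    m <- length(codes)
    for (p in profiles) {
      r <- .pssm_local_cpp(codes, p$match_scores, p$gap_open, p$gap_extend)
      if (r$score > 0) {
        n <- n + 1L
        hits[[n]] <- data.frame(
          protein_id = proteins$protein_id[i],
          genome_id = proteins$genome_id[i],
          profile_id = p$profile_id,
          bit_score = r$score,
          e_value = karlin_evalue(r$score, m, p$length * db_factor, K),
          q_span = (r$q_end - r$q_begin + 1) / m,
          t_span = (r$t_end - r$t_begin + 1) / p$length,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n == 0L) {
    return(data.frame(protein_id = character(), genome_id = character(),
                      profile_id = character(), bit_score = numeric(),
                      e_value = numeric(), q_span = numeric(),
                      t_span = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits[seq_len(n)])
}

#' Assemble the genomes x protein-cluster best-bit-score matrix
#'
#' Hits failing any filter are discarded; each retained cell holds the best
#' bit score of any protein of that genome against that cluster, zero
#' otherwise.  Genomes with no retained hits keep an all-zero row.
#'
#' @param hits hit table data.frame (genome_id resolvable for every row;
#'   rows with missing genome_id derive it from protein_id before the last
#'   `|`).
#' @param genomes character vector of genome ids (row universe).
#' @param pcs character vector of profile ids (column universe).
#' @param max_evalue,min_span,min_score the hit filters.
#' @return numeric matrix (genomes x pcs) with dimnames.
#' @export
build_matrix <- function(hits, genomes, pcs, max_evalue = 1e-5,
                         min_span = 0.70, min_score = 50) {
  mat <- matrix(0, nrow = length(genomes), ncol = length(pcs),
                dimnames = list(genomes, pcs))
  if (nrow(hits) > 0) {
    gid <- hits$genome_id
    fix <- is.na(gid) | gid == ""
    gid[fix] <- sub("\\|[^|]*$", "", hits$protein_id[fix])
    if (any(!gid %in% genomes)) {
      stop("hit(s) reference unknown genome(s): ",
           paste(unique(gid[!gid %in% genomes]), collapse = ", "))
    }
    keep <- hits$e_value <= max_evalue & hits$q_span >= min_span &
      hits$t_span >= min_span & hits$bit_score >= min_score &
      hits$profile_id %in% pcs
    h <- hits[keep, , drop = FALSE]
    gid <- gid[keep]
    if (nrow(h) > 0) {
      best <- tapply(h$bit_score, list(gid, h$profile_id), max)
      mat[rownames(best), colnames(best)] <-
        ifelse(is.na(best), mat[rownames(best), colnames(best)], best)
    }
  }
  mat
}

# union-find over column indices
#' @noRd
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Prune correlated protein clusters into superclusters
#'
#' Pearson correlation is computed between every pair of PC score columns
#' across genomes (zeros included); the graph with edges at r >= threshold
#' is split into connected components (superclusters) and only the member
#' with the largest column sum (tie: lexicographic id) is retained per
#' component.  Constant columns have undefined r and are treated as r = 0
#' against everything.
#'
#' @param mat feature matrix (genomes x pcs).
#' @param r_threshold Pearson threshold.
#' @return list(matrix = pruned matrix, map = data.frame(pc_id,
#'   representative), r_threshold).
#' @export
prune_superclusters <- function(mat, r_threshold = 0.9) {
  stopifnot(ncol(mat) >= 2)
  suppressWarnings(cc <- cor(mat))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  idx <- which(cc >= r_threshold & upper.tri(cc), arr.ind = TRUE)
  comp <- uf_components(ncol(mat), idx)
  sums <- colSums(mat)
  ids <- colnames(mat)
  rep_of <- vapply(split(seq_len(ncol(mat)), comp), function(mem) {
    mem[order(-sums[mem], ids[mem])][1]
  }, integer(1))
  reps <- setNames(ids[rep_of[as.character(comp)]], ids)
  keep <- sort(match(unique(unname(reps)), ids))
  list(matrix = mat[, keep, drop = FALSE],
       map = data.frame(pc_id = ids, representative = unname(reps),
                        stringsAsFactors = FALSE),
       r_threshold = r_threshold)
}

#' Read / write a feature matrix as TSV (genomes as rows)
#'
#' @param mat feature matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(genome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write a feature matrix as sparse MatrixMarket (MTX)
#'
#' Writes `<path>.mtx` plus `<path>.rows` / `<path>.cols` id lists.
#'
#' @param mat feature matrix.
#' @param path base path (without extension).
#' @export
write_matrix_mtx <- function(mat, path) {
  sm <- Matrix::Matrix(mat, sparse = TRUE)
  Matrix::writeMM(sm, paste0(path, ".mtx"))
  writeLines(rownames(mat), paste0(path, ".rows"))
  writeLines(colnames(mat), paste0(path, ".cols"))
  invisible(path)
}
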
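# Group viral proteins into clusters of homologs, align each cluster with
# a center-star MSA, and build a position-specific scoring model (PSSM)
# per cluster.  Greedy incremental clustering mirrors CD-HIT: sequences are
# visited longest-first and join the first existing cluster whose
# representative they match at >= min_identity over >= min_coverage of both
# sequences.

#' Greedy incremental protein clustering
#'
#' @param proteins protein record data.frame (protein_id, aa_sequence, ...).
#' @param min_identity minimum pairwise identity to the representative.
#' @param min_coverage minimum aligned fraction of both sequences.
#' @param prefilter_word optional exact shared-word prefilter length
#'   (0 disables; any value > 0 is a speed heuristic).
#' @return list of protein clusters: cluster_id, representative_id,
#'   member_ids, msa (NULL until [star_msa()] fills it).
#' @export
greedy_cluster <- function(proteins, min_identity = 0.35, min_coverage = 0.70,
                           prefilter_word = 0L) {
  stopifnot(nrow(proteins) >= 1)
  lens <- nchar(proteins$aa_sequence)
  ord <- order(-lens, proteins$protein_id)
  seqs <- proteins$aa_sequence[ord]
  ids <- proteins$protein_id[ord]
  codes <- lapply(seqs, aa_codes)
  rep_codes <- list()
  rep_ids <- character()
  members <- list()
  for (i in seq_along(ids)) {
    joined <- FALSE
    if (length(rep_codes)) {
      sc <- align_to_refs(codes[[i]], rep_codes,
                          prefilter_word = prefilter_word)
      ok <- which(!is.na(sc[, "score"]) &
                    sc[, "identity"] >= min_identity &
                    sc[, "cov_q"] >= min_coverage &
                    sc[, "cov_r"] >= min_coverage)
      if (length(ok)) {
        k <- ok[1]
        members[[k]] <- c(members[[k]], ids[i])
        joined <- TRUE
      }
    }
    if (!joined) {
      rep_codes[[length(rep_codes) + 1]] <- codes[[i]]
      rep_ids[length(rep_ids) + 1] <- ids[i]
      members[[length(members) + 1]] <- ids[i]
    }
  }
  lapply(seq_along(rep_ids), function(k) {
    list(cluster_id = sprintf("PC%05d", k), representative_id = rep_ids[k],
         member_ids = members[[k]], msa = NULL)
  })
}

# reconstruct the gapped member/representative rows of one ends-free
# pairwise alignment (member = a, representative = b), overhangs included
#' @noRd
pair_rows <- function(a, b, aln) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  arow <- character(0)
  brow <- character(0)
  # leading overhangs
  if (aln$a_start > 0) {
    arow <- c(arow, ac[seq_len(aln$a_start)])
    brow <- c(brow, rep("-", aln$a_start))
  }
  if (aln$b_start > 0) {
    arow <- c(arow, rep("-", aln$b_start))
    brow <- c(brow, bc[seq_len(aln$b_start)])
  }
  i <- aln$a_start
  j <- aln$b_start
  for (s in aln$steps) {
    if (s == 1) {
      i <- i + 1; j <- j + 1
      arow <- c(arow, ac[i]); brow <- c(brow, bc[j])
    } else if (s == 2) {
      i <- i + 1
      arow <- c(arow, ac[i]); brow <- c(brow, "-")
    } else {
      j <- j + 1
      arow <- c(arow, "-"); brow <- c(brow, bc[j])
    }
  }
  if (aln$a_stop < length(ac)) {
    idx <- (aln$a_stop + 1):length(ac)
    arow <- c(arow, ac[idx]); brow <- c(brow, rep("-", length(idx)))
  }
  if (aln$b_stop < length(bc)) {
    idx <- (aln$b_stop + 1):length(bc)
    arow <- c(arow, rep("-", length(idx))); brow <- c(brow, bc[idx])
  }
  list(a = arow, b = brow)
}

#' Center-star multiple alignment of a cluster
#'
#' Every member is globally aligned to the representative; gaps are merged
#' by the center-star rule (the union of insertions relative to the
#' representative).  Degapping any row reproduces the member's sequence.
#'
#' @param cluster one cluster from [greedy_cluster()].
#' @param proteins protein record data.frame covering the members.
#' @return the cluster with `msa` filled: named character vector of
#'   equal-length gapped rows keyed by member id.
#' @export
star_msa <- function(cluster, proteins) {
  seqs <- setNames(proteins$aa_sequence, proteins$protein_id)
  rep_seq <- seqs[[cluster$representative_id]]
  L <- nchar(rep_seq)
  mem <- cluster$member_ids
  if (length(mem) == 1) {
    cluster$msa <- setNames(rep_seq, mem)
    return(cluster)
  }
  # per member: chars at rep positions (1..L) and inserted chars per gap slot
  per <- lapply(mem, function(id) {
    if (id == cluster$representative_id) {
      list(at_rep = strsplit(rep_seq, "")[[1]],
           ins = rep(list(character(0)), L + 1))
    } else {
      a <- seqs[[id]]
      aln <- .aa_align_pair_cpp(aa_codes(a), aa_codes(rep_seq), aa_submat(),
                                11, 1)
      rows <- pair_rows(a, rep_seq, aln)
      at_rep <- rep("-", L)
      ins <- rep(list(character(0)), L + 1)
      rpos <- 0L
      for (col in seq_along(rows$b)) {
        if (rows$b[col] != "-") {
          rpos <- rpos + 1L
          at_rep[rpos] <- rows$a[col]
        } else if (rows$a[col] != "-") {
          ins[[rpos + 1L]] <- c(ins[[rpos + 1L]], rows$a[col])
        }
      }
      list(at_rep = at_rep, ins = ins)
    }
  })
  ins_width <- vapply(seq_len(L + 1), function(slot) {
    max(vapply(per, function(p) length(p$ins[[slot]]), integer(1)))
  }, integer(1))
  rows <- vapply(per, function(p) {
    parts <- character(0)
    for (slot in seq_len(L + 1)) {
      w <- ins_width[slot]
      if (w > 0) {
        chars <- p$ins[[slot]]
        parts <- c(parts, chars, rep("-", w - length(chars)))
      }
      if (slot <= L) parts <- c(parts, p$at_rep[slot])
    }
    paste(parts, collapse = "")
  }, character(1))
  cluster$msa <- setNames(rows, mem)
  cluster
}

#' Build a position-specific scoring model from a cluster MSA
#'
#' Columns with more than 50% gaps are dropped.  The score of residue x in
#' a retained column with counts `count_x` over `n_eff` non-gap residues is
#' `log2((count_x + pseudocount * bg_x) / (n_eff + pseudocount) / bg_x)`
#' (log-odds in bits against the background distribution).
#'
#' @param cluster cluster with msa filled (see [star_msa()]).
#' @param pseudocount background-weighted pseudocount mass.
#' @param background optional 20-vector of residue frequencies (names =
#'   residues); defaults to the residue frequencies of the cluster members
#'   with Laplace smoothing.
#' @param gap_open,gap_ext affine gap penalties (bits) used when the model
#'   is searched.
#' @return a `profile_model`: profile_id, length, match_scores (length x 21
#'   matrix, column 21 = X scored 0), gap penalties and background.
#' @export
build_profile <- function(cluster, pseudocount = 0.5, background = NULL,
                          gap_open = 11, gap_ext = 1) {
  if (is.null(cluster$msa) || length(cluster$msa) == 0) {
    stop("cluster has no MSA; run star_msa() first")
  }
  rows <- do.call(rbind, strsplit(cluster$msa, ""))
  gap_frac <- colMeans(rows == "-")
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stop("all MSA columns are majority-gap")
  if (is.null(background)) {
    res <- rows[rows != "-" & rows != "X"]
    cnt <- table(factor(res, levels = AA20))
    background <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
    names(background) <- AA20
  } else {
    background <- background[AA20]
    stopifnot(abs(sum(background) - 1) < 1e-6)
  }
  scores <- matrix(0, nrow = length(keep), ncol = 21)
  for (ci in seq_along(keep)) {
    col <- rows[, keep[ci]]
    col <- col[col != "-" & col != "X"]
    n_eff <- length(col)
    cnt <- as.numeric(table(factor(col, levels = AA20)))
    scores[ci, 1:20] <- log2((cnt + pseudocount * background) /
                               (n_eff + pseudocount) / background)
  }
  structure(list(profile_id = cluster$cluster_id, length = length(keep),
                 match_scores = scores, gap_open = gap_open,
                 gap_extend = gap_ext, background = background,
                 n_seqs = length(cluster$msa)),
            class = "profile_model")
}

#' Cluster assignments as a data.frame
#'
#' @param clusters list of clusters from [greedy_cluster()].
#' @return data.frame: protein_id, cluster_id, is_representative.
#' @export
cluster_frame <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(protein_id = cl$member_ids, cluster_id = cl$cluster_id,
               is_representative = cl$member_ids == cl$representative_id,
               stringsAsFactors = FALSE)
  }))
}

#' Serialize / load profile models (plain text, one column per line)
#'
#' @param profiles list of profile models.
#' @param path file path.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    writeLines(sprintf("#profile\t%s\tlength\t%d\tgap_open\t%g\tgap_extend\t%g\tn_seqs\t%d",
                       p$profile_id, p$length, p$gap_open, p$gap_extend,
                       p$n_seqs %||% 1L), con)
    writeLines(paste0("#background\t",
                      paste(formatC(p$background, digits = 8, format = "g"),
                            collapse = "\t")), con)
    for (i in seq_len(p$length)) {
      writeLines(paste(formatC(p$match_scores[i, 1:20], digits = 8,
                               format = "g"), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  starts <- grep("^#profile\t", lines)
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(k) {
    hdr <- strsplit(lines[starts[k]], "\t")[[1]]
    len <- as.integer(hdr[4])
    bg <- as.numeric(strsplit(lines[starts[k] + 1], "\t")[[1]][-1])
    names(bg) <- AA20
    rows <- lines[(starts[k] + 2):(starts[k] + 1 + len)]
    m <- do.call(rbind, lapply(strsplit(rows, "\t"), as.numeric))
    scores <- cbind(m, 0)
    structure(list(profile_id = hdr[2], length = len, match_scores = scores,
                   gap_open = as.numeric(hdr[6]), gap_extend = as.numeric(hdr[8]),
                   background = bg, n_seqs = as.integer(hdr[10])),
              class = "profile_model")
  })
}

#' Cluster, align and model a protein set in one call
#'
#' @inheritParams greedy_cluster
#' @inheritParams build_profile
#' @return list(clusters, profiles).
#' @export
build_protein_profiles <- function(proteins, min_identity = 0.35,
                                   min_coverage = 0.70, pseudocount = 0.5,
                                   prefilter_word = 0L) {
  clusters <- greedy_cluster(proteins, min_identity, min_coverage,
                             prefilter_word = prefilter_word)
  clusters <- lapply(clusters, star_msa, proteins = proteins)
  # global background over all input proteins keeps models comparable
  res <- unlist(strsplit(proteins$aa_sequence, ""))
  res <- res[res != "X"]
  cnt <- table(factor(res, levels = AA20))
  bg <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
  names(bg) <- AA20
  profiles <- lapply(clusters, build_profile, pseudocount = pseudocount,
                     background = bg)
  list(clusters = clusters, profiles = profiles)
}
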
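# The alignment-dependent host-assignment pipeline: CRISPR-spacer,
# homology and shared-tRNA matchers; viral-population (VP) clustering at
# 95% ANI / 80% shared genes; and the per-VP 3/2/1 point-scoring consensus.

EVIDENCE_WEIGHTS <- c(crispr = 3, homology = 2, trna = 1)

#' @noRd
empty_signals <- function() {
  data.frame(viral_id = character(), host_genus = character(),
             kind = character(), points = numeric(), detail = character(),
             stringsAsFactors = FALSE)
}

#' @noRd
signal_rows <- function(viral_id, host_genus, kind, detail) {
  data.frame(viral_id = viral_id, host_genus = host_genus, kind = kind,
             points = unname(EVIDENCE_WEIGHTS[kind]), detail = detail,
             stringsAsFactors = FALSE)
}

#' Detect CRISPR-like arrays in a host genome
#'
#' Finds maximal runs of at least `min_repeats` exact copies of a repeat
#' word separated by mutually distinct spacers; an array of n repeats
#' yields n - 1 spacers.
#'
#' @param host a genome record (list/row with genome_id, sequence).
#' @param repeat_len,spacer_len length-2 integer ranges.
#' @param min_repeats minimum number of repeat copies.
#' @return list of arrays: host_genome_id, repeat, spacers, begin, end.
#' @export
detect_crispr_arrays <- function(host, repeat_len = c(23, 47),
                                 spacer_len = c(20, 50), min_repeats = 3) {
  stopifnot(nchar(host$sequence) >= 200)
  raw <- .detect_crispr_cpp(host$sequence, as.integer(repeat_len[1]),
                            as.integer(repeat_len[2]),
                            as.integer(spacer_len[1]),
                            as.integer(spacer_len[2]),
                            as.integer(min_repeats))
  lapply(raw, function(a) {
    list(host_genome_id = host$genome_id, repeat_seq = a$`repeat`,
         spacers = a$spacers, begin = a$begin, end = a$end)
  })
}

#' Match CRISPR spacers against viral genomes
#'
#' A signal is emitted iff the full spacer occurs exactly (zero mismatches,
#' full length) in a viral sequence on either strand; one signal per
#' (spacer, viral genome).
#'
#' @param arrays list of arrays from [detect_crispr_arrays()].
#' @param viral genome record data.frame of viral sequences.
#' @param host_genera named character vector host_genome_id -> genus.
#' @return evidence signal data.frame.
#' @export
match_spacers <- function(arrays, viral, host_genera) {
  out <- list()
  for (a in arrays) {
    genus <- unname(host_genera[[a$host_genome_id]])
    for (si in seq_along(a$spacers)) {
      sp <- a$spacers[si]
      if (nchar(sp) < 20) next
      rc <- revcomp(sp)
      hit <- grepl(sp, viral$sequence, fixed = TRUE) |
        grepl(rc, viral$sequence, fixed = TRUE)
      if (any(hit)) {
        out[[length(out) + 1]] <- signal_rows(
          viral$genome_id[hit], genus, "crispr",
          sprintf("spacer %d of array %s:%d-%d", si, a$host_genome_id,
                  a$begin, a$end))
      }
    }
  }
  if (!length(out)) return(empty_signals())
  do.call(rbind, out)
}

#' Match viral sequences against host genomes by homology
#'
#' Seed-and-extend local alignment (exact seed word 11, gapped extension)
#' on both strands; a signal requires alignment length >= min_len,
#' identity >= min_identity and e-value <= max_evalue.  At most one signal
#' per (viral genome, host genus).
#'
#' @param viral,hosts genome record data.frames.
#' @param host_genera named character vector host_genome_id -> genus.
#' @param min_len,min_identity,max_evalue the match thresholds.
#' @return evidence signal data.frame.
#' @export
match_homology <- function(viral, hosts, host_genera, min_len = 500,
                           min_identity = 0.95, max_evalue = 1e-3) {
  out <- list()
  for (vi in seq_len(nrow(viral))) {
    seen <- character(0)
    for (hi in seq_len(nrow(hosts))) {
      genus <- unname(host_genera[[hosts$genome_id[hi]]])
      if (genus %in% seen) next
      aln <- nt_best_local(viral$sequence[vi], hosts$sequence[hi])
      if (!is.null(aln) && aln$length >= min_len &&
            aln$identity >= min_identity && aln$e_value <= max_evalue) {
        out[[length(out) + 1]] <- signal_rows(
          viral$genome_id[vi], genus, "homology",
          sprintf("%s %d-%d vs %s (%.1f%% over %d bp)", viral$genome_id[vi],
                  aln$a_begin, aln$a_end, hosts$genome_id[hi],
                  100 * aln$identity, aln$length))
        seen <- c(seen, genus)
      }
    }
  }
  if (!length(out)) return(empty_signals())
  do.call(rbind, out)
}

#' Match viral tRNAs against host genomes
#'
#' Viral tRNA sequences are supplied externally (tRNA detection is out of
#' scope).  A signal requires alignment length >= min_len, identity >=
#' min_identity, query coverage >= min_qcov, at most max_mismatches
#' mismatches and e-value <= max_evalue.
#'
#' @param viral_trnas data.frame with columns viral_id, sequence.
#' @param hosts genome record data.frame.
#' @param host_genera named character vector host_genome_id -> genus.
#' @param min_len,min_identity,min_qcov,max_mismatches,max_evalue thresholds.
#' @return evidence signal data.frame.
#' @export
match_trnas <- function(viral_trnas, hosts, host_genera, min_len = 60,
                        min_identity = 0.97, min_qcov = 0.95,
                        max_mismatches = 10, max_evalue = 1e-3) {
  out <- list()
  for (ti in seq_len(nrow(viral_trnas))) {
    for (hi in seq_len(nrow(hosts))) {
      aln <- nt_best_local(viral_trnas$sequence[ti], hosts$sequence[hi],
                           word = 8)
      if (!is.null(aln) && aln$length >= min_len &&
            aln$identity >= min_identity && aln$qcov >= min_qcov &&
            aln$mismatches <= max_mismatches && aln$e_value <= max_evalue) {
        out[[length(out) + 1]] <- signal_rows(
          viral_trnas$viral_id[ti],
          unname(host_genera[[hosts$genome_id[hi]]]), "trna",
          sprintf("tRNA vs %s (%.1f%% over %d bp)", hosts$genome_id[hi],
                  100 * aln$identity, aln$length))
      }
    }
  }
  if (!length(out)) return(empty_signals())
  do.call(rbind, out)
}

# gene-based ANI between two genomes: reciprocal best local alignments of
# gene nucleotide sequences; shared fraction over the smaller gene set
#' @noRd
gene_ani <- function(genes_a, genes_b, min_qual_identity = 0.7,
                     min_qual_cov = 0.5) {
  na <- length(genes_a); nb <- length(genes_b)
  score <- matrix(0, na, nb)
  ident <- matrix(0, na, nb)
  covs <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      aln <- nt_best_local(genes_a[i], genes_b[j], word = 11)
      if (!is.null(aln)) {
        score[i, j] <- aln$score
        ident[i, j] <- aln$identity
        covs[i, j] <- aln$length /
          min(nchar(genes_a[i]), nchar(genes_b[j]))
      }
    }
  }
  best_a <- max.col(score, ties.method = "first")
  best_b <- max.col(t(score), ties.method = "first")
  rbh <- which(best_b[best_a] == seq_len(na) & score[cbind(seq_len(na), best_a)] > 0)
  if (!length(rbh)) return(list(ani = 0, shared = 0))
  ids <- ident[cbind(rbh, best_a[rbh])]
  cvs <- covs[cbind(rbh, best_a[rbh])]
  qual <- ids >= min_qual_identity & cvs >= min_qual_cov
  list(ani = mean(ids), shared = sum(qual) / min(na, nb))
}

#' Cluster viral genomes into viral populations
#'
#' Pairwise ANI (mean identity over reciprocal best local alignments of
#' genes) and shared-gene fraction (qualifying reciprocal pairs over the
#' gene count of the genome with fewer genes) define edges at
#' ANI >= min_ani AND shared >= min_shared_genes; populations are the
#' connected components.  A MinHash prescreen skips obviously unrelated
#' pairs.
#'
#' @param viral genome record data.frame.
#' @param proteins protein record data.frame (grouped by genome via
#'   genome_id; gene nucleotide sequences are cut from the genome
#'   coordinates).
#' @param min_ani,min_shared_genes the edge thresholds.
#' @return data.frame: vp_id, genome_id (populations partition the input).
#' @export
cluster_viral_populations <- function(viral, proteins, min_ani = 0.95,
                                      min_shared_genes = 0.80) {
  n <- nrow(viral)
  genes <- lapply(seq_len(n), function(i) {
    p <- proteins[proteins$genome_id == viral$genome_id[i] &
                    !is.na(proteins$begin), , drop = FALSE]
    if (nrow(p) == 0) return(character(0))
    g <- substring(viral$sequence[i], p$begin, p$end)
    neg <- p$strand == "-"
    if (any(neg)) g[neg] <- revcomp(g[neg])
    g
  })
  none <- vapply(genes, length, integer(1)) == 0
  if (any(none)) {
    warning("genome(s) with zero genes form singleton populations: ",
            paste(viral$genome_id[none], collapse = ", "))
  }
  sketches <- lapply(viral$sequence, function(s) {
    if (nchar(s) >= 15) .minhash_sketch_cpp(s, 15L, 300L, 7) else numeric(0)
  })
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (none[i]) next
      for (j in (i + 1):n) {
        if (none[j]) next
        # prescreen: skip pairs sharing no sketch minima at all
        if (length(sketches[[i]]) && length(sketches[[j]]) &&
              !any(sketches[[i]] %in% sketches[[j]])) next
        r <- gene_ani(genes[[i]], genes[[j]])
        if (r$ani >= min_ani && r$shared >= min_shared_genes) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  comp <- uf_components(n, edges)
  comp_ids <- match(comp, unique(comp))
  data.frame(vp_id = sprintf("VP%05d", comp_ids), genome_id = viral$genome_id,
             stringsAsFactors = FALSE)
}

#' Score a viral population's candidate hosts
#'
#' Sums the 3/2/1 point weights of all evidence signals across the
#' population's members; the top-scoring genus is assigned to every member.
#' A tie for the top score yields no prediction (reported via the `ties`
#' attribute).
#'
#' @param vp list with vp_id and member_ids, or a vp_id plus the membership
#'   data.frame from [cluster_viral_populations()].
#' @param signals evidence signal data.frame (restricted to vp members;
#'   other rows are ignored).
#' @param taxonomy optional taxonomy table for lineage expansion.
#' @param dedupe_per_kind if TRUE, count each (viral, genus, kind) signal
#'   once instead of accumulating every occurrence.
#' @return a [host_prediction()] (method classical_combined, score = the
#'   winning point total) replicated over members via the `member_ids`
#'   field; NULL when there are no signals; a `host_tie` object naming the
#'   tied genera when the top score is tied.
#' @export
score_population_hosts <- function(vp, signals, taxonomy = NULL,
                                   dedupe_per_kind = FALSE) {
  sig <- signals[signals$viral_id %in% vp$member_ids, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  if (dedupe_per_kind) {
    sig <- sig[!duplicated(sig[c("viral_id", "host_genus", "kind")]), ,
               drop = FALSE]
  }
  totals <- tapply(sig$points, sig$host_genus, sum)
  totals <- sort(totals, decreasing = TRUE)
  top <- names(totals)[totals == totals[1]]
  if (length(top) > 1) {
    return(structure(list(vp_id = vp$vp_id, tied_genera = sort(top),
                          points = unname(totals[1])),
                     class = "host_tie"))
  }
  genus <- top[1]
  lineage <- if (!is.null(taxonomy)) expand_lineage(genus, taxonomy) else
    setNames(c(genus, rep(NA_character_, 5)), TAX_RANKS)
  pred <- host_prediction(vp$vp_id, setNames(as.numeric(totals), names(totals)),
                          lineage, "classical_combined")
  pred$member_ids <- vp$member_ids
  pred
}

#' Run the full classical host-assignment pipeline
#'
#' Detects CRISPR arrays in the hosts, gathers CRISPR/homology/tRNA
#' signals, clusters viruses into populations and scores each population.
#' Host records whose description matches the keyword "plasmid"
#' (case-insensitive) are excluded from the reference set.  An optional
#' known-host table short-circuits a population's assignment.
#'
#' @param viral,hosts genome record data.frames.
#' @param host_genera named character vector host_genome_id -> genus.
#' @param taxonomy taxonomy table.
#' @param proteins viral protein records (for population clustering).
#' @param viral_trnas optional data.frame(viral_id, sequence).
#' @param known_hosts optional data.frame(viral_id, genus): confident prior
#'   assignments (e.g. prophages) that bypass evidence scoring.
#' @return list(predictions = data.frame(one row per assigned viral genome:
#'   viral_id, vp_id, genus, points, lineage ranks), signals, vps, ties).
#' @export
classical_predict <- function(viral, hosts, host_genera, taxonomy,
                              proteins, viral_trnas = NULL,
                              known_hosts = NULL) {
  drop <- grepl("plasmid", hosts$source %||% "", ignore.case = TRUE)
  hosts <- hosts[!drop, , drop = FALSE]
  arrays <- do.call(c, lapply(seq_len(nrow(hosts)), function(i) {
    detect_crispr_arrays(hosts[i, ])
  }))
  signals <- rbind(
    match_spacers(arrays %||% list(), viral, host_genera),
    match_homology(viral, hosts, host_genera),
    if (!is.null(viral_trnas) && nrow(viral_trnas) > 0) {
      match_trnas(viral_trnas, hosts, host_genera)
    } else empty_signals())
  vps <- cluster_viral_populations(viral, proteins)
  preds <- list()
  ties <- list()
  for (vid in unique(vps$vp_id)) {
    members <- vps$genome_id[vps$vp_id == vid]
    vp <- list(vp_id = vid, member_ids = members)
    if (!is.null(known_hosts)) {
      kh <- known_hosts[known_hosts$viral_id %in% members, , drop = FALSE]
      if (nrow(kh) > 0 && length(unique(kh$genus)) == 1) {
        genus <- kh$genus[1]
        lineage <- expand_lineage(genus, taxonomy)
        p <- host_prediction(vid, setNames(Inf, genus), lineage,
                             "classical_combined")
        p$member_ids <- members
        preds[[length(preds) + 1]] <- p
        next
      }
    }
    p <- score_population_hosts(vp, signals, taxonomy)
    if (is.null(p)) next
    if (inherits(p, "host_tie")) {
      ties[[vid]] <- p$tied_genera
      next
    }
    preds[[length(preds) + 1]] <- p
  }
  rows <- do.call(rbind, lapply(preds, function(p) {
    lin <- p$lineage
    data.frame(viral_id = p$member_ids, vp_id = p$genome_id,
               genus = p$best_genus, points = p$best_score,
               family = lin[["family"]], order = lin[["order"]],
               class = lin[["class"]], phylum = lin[["phylum"]],
               domain = lin[["domain"]], stringsAsFactors = FALSE)
  }))
  list(predictions = rows %||%
         data.frame(viral_id = character(), vp_id = character(),
                    genus = character(), points = numeric(),
                    family = character(), order = character(),
                    class = character(), phylum = character(),
                    domain = character(), stringsAsFactors = FALSE),
       signals = signals, vps = vps, ties = ties)
}
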
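# Precision/recall/F1 per taxonomic rank, score-cutoff sweeps, bootstrap
# precision, genome dereplication and AAI-based train/test independence
# filtering.
#
# Recall = sequences with >= 1 prediction passing the cutoff / all
# sequences, regardless of correctness.  Precision = sequences counted
# correct / predicted sequences evaluable at the rank; a sequence with
# multiple predictions is correct if ANY matches the truth at the rank and
# is counted once.  Sequences whose truth is missing at the rank leave the
# precision denominator but still count in recall's total.

#' @noRd
truth_frame <- function(truth) {
  if (is.data.frame(truth)) {
    key <- if ("viral_id" %in% names(truth)) "viral_id" else "genome_id"
    stopifnot(key %in% names(truth))
    rownames(truth) <- truth[[key]]
    truth
  } else stop("truth must be a data.frame with viral_id/genome_id + rank columns")
}

#' @noRd
pred_frame <- function(preds) {
  if (is.data.frame(preds)) {
    df <- preds
    if (!"viral_id" %in% names(df)) df$viral_id <- df$genome_id
    if (!"score" %in% names(df)) {
      df$score <- if ("best_score" %in% names(df)) df$best_score else
        if ("points" %in% names(df)) df$points else 1
    }
    df
  } else {
    df <- prediction_frame(preds)
    df$viral_id <- df$genome_id
    df$score <- df$best_score
    df
  }
}

#' Precision, recall and F1 at one taxonomic rank
#'
#' @param preds predictions: a data.frame (viral_id/genome_id, a column for
#'   the rank, and score/best_score/points) or a list of
#'   [host_prediction()] objects; multiple rows per sequence allowed.
#' @param truth data.frame keyed by viral_id/genome_id with lineage
#'   columns; defines the evaluation universe (recall denominator).
#' @param rank taxonomic rank to evaluate.
#' @param cutoff minimum score for a prediction to count.
#' @return a `metrics_record` data.frame row: rank, cutoff, precision,
#'   recall, f1, n_total, n_predicted, n_correct, n_evaluable.
#' @export
compute_metrics <- function(preds, truth, rank, cutoff = 0) {
  if (!rank %in% TAX_RANKS) stop("invalid rank name: ", rank)
  truth <- truth_frame(truth)
  preds <- pred_frame(preds)
  if (rank == "genus" && !"genus" %in% names(preds) &&
        "best_genus" %in% names(preds)) {
    preds$genus <- preds$best_genus
  }
  n_total <- nrow(truth)
  pass <- preds[!is.na(preds$score) & preds$score >= cutoff, , drop = FALSE]
  pass <- pass[pass$viral_id %in% rownames(truth), , drop = FALSE]
  predicted_ids <- unique(pass$viral_id)
  n_predicted <- length(predicted_ids)
  truth_vals <- truth[predicted_ids, rank]
  evaluable <- !is.na(truth_vals)
  n_evaluable <- sum(evaluable)
  correct <- vapply(predicted_ids[evaluable], function(id) {
    tv <- truth[id, rank]
    pv <- pass[[rank]][pass$viral_id == id]
    any(!is.na(pv) & pv == tv)
  }, logical(1))
  n_correct <- sum(correct)
  precision <- if (n_evaluable > 0) n_correct / n_evaluable else 0
  recall <- if (n_total > 0) n_predicted / n_total else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(data.frame(rank = rank, cutoff = cutoff, precision = precision,
                       recall = recall, f1 = f1, n_total = n_total,
                       n_predicted = n_predicted, n_correct = n_correct,
                       n_evaluable = n_evaluable, stringsAsFactors = FALSE),
            class = c("metrics_record", "data.frame"))
}

#' Metrics across a grid of score cutoffs
#'
#' @inheritParams compute_metrics
#' @param cutoffs ascending numeric grid.
#' @return data.frame of one metrics row per cutoff; recall is
#'   non-increasing along the grid.
#' @export
cutoff_sweep <- function(preds, truth, rank, cutoffs) {
  stopifnot(!is.unsorted(cutoffs))
  do.call(rbind, lapply(cutoffs, function(ct) {
    compute_metrics(preds, truth, rank, ct)
  }))
}

#' Bootstrap precision over random subsamples
#'
#' Each replicate samples `floor(frac * n)` sequences without replacement
#' and recomputes precision; deterministic under a fixed seed.
#'
#' @inheritParams compute_metrics
#' @param frac subsample fraction in (0, 1].
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return list(mean, sd, values).
#' @export
bootstrap_precision <- function(preds, truth, rank, cutoff = 0, frac = 0.2,
                                reps = 1000, seed = 1) {
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  truth <- truth_frame(truth)
  n <- nrow(truth)
  stopifnot(n >= 5)
  m <- floor(frac * n)
  preds <- pred_frame(preds)
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(r) {
    ids <- rownames(truth)[sample.int(n, m)]
    compute_metrics(preds[preds$viral_id %in% ids, , drop = FALSE],
                    truth[ids, , drop = FALSE], rank, cutoff)$precision
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Dereplicate genomes (greedy longest-first)
#'
#' A genome is redundant if it aligns to an already-retained genome at
#' identity >= min_identity over at least min_shorter_cov of the shorter
#' sequence.
#'
#' @param genomes genome record data.frame.
#' @param min_identity,min_shorter_cov the redundancy thresholds.
#' @return the retained subset, in input order.
#' @export
dereplicate <- function(genomes, min_identity = 0.95, min_shorter_cov = 0.50) {
  stopifnot(nrow(genomes) >= 1)
  ord <- order(-nchar(genomes$sequence), genomes$genome_id)
  retained <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in retained) {
      shorter <- min(nchar(genomes$sequence[i]), nchar(genomes$sequence[j]))
      aln <- nt_best_local(genomes$sequence[i], genomes$sequence[j])
      if (!is.null(aln) && aln$identity >= min_identity &&
            aln$length >= min_shorter_cov * shorter) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, i)
  }
  genomes[sort(retained), , drop = FALSE]
}

#' Average amino-acid identity between two proteomes
#'
#' Reciprocal best hits by pairwise protein alignment; AAI is the mean
#' percent identity over best-hit pairs with identity >= min_hit_identity,
#' and shared_fraction the fraction of a's proteins with such a hit in b.
#'
#' @param proteome_a,proteome_b character vectors of amino-acid sequences.
#' @param min_hit_identity minimum identity for a qualifying hit.
#' @return list(aai in [0, 100], shared_fraction in [0, 1], n_hits).
#' @export
compute_aai <- function(proteome_a, proteome_b, min_hit_identity = 0.30) {
  na <- length(proteome_a); nb <- length(proteome_b)
  if (na == 0 || nb == 0) stop("empty proteome")
  codes_a <- lapply(proteome_a, aa_codes)
  codes_b <- lapply(proteome_b, aa_codes)
  score <- matrix(0, na, nb)
  ident <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    sc <- align_to_refs(codes_a[[i]], codes_b, prefilter_word = 3L)
    s <- sc[, "score"]; s[is.na(s)] <- -Inf
    score[i, ] <- s
    id <- sc[, "identity"]; id[is.na(id)] <- 0
    ident[i, ] <- id
  }
  best_a <- max.col(score, ties.method = "first")
  best_b <- max.col(t(score), ties.method = "first")
  rbh <- which(best_b[best_a] == seq_len(na) &
                 is.finite(score[cbind(seq_len(na), best_a)]))
  ids <- ident[cbind(rbh, best_a[rbh])]
  qual <- ids >= min_hit_identity
  aai <- if (any(qual)) 100 * mean(ids[qual]) else 0
  list(aai = aai, shared_fraction = sum(qual) / na, n_hits = sum(qual))
}

#' Filter test genomes for independence from a training set
#'
#' A test genome is removed iff, against ANY training genome, its
#' shared-protein fraction exceeds max_shared OR its AAI exceeds max_aai
#' (the test genome is the `a` side of the asymmetric shared fraction).
#'
#' @param test,train named lists of proteomes (character vectors of
#'   amino-acid sequences keyed by genome id).
#' @param max_shared,max_aai removal thresholds.
#' @return character vector of retained test genome ids.
#' @export
filter_test_independence <- function(test, train, max_shared = 0.70,
                                     max_aai = 70) {
  keep <- vapply(names(test), function(id) {
    for (tr in train) {
      r <- compute_aai(test[[id]], tr)
      if (r$shared_fraction > max_shared || r$aai > max_aai) return(FALSE)
    }
    TRUE
  }, logical(1))
  names(test)[keep]
}

#' Write a metrics table TSV
#'
#' @param metrics data.frame of metrics rows.
#' @param path file path.
#' @export
write_metrics_tsv <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
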
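# Taxonomy tables, lineage expansion, and the per-rank match contract.
#
# A taxonomy table maps each host genus to its lineage up to the domain
# level.  Missing ranks are explicit (NA, written as literal "NA" in TSV);
# rank gaps are allowed, e.g. a genus whose class is undetermined while
# phylum and domain are known.

TAX_RANKS <- c("genus", "family", "order", "class", "phylum", "domain")

#' Construct a taxonomy table
#'
#' @param df data.frame with columns `genus`, `family`, `order`, `class`,
#'   `phylum`, `domain`; `NA` marks a missing rank.
#' @return the validated data.frame, genus names as unique keys.
#' @export
taxonomy_table <- function(df) {
  missing_cols <- setdiff(TAX_RANKS, names(df))
  if (length(missing_cols)) {
    stop("taxonomy table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[TAX_RANKS]
  for (cn in TAX_RANKS) df[[cn]] <- as.character(df[[cn]])
  if (anyDuplicated(df$genus)) stop("duplicated genus names in taxonomy table")
  if (any(is.na(df$genus) | df$genus == "")) stop("empty genus name in taxonomy table")
  df
}

#' Read / write a taxonomy table TSV
#'
#' Headered TSV with columns genus, family, order, class, phylum, domain;
#' the literal string "NA" encodes a missing rank.
#'
#' @param path file path.
#' @return `read_taxonomy()` returns the taxonomy data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   na.strings = "NA", check.names = FALSE)
  taxonomy_table(df)
}

#' @rdname read_taxonomy
#' @param table taxonomy data.frame as from [taxonomy_table()].
#' @export
write_taxonomy <- function(table, path) {
  write.table(taxonomy_table(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Expand a genus to its full lineage
#'
#' Pure lookup: the stored lineage is returned verbatim, missing ranks stay
#' `NA` and are never fabricated.
#'
#' @param genus genus name (exact, case-sensitive).
#' @param table taxonomy data.frame.
#' @return named character vector over genus, family, order, class, phylum,
#'   domain (`NA` for a missing rank).
#' @export
expand_lineage <- function(genus, table) {
  if (!is.character(genus) || length(genus) != 1 || is.na(genus) || genus == "") {
    stop("genus must be a non-empty string")
  }
  i <- match(genus, table$genus)
  if (is.na(i)) {
    new_error(paste0("unknown taxon: ", genus), "hostforest_unknown_taxon")
  }
  setNames(vapply(TAX_RANKS, function(r) table[[r]][i], character(1)), TAX_RANKS)
}

#' Compare two lineages at one rank
#'
#' @param pred,truth lineages as returned by [expand_lineage()].
#' @param rank one of genus, family, order, class, phylum, domain.
#' @return `"match"`, `"mismatch"`, or `"not_evaluable"` (either lineage
#'   missing at that rank).
#' @export
rank_match <- function(pred, truth, rank) {
  if (!is.character(rank) || length(rank) != 1 || !(rank %in% TAX_RANKS)) {
    stop("invalid rank name: ", paste(rank, collapse = ","))
  }
  p <- pred[[rank]]
  t <- truth[[rank]]
  if (is.null(p) || is.null(t) || is.na(p) || is.na(t)) return("not_evaluable")
  if (identical(p, t)) "match" else "mismatch"
}

#' Construct a single host prediction
#'
#' @param genome_id viral genome/contig id.
#' @param scores named numeric vector of per-genus scores.  For the random
#'   forest these are class probabilities summing to 1; other methods carry
#'   unnormalized scores (e.g. evidence points).
#' @param lineage lineage of the winning genus.
#' @param method one of rf, crispr, homology, trna, classical_combined, kmer.
#' @param tie logical; TRUE when the top score was tied (winner chosen
#'   lexicographically, or no winner for the classical scorer).
#' @return a `host_prediction` list with best_genus/best_score fields.
#' @export
host_prediction <- function(genome_id, scores, lineage, method, tie = FALSE) {
  stopifnot(length(scores) >= 1, !is.null(names(scores)))
  method <- match.arg(method,
                      c("rf", "crispr", "homology", "trna",
                        "classical_combined", "kmer"))
  ord <- order(-scores, names(scores))
  best <- ord[1]
  structure(list(genome_id = genome_id, scores = scores,
                 best_genus = names(scores)[best],
                 best_score = unname(scores[best]),
                 lineage = lineage, method = method, tie = tie),
            class = "host_prediction")
}

#' Flatten host predictions to a data.frame
#'
#' @param preds a list of [host_prediction()] objects (or a single one).
#' @return data.frame with genome_id, method, best_genus, best_score and the
#'   six lineage ranks.
#' @export
prediction_frame <- function(preds) {
  if (inherits(preds, "host_prediction")) preds <- list(preds)
  if (length(preds) == 0) {
    return(data.frame(genome_id = character(), method = character(),
                      best_genus = character(), best_score = numeric(),
                      genus = character(), family = character(),
                      order = character(), class = character(),
                      phylum = character(), domain = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(preds, function(p) {
    lin <- p$lineage
    rk <- function(r) if (r %in% names(lin)) lin[[r]] else NA_character_
    data.frame(genome_id = p$genome_id, method = p$method,
               best_genus = p$best_genus, best_score = p$best_score,
               genus = rk("genus"), family = rk("family"), order = rk("order"),
               class = rk("class"), phylum = rk("phylum"),
               domain = rk("domain"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.host_prediction <- function(x, ...) {
  cat(sprintf("<host_prediction> %s -> %s (%s, score %.4g)%s\n",
              x$genome_id, x$best_genus, x$method, x$best_score,
              if (isTRUE(x$tie)) " [tie]" else ""))
  invisible(x)
}
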
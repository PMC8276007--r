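# Probabilistic multi-class random forest over the genomes x PC bit-score
# matrix: 1,000 trees, up to 5,000 candidate split variables per node
# (capped at the feature count), impurity variable importance.  Class
# probabilities are the mean of per-tree class-proportion votes; the
# predicted host is the genus with the highest probability.

#' Random forest configuration
#'
#' @param n_trees number of trees.
#' @param mtry candidate split variables per node (capped at the feature
#'   count when training).
#' @param seed integer seed; fixing it makes training deterministic.
#' @param min_node_size minimal node size.
#' @return an `rf_config` list.
#' @export
rf_config <- function(n_trees = 1000, mtry = 5000, seed = 1,
                      min_node_size = 1) {
  stopifnot(n_trees >= 1, mtry >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 seed = as.integer(seed),
                 min_node_size = as.integer(min_node_size)),
            class = "rf_config")
}

#' Train the host-genus random forest
#'
#' @param mat feature matrix (genomes x pcs) with rownames/colnames.
#' @param labels named character vector genome_id -> genus covering every
#'   training genome.  Genera represented by a single genome are legal.
#' @param config an [rf_config()].
#' @return an `rf_host_model`: classes, feature_ids, fitted ensemble,
#'   config and impurity importances.
#' @export
rf_train <- function(mat, labels, config = rf_config()) {
  stopifnot(nrow(mat) >= 2)
  unknown <- setdiff(names(labels), rownames(mat))
  if (length(unknown)) {
    stop("label(s) for unknown genome(s): ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(rownames(mat), names(labels))
  if (length(miss)) {
    stop("unlabeled training genome(s): ", paste(miss, collapse = ", "))
  }
  y <- labels[rownames(mat)]
  classes <- sort(unique(unname(y)))
  if (length(classes) == 1) {
    warning("single distinct class; returning a degenerate constant model")
    return(structure(list(classes = classes, feature_ids = colnames(mat),
                          forest = NULL, config = config,
                          importances = setNames(rep(0, ncol(mat)),
                                                 colnames(mat))),
                     class = "rf_host_model"))
  }
  x <- as.data.frame(mat)
  names(x) <- paste0("pc_", seq_len(ncol(mat)))  # syntactic, order-stable
  fit <- ranger::ranger(
    x = x, y = factor(unname(y), levels = classes),
    num.trees = config$n_trees,
    mtry = min(config$mtry, ncol(mat)),
    probability = TRUE,
    importance = "impurity",
    min.node.size = config$min_node_size,
    seed = config$seed,
    num.threads = 1)
  imp <- setNames(as.numeric(fit$variable.importance), colnames(mat))
  structure(list(classes = classes, feature_ids = colnames(mat),
                 forest = fit, config = config, importances = imp),
            class = "rf_host_model")
}

#' Predict host genera with a trained model
#'
#' Matrix columns are reconciled to the model's features: missing PCs are
#' filled with zeros, extra PCs dropped with a warning.  Each genome gets a
#' probability vector over the classes summing to 1; the winner is the
#' argmax (ties broken lexicographically and flagged).
#'
#' @param model an `rf_host_model`.
#' @param mat feature matrix of the genomes to predict.
#' @param taxonomy taxonomy table for lineage expansion.
#' @return list of [host_prediction()] objects (method rf) with the full
#'   probability matrix attached as attribute `prob`.
#' @export
rf_predict <- function(model, mat, taxonomy) {
  if (nrow(mat) == 0) return(list())
  extra <- setdiff(colnames(mat), model$feature_ids)
  if (length(extra)) {
    warning(length(extra), " feature column(s) unknown to the model dropped")
  }
  full <- matrix(0, nrow = nrow(mat), ncol = length(model$feature_ids),
                 dimnames = list(rownames(mat), model$feature_ids))
  shared <- intersect(colnames(mat), model$feature_ids)
  full[, shared] <- mat[, shared, drop = FALSE]
  if (is.null(model$forest)) { # degenerate single-class model
    prob <- matrix(1, nrow = nrow(full), ncol = 1,
                   dimnames = list(rownames(full), model$classes))
  } else {
    x <- as.data.frame(full)
    names(x) <- paste0("pc_", seq_len(ncol(full)))
    prob <- predict(model$forest, data = x, num.threads = 1)$predictions
    rownames(prob) <- rownames(full)
  }
  prob <- prob[, sort(colnames(prob)), drop = FALSE]
  preds <- lapply(seq_len(nrow(prob)), function(i) {
    p <- setNames(as.numeric(prob[i, ]), colnames(prob))
    best <- which(p == max(p))
    tie <- length(best) > 1
    genus <- colnames(prob)[min(best)]
    lineage <- tryCatch(expand_lineage(genus, taxonomy),
                        hostforest_unknown_taxon = function(e) {
                          setNames(c(genus, rep(NA_character_, 5)), TAX_RANKS)
                        })
    host_prediction(rownames(prob)[i], p, lineage, "rf", tie = tie)
  })
  attr(preds, "prob") <- prob
  preds
}

#' Impurity importance ranking
#'
#' @param model an `rf_host_model`.
#' @return data.frame(pc_id, importance) in descending importance
#'   (ties broken lexicographically).
#' @export
importance_ranking <- function(model) {
  imp <- model$importances
  ord <- order(-imp, names(imp))
  data.frame(pc_id = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Filter predictions by score threshold
#'
#' @param preds list of [host_prediction()] objects (or a prediction
#'   data.frame with a best_score column).
#' @param cutoff minimum best_score retained, in [0, 1] for rf scores.
#' @param rank taxonomic rank the cutoff is aimed at; recorded as metadata.
#' @return the retained predictions with attribute `rank`.
#' @export
apply_threshold <- function(preds, cutoff, rank = "genus") {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (is.data.frame(preds)) {
    out <- preds[preds$best_score >= cutoff, , drop = FALSE]
  } else {
    out <- Filter(function(p) p$best_score >= cutoff, preds)
  }
  attr(out, "rank") <- rank
  attr(out, "cutoff") <- cutoff
  out
}

#' Persist / restore a trained model archive
#'
#' The archive bundles the fitted ensemble with its feature list, class
#' list, profiles (optional) and configuration so that `predict` can run
#' from a viral FASTA alone.
#'
#' @param model an `rf_host_model`.
#' @param path file path (RDS).
#' @param profiles optional list of profile models to bundle.
#' @param taxonomy optional taxonomy table to bundle.
#' @export
write_model <- function(model, path, profiles = NULL, taxonomy = NULL) {
  saveRDS(list(format_version = 1L, model = model, profiles = profiles,
               taxonomy = taxonomy), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version) || x$format_version != 1L) {
    stop("unsupported model archive version")
  }
  x
}
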
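# End-to-end orchestration: proteins -> clusters -> profiles -> feature
# matrix -> random forest, and FASTA -> prediction for a trained model
# archive.

#' Train a host-prediction model from proteins and labels
#'
#' Runs clustering, profile building, profile search, matrix assembly,
#' supercluster pruning and forest training in one pass.
#'
#' @param proteins viral protein record data.frame.
#' @param genome_ids ids of all training genomes (rows of the matrix; kept
#'   even when a genome has no qualifying hit).
#' @param labels named character vector genome_id -> host genus.
#' @param taxonomy taxonomy table.
#' @param config an [rf_config()].
#' @param min_identity,min_coverage clustering thresholds.
#' @param max_evalue,min_span,min_score hit filters.
#' @param r_threshold supercluster Pearson threshold.
#' @return list(model, profiles, clusters, matrix, pruned, supercluster_map,
#'   taxonomy).
#' @export
train_pipeline <- function(proteins, genome_ids, labels, taxonomy,
                           config = rf_config(),
                           min_identity = 0.35, min_coverage = 0.70,
                           max_evalue = 1e-5, min_span = 0.70,
                           min_score = 50, r_threshold = 0.9) {
  built <- build_protein_profiles(proteins, min_identity, min_coverage)
  hits <- score_proteins(proteins, built$profiles)
  pcs <- vapply(built$profiles, `[[`, character(1), "profile_id")
  mat <- build_matrix(hits, genome_ids, pcs, max_evalue, min_span, min_score)
  pr <- if (ncol(mat) >= 2) prune_superclusters(mat, r_threshold) else
    list(matrix = mat, map = data.frame(pc_id = colnames(mat),
                                        representative = colnames(mat)),
         r_threshold = r_threshold)
  model <- rf_train(pr$matrix, labels, config)
  keep <- vapply(built$profiles, function(p) {
    p$profile_id %in% colnames(pr$matrix)
  }, logical(1))
  list(model = model, profiles = built$profiles[keep],
       clusters = built$clusters, matrix = mat, pruned = pr$matrix,
       supercluster_map = pr$map, taxonomy = taxonomy)
}

#' Predict hosts for viral genomes with a trained pipeline
#'
#' @param trained output of [train_pipeline()] (or a model archive read by
#'   [read_model()] with profiles and taxonomy bundled).
#' @param proteins protein records of the genomes to predict (e.g. from
#'   [extract_orfs()] or the generator).
#' @param genome_ids ids of all genomes to predict.
#' @inheritParams train_pipeline
#' @return list of [host_prediction()] objects (method rf).
#' @export
predict_pipeline <- function(trained, proteins, genome_ids,
                             max_evalue = 1e-5, min_span = 0.70,
                             min_score = 50) {
  profiles <- trained$profiles
  hits <- score_proteins(proteins, profiles)
  pcs <- vapply(profiles, `[[`, character(1), "profile_id")
  mat <- build_matrix(hits, genome_ids, pcs, max_evalue, min_span, min_score)
  rf_predict(trained$model, mat, trained$taxonomy)
}
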
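# Shared fixtures, all generated in code.  Expensive objects (the default
# synthetic universe and its trained forest) are computed once per test
# session and cached.

.fixtures <- new.env(parent = emptyenv())

rnd_dna <- function(n) hostforest:::random_dna(n)
rnd_prot <- function(n) hostforest:::random_protein(n)
mutate_dna_at <- function(seq, rate) hostforest:::mutate_dna(seq, rate)

# substitute amino acids at `rate` (first residue kept)
mutate_prot <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  hit <- hit[hit > 1]
  for (p in hit) {
    chars[p] <- sample(setdiff(hostforest:::AA20, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# simple protein record frame
prot_frame <- function(ids, seqs, genome_ids = ids) {
  data.frame(protein_id = ids, genome_id = genome_ids,
             begin = NA_integer_, end = NA_integer_, strand = NA_character_,
             aa_sequence = seqs, stringsAsFactors = FALSE)
}

# small taxonomy over two plain genera
toy_taxonomy <- function(genera = c("GenusA", "GenusB")) {
  taxonomy_table(data.frame(
    genus = genera,
    family = paste0("Fam", seq_along(genera)),
    order = "Order1", class = "Class1", phylum = "Phylum1",
    domain = "Bacteria", stringsAsFactors = FALSE))
}

# The study-conditions universe (generator defaults) with an 80/20 split
# and a trained forest; cached because several checks share it.
default_rf_fit <- function() {
  if (!is.null(.fixtures$rf_fit)) return(.fixtures$rf_fit)
  u <- generate_universe(universe_config(seed = 5))
  labels <- setNames(u$truth$virus_truth$genus, u$truth$virus_truth$viral_id)
  set.seed(42)
  test_ids <- sort(sample(u$viruses$genome_id,
                          round(0.2 * nrow(u$viruses))))
  train_ids <- setdiff(u$viruses$genome_id, test_ids)
  tr <- train_pipeline(u$proteins[u$proteins$genome_id %in% train_ids, ],
                       train_ids, labels[train_ids], u$truth$taxonomy,
                       config = rf_config(seed = 11))
  preds <- predict_pipeline(tr, u$proteins[u$proteins$genome_id %in% test_ids, ],
                            test_ids)
  # map clusters to planted families to identify the planted marker PCs
  cf <- cluster_frame(tr$clusters)
  ptr <- u$truth$protein_truth
  fam <- tapply(ptr$family_id[match(cf$protein_id, ptr$protein_id)],
                cf$cluster_id,
                function(x) names(sort(table(x), decreasing = TRUE))[1])
  marker_pcs <- intersect(names(fam)[startsWith(unname(fam), "MF_")],
                          colnames(tr$pruned))
  .fixtures$rf_fit <- list(universe = u, labels = labels,
                           train_ids = train_ids, test_ids = test_ids,
                           trained = tr, preds = preds,
                           pred_df = prediction_frame(preds),
                           marker_pcs = marker_pcs)
  .fixtures$rf_fit
}

# a separable two-genus feature matrix (disjoint marker PCs + noise)
separable_matrix <- function(n_per_genus = 20, seed = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(2 * n_per_genus))
  genus <- rep(c("GenusA", "GenusB"), each = n_per_genus)
  pcs <- c(paste0("mA", 1:5), paste0("mB", 1:5), paste0("noise", 1:20))
  mat <- matrix(0, length(ids), length(pcs), dimnames = list(ids, pcs))
  for (i in seq_along(ids)) {
    mk <- if (genus[i] == "GenusA") paste0("mA", 1:5) else paste0("mB", 1:5)
    mat[i, mk] <- runif(5, 200, 400)
    mat[i, sample(paste0("noise", 1:20), 3)] <- runif(3, 60, 120)
  }
  list(matrix = mat, labels = setNames(genus, ids),
       taxonomy = toy_taxonomy())
}
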
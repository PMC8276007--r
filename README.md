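# hostforest

Host-genus prediction for viruses of Bacteria and Archaea from protein
content.

Most environmental viral contigs carry none of the classical virus–host
signals (CRISPR protospacers, long homology matches, shared tRNAs), so the
precise alignment-dependent methods leave the majority of viruses without a
host, while alignment-free composition methods assign almost everything at
low precision.  `hostforest` takes the machine-learning route: viral
proteins are clustered into families, every genome is summarised as a
vector of best-hit bit scores against the family profiles, and a
probabilistic multi-class random forest maps that vector to a host genus
with a probability for every candidate genus and the full lineage up to the
domain level.

The core objects and steps:

* **Protein clusters → profiles.** Greedy incremental clustering at ≥ 35%
  identity over ≥ 70% of both sequences (BLOSUM62, affine gaps 11/1),
  center-star MSA, and a per-column log-odds model
  `s(x) = log2(((c_x + α·b_x)/(n + α))/b_x)` per cluster.
* **Feature matrix.** Best local alignment of each protein against each
  profile; hits filtered at e-value ≤ 1e−5, ≥ 70% span of both, bit score
  ≥ 50; cell = best hit per (genome, cluster).  Clusters correlated at
  Pearson r ≥ 0.9 collapse into superclusters (one representative kept).
* **Forest.** 1,000 trees, mtry = min(5000, features), probability mode,
  impurity importances; prediction = argmax genus, with score thresholds
  to trade recall for precision.
* **Classical pipeline.** CRISPR spacer (exact, both strands), homology
  (≥ 500 bp, ≥ 95% id), and tRNA (≥ 60 bp, ≥ 97% id, ≤ 10 mismatches)
  evidence pooled per viral population (≥ 95% ANI, ≥ 80% shared genes)
  with 3/2/1 points; the top-scoring genus wins, ties abstain.
* **Alignment-free checks.** MinHash sketches with the Mash distance
  `d = −ln(2j/(1+j))/k` (k = 13..20) and Manhattan/correlation over
  canonical 6-mer frequencies; `nearest_host()` picks the closest
  reference.
* **Evaluation.** Per-rank precision/recall/F1 (multiple predictions per
  sequence count once, correct if any matches), cutoff sweeps, bootstrap
  precision (20% × 1,000 reps), CD-HIT-style dereplication, and AAI-based
  train/test independence filtering (> 70% shared proteins or > 70% AAI
  removes a test genome).
* **Synthetic universe.** A generator plants genus-private marker
  families, CRISPR arrays, homologous segments, shared tRNAs and
  fragmented genomes, so every stage of the pipeline is exercisable — and
  fully deterministic — without external downloads.

## Worked example

```r
library(hostforest)

# 1. a small synthetic virus-host universe (4 genera x 6 viruses)
u <- generate_universe(universe_config(n_genera = 4, viruses_per_genus = 6,
                                       seed = 42))
labels <- setNames(u$truth$virus_truth$genus, u$truth$virus_truth$viral_id)

# 2. hold out five genomes, train the forest on the rest
set.seed(1)
test_ids  <- sort(sample(u$viruses$genome_id, 5))
train_ids <- setdiff(u$viruses$genome_id, test_ids)
trained <- train_pipeline(u$proteins[u$proteins$genome_id %in% train_ids, ],
                          train_ids, labels[train_ids], u$truth$taxonomy,
                          config = rf_config(seed = 1))

# 3. predict the held-out genomes
preds <- predict_pipeline(trained,
                          u$proteins[u$proteins$genome_id %in% test_ids, ],
                          test_ids)
pred_df <- prediction_frame(preds)
pred_df[, c("genome_id", "best_genus", "best_score", "phylum", "domain")]
#>   genome_id best_genus best_score    phylum   domain
#> 1     V0001    Genus01      0.742 PhylumB01 Bacteria
#> 2     V0002    Genus01      0.757 PhylumB01 Bacteria
#> 3     V0004    Genus01      0.753 PhylumB01 Bacteria
#> 4     V0007    Genus02      0.948 PhylumB01 Bacteria
#> 5     V0011    Genus02      0.955 PhylumB01 Bacteria

# 4. evaluate at genus level
truth <- data.frame(viral_id = names(labels), genus = unname(labels))
compute_metrics(pred_df, truth[truth$viral_id %in% test_ids, ], "genus")
#>    rank cutoff precision recall f1 n_total n_predicted n_correct n_evaluable
#> 1 genus      0         1      1  1       5           5         5           5
```

Each held-out virus is assigned its true genus; `best_score` is the
forest's probability for the winning genus (the full per-genus vector is on
each prediction object), and the lineage columns come from the taxonomy
table.  `compute_metrics` reports recall (fraction of genomes given any
prediction), precision (fraction of evaluable predictions that are
correct), and their harmonic mean.

A command-line surface mirrors the same flow
(`fixtures → train → predict → evaluate`, plus `classical`, `distance`,
`cluster`, `matrix`); see `inst/scripts/hostforest`:

```sh
Rscript inst/scripts/hostforest fixtures --seed 7 --out fx/
Rscript inst/scripts/hostforest train --viruses fx/viruses.fna \
    --proteins fx/proteins.faa --labels fx/virus_truth.tsv \
    --taxonomy fx/taxonomy.tsv --out model.rds
Rscript inst/scripts/hostforest predict --model model.rds \
    --viruses fx/viruses.fna --proteins fx/proteins.faa --out preds.tsv
```

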
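# Metrics, cutoff sweeps, bootstrap precision, dereplication and AAI
# independence filtering.

test_that("compute_metrics reproduces the four-sequence worked example", {
  truth <- data.frame(viral_id = paste0("s", 1:4),
                      genus = c("A", "B", "C", "D"), stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = c("s1", "s2", "s3"),
                      genus = c("A", "B", "X"), score = 1,
                      stringsAsFactors = FALSE)
  m <- compute_metrics(preds, truth, "genus")
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$f1, 2 * 0.75 * (2 / 3) / (0.75 + 2 / 3), tolerance = 1e-9)
  expect_equal(m$n_predicted, 3)
  expect_equal(m$n_correct, 2)
})

test_that("multiple predictions count once, correct if any matches", {
  truth <- data.frame(viral_id = "s1", genus = "A", stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = c("s1", "s1"), genus = c("B", "A"),
                      score = 1, stringsAsFactors = FALSE)
  m <- compute_metrics(preds, truth, "genus")
  expect_equal(m$n_predicted, 1)
  expect_equal(m$n_correct, 1)
  expect_equal(m$precision, 1)
})

test_that("missing truth ranks leave precision but not recall", {
  truth <- data.frame(viral_id = paste0("s", 1:3),
                      genus = c("A", "B", "C"),
                      class = c("C1", NA, "C3"), stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = paste0("s", 1:3),
                      class = c("C1", "Cx", "Cwrong"), score = 1,
                      stringsAsFactors = FALSE)
  m <- compute_metrics(preds, truth, "class")
  expect_equal(m$recall, 1)          # all three predicted
  expect_equal(m$n_evaluable, 2)     # s2's truth class is undetermined
  expect_equal(m$precision, 0.5)     # s1 correct, s3 wrong
})

test_that("no passing predictions yields zero with explicit counts", {
  truth <- data.frame(viral_id = paste0("s", 1:3), genus = "A",
                      stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = "s1", genus = "A", score = 0.2,
                      stringsAsFactors = FALSE)
  m <- compute_metrics(preds, truth, "genus", cutoff = 0.5)
  expect_equal(m$recall, 0)
  expect_equal(m$precision, 0)
  expect_equal(m$n_predicted, 0)
  expect_error(compute_metrics(preds, truth, "species"), "invalid rank")
})

test_that("cutoff sweeps are non-increasing in recall (brute-force check)", {
  set.seed(241)
  n <- 60
  truth <- data.frame(viral_id = sprintf("s%02d", 1:n),
                      genus = sample(LETTERS[1:4], n, TRUE),
                      stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = sample(truth$viral_id, 45),
                      genus = sample(LETTERS[1:4], 45, TRUE),
                      score = runif(45), stringsAsFactors = FALSE)
  grid <- seq(0, 1, 0.1)
  sw <- cutoff_sweep(preds, truth, "genus", grid)
  expect_true(all(diff(sw$recall) <= 1e-12))
  # each row equals an independent recomputation at that cutoff
  for (i in c(1, 5, 11)) {
    keep <- preds[preds$score >= grid[i], , drop = FALSE]
    expect_equal(sw$recall[i], length(unique(keep$viral_id)) / n)
  }
  one <- cutoff_sweep(preds, truth, "genus", 0)
  expect_equal(one$precision, compute_metrics(preds, truth, "genus")$precision)
})

test_that("precision improves from genus to domain on consistent lineages", {
  tab <- taxonomy_table(data.frame(
    genus = c("A", "B", "C"), family = c("F1", "F1", "F2"),
    order = "O1", class = "C1", phylum = "P1", domain = "Bacteria",
    stringsAsFactors = FALSE))
  lin <- function(g) as.data.frame(t(expand_lineage(g, tab)),
                                   stringsAsFactors = FALSE)
  truth <- cbind(data.frame(viral_id = paste0("s", 1:3)),
                 rbind(lin("A"), lin("B"), lin("C")))
  preds <- cbind(data.frame(viral_id = paste0("s", 1:3), score = 1),
                 rbind(lin("B"), lin("B"), lin("C")))
  pg <- compute_metrics(preds, truth, "genus")$precision
  pd <- compute_metrics(preds, truth, "domain")$precision
  expect_gte(pd, pg)
})

test_that("bootstrap precision is deterministic and well-calibrated", {
  truth <- data.frame(viral_id = sprintf("s%03d", 1:100), genus = "A",
                      stringsAsFactors = FALSE)
  preds <- data.frame(viral_id = truth$viral_id,
                      genus = c(rep("A", 80), rep("B", 20)), score = 1,
                      stringsAsFactors = FALSE)
  b1 <- bootstrap_precision(preds, truth, "genus", reps = 200, seed = 4)
  b2 <- bootstrap_precision(preds, truth, "genus", reps = 200, seed = 4)
  expect_identical(b1$values, b2$values)
  expect_gt(b1$sd, 0)
  expect_equal(b1$mean, 0.8, tolerance = 0.03)
  # all-correct fixture: mean 1, sd 0
  all_ok <- bootstrap_precision(preds[1:80, ], truth[1:80, ], "genus",
                                reps = 50, seed = 4)
  expect_equal(all_ok$mean, 1)
  expect_equal(all_ok$sd, 0)
  # frac = 1 with one rep equals the full-data precision
  full <- bootstrap_precision(preds, truth, "genus", frac = 1, reps = 1,
                              seed = 1)
  expect_equal(full$mean, compute_metrics(preds, truth, "genus")$precision)
  expect_error(bootstrap_precision(preds, truth, "genus", frac = 1.2), "frac")
})

test_that("dereplication removes near-duplicates but keeps chimeras", {
  set.seed(251)
  g1 <- rnd_dna(3000)
  genomes <- data.frame(genome_id = c("a", "dup"), sequence = c(g1, g1),
                        stringsAsFactors = FALSE)
  expect_equal(dereplicate(genomes)$genome_id, "a")
  # 96% identical full-length pair collapses
  g2 <- mutate_dna_at(g1, 0.04)
  expect_equal(nrow(dereplicate(data.frame(genome_id = c("a", "b"),
                                           sequence = c(g1, g2),
                                           stringsAsFactors = FALSE))), 1)
  # high identity over only 30% of the shorter: both retained, input order
  g3 <- paste0(substr(g1, 1, 900), rnd_dna(2100))
  out <- dereplicate(data.frame(genome_id = c("c", "a"),
                                sequence = c(g3, g1),
                                stringsAsFactors = FALSE))
  expect_equal(out$genome_id, c("c", "a"))
})

test_that("AAI criteria drive the independence filter", {
  set.seed(261)
  pa <- vapply(1:6, function(i) rnd_prot(100), character(1))
  r <- compute_aai(pa, pa)
  expect_equal(r$aai, 100)
  expect_equal(r$shared_fraction, 1)
  # half-shared proteome: shared 0.5 but AAI 100
  r2 <- compute_aai(pa, pa[1:3])
  expect_equal(r2$aai, 100)
  expect_equal(r2$shared_fraction, 0.5)
  # unrelated proteomes share nothing qualifying
  pb <- vapply(1:6, function(i) rnd_prot(100), character(1))
  r3 <- compute_aai(pa, pb)
  expect_lt(r3$shared_fraction, 0.2)
  expect_error(compute_aai(pa, character(0)), "empty proteome")
  kept <- filter_test_independence(
    list(ident = pa, half = pa[1:4], unrel = pb),
    list(train1 = pa))
  expect_equal(kept, "unrel")
})
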
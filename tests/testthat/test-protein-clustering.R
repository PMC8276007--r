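# Pairwise alignment contract, greedy clustering, star MSA and profile
# models.

test_that("align_pair identity/coverage match hand-computed cases", {
  r <- align_pair("MKVLAT", "MKV")
  expect_equal(r$identity, 1)
  expect_equal(r$cov_a, 0.5)
  expect_equal(r$cov_b, 1)
  self <- align_pair("MKVLATPEWQRS", "MKVLATPEWQRS")
  expect_equal(self$identity, 1)
  expect_equal(self$cov_a, 1)
  expect_equal(self$cov_b, 1)
  expect_error(align_pair("MKB*", "MKV"), "non-amino-acid")
})

test_that("align_pair is symmetric and near-random identity stays low", {
  set.seed(21)
  for (rep in 1:5) {
    a <- rnd_prot(sample(50:150, 1))
    b <- rnd_prot(sample(50:150, 1))
    ra <- align_pair(a, b)
    rb <- align_pair(b, a)
    expect_equal(ra$identity, rb$identity)
    expect_equal(ra$cov_a, rb$cov_b)
    expect_equal(ra$cov_b, rb$cov_a)
  }
  ids <- replicate(100, align_pair(rnd_prot(200), rnd_prot(200))$identity)
  expect_gte(mean(ids < 0.30), 0.95)
  expect_lt(mean(ids), 0.30)
})

test_that("greedy clustering separates planted families (ARI = 1)", {
  set.seed(31)
  seed_a <- rnd_prot(150)
  seed_b <- rnd_prot(150)
  # confirm the seeds are unrelated under the alignment oracle
  expect_lt(align_pair(seed_a, seed_b)$identity, 0.20)
  seqs <- c(vapply(1:10, function(i) mutate_prot(seed_a, 0.10), character(1)),
            vapply(1:10, function(i) mutate_prot(seed_b, 0.10), character(1)))
  fam <- rep(c("A", "B"), each = 10)
  prot <- prot_frame(sprintf("p%02d", 1:20), seqs)
  # all-pairs oracle: within-family identities comfortably above threshold
  for (i in c(1, 5)) {
    expect_gte(align_pair(seqs[i], seqs[i + 1])$identity, 0.70)
  }
  cl <- greedy_cluster(prot)
  expect_equal(length(cl), 2)
  got <- cluster_frame(cl)
  split_fams <- split(fam[match(got$protein_id, prot$protein_id)],
                      got$cluster_id)
  expect_true(all(vapply(split_fams, function(x) length(unique(x)) == 1,
                         logical(1))))
})

test_that("coverage gates fragments out of their parent cluster", {
  long <- rnd_prot(100)
  frag <- substr(long, 1, 60)
  cl <- greedy_cluster(prot_frame(c("full", "frag"), c(long, frag)))
  expect_equal(length(cl), 2)  # fragment covers only 0.6 of the representative
  # identical copies collapse into one cluster
  cl5 <- greedy_cluster(prot_frame(paste0("c", 1:5), rep(long, 5)))
  expect_equal(length(cl5), 1)
  expect_equal(length(cl5[[1]]$member_ids), 5)
})

test_that("clustering is order-invariant and monotone in min_identity", {
  set.seed(41)
  seeds <- replicate(3, rnd_prot(120))
  seqs <- unlist(lapply(seeds, function(s) {
    vapply(1:5, function(i) mutate_prot(s, 0.15), character(1))
  }))
  prot <- prot_frame(sprintf("p%02d", seq_along(seqs)), seqs)
  canon <- function(cl) {
    unname(lapply(cl, function(c) sort(c$member_ids)))
  }
  base <- canon(greedy_cluster(prot))
  perm <- prot[sample(nrow(prot)), ]
  expect_setequal(canon(greedy_cluster(perm)), base)
  n_loose <- length(greedy_cluster(prot, min_identity = 0.35))
  n_tight <- length(greedy_cluster(prot, min_identity = 0.80))
  expect_gte(n_tight, n_loose)
})

test_that("star MSA merges gaps and preserves members on degapping", {
  p <- data.frame(protein_id = c("r", "m"),
                  aa_sequence = c("MKVL", "MKL"), stringsAsFactors = FALSE)
  cl <- star_msa(list(cluster_id = "PC1", representative_id = "r",
                      member_ids = c("r", "m")), p)
  expect_equal(unname(cl$msa), c("MKVL", "MK-L"))
  # singleton: the sequence itself
  s <- star_msa(list(cluster_id = "PC2", representative_id = "r",
                     member_ids = "r"), p)
  expect_equal(unname(s$msa), "MKVL")
  # identical members: gap-free identical rows
  p3 <- prot_frame(c("a", "b", "c"), rep("MKVLATPEW", 3))
  cl3 <- star_msa(list(cluster_id = "PC3", representative_id = "a",
                       member_ids = c("a", "b", "c")), p3)
  expect_equal(unname(cl3$msa), rep("MKVLATPEW", 3))
  # degap invariant on a mutated family
  set.seed(51)
  seed <- rnd_prot(80)
  seqs <- c(seed, vapply(1:4, function(i) mutate_prot(seed, 0.1), character(1)))
  pf <- prot_frame(paste0("q", 1:5), seqs)
  clf <- star_msa(list(cluster_id = "PC4", representative_id = "q1",
                       member_ids = pf$protein_id), pf)
  expect_equal(length(unique(nchar(clf$msa))), 1)
  expect_equal(unname(gsub("-", "", clf$msa)), seqs)
})

test_that("profile scores follow the log-odds formula and drop gappy columns", {
  bg <- setNames(rep(0.05, 20), hostforest:::AA20)
  cl <- list(cluster_id = "P", representative_id = "p1",
             member_ids = paste0("p", 1:10),
             msa = setNames(rep("K", 10), paste0("p", 1:10)))
  prof <- build_profile(cl, pseudocount = 0.5, background = bg)
  k <- which(hostforest:::AA20 == "K")
  expect_equal(prof$match_scores[1, k],
               log2((10 + 0.5 * 0.05) / 10.5 / 0.05), tolerance = 1e-9)
  expect_equal(prof$match_scores[1, k], 4.2551, tolerance = 1e-4)
  # column with counts proportional to background scores ~0
  msa20 <- setNames(hostforest:::AA20, paste0("m", 1:20))
  clb <- list(cluster_id = "P2", representative_id = "m1",
              member_ids = names(msa20), msa = msa20)
  pb <- build_profile(clb, pseudocount = 0.5, background = bg)
  expect_lt(max(abs(pb$match_scores[1, 1:20])), 0.05)
  # 60%-gap column dropped
  rows <- setNames(c("MK", "M-", "M-", "M-"), paste0("r", 1:4))
  clg <- list(cluster_id = "P3", representative_id = "r1",
              member_ids = names(rows), msa = rows)
  pg <- build_profile(clg, background = bg)
  expect_equal(pg$length, 1)
  # expected score under background is never positive
  set.seed(61)
  seqs <- vapply(1:6, function(i) mutate_prot(rnd_prot(40), 0.2), character(1))
  pf <- prot_frame(paste0("x", 1:6), seqs)
  clx <- star_msa(list(cluster_id = "P4", representative_id = "x1",
                       member_ids = pf$protein_id), pf)
  px <- build_profile(clx)
  exp_scores <- px$match_scores[, 1:20] %*% px$background
  expect_true(all(exp_scores <= 1e-9))
  expect_error(build_profile(list(cluster_id = "P5", msa = NULL)), "MSA")
})

test_that("profile serialization round-trips", {
  set.seed(71)
  pf <- prot_frame(paste0("x", 1:4),
                   vapply(1:4, function(i) mutate_prot(rnd_prot(50), 0.1),
                          character(1)))
  built <- build_protein_profiles(pf)
  path <- withr::local_tempfile(fileext = ".txt")
  write_profiles(built$profiles, path)
  back <- read_profiles(path)
  expect_equal(length(back), length(built$profiles))
  expect_equal(back[[1]]$match_scores[, 1:20],
               built$profiles[[1]]$match_scores[, 1:20], tolerance = 1e-6)
  expect_equal(back[[1]]$profile_id, built$profiles[[1]]$profile_id)
})
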
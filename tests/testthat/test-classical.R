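# CRISPR / homology / tRNA matchers, viral population clustering and the
# per-population point scoring.

test_that("CRISPR detector recovers a planted array and rejects noise", {
  set.seed(121)
  rep_word <- rnd_dna(29)
  spacers <- replicate(3, rnd_dna(32))
  array <- paste0(rep_word, paste(paste0(spacers, rep_word), collapse = ""))
  host <- list(genome_id = "h",
               sequence = paste0(rnd_dna(1500), array, rnd_dna(1500)))
  found <- detect_crispr_arrays(host)
  expect_equal(length(found), 1)
  expect_equal(found[[1]]$repeat_seq, rep_word)
  expect_equal(found[[1]]$spacers, spacers)
  # two repeat copies only: below min_repeats
  two <- list(genome_id = "h2",
              sequence = paste0(rnd_dna(500), rep_word, spacers[1], rep_word,
                                rnd_dna(500)))
  expect_equal(length(detect_crispr_arrays(two)), 0)
  # random sequence: no arrays
  hits <- vapply(1:100, function(i) {
    length(detect_crispr_arrays(list(genome_id = "r", sequence = rnd_dna(5000))))
  }, integer(1))
  expect_equal(sum(hits), 0)
})

test_that("spacer matching is exact-only and strand-symmetric", {
  set.seed(131)
  sp <- rnd_dna(32)
  arrays <- list(list(host_genome_id = "h1", repeat_seq = rnd_dna(29),
                      spacers = sp, begin = 1, end = 100))
  hg <- c(h1 = "GenusA")
  viral <- data.frame(
    genome_id = c("exact", "mism", "rc"),
    sequence = c(paste0(rnd_dna(300), sp, rnd_dna(300)),
                 paste0(rnd_dna(300), mutate_dna_at(sp, 0), rnd_dna(300)),
                 paste0(rnd_dna(300), revcomp(sp), rnd_dna(300))),
    stringsAsFactors = FALSE)
  # plant exactly one substitution in the second genome's copy
  ch <- strsplit(sp, "")[[1]]
  ch[16] <- setdiff(c("A", "C", "G", "T"), ch[16])[1]
  viral$sequence[2] <- paste0(rnd_dna(300), paste(ch, collapse = ""),
                              rnd_dna(300))
  sig <- match_spacers(arrays, viral, hg)
  expect_setequal(sig$viral_id, c("exact", "rc"))
  expect_true(all(sig$kind == "crispr"))
  expect_true(all(sig$points == 3))
})

test_that("homology matching enforces length, identity and host dedupe", {
  set.seed(141)
  host <- rnd_dna(8000)
  hdf <- data.frame(genome_id = "H1", sequence = host, source = "H1 ref",
                    stringsAsFactors = FALSE)
  hg <- c(H1 = "GenusA")
  seg <- substr(host, 3000, 3599)
  mk <- function(id, insert) data.frame(
    genome_id = id, sequence = paste0(rnd_dna(800), insert, rnd_dna(700)),
    stringsAsFactors = FALSE)
  expect_equal(nrow(match_homology(mk("ok", seg), hdf, hg)), 1)
  expect_equal(nrow(match_homology(mk("short", substr(seg, 1, 400)), hdf, hg)),
               0)
  expect_equal(nrow(match_homology(mk("weak", mutate_dna_at(seg, 0.10)),
                                   hdf, hg)), 0)
  # reverse-complement insert still matches
  expect_equal(nrow(match_homology(mk("rc", revcomp(seg)), hdf, hg)), 1)
  # one signal per (virus, genus) even with two qualifying hosts
  hdf2 <- rbind(hdf, data.frame(genome_id = "H2", sequence = host,
                                source = "H2 ref", stringsAsFactors = FALSE))
  sig <- match_homology(mk("ok", seg), hdf2, c(H1 = "GenusA", H2 = "GenusA"))
  expect_equal(nrow(sig), 1)
})

test_that("tRNA matching applies all five thresholds", {
  set.seed(151)
  tr <- rnd_dna(72)
  host <- data.frame(genome_id = "H1",
                     sequence = paste0(rnd_dna(2500), tr, rnd_dna(2500)),
                     source = "", stringsAsFactors = FALSE)
  hg <- c(H1 = "GenusA")
  sub_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in c(12, 33, 55)[seq_len(k)]) {
      ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    paste(ch, collapse = "")
  }
  trnas <- data.frame(viral_id = c("v0", "v2", "v3"),
                      sequence = c(tr, sub_at(tr, 2), sub_at(tr, 3)),
                      stringsAsFactors = FALSE)
  sig <- match_trnas(trnas, host, hg)
  # identity 70/72 = 0.972 passes; 69/72 = 0.958 fails
  expect_setequal(sig$viral_id, c("v0", "v2"))
  expect_true(all(sig$points == 1))
})

test_that("viral populations follow ANI/shared-gene edges transitively", {
  set.seed(161)
  genes <- replicate(3, paste0("ATG", rnd_dna(597)))
  assemble <- function(gs) {
    parts <- character(0); pos <- 0; coords <- list()
    for (g in gs) {
      gap <- rnd_dna(30)
      parts <- c(parts, gap, g)
      coords[[length(coords) + 1]] <- c(pos + 31, pos + 30 + nchar(g))
      pos <- pos + 30 + nchar(g)
    }
    list(seq = paste(parts, collapse = ""), coords = coords)
  }
  genes_b <- lapply(genes, mutate_dna_at, rate = 0.03)
  genes_c <- lapply(genes_b, mutate_dna_at, rate = 0.03)
  gA <- assemble(genes)
  gB <- assemble(genes_b)
  gC <- assemble(genes_c)
  gD <- assemble(lapply(genes, mutate_dna_at, rate = 0.10))
  viral <- data.frame(genome_id = c("A", "A2", "B", "C", "D"),
                      sequence = c(gA$seq, gA$seq, gB$seq, gC$seq, gD$seq),
                      stringsAsFactors = FALSE)
  prot <- do.call(rbind, lapply(c("A", "A2", "B", "C", "D"), function(id) {
    cc <- switch(id, A = gA, A2 = gA, B = gB, C = gC, D = gD)
    do.call(rbind, lapply(seq_along(cc$coords), function(k) {
      data.frame(protein_id = paste0(id, "|", k), genome_id = id,
                 begin = cc$coords[[k]][1], end = cc$coords[[k]][2],
                 strand = "+", aa_sequence = "M", stringsAsFactors = FALSE)
    }))
  }))
  vps <- cluster_viral_populations(viral, prot)
  vp_of <- setNames(vps$vp_id, vps$genome_id)
  expect_equal(vp_of[["A"]], vp_of[["A2"]])   # identical genomes: one VP
  expect_equal(vp_of[["A"]], vp_of[["B"]])    # ~97% ANI: same VP
  # C joins through B (A~C below threshold on its own): transitive closure
  expect_equal(vp_of[["C"]], vp_of[["A"]])
  expect_false(vp_of[["D"]] == vp_of[["A"]])  # ~90% ANI: separate VP
  # populations partition the input
  expect_setequal(vps$genome_id, viral$genome_id)
  expect_equal(anyDuplicated(vps$genome_id), 0L)
})

test_that("population scoring sums 3/2/1 points and reports ties", {
  sig <- function(v, g, kind) data.frame(
    viral_id = v, host_genus = g, kind = kind,
    points = c(crispr = 3, homology = 2, trna = 1)[[kind]],
    detail = "", stringsAsFactors = FALSE)
  vp <- list(vp_id = "VP1", member_ids = c("v1", "v2"))
  p <- score_population_hosts(vp, rbind(sig("v1", "A", "crispr"),
                                        sig("v2", "B", "trna")))
  expect_equal(p$best_genus, "A")
  expect_equal(p$best_score, 3)
  p2 <- score_population_hosts(vp, rbind(sig("v1", "A", "homology"),
                                         sig("v2", "A", "homology"),
                                         sig("v1", "B", "trna")))
  expect_equal(p2$best_genus, "A")
  expect_equal(p2$best_score, 4)  # every signal accumulates
  expect_null(score_population_hosts(vp, sig("v3", "A", "crispr")[0, ]))
  tie <- score_population_hosts(vp, rbind(sig("v1", "A", "crispr"),
                                          sig("v2", "B", "crispr")))
  expect_s3_class(tie, "host_tie")
  expect_equal(tie$tied_genera, c("A", "B"))
  # permutation invariance
  s3 <- rbind(sig("v1", "A", "crispr"), sig("v1", "B", "homology"),
              sig("v2", "B", "homology"), sig("v2", "A", "trna"))
  p3a <- score_population_hosts(vp, s3)
  p3b <- score_population_hosts(vp, s3[sample(nrow(s3)), ])
  expect_equal(p3a$scores, p3b$scores)
  # dedupe flag collapses repeated (virus, genus, kind) signals
  pd <- score_population_hosts(vp, rbind(sig("v1", "A", "homology"),
                                         sig("v1", "A", "homology"),
                                         sig("v1", "B", "crispr")),
                               dedupe_per_kind = TRUE)
  expect_equal(pd$best_genus, "B")
})

test_that("classical_predict recovers planted hosts and filters plasmids", {
  cfg <- universe_config(n_genera = 3, viruses_per_genus = 3,
                         plant_crispr = 1, plant_homology = 1, plant_trna = 1,
                         seed = 19)
  u <- generate_universe(cfg)
  hosts <- rbind(u$hosts,
                 data.frame(genome_id = "PL1", sequence = rnd_dna(5000),
                            source = "PL1 plasmid sequence", genus = "Genus01",
                            stringsAsFactors = FALSE))
  hg <- c(u$truth$host_genera, PL1 = "Genus01")
  res <- classical_predict(u$viruses, hosts, hg, u$truth$taxonomy,
                           u$proteins, viral_trnas = u$truth$viral_trnas)
  truth <- setNames(u$truth$virus_truth$genus, u$truth$virus_truth$viral_id)
  expect_equal(nrow(res$predictions), nrow(u$viruses))
  expect_true(all(res$predictions$genus ==
                    truth[res$predictions$viral_id]))
  # every member of a VP carries the identical host genus
  by_vp <- split(res$predictions$genus, res$predictions$vp_id)
  expect_true(all(vapply(by_vp, function(x) length(unique(x)) == 1,
                         logical(1))))
  # plasmid record contributed no signals
  expect_false(any(grepl("PL1", res$signals$detail)))
})

test_that("known-host table short-circuits a population's assignment", {
  cfg <- universe_config(n_genera = 2, viruses_per_genus = 2,
                         plant_crispr = 0, plant_homology = 0, plant_trna = 0,
                         seed = 23)
  u <- generate_universe(cfg)
  known <- data.frame(viral_id = u$viruses$genome_id[1], genus = "Genus02",
                      stringsAsFactors = FALSE)
  res <- classical_predict(u$viruses, u$hosts, u$truth$host_genera,
                           u$truth$taxonomy, u$proteins, known_hosts = known)
  row <- res$predictions[res$predictions$viral_id == known$viral_id, ]
  expect_equal(row$genus, "Genus02")
})
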
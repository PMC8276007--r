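# MinHash sketches, Mash distances and k-mer frequency metrics.

test_that("sketching is deterministic, canonical and size-bounded", {
  set.seed(171)
  s <- rnd_dna(5000)
  a <- sketch(s, 13, 1000)
  expect_identical(a$minima, sketch(s, 13, 1000)$minima)
  expect_identical(a$minima, sketch(revcomp(s), 13, 1000)$minima)
  expect_lte(length(a$minima), 1000)
  expect_false(is.unsorted(a$minima))
  # sequence of length k: exactly one minimum
  expect_equal(length(sketch(rnd_dna(13), 13, 1000)$minima), 1)
  expect_error(sketch("ACGT", 13), "shorter than k")
  # a different hash seed produces a different sketch
  expect_false(identical(a$minima, sketch(s, 13, 1000, hash_seed = 7)$minima))
})

test_that("mash distance obeys identity, disjointness and the transform", {
  set.seed(181)
  s <- rnd_dna(4000)
  a <- sketch(s, 13, 1000)
  expect_equal(mash_distance(a, a), 0)
  polyA <- sketch(strrep("A", 500), 13, 1000)
  polyC <- sketch(strrep("C", 500), 13, 1000)
  expect_equal(mash_distance(polyA, polyC), 1)
  # symmetric
  b <- sketch(rnd_dna(4000), 13, 1000)
  expect_equal(mash_distance(a, b), mash_distance(b, a))
  expect_error(mash_distance(a, sketch(s, 15, 1000)), "mismatched k")
  # constructed sketches with Jaccard exactly 1/3
  mk <- function(m) structure(list(k = 13L, size = 1000L, hash_seed = 42,
                                   minima = m, seq_id = NA),
                              class = "minhash_sketch")
  d <- mash_distance(mk(c(1, 2, 3, 4)), mk(c(3, 4, 5, 6)))
  expect_equal(d, -log(2 * (1 / 3) / (1 + 1 / 3)) / 13, tolerance = 1e-12)
  expect_lt(abs(d - 0.0533), 1e-4)
})

test_that("MinHash Jaccard tracks the exact Jaccard within 3 SE", {
  set.seed(191)
  size <- 500
  for (rep in 1:20) {
    base <- rnd_dna(6000)
    other <- paste0(substr(base, 1, sample(1000:5000, 1)),
                    rnd_dna(sample(1000:4000, 1)))
    sa <- sketch(base, 15, size)
    sb <- sketch(other, 15, size)
    # exact Jaccard from the full hashed k-mer sets
    fa <- sketch(base, 15, Inf)$minima
    fb <- sketch(other, 15, Inf)$minima
    j_exact <- length(intersect(fa, fb)) / length(union(fa, fb))
    u <- sort(unique(c(sa$minima, sb$minima)))
    bottom <- u[seq_len(min(size, length(u)))]
    j_est <- sum(bottom %in% sa$minima & bottom %in% sb$minima) /
      min(size, length(u))
    se <- sqrt(max(j_exact * (1 - j_exact), 1e-6) / size)
    expect_lte(abs(j_est - j_exact), 3 * se + 1e-9)
  }
})

test_that("expected mash distance grows with mutation rate", {
  set.seed(201)
  base <- rnd_dna(20000)
  sa <- sketch(base, 15, 1000)
  mean_d <- vapply(c(0.01, 0.05, 0.10, 0.20), function(rate) {
    mean(vapply(1:3, function(i) {
      mash_distance(sa, sketch(mutate_dna_at(base, rate), 15, 1000))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})

test_that("k-mer frequency metrics behave on identical/disjoint inputs", {
  set.seed(211)
  s <- rnd_dna(3000)
  v <- kmer_profile(s)
  expect_equal(sum(v), 1)
  expect_equal(kmer_manhattan(v, v), 0)
  expect_equal(kmer_correlation(v, v), 1)
  disj <- kmer_manhattan(kmer_profile(strrep("A", 300)),
                         kmer_profile(strrep("C", 300)))
  expect_equal(disj, 2)
  # mutated copy is closer than an unrelated sequence (L1)
  wins <- vapply(1:20, function(i) {
    base <- rnd_dna(20000)
    pa <- kmer_profile(base)
    kmer_manhattan(pa, kmer_profile(mutate_dna_at(base, 0.05))) <
      kmer_manhattan(pa, kmer_profile(rnd_dna(20000)))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("nearest_host picks the closest reference and breaks ties stably", {
  set.seed(221)
  hostA <- rnd_dna(12000)
  hostB <- rnd_dna(12000)
  hosts <- data.frame(genome_id = c("HA", "HB"),
                      sequence = c(hostA, hostB), stringsAsFactors = FALSE)
  hg <- c(HA = "GenusA", HB = "GenusB")
  # mosaic of host-A segments
  segs <- vapply(1:5, function(i) {
    o <- sample(1:(nchar(hostA) - 2000), 1)
    substr(hostA, o, o + 1999)
  }, character(1))
  viral <- list(genome_id = "v1", sequence = paste(segs, collapse = ""))
  p <- nearest_host(viral, hosts, "mash", k = 15, host_genera = hg)
  expect_equal(p$best_genus, "GenusA")
  # the viral sequence itself among hosts wins with distance 0
  hosts2 <- rbind(hosts, data.frame(genome_id = "HV",
                                    sequence = viral$sequence,
                                    stringsAsFactors = FALSE))
  p2 <- nearest_host(viral, hosts2, "mash", k = 15,
                     host_genera = c(hg, HV = "GenusV"))
  expect_equal(p2$best_genus, "GenusV")
  expect_equal(unname(attr(p2, "distances")["HV"]), 0)
  # single host: returned regardless of distance
  p3 <- nearest_host(viral, hosts[2, ], "manhattan", host_genera = hg)
  expect_equal(p3$best_genus, "GenusB")
  # correlation metric maximises
  p4 <- nearest_host(viral, hosts, "correlation", host_genera = hg)
  expect_equal(p4$best_genus, "GenusA")
})

test_that("sketch JSON round-trips", {
  set.seed(231)
  s <- sketch(rnd_dna(2000), 14, 200, seq_id = "x1")
  path <- withr::local_tempfile(fileext = ".json")
  write_sketch(s, path)
  back <- read_sketch(path)
  expect_equal(back$minima, s$minima)
  expect_equal(back$k, s$k)
  expect_equal(back$seq_id, "x1")
})
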
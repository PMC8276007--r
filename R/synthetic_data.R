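# Self-contained synthetic virus-host universe with planted, recoverable
# signal for every pipeline stage: genus-private marker gene families,
# a shared noise-gene pool, host genomes carrying CRISPR arrays whose
# spacers target their genus's viruses, genus-private tRNA sets, planted
# homology segments, and fragmented viral genomes of varying completeness.
#
# Genes are built as nucleotide sequences (family seed reverse-translated
# once, members mutated per site at the configured rate, never through a
# stop codon); protein records are the exact translations of their
# coordinates, so the sequence/coordinate invariants hold by construction.

#' Synthetic universe configuration
#'
#' @param n_genera number of host genera (>= 2).
#' @param viruses_per_genus viral genomes per genus.
#' @param marker_families_per_genus genus-private marker protein families.
#' @param noise_gene_fraction fraction of each virus's genes drawn from the
#'   global noise pool.
#' @param per_site_mutation_rate per-nucleotide substitution rate applied
#'   to each gene copy relative to its family seed.
#' @param completeness_range percent range [lo, hi]; each viral genome is
#'   truncated to a completeness drawn uniformly from it.
#' @param plant_crispr,plant_homology,plant_trna per-virus probabilities of
#'   planting each classical evidence type (logical TRUE/FALSE map to
#'   0.3/0).
#' @param noise_pool_size size of the shared noise-family pool.
#' @param marker_len_range protein length range (residues) for family seeds.
#' @param host_len host genome backbone length (bp).
#' @param shared_marker_fraction "hard mode": fraction of marker families a
#'   genus shares with its sister genus (0 = fully genus-private).
#' @param seed RNG seed; the whole universe is deterministic given it.
#' @return a `universe_config` list.
#' @export
universe_config <- function(n_genera = 10, viruses_per_genus = 30,
                            marker_families_per_genus = 5,
                            noise_gene_fraction = 0.30,
                            per_site_mutation_rate = 0.05,
                            completeness_range = c(50, 100),
                            plant_crispr = 0.3, plant_homology = 0.3,
                            plant_trna = 0.3, noise_pool_size = 40,
                            marker_len_range = c(120, 240),
                            host_len = 12000,
                            shared_marker_fraction = 0, seed = 1) {
  as_prob <- function(x) {
    if (is.logical(x)) ifelse(x, 0.3, 0) else x
  }
  cfg <- list(n_genera = as.integer(n_genera),
              viruses_per_genus = as.integer(viruses_per_genus),
              marker_families_per_genus = as.integer(marker_families_per_genus),
              noise_gene_fraction = noise_gene_fraction,
              per_site_mutation_rate = per_site_mutation_rate,
              completeness_range = completeness_range,
              plant_crispr = as_prob(plant_crispr),
              plant_homology = as_prob(plant_homology),
              plant_trna = as_prob(plant_trna),
              noise_pool_size = as.integer(noise_pool_size),
              marker_len_range = as.integer(marker_len_range),
              host_len = as.integer(host_len),
              shared_marker_fraction = shared_marker_fraction,
              seed = as.integer(seed))
  probs <- c(cfg$noise_gene_fraction, cfg$per_site_mutation_rate,
             cfg$plant_crispr, cfg$plant_homology, cfg$plant_trna,
             cfg$shared_marker_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities/fractions must lie in [0,1]")
  if (cfg$n_genera < 2) stop("n_genera must be >= 2")
  if (any(cfg$completeness_range < 0 | cfg$completeness_range > 100) ||
        cfg$completeness_range[1] > cfg$completeness_range[2]) {
    stop("invalid completeness_range")
  }
  structure(cfg, class = "universe_config")
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @noRd
random_protein <- function(n) {
  paste(c("M", sample(AA20, n - 1, replace = TRUE)), collapse = "")
}

# codons per amino acid (stops excluded), fixed order for determinism
#' @noRd
codons_by_aa <- function() {
  if (is.null(.hf_cache$codons_by_aa)) {
    gc <- codon_table()
    gc <- gc[gc != "*"]
    .hf_cache$codons_by_aa <- split(names(gc), gc)
  }
  .hf_cache$codons_by_aa
}

#' @noRd
reverse_translate <- function(aa) {
  cba <- codons_by_aa()
  chars <- strsplit(aa, "")[[1]]
  paste(vapply(chars, function(a) {
    opts <- cba[[a]]
    opts[sample.int(length(opts), 1)]
  }, character(1)), collapse = "")
}

# substitute nucleotides at `rate`, redrawing any mutation that would turn
# an in-frame codon into a stop
#' @noRd
mutate_gene <- function(gene, rate) {
  if (rate <= 0) return(gene)
  chars <- strsplit(gene, "")[[1]]
  n <- length(chars)
  hit <- which(runif(n) < rate)
  hit <- hit[hit > 3 & hit <= n - 3] # keep the ATG and the stop codon
  stops <- c("TAA", "TAG", "TGA")
  for (p in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    new <- alt[sample.int(3, 1)]
    cod <- (p - 1) %/% 3
    old <- chars[p]
    chars[p] <- new
    codon <- paste(chars[(cod * 3 + 1):(cod * 3 + 3)], collapse = "")
    if (codon %in% stops) chars[p] <- old
  }
  paste(chars, collapse = "")
}

#' @noRd
mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (p in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])
    chars[p] <- alt[sample.int(3, 1)]
  }
  paste(chars, collapse = "")
}

#' @noRd
build_taxonomy <- function(n_genera) {
  n_arch <- floor(n_genera / 5)
  n_bact <- n_genera - n_arch
  rows <- lapply(seq_len(n_genera), function(i) {
    dom <- if (i <= n_bact) "Bacteria" else "Archaea"
    j <- if (i <= n_bact) i else i - n_bact
    dl <- substr(dom, 1, 1)
    data.frame(genus = sprintf("Genus%02d", i),
               family = sprintf("Family%s%02d", dl, ceiling(j / 2)),
               order = sprintf("Order%s%02d", dl, ceiling(j / 4)),
               class = sprintf("Class%s%02d", dl, ceiling(j / 8)),
               phylum = sprintf("Phylum%s%02d", dl, ceiling(j / 8)),
               domain = dom, stringsAsFactors = FALSE)
  })
  tax <- do.call(rbind, rows)
  # one genus without a determined class, emulating real rank gaps
  if (n_genera >= 5) tax$class[5] <- NA_character_
  tax
}

#' Generate a synthetic virus-host universe
#'
#' @param config a [universe_config()].
#' @return a `synthetic_universe` list: hosts, viruses and proteins
#'   (record data.frames), truth (taxonomy, virus_truth, protein_truth,
#'   evidence registry, viral_trnas, host_genera) and the config.
#' @export
generate_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "universe_config"))
  set.seed(config$seed)
  tax <- build_taxonomy(config$n_genera)
  genera <- tax$genus
  nm <- config$marker_families_per_genus
  n_noise_genes <- round(config$noise_gene_fraction /
                           max(1e-9, 1 - config$noise_gene_fraction) * nm)

  # family seeds: genus-private markers + global noise pool (NT level)
  marker_seeds <- list()
  for (g in genera) {
    for (k in seq_len(nm)) {
      len <- sample(config$marker_len_range[1]:config$marker_len_range[2], 1)
      marker_seeds[[sprintf("MF_%s_%d", g, k)]] <-
        paste0(reverse_translate(random_protein(len)),
               sample(c("TAA", "TAG", "TGA"), 1))
    }
  }
  if (config$shared_marker_fraction > 0) {
    n_share <- floor(config$shared_marker_fraction * nm)
    for (gi in seq(2, config$n_genera, by = 2)) {
      for (k in seq_len(n_share)) {
        marker_seeds[[sprintf("MF_%s_%d", genera[gi], k)]] <-
          marker_seeds[[sprintf("MF_%s_%d", genera[gi - 1], k)]]
      }
    }
  }
  noise_seeds <- list()
  for (k in seq_len(config$noise_pool_size)) {
    len <- sample(config$marker_len_range[1]:config$marker_len_range[2], 1)
    noise_seeds[[sprintf("NF%03d", k)]] <-
      paste0(reverse_translate(random_protein(len)),
             sample(c("TAA", "TAG", "TGA"), 1))
  }

  # host backbones (insertions go into the first half; homology source
  # segments are copied from the second half so they stay contiguous)
  backbones <- setNames(lapply(genera, function(g) random_dna(config$host_len)),
                        genera)
  trnas <- setNames(lapply(genera, function(g) {
    lapply(seq_len(2), function(t) random_dna(sample(72:75, 1)))
  }), genera)

  viruses <- list(); proteins <- list(); virus_truth <- list()
  protein_truth <- list(); evidence <- list(); viral_trnas <- list()
  protospacers <- setNames(vector("list", length(genera)), genera)
  vid <- 0L
  for (gi in seq_along(genera)) {
    g <- genera[gi]
    for (v in seq_len(config$viruses_per_genus)) {
      vid <- vid + 1L
      viral_id <- sprintf("V%04d", vid)
      fam_ids <- c(sprintf("MF_%s_%d", g, seq_len(nm)),
                   if (n_noise_genes > 0) {
                     names(noise_seeds)[sample.int(config$noise_pool_size,
                                                   n_noise_genes)]
                   })
      genes <- vapply(fam_ids, function(f) {
        seed_nt <- if (startsWith(f, "MF_")) marker_seeds[[f]] else noise_seeds[[f]]
        mutate_gene(seed_nt, config$per_site_mutation_rate)
      }, character(1))
      ord <- sample.int(length(genes))
      genes <- genes[ord]; fam_ids <- fam_ids[ord]
      strands <- sample(c("+", "-"), length(genes), replace = TRUE)
      seq_parts <- character(0)
      pos <- 0L
      coords <- list()
      for (k in seq_along(genes)) {
        gap <- random_dna(sample.int(50, 1))
        seq_parts <- c(seq_parts, gap)
        pos <- pos + nchar(gap)
        gene_nt <- if (strands[k] == "+") genes[k] else revcomp(genes[k])
        # coordinates cover start codon through last sense codon (stop
        # codon excluded), on the forward strand
        glen <- nchar(genes[k])
        if (strands[k] == "+") {
          begin <- pos + 1L
          end <- pos + glen - 3L
        } else {
          begin <- pos + 4L
          end <- pos + glen
        }
        coords[[k]] <- list(begin = begin, end = end, strand = strands[k],
                            family = fam_ids[k])
        seq_parts <- c(seq_parts, gene_nt)
        pos <- pos + glen
      }
      genome <- paste(seq_parts, collapse = "")
      comp <- runif(1, config$completeness_range[1], config$completeness_range[2])
      keep_len <- max(1L, round(nchar(genome) * comp / 100))
      genome <- substr(genome, 1, keep_len)
      coords <- Filter(function(cc) {
        lo <- if (cc$strand == "+") cc$begin else cc$begin - 3L
        hi <- if (cc$strand == "+") cc$end + 3L else cc$end
        lo >= 1 && hi <= keep_len
      }, coords)

      # classical evidence plants, appended after the truncation point
      tail_parts <- character(0)
      if (runif(1) < config$plant_homology) {
        src <- sample((config$host_len %/% 2):(config$host_len - 650), 1)
        seg <- substr(backbones[[g]], src, src + 599)
        tail_parts <- c(tail_parts, random_dna(sample(5:10, 1)), seg)
        evidence[[length(evidence) + 1]] <- data.frame(
          kind = "homology", viral_id = viral_id, genus = g,
          host_genome_id = paste0("H_", g),
          detail = sprintf("backbone %d-%d", src, src + 599),
          stringsAsFactors = FALSE)
      }
      if (runif(1) < config$plant_trna) {
        tr <- trnas[[g]][[sample.int(2, 1)]]
        tail_parts <- c(tail_parts, random_dna(sample(5:10, 1)), tr)
        viral_trnas[[length(viral_trnas) + 1]] <- data.frame(
          viral_id = viral_id, sequence = tr, stringsAsFactors = FALSE)
        evidence[[length(evidence) + 1]] <- data.frame(
          kind = "trna", viral_id = viral_id, genus = g,
          host_genome_id = paste0("H_", g), detail = "shared tRNA",
          stringsAsFactors = FALSE)
      }
      if (length(tail_parts)) {
        genome <- paste(c(genome, tail_parts), collapse = "")
      }
      if (runif(1) < config$plant_crispr) {
        # protospacer from a retained marker gene (genus-private material)
        markers <- Filter(function(cc) startsWith(cc$family, "MF_"), coords)
        sp <- NULL
        if (length(markers)) {
          cc <- markers[[sample.int(length(markers), 1)]]
          if (cc$end - cc$begin + 1 >= 32) {
            off <- sample.int(cc$end - cc$begin + 1 - 31, 1)
            sp <- substr(genome, cc$begin + off - 1, cc$begin + off + 30)
          }
        }
        if (is.null(sp) && nchar(genome) >= 32) {
          off <- sample.int(nchar(genome) - 31, 1)
          sp <- substr(genome, off, off + 31)
        }
        if (!is.null(sp)) {
          protospacers[[g]] <- c(protospacers[[g]], sp)
          evidence[[length(evidence) + 1]] <- data.frame(
            kind = "crispr", viral_id = viral_id, genus = g,
            host_genome_id = paste0("H_", g), detail = sp,
            stringsAsFactors = FALSE)
        }
      }

      viruses[[vid]] <- data.frame(
        genome_id = viral_id, sequence = genome,
        source = sprintf("%s synthetic virus of %s completeness=%.1f",
                         viral_id, g, comp),
        completeness = comp, stringsAsFactors = FALSE)
      virus_truth[[vid]] <- data.frame(
        viral_id = viral_id, genus = g, completeness = comp,
        stringsAsFactors = FALSE)
      if (length(coords)) {
        ords <- order(vapply(coords, function(cc) cc$begin, numeric(1)))
        for (oi in seq_along(ords)) {
          cc <- coords[[ords[oi]]]
          nt <- substr(genome, cc$begin, cc$end)
          if (cc$strand == "-") nt <- revcomp(nt)
          pos3 <- seq(1, nchar(nt), by = 3)
          aa <- paste(translate_codons(substring(nt, pos3, pos3 + 2)),
                      collapse = "")
          pid <- paste0(viral_id, "|", oi)
          proteins[[length(proteins) + 1]] <- data.frame(
            protein_id = pid, genome_id = viral_id,
            begin = cc$begin, end = cc$end, strand = cc$strand,
            aa_sequence = aa, stringsAsFactors = FALSE)
          protein_truth[[length(protein_truth) + 1]] <- data.frame(
            protein_id = pid, family_id = cc$family,
            is_marker = startsWith(cc$family, "MF_"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # finalize hosts: tRNAs and the CRISPR array inserted into the first half
  hosts <- list()
  for (gi in seq_along(genera)) {
    g <- genera[gi]
    inserts <- unlist(trnas[[g]])
    spacers <- protospacers[[g]]
    if (config$plant_crispr > 0) {
      while (length(spacers) < 2) {
        pad <- random_dna(32)
        if (!pad %in% spacers) spacers <- c(spacers, pad)
      }
      spacers <- unique(spacers)
      rep_word <- random_dna(sample(24:40, 1))
      array <- paste0(rep_word,
                      paste(vapply(spacers, function(s) paste0(s, rep_word),
                                   character(1)), collapse = ""))
      inserts <- c(inserts, array)
    }
    cuts <- sort(sample.int(config$host_len %/% 2, length(inserts)))
    parts <- character(0)
    prev <- 1L
    for (k in seq_along(inserts)) {
      parts <- c(parts, substr(backbones[[g]], prev, cuts[k]), inserts[k])
      prev <- cuts[k] + 1L
    }
    parts <- c(parts, substr(backbones[[g]], prev, config$host_len))
    hosts[[gi]] <- data.frame(
      genome_id = paste0("H_", g),
      sequence = paste(parts, collapse = ""),
      source = sprintf("H_%s synthetic host genome of genus %s", g, g),
      genus = g, stringsAsFactors = FALSE)
  }

  bind <- function(x, empty) if (length(x)) do.call(rbind, x) else empty
  structure(list(
    hosts = do.call(rbind, hosts),
    viruses = do.call(rbind, viruses),
    proteins = bind(proteins, data.frame()),
    truth = list(
      taxonomy = tax,
      virus_truth = do.call(rbind, virus_truth),
      protein_truth = bind(protein_truth, data.frame()),
      evidence = bind(evidence, data.frame(kind = character(),
                                           viral_id = character(),
                                           genus = character(),
                                           host_genome_id = character(),
                                           detail = character())),
      viral_trnas = bind(viral_trnas, data.frame(viral_id = character(),
                                                 sequence = character())),
      host_genera = setNames(genera, paste0("H_", genera))),
    config = config), class = "synthetic_universe")
}

#' Apply extra mutations to a universe's viral genomes
#'
#' Returns a copy with additional per-site substitutions applied to the
#' viral genomes only; truth labels are unchanged.  Protein records are
#' re-derived from the mutated genomes (translations truncate at a newly
#' created stop codon; proteins falling below 20 residues are dropped).
#'
#' @param universe a `synthetic_universe`.
#' @param extra_mutation_rate per-site substitution rate in [0, 1].
#' @return the mutated universe.
#' @export
corrupt <- function(universe, extra_mutation_rate) {
  stopifnot(extra_mutation_rate >= 0, extra_mutation_rate <= 1)
  if (extra_mutation_rate == 0) return(universe)
  set.seed(universe$config$seed + 101L)
  u <- universe
  u$viruses$sequence <- vapply(u$viruses$sequence, mutate_dna,
                               character(1), rate = extra_mutation_rate,
                               USE.NAMES = FALSE)
  seqs <- setNames(u$viruses$sequence, u$viruses$genome_id)
  keep <- logical(nrow(u$proteins))
  aa_new <- character(nrow(u$proteins))
  for (i in seq_len(nrow(u$proteins))) {
    p <- u$proteins[i, ]
    nt <- substr(seqs[[p$genome_id]], p$begin, p$end)
    if (p$strand == "-") nt <- revcomp(nt)
    pos3 <- seq(1, nchar(nt), by = 3)
    aa <- translate_codons(substring(nt, pos3, pos3 + 2))
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1)]
    keep[i] <- length(aa) >= 20
    aa_new[i] <- paste(aa, collapse = "")
  }
  u$proteins$aa_sequence <- aa_new
  u$proteins <- u$proteins[keep, , drop = FALSE]
  u
}

#' Write a universe to a directory
#'
#' Emits hosts.fna, viruses.fna, proteins.faa, taxonomy.tsv,
#' virus_truth.tsv, protein_truth.tsv, evidence.tsv, viral_trnas.tsv and
#' host_genera.tsv.
#'
#' @param universe a `synthetic_universe`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(universe$hosts$source, universe$hosts$sequence,
              file.path(dir, "hosts.fna"))
  write_fasta(universe$viruses$source, universe$viruses$sequence,
              file.path(dir, "viruses.fna"))
  write_proteins(universe$proteins, file.path(dir, "proteins.faa"))
  write_taxonomy(universe$truth$taxonomy, file.path(dir, "taxonomy.tsv"))
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  }
  tsv(universe$truth$virus_truth, "virus_truth.tsv")
  tsv(universe$truth$protein_truth, "protein_truth.tsv")
  tsv(universe$truth$evidence, "evidence.tsv")
  tsv(universe$truth$viral_trnas, "viral_trnas.tsv")
  tsv(data.frame(host_genome_id = names(universe$truth$host_genera),
                 genus = unname(universe$truth$host_genera),
                 stringsAsFactors = FALSE), "host_genera.tsv")
  invisible(dir)
}
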
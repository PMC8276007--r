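# Alignment-free distances used to corroborate host predictions: MinHash
# bottom-sketches with the Mash distance transform
# d = -ln(2j/(1+j))/k over the bottom-size-of-the-union Jaccard estimate j,
# and Manhattan / Pearson distances over canonical k-mer frequency vectors
# (k = 6).

#' MinHash sketch of a DNA sequence
#'
#' Canonical k-mers (lexicographic minimum of k-mer and reverse complement)
#' are hashed with a fixed 64-bit hash; the `size` smallest distinct hash
#' values are retained.  k-mers containing N are skipped.
#'
#' @param seq DNA string.
#' @param k k-mer length (13..20 for host assignment; other values allowed).
#' @param size sketch size (number of retained minima); `Inf` or 0 keeps
#'   the full hashed k-mer set.
#' @param hash_seed seed of the hash function (must match between compared
#'   sketches).
#' @param seq_id optional id carried along.
#' @return a `minhash_sketch`: k, size, hash_seed, sorted minima, seq_id.
#' @export
sketch <- function(seq, k, size = 1000, hash_seed = 42, seq_id = NA_character_) {
  if (nchar(seq) < k) stop("sequence shorter than k")
  sz <- if (!is.finite(size) || size <= 0) 0L else as.integer(size)
  minima <- .minhash_sketch_cpp(seq, as.integer(k), sz, hash_seed)
  structure(list(k = as.integer(k), size = if (sz == 0L) Inf else sz,
                 hash_seed = hash_seed, minima = minima, seq_id = seq_id),
            class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' Jaccard estimate j = shared minima among the bottom-`size` of the union
#' over the number considered; distance d = min(1, -ln(2j/(1+j))/k), with
#' d = 1 when j = 0.
#'
#' @param a,b `minhash_sketch` objects with equal k, size and hash seed.
#' @return distance in [0, 1].
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) stop("mismatched k between sketches")
  if (!identical(a$size, b$size) || !identical(a$hash_seed, b$hash_seed)) {
    stop("sketches built with different size or hash seed")
  }
  u <- sort(unique(c(a$minima, b$minima)))
  s <- if (is.finite(a$size)) min(a$size, length(u)) else length(u)
  bottom <- u[seq_len(s)]
  shared <- sum(bottom %in% a$minima & bottom %in% b$minima)
  j <- shared / s
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Canonical k-mer frequency vector
#'
#' @param seq DNA string.
#' @param k k-mer length (default 6).
#' @return named numeric vector of canonical k-mer frequencies summing
#'   to 1 (k-mers containing N skipped).
#' @export
kmer_profile <- function(seq, k = 6) {
  if (nchar(seq) < k) stop("sequence shorter than k")
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), k)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no valid k-mers in sequence")
  kmers <- names(counts)
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  v <- tapply(as.numeric(counts), canon, sum)
  out <- as.numeric(v) / sum(v)
  names(out) <- names(v)
  out
}

#' Manhattan distance between two k-mer frequency vectors
#'
#' Sum of absolute frequency differences over the union of k-mers (absent
#' keys count 0); range [0, 2].
#'
#' @param a,b named frequency vectors from [kmer_profile()].
#' @return numeric distance.
#' @export
kmer_manhattan <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  sum(abs(av - bv))
}

#' @rdname kmer_manhattan
#' @return `kmer_correlation()` returns the Pearson correlation over the
#'   union of k-mers.
#' @export
kmer_correlation <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- ifelse(keys %in% names(a), a[keys], 0)
  bv <- ifelse(keys %in% names(b), b[keys], 0)
  cor(av, bv)
}

#' Pick the host with the smallest alignment-free distance
#'
#' Evaluates the chosen metric between the viral genome and every host and
#' returns the host taxon of the minimiser (for correlation, the
#' maximiser); ties broken by lexicographic host id.
#'
#' @param viral a genome record (genome_id, sequence).
#' @param hosts genome record data.frame.
#' @param metric "mash", "manhattan" or "correlation".
#' @param k k-mer size (13..20 for mash; 6 for the frequency metrics).
#' @param host_genera named character vector host_genome_id -> genus.
#' @param taxonomy optional taxonomy table.
#' @param size,hash_seed sketch parameters (mash only).
#' @return a [host_prediction()] (method kmer, score = 1 - distance, or r
#'   for correlation) with the per-host values attached as attribute
#'   `distances`.
#' @export
nearest_host <- function(viral, hosts, metric = c("mash", "manhattan",
                                                  "correlation"),
                         k = NULL, host_genera = NULL, taxonomy = NULL,
                         size = 1000, hash_seed = 42) {
  metric <- match.arg(metric)
  stopifnot(nrow(hosts) >= 1)
  if (is.null(k)) k <- if (metric == "mash") 15 else 6
  if (metric == "mash") {
    vs <- sketch(viral$sequence, k, size, hash_seed)
    vals <- vapply(hosts$sequence, function(h) {
      mash_distance(vs, sketch(h, k, size, hash_seed))
    }, numeric(1))
  } else {
    vp <- kmer_profile(viral$sequence, k)
    vals <- vapply(hosts$sequence, function(h) {
      hp <- kmer_profile(h, k)
      if (metric == "manhattan") kmer_manhattan(vp, hp)
      else kmer_correlation(vp, hp)
    }, numeric(1))
  }
  names(vals) <- hosts$genome_id
  ord <- if (metric == "correlation") order(-vals, hosts$genome_id) else
    order(vals, hosts$genome_id)
  win <- ord[1]
  host_id <- hosts$genome_id[win]
  genus <- if (!is.null(host_genera)) unname(host_genera[[host_id]]) else host_id
  lineage <- if (!is.null(taxonomy)) expand_lineage(genus, taxonomy) else
    setNames(c(genus, rep(NA_character_, 5)), TAX_RANKS)
  score <- if (metric == "correlation") vals[win] else 1 - vals[win]
  pred <- host_prediction(viral$genome_id, setNames(unname(score), genus),
                          lineage, "kmer")
  attr(pred, "distances") <- vals
  attr(pred, "metric") <- metric
  attr(pred, "k") <- k
  pred
}

#' Write / read a sketch as JSON
#'
#' @param s a `minhash_sketch`.
#' @param path file path.
#' @export
write_sketch <- function(s, path) {
  jsonlite::write_json(list(k = s$k, size = if (is.finite(s$size)) s$size else 0,
                            hash_seed = s$hash_seed, seq_id = s$seq_id,
                            minima = s$minima),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(x$k),
                 size = if (x$size == 0) Inf else as.integer(x$size),
                 hash_seed = x$hash_seed, minima = as.numeric(x$minima),
                 seq_id = x$seq_id),
            class = "minhash_sketch")
}
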
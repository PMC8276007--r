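---
title: "Predicting virus hosts from protein content: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting virus hosts from protein content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most viruses of Bacteria and Archaea are known only from metagenomic
assemblies, so their hosts cannot be observed directly.  Classical
alignment-dependent signals — a CRISPR spacer in a host genome that exactly
matches a viral protospacer, a long high-identity homology match, a shared
tRNA — are precise but sparse: the majority of environmental viral contigs
carry none of them.  Alignment-free nucleotide-composition methods assign
almost everything but with much lower precision.  `hostforest` implements a
third route: learn which *combinations of protein families* a virus carries
are diagnostic of its host, using a probabilistic multi-class random forest
over a genomes × protein-cluster score matrix.  The classical evidence
pipeline, alignment-free distances, and a full evaluation layer are included
both because they are needed to label training data and because they are the
natural yardsticks for the forest.

## The model

### Protein clusters and profile models

Viral proteins are grouped into clusters of homologs by greedy incremental
clustering (CD-HIT style): sequences are visited longest-first and join the
first cluster whose representative they match at ≥ 35% identity with ≥ 70%
bidirectional coverage, otherwise they found a new cluster.  Pairwise
alignment is global (Needleman–Wunsch) under BLOSUM62 with affine gaps
(open 11, extend 1).  Identity is counted over alignment columns between the
outermost aligned residue pairs; coverage is the aligned span of each
sequence over its length.  Ties in the greedy ordering are broken by
lexicographic id so the partition is deterministic; permuting the input
yields the same clusters.

Each cluster is aligned with a center-star MSA against its representative
and converted into a position-specific scoring model (PSSM).  Columns with
more than 50% gaps are dropped; the score of residue $x$ in a column with
counts $c_x$ over $n$ non-gap residues is

$$s(x) = \log_2 \frac{(c_x + \alpha\,b_x)/(n + \alpha)}{b_x}$$

with pseudocount mass $\alpha = 0.5$ and background $b$ taken from the
residue frequencies of the training proteins (Laplace-smoothed).  This is a
deliberate simplification of full profile HMMs: there are no insert/delete
states and scoring is best local alignment against the columns with affine
gap penalties (11/1, in bits).  The simplification is absorbed by the
downstream hit filters, and the hit-table TSV interface lets production
users substitute genuine profile-search output (e.g. hmmsearch domain
tables) without touching the rest of the pipeline.

### The feature matrix

Every protein is scored against every profile.  A hit is retained when its
expectation is ≤ 1e−5, the aligned span covers ≥ 70% of *both* the protein
and the profile, and the bit score is ≥ 50 (the boundary value 50.0 is
retained).  Expectations use the Karlin–Altschul form
$E = K\,m\,n\,2^{-S}$ with calibration constant $K = 0.1$ and effective
database size equal to profile length × number of profiles; these constants
are configuration values, not fitted quantities, and are irrelevant when an
external search program supplies the hit table.  The matrix cell for
(genome, cluster) is the best bit score of any protein of that genome
against that cluster, zero otherwise; genomes with no qualifying hits keep
an all-zero row rather than being dropped.

Highly correlated clusters carry redundant information, so clusters whose
score columns correlate at Pearson $r \ge 0.9$ are grouped into
superclusters and only one member is kept.  Grouping uses transitive
closure (connected components of the $r \ge 0.9$ graph), which yields a
well-defined partition; the retained representative is the member with the
largest column sum (tie: lexicographic id), maximising retained
information.  Constant columns have undefined $r$ and are defined to
correlate with nothing.  Zeros are included in the correlation because
absence of a hit is informative.

### The forest

The classifier is a probability forest (ranger): 1,000 trees, up to 5,000
candidate split variables per node (capped at the feature count — small
studies have far fewer clusters than 5,000), impurity variable importance,
minimal node size 1, unweighted classes, trained on a single thread with a
fixed seed so results are exactly reproducible.  Class probabilities are
the mean of per-tree class-proportion votes and sum to 1 by construction.
The predicted host is the genus with the highest probability; ties are
broken lexicographically and flagged, since near-equal scores are themselves
evidence that a virus may infect several genera.  A virus is assumed to
infect exactly one genus; multi-host reporting is limited to exposing the
full probability vector.  Genera represented by a single training genome are
legal.  Lineages up to the domain level are attached by lookup in a flat
genus → lineage table; missing ranks are explicit (`NA`) and are never
fabricated, and unknown genera surface as a distinct error rather than being
silently skipped.

Score thresholding trades recall for precision.  The package ships 0.14 as
a documented default for phylum-level work, but whether any particular
cutoff transfers to a retrained model depends on the training data; users
should derive cutoffs from their own sweeps (`cutoff_sweep()`).

### Classical evidence and viral populations

The alignment-dependent pipeline mirrors standard practice.  CRISPR arrays
are detected in host genomes as runs of ≥ 3 exact copies of a repeat word
(23–47 bp) separated by distinct spacers (20–50 bp); an array of $n$
repeats yields $n-1$ spacers.  A spacer match requires the full spacer to
occur *exactly* (zero mismatches, 100% coverage) in the viral genome on
either strand.  Homology matches require ≥ 500 bp at ≥ 95% identity with
expectation ≤ 1e−3; shared tRNAs require ≥ 60 bp at ≥ 97% identity,
≥ 95% query coverage, ≤ 10 mismatches and expectation ≤ 1e−3.  Viral tRNA
sequences are inputs (tRNA gene finding is out of scope).  Nucleotide
matching is seed-and-extend: exact shared 11-mers (8-mers for short tRNA
queries) nominate diagonals, which are then aligned with a banded local
Smith–Waterman (match +1, mismatch −2, gap 5/2).

Viruses are grouped into viral populations (VPs) at ≥ 95% ANI and ≥ 80%
shared genes, where ANI is the mean identity of reciprocal best local
alignments of gene sequences and the shared-gene fraction is normalised by
the genome with fewer genes (a gene pair qualifies at ≥ 70% identity over
≥ 50% of the shorter gene).  A MinHash prescreen skips pairs sharing no
15-mers.  Evidence is pooled per VP: every signal adds 3 (CRISPR), 2
(homology) or 1 (tRNA) point to its host genus, the top-scoring genus is
assigned to every member, and a tie at the top yields *no* prediction
(precision over recall) with the tied genera reported.  A configuration
flag collapses repeated (virus, genus, kind) signals for users who prefer
deduplicated counting.  Host records whose description contains "plasmid"
are excluded, and an optional known-host table (e.g. prophages) bypasses
evidence scoring for its populations.

### Alignment-free corroboration

MinHash bottom-sketches over canonical k-mers (lexicographic minimum of
k-mer and reverse complement, k-mers with N skipped, sketch size 1000,
hashes truncated to 53 bits so they remain exact in doubles) feed the Mash
distance $d = -\ln(2j/(1+j))/k$, where $j$ is the shared fraction among the
bottom-`size` of the union of two sketches; $j = 0$ maps to $d = 1$.
Host-assignment distances use k = 13..20; the package reports all requested
k values and leaves aggregation across k to the user.  Additionally,
canonical 6-mer frequency vectors support Manhattan distance (range [0, 2])
and Pearson correlation over the union of observed k-mers.  `nearest_host()`
returns the host minimising the distance (maximising correlation), with
ties broken by lexicographic host id.

### Evaluation

Recall is the fraction of sequences with at least one prediction passing
the cutoff, regardless of correctness.  Precision is computed over
predicted sequences whose truth is defined at the evaluated rank: a
sequence with several predictions counts once and is correct if *any*
prediction matches.  Sequences whose true lineage is missing at a rank
leave the precision denominator but still count in recall's total; a
prediction whose own lineage is missing at the rank simply cannot match.
With zero passing predictions, precision is reported as 0 with an explicit
`n_predicted = 0` rather than NaN.  F1 is the harmonic mean, 0 when both
terms are 0.  Bootstrap precision samples ⌊0.2 n⌋ sequences without
replacement in 1,000 replicates under a fixed seed.  Dereplication is
greedy longest-first at ≥ 95% identity over ≥ 50% of the shorter sequence;
train/test independence removes a test genome when it shares > 70% of its
proteins or > 70% AAI with any training genome, with the shared fraction
normalised by the *test* proteome (the direction that is conservative for
the test set) and AAI averaged over reciprocal best hits at ≥ 30% identity.

## The synthetic universe

All tests and the acceptance script run on a generated virus–host universe
with planted, recoverable signal, because the real training corpora are
external downloads.  Defaults (chosen once, as the package's study
conditions): 10 genera, 30 viruses per genus, 5 genus-private marker
protein families per genus, a global pool of 40 noise families from which
each virus draws 2 genes (30% of its genes), per-site nucleotide mutation
rate 0.05 applied to each gene copy relative to its family seed,
completeness drawn uniformly from [50, 100]% (partial genomes dominate, as
in real viral metagenomes), and per-virus planting probabilities of 0.3 for
each classical evidence type.  Two of the ten genera are archaeal; one
genus lacks a determined class, exercising rank-gap handling.  Genes are
reverse-translated family seeds mutated at the nucleotide level (never
through a stop codon), so every protein record is the exact translation of
its coordinates.  CRISPR spacers and homology segments are drawn from
genus-private material (marker genes, host backbones), so default universes
carry no planted cross-genus conflicts; protospacers become spacers of the
host's array, and host tRNAs are copied into viruses.  Host insertions go
into the first half of the backbone while homology source segments come
from the second half, keeping planted homology contiguous.  A "hard mode"
flag shares a fraction of marker families between sister genera to create
realistic confusion, and `corrupt()` adds extra mutations to viral genomes
only, emulating test sets that diverge from the training data.

What the generator does *not* emulate: realistic phage genome architecture,
codon usage or GC bias, gene gain/loss within genera, hosts with real gene
content, or cross-genus marker sharing (off by default).  Passing tests
therefore demonstrate that each component recovers signal it was designed
to detect and that the machinery composes correctly — not field performance
on real viromes, which depends on database coverage and true host diversity.

## Numerical choices and scale

Alignment kernels (global protein, PSSM local, banded nucleotide) are
implemented in C++ for speed; the default-universe pipeline (about 1,400
proteins, ~90 clusters) trains in roughly two minutes on one core, and the
test suite uses smaller universes (2–5 genera) for the matcher and
population checks.  The ORF caller is deliberately naive (ATG-to-stop, six
frames, first ATG per stop segment, minimum 60 residues, N translates to X
and never forms a start or stop) — gene calling is not this package's
contribution, and user-supplied protein FASTA bypasses it.  Coordinates are
1-based inclusive on the forward strand, excluding the stop codon, so that
the stored protein equals the translation of its coordinates.  All
randomness flows from explicit seeds; identical seeds give byte-identical
outputs end to end (the forest is trained single-threaded for exactly this
reason).

## Known limitations

* The PSSM search is a stand-in for profile HMM search; bit scores are not
  numerically comparable with hmmsearch output, only contractually (same
  filters).  Users wanting genuine HMM scores should import a hit table.
* The e-value calibration constant is nominal; e-value filters act mostly
  as documented pass-throughs at fixture scale.
* Greedy clustering is quadratic in the number of cluster representatives;
  at >10⁵ proteins an external clusterer (imported via the cluster TSV) is
  the right tool.
* The classical matchers assume the host database fits in memory and score
  every (virus, host) pair; they are meant for reference sets of hundreds,
  not hundreds of thousands, of genomes.
* The recommended 0.14 phylum cutoff is a property of one published model;
  retrained models must re-derive their own cutoffs from sweeps.
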
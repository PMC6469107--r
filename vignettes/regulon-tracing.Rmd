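---
title: "Tracing a curated regulon across genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing a curated regulon across genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and rationale

`regulonTracer` packages the comparative-genomics workflow used to study
the Crl regulon of *Escherichia coli* K-12: a curated, signed
transcriptional regulatory network is summarised; its genes are traced
across a panel of bacterial and archaeal proteomes by exact sequence
search and reciprocal-best-hit orthology; ortholog presence is collapsed
into per-division phylogenetic profiles and clustered; and the history of
a gene family is summarised by a distance phylogeny with bootstrap
support. Crl is unusual among transcription factors: it does not bind
operators but promotes the association of the stationary-phase sigma
factor sigma-S (RpoS) with the RNA-polymerase core, so its regulon is a
subset of the sigma-S sigmulon and its taxonomic history is informative
about how that regulon was assembled.

Because the original genome panel (thousands of RefSeq genomes) is not
redistributable at package scale, every genome-scale stage is validated
against a synthetic proteome generator with planted ground truth. The
generator is a first-class, tested component, not a fixture.

# The curated regulon model

The packaged table (`inst/extdata/crl_regulon.tsv`) transcribes the
published compendium of 86 Crl-controlled genes: locus tags,
transcription units (TUs), co-regulating transcription factors with
signs, the sign of the Crl effect, evidence codes (APPH, GEA, MSI, IMP)
and GO annotations. `loadRegulonTable()` validates it into a
`RegulonNetwork` whose statistics reproduce the published aggregates:

* 86 gene records over 85 distinct loci (two rows share locus tag
  b0885); sign tallies deduplicate by locus tag, giving 73 activated and
  12 repressed genes;
* 24 genes exclusively under Crl control versus 62 with co-regulators;
* 77 transcription units, 52% monogenic;
* 19/11/14 co-regulated genes with exactly one/two/three distinct TFs.

Three modelling conventions matter here, each chosen once and recorded in
the fixture's header comments. First, complexes printed as single
entities (`GadE-RcsB`, `RcsAB`, `FlhDC`) count as one regulator, and a
regulator listed with both signs counts once in degree statistics;
dual-sign entries become a single `+/-` edge. A `+/-` effect on a Crl
edge would count toward neither sign tally (the packaged table contains
none). Second, TU gene content is expanded from the operon-style TU name
(`csgBAC` is csgB, csgA, csgC), because monogenicity refers to the full
operon, not to the subset of regulon members; TU members that are not
regulon genes are kept as context. Third, the distinct co-regulator name
count is reported but never asserted against the published "55 different
TFs", whose complex-counting convention is not reconstructible; our
tokenization yields a different distinct-name count and we treat that as
an honest representation choice rather than an error to calibrate away.

Functional enrichment replaces an external classification service with
the fully specified statistic it implements: a one-sided hypergeometric
test, $P(X \ge k)$ with $k$ query hits among $K$ category members, query
size $n$, background $N$, with Benjamini-Hochberg correction across
categories. For backgrounds of up to a dozen genes the p-values are
checked against exhaustive enumeration of all $\binom{N}{n}$ draws.

# The alignment core

Searches use an exact Smith-Waterman local aligner under the Gotoh
three-state affine-gap recurrence, written in C++ for speed; there is no
heuristic seeding, which is affordable at the package's panel sizes. A
gap of length $L$ costs `gapOpen` $+ L\,\cdot$ `gapExtend` (the BLAST
convention; defaults 11/1 with BLOSUM62, packaged in NCBI text format).
Raw scores convert to E-values by the Karlin-Altschul formula
$E = K m n e^{-\lambda S}$ with query length $m$ and a **fixed** database
length $n = 5\times 10^8$, so E-values are comparable across genomes of
different sizes. $\lambda = 0.267$ and $K = 0.041$, the standard gapped
BLOSUM62/11,1 constants, are declared defaults (the original analysis
names its search tool but not its statistical parameters) and are
configurable on the `ScoringScheme`.

Tie-breaking among equal-scoring optima is deterministic (prefer the
continuation over a restart, diagonal over vertical over horizontal,
first-found endpoint), which pins down reported coordinates without
affecting scores; scores are what all downstream thresholds consume.
Correctness is established against a brute-force enumeration oracle over
all alignments of short sequences on a reduced alphabet, plus re-scoring
of every reported alignment string.

Coverage is computed on the query side, `(q_end - q_start + 1) /
query_length`, the common convention when a published threshold does not
name the side.

# Homology and orthology

Two threshold regimes mirror the published workflow: a permissive
homolog survey (E $\le 10^{-3}$, coverage $\ge 60\%$) that reports every
passing subject in every genome, and a strict ortholog assignment
(E $\le 10^{-6}$, coverage $\ge 60\%$) by bidirectional best hits
(BDBH): the best target-genome hit of the seed must find the seed itself
as its best hit back in the reference proteome. Ranking is by raw score
with E-value and lexicographic subject id as tie-breakers — E is monotone
in the score at fixed lengths, so this is equivalent but stable under
floating point. Whether the published coverage filter applied to the
reverse direction is not stated; we enforce it in both directions and
record that as this package's choice (it can only make assignments more
conservative). BDBH yields at most one subject per (seed, genome):
co-ortholog detection is out of scope, matching the binary
presence/absence use downstream.

Genome de-duplication by genome-similarity score is replaced by an
explicitly labelled stand-in, `dedupeGenomes()`, which removes only
exactly duplicated protein sets; the similarity-score definition lives
outside the source analysis and synthetic panels do not need it.

# Phylogenetic profiling

`relativeAbundance()` collapses the gene-by-genome indicator matrix to a
division-by-gene grid: the fraction of genomes of a division carrying an
ortholog, so 1 means universal presence and 0 a division with no
ortholog. Rows or columns are clustered agglomeratively. The source
analysis states complete linkage with uncentered correlation in its
methods and single linkage with Pearson distance in its figure legend;
both combinations are implemented, the methods variant is the default,
and pipeline outputs record which was used. Distances are
$1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ (uncentered) and
$1 - r$ (Pearson); both are undefined for all-zero or zero-variance
rows and fail loudly, naming the offending pair. Ties between equal
minimal distances merge the pair with the lexicographically smallest
(smallest member index, other index); leaf order is the merge-induced
order with no leaf-order optimization. The implementation recomputes
linkage from cluster members; tests compare it against an independent
from-scratch reference on up to six items and against `stats::hclust`
on tie-free data.

# Phylogeny

The tree stack operates on nucleotide coding sequences. The source
analysis applies the Tamura-Nei model to a protein phylogeny without
stating how; rather than guess a back-translation we follow the stated
model literally: the synthetic generator emits coding sequences, and
protein substitution models are a non-goal.

* **TN93 distance**: closed form from the observed purine-transition,
  pyrimidine-transition and transversion proportions with empirical base
  frequencies over the comparable sites; gaps and ambiguities are
  deleted pairwise. Non-positive logarithm arguments mean saturation:
  the pair is flagged rather than silently truncated.
* **Tree building**: Saitou-Nei neighbor joining (via `ape::nj`, exact
  on additive matrices), with negative branch lengths clamped to zero
  and the deficit recorded. A full maximum-likelihood topology search is
  deliberately replaced by this distance method: the original tree is
  not reproducible without its genome panel, so the acceptance surface
  here is property-based (exactness on additive inputs, robustness to
  small perturbations).
* **Likelihood**: `tn93Loglik()` evaluates a tree by Felsenstein pruning
  with TN93 transition probabilities obtained by eigendecomposition of
  the frequency-symmetrised rate matrix, normalised to one expected
  substitution per site per unit branch length. Two-taxon results match
  the analytic pairwise likelihood to $10^{-9}$ and the value is
  invariant under re-rooting.
* **Multiple alignment**: a basic progressive aligner (pairwise global
  identities, complete-linkage guide tree, profile-profile
  Needleman-Wunsch with mean-pair column scores) stands in for a
  production MSA tool; for the generator's indel-free families it is
  exact, and that is the regime the tests exercise.
* **Bootstrap**: columns are resampled with replacement, the tree is
  rebuilt per replicate, and supports are the percentage of replicates
  containing each internal bipartition of the main tree (counted with
  `ape::prop.clades`). Zero-length internal branches of the main tree
  are collapsed first, so an alignment of identical sequences yields no
  resolved bipartitions and an empty support set. Saturated pairs in a
  replicate fall back to the raw mismatch proportion so extreme
  resamples remain usable. The conventional full run uses B = 1000 with
  a 60% display threshold: rendering masks weaker supports, the data
  retain all of them.

# The synthetic proteome generator

`simulateProteomes()` emulates the study design: a panel of taxonomic
divisions (defaults 18 archaeal + 69 bacterial, the published panel
shape; 61 genomes per division, matching the order of the published
genome count), gene families seeded from random stop-free coding
sequences, per-(division, family) retention probabilities, evolution
along a random tree whose every branch has the configured expected
substitutions per site (TN93 with mildly AT-rich frequencies,
transition/transversion bias 2), and translation to proteins. A
designated reference genome retains every family so each family has a
seed — the panel's *E. coli* analogue. Decoy proteins drawn from the
shuffled pooled residue composition of the family proteins are appended
to every genome; they are composition-realistic but unrelated, so they
exercise the E-value threshold rather than trivially failing it.
`crlLikeFamily()` plants a single-copy family restricted to designated
divisions, emulating a regulator conserved in, and constrained to, one
clade.

What the generator does **not** emulate — indels, rate heterogeneity
across sites, horizontal transfer, paralogous family expansions, genome
rearrangement — bounds what passing tests show: they demonstrate that
the search, reciprocity, profiling and tree machinery are correct and
deterministic under the stated model, not that the biological
conclusions of any genome-scale analysis would be recovered on real
data.

Tests and the acceptance script use a scaled panel — 5 divisions
(1 archaeal + 4 bacterial) of 4 genomes, 6 families, retention 0.5,
8 decoys per genome, 100-residue proteins — at divergence 0 and 0.05.
At divergence 0 BDBH recovery of the planted truth is exact by
construction (unique sequences, identical copies); at 0.05 the expected
pairwise identity stays high enough that recovery remains at or near
100%, and the acceptance criterion is 0.95. All generator draws flow
from a single seed, and writing the panel twice from the same
configuration produces byte-identical files.

# Numerical and degenerate-input conventions

* Empty local alignments (no positive-scoring pair) are returned as
  score 0 with empty strings and zero coverage, never as an error.
* Substitution-matrix lookups fail with the offending residue named;
  schema violations in the regulon table fail with the row number.
* Distance saturation, zero-variance profiles and all-zero vectors are
  errors or flags, never silent zeros.
* Bootstrap, simulation and pipeline runs are reproducible from a single
  integer seed; the pipeline writes provenance headers (package version
  and parameters) into its artifacts.

# Known limitations

The aligner is exact but quadratic: it is meant for panels of tens of
genomes with hundreds of proteins, not for thousands of RefSeq genomes.
The progressive aligner has no iterative refinement and will be
outperformed by dedicated MSA tools on gappy real data. NJ plus a TN93
pruning likelihood is a stand-in for a full ML search. The published
figure-level results that depend on the original genome panel are out
of reach by design; what this package offers instead is a fully
reproducible, property-tested implementation of the same analytical
machinery.
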
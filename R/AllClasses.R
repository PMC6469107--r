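#' @useDynLib regulonTracer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Scoring scheme for pairwise sequence alignment
#'
#' Bundles a symmetric substitution matrix, affine gap penalties and the
#' Karlin-Altschul statistical parameters used to convert raw alignment
#' scores into E-values. A gap of length \eqn{L} costs
#' \code{gapOpen + L * gapExtend} (the BLAST convention, so the default
#' 11/1 reproduces BLAST-comparable scores). The database length is fixed
#' rather than taken from the searched set, mirroring a search run with a
#' constant database size of 5e8 so that E-values are comparable across
#' genomes of different sizes.
#'
#' @slot matrix symmetric numeric substitution matrix with residue dimnames.
#' @slot gapOpen,gapExtend positive gap penalties, \code{gapExtend <= gapOpen}.
#' @slot lambda,K Karlin-Altschul parameters; defaults 0.267 and 0.041 are
#'   the standard gapped BLOSUM62/11,1 constants.
#' @slot dbLength effective database length \eqn{n} used in the E-value.
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", K = "numeric", dbLength = "numeric"),
  validity = function(object) {
    msg <- character()
    m <- object@matrix
    if (is.null(dimnames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "substitution matrix must have identical row/col names")
    else if (!isTRUE(all.equal(m, t(m))))
      msg <- c(msg, "substitution matrix must be symmetric")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
      msg <- c(msg, "gap penalties must be positive")
    if (object@gapExtend > object@gapOpen)
      msg <- c(msg, "gapExtend must not exceed gapOpen")
    if (object@lambda <= 0 || object@K <= 0 || object@dbLength <= 0)
      msg <- c(msg, "lambda, K and dbLength must be positive")
    if (length(msg)) msg else TRUE
  })

#' Pairwise alignment result
#'
#' One scored local or global alignment between a query and a subject.
#' Coordinates are 1-based inclusive positions on the ungapped sequences;
#' an empty local alignment (no positive-scoring residue pair) has score 0
#' and all coordinates 0.
#'
#' @slot queryId,subjectId sequence identifiers.
#' @slot alignedQuery,alignedSubject gapped strings of equal length.
#' @slot rawScore alignment score under the scheme that produced it.
#' @slot qStart,qEnd,sStart,sEnd 1-based inclusive coordinates.
#' @slot identity fraction of alignment columns with identical residues.
#' @slot qCoverage,sCoverage aligned span divided by sequence length.
#' @export
setClass("PairAlignment",
  representation(queryId = "character", subjectId = "character",
                 alignedQuery = "character", alignedSubject = "character",
                 rawScore = "numeric",
                 qStart = "integer", qEnd = "integer",
                 sStart = "integer", sEnd = "integer",
                 identity = "numeric",
                 qCoverage = "numeric", sCoverage = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@alignedQuery) != nchar(object@alignedSubject))
      msg <- c(msg, "aligned strings must have equal length")
    if (any(c(object@qCoverage, object@sCoverage) < 0) ||
        any(c(object@qCoverage, object@sCoverage) > 1))
      msg <- c(msg, "coverages must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Signed regulatory network curated from the regulon table
#'
#' Holds the gene records, transcription units and signed regulator->gene
#' edges of a curated regulon. Edges whose regulator is \code{"Crl"} carry
#' the effect of the master regulator itself; all other edges are
#' co-regulator interactions copied from the table. Transcription-unit gene
#' content is expanded from the operon-style TU name, and TU members that
#' are not themselves regulon genes are retained as context genes.
#'
#' @slot genes data.frame with columns \code{gene}, \code{bnumber},
#'   \code{tus} (list), \code{go_terms} (list), \code{dup_bnumber} (logical
#'   flag for locus tags shared between rows).
#' @slot tus data.frame with columns \code{name}, \code{genes} (list of the
#'   full gene complement parsed from the TU name), \code{context} (list of
#'   members that are not regulon genes).
#' @slot edges data.frame with columns \code{regulator}, \code{target},
#'   \code{effect} (one of \code{"+"}, \code{"-"}, \code{"+/-"}),
#'   \code{evidence} (list), \code{references} (list).
#' @export
setClass("RegulonNetwork",
  representation(genes = "data.frame", tus = "data.frame",
                 edges = "data.frame", regulator = "character"),
  validity = function(object) {
    msg <- character()
    ok_eff <- c("+", "-", "+/-")
    if (nrow(object@edges)) {
      if (!all(object@edges$effect %in% ok_eff))
        msg <- c(msg, "edge effects must be one of +, -, +/-")
      if (!all(object@edges$target %in% object@genes$gene))
        msg <- c(msg, "every edge target must be a known gene")
      crl <- object@edges$regulator == object@regulator
      if (any(crl) && any(lengths(object@edges$evidence[crl]) == 0))
        msg <- c(msg, "Crl edges must carry at least one evidence code")
    }
    if (length(msg)) msg else TRUE
  })

#' A set of proteomes with taxonomic assignments
#'
#' Container for per-genome protein sets (and optionally the underlying
#' nucleotide coding sequences), together with a genome -> taxonomic
#' division map and a division -> domain (archaeal/bacterial) map.
#'
#' @slot proteins named list of \linkS4class{AAStringSet}, one per genome.
#' @slot nucleotides named list of \linkS4class{DNAStringSet} (may be empty).
#' @slot taxonomy data.frame with columns \code{genome_id}, \code{division}.
#' @slot domains data.frame with columns \code{division}, \code{domain}.
#' @export
setClass("ProteomeSet",
  representation(proteins = "list", nucleotides = "list",
                 taxonomy = "data.frame", domains = "data.frame"),
  validity = function(object) {
    msg <- character()
    ids <- names(object@proteins)
    if (length(object@proteins) && (is.null(ids) || anyDuplicated(ids)))
      msg <- c(msg, "proteomes must be uniquely named by genome id")
    if (!all(ids %in% object@taxonomy$genome_id))
      msg <- c(msg, "every genome must have a taxonomy entry")
    for (g in ids) {
      if (anyDuplicated(names(object@proteins[[g]]))) {
        msg <- c(msg, sprintf("duplicate protein ids within genome '%s'", g))
        break
      }
    }
    if (nrow(object@domains) &&
        !all(object@domains$domain %in% c("archaeal", "bacterial")))
      msg <- c(msg, "domains must be 'archaeal' or 'bacterial'")
    if (length(msg)) msg else TRUE
  })

#' Gene-by-genome ortholog indicator matrix
#'
#' Boolean grid recording, for every (seed gene, genome) pair, whether a
#' bidirectional-best-hit ortholog was assigned. Rows are genes, columns
#' genomes. This is the bridge between ortholog assignment and taxonomic
#' profiling.
#'
#' @slot presence logical matrix with gene rownames and genome colnames.
#' @export
setClass("PresenceAbsenceMatrix",
  representation(presence = "matrix"),
  validity = function(object) {
    p <- object@presence
    msg <- character()
    if (!is.logical(p)) msg <- c(msg, "presence grid must be logical")
    if (is.null(rownames(p)) || is.null(colnames(p)))
      msg <- c(msg, "presence grid needs gene rownames and genome colnames")
    if (length(msg)) msg else TRUE
  })

#' Division-by-gene relative-abundance profile
#'
#' Real-valued grid in \[0, 1\]: the fraction of genomes in each taxonomic
#' division that carry an ortholog of each gene. A value of 1 is 100%
#' presence; 0 marks a division without any ortholog.
#'
#' @slot values numeric matrix, divisions in rows, genes in columns.
#' @slot domains named character vector tagging each division as
#'   \code{"archaeal"} or \code{"bacterial"} (may be empty).
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", domains = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (any(v < 0 | v > 1)) msg <- c(msg, "profile values must lie in [0, 1]")
    if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "divisions and genes must be unique")
    if (length(msg)) msg else TRUE
  })

#' Agglomerative clustering result
#'
#' Merge sequence of a hierarchical clustering in the \code{\link{hclust}}
#' encoding (negative entries are singletons, positive entries earlier
#' merges), with merge heights and the merge-induced leaf order. No
#' leaf-order optimization is applied.
#'
#' @slot merge integer matrix (n-1 x 2).
#' @slot height numeric merge heights.
#' @slot order integer leaf permutation.
#' @slot labels character leaf labels.
#' @slot linkage,distance the linkage and distance used.
#' @export
setClass("LinkageDendrogram",
  representation(merge = "matrix", height = "numeric", order = "integer",
                 labels = "character", linkage = "character",
                 distance = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@labels)
    if (nrow(object@merge) != n - 1L)
      msg <- c(msg, "a clustering of n leaves must contain n-1 merges")
    if (length(object@height) != n - 1L)
      msg <- c(msg, "one height per merge required")
    if (length(msg)) msg else TRUE
  })

#' Parameters of the Tamura-Nei (TN93) substitution model
#'
#' Unequal base frequencies with distinct purine (A<->G) and pyrimidine
#' (C<->T) transition rates and a single transversion rate. The rate matrix
#' built from these parameters is normalised to one expected substitution
#' per site per unit branch length.
#'
#' @slot baseFreqs named numeric (A, C, G, T) summing to 1.
#' @slot alpha1 purine transition rate.
#' @slot alpha2 pyrimidine transition rate.
#' @slot beta transversion rate.
#' @export
setClass("TN93Params",
  representation(baseFreqs = "numeric", alpha1 = "numeric",
                 alpha2 = "numeric", beta = "numeric"),
  validity = function(object) {
    msg <- character()
    f <- object@baseFreqs
    if (!identical(names(f), c("A", "C", "G", "T")))
      msg <- c(msg, "baseFreqs must be named A, C, G, T in that order")
    if (any(f <= 0) || abs(sum(f) - 1) > 1e-12)
      msg <- c(msg, "base frequencies must be positive and sum to 1")
    if (object@alpha1 <= 0 || object@alpha2 <= 0 || object@beta <= 0)
      msg <- c(msg, "substitution rates must be positive")
    if (length(msg)) msg else TRUE
  })

#' Multiple sequence alignment
#'
#' Named gapped rows of equal length; deleting the gap characters recovers
#' the input sequences.
#'
#' @slot rows named character vector of gapped sequences.
#' @export
setClass("ProgressiveAlignment",
  representation(rows = "character"),
  validity = function(object) {
    if (length(unique(nchar(object@rows))) > 1)
      "all alignment rows must have equal length" else TRUE
  })

#' Configuration of the synthetic proteome generator
#'
#' Describes a panel of taxonomic divisions (archaeal and bacterial),
#' genomes per division, gene families with per-(division, family)
#' retention probabilities, coding-sequence length, per-branch divergence
#' and per-genome decoy count. The default division counts emulate a panel
#' of 18 archaeal and 69 bacterial divisions. A fixed seed makes the
#' generator byte-reproducible.
#'
#' @slot nArchaealDivisions,nBacterialDivisions division counts.
#' @slot genomesPerDivision genomes simulated per division.
#' @slot nFamilies number of seeded gene families.
#' @slot retention either a scalar probability or a divisions x families
#'   matrix of retention probabilities.
#' @slot seqLength ancestral coding-sequence length in nt (multiple of 3).
#' @slot divergence expected substitutions per site per branch.
#' @slot decoysPerGenome unrelated decoy proteins appended per genome.
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(nArchaealDivisions = "integer", nBacterialDivisions = "integer",
                 genomesPerDivision = "integer", nFamilies = "integer",
                 retention = "ANY", seqLength = "integer",
                 divergence = "numeric", decoysPerGenome = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    ndiv <- object@nArchaealDivisions + object@nBacterialDivisions
    if (ndiv < 1 || object@genomesPerDivision < 1)
      msg <- c(msg, "at least one division and one genome per division required")
    if (object@nFamilies < 1) msg <- c(msg, "nFamilies must be >= 1")
    if (object@seqLength < 30 || object@seqLength %% 3 != 0)
      msg <- c(msg, "seqLength must be a multiple of 3 and >= 30")
    r <- object@retention
    if (is.matrix(r)) {
      if (!all(dim(r) == c(ndiv, object@nFamilies)))
        msg <- c(msg, "retention matrix must be divisions x families")
      r <- as.vector(r)
    }
    if (any(r < 0 | r > 1))
      msg <- c(msg, "retention probabilities must lie in [0, 1]")
    if (object@divergence < 0) msg <- c(msg, "divergence must be >= 0")
    if (object@decoysPerGenome < 0) msg <- c(msg, "decoysPerGenome must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a simulated proteome panel
#'
#' @slot presence \linkS4class{PresenceAbsenceMatrix} of planted families.
#' @slot pairs data.frame of (seed_gene, genome_id, protein_id) planted
#'   ortholog pairs.
#' @slot trees named list of per-family \code{phylo} generating trees.
#' @export
setClass("SimulationTruth",
  representation(presence = "PresenceAbsenceMatrix", pairs = "data.frame",
                 trees = "list"))
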
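#' @name accessors
#' @title Accessors for regulonTracer classes
#'
#' @description Slot accessors. \code{regulonGenes}, \code{regulonTUs} and
#' \code{regulonEdges} return the gene, transcription-unit and edge tables
#' of a \linkS4class{RegulonNetwork}; \code{presence} the logical grid of a
#' \linkS4class{PresenceAbsenceMatrix}; \code{profileValues} and
#' \code{divisionDomains} the grid and domain tags of a
#' \linkS4class{ProfileMatrix}; \code{proteomes} and \code{taxonomyMap}
#' the per-genome protein sets and taxonomy of a
#' \linkS4class{ProteomeSet}; \code{alignmentRows} the gapped rows of a
#' \linkS4class{ProgressiveAlignment}.
#'
#' @param x the object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("regulonGenes", function(x) standardGeneric("regulonGenes"))
#' @rdname accessors
#' @export
setGeneric("regulonTUs", function(x) standardGeneric("regulonTUs"))
#' @rdname accessors
#' @export
setGeneric("regulonEdges", function(x) standardGeneric("regulonEdges"))
#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setGeneric("divisionDomains", function(x) standardGeneric("divisionDomains"))
#' @rdname accessors
#' @export
setGeneric("proteomes", function(x) standardGeneric("proteomes"))
#' @rdname accessors
#' @export
setGeneric("taxonomyMap", function(x) standardGeneric("taxonomyMap"))
#' @rdname accessors
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname accessors
setMethod("regulonGenes", "RegulonNetwork", function(x) x@genes)
#' @rdname accessors
setMethod("regulonTUs", "RegulonNetwork", function(x) x@tus)
#' @rdname accessors
setMethod("regulonEdges", "RegulonNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("presence", "PresenceAbsenceMatrix", function(x) x@presence)
#' @rdname accessors
setMethod("profileValues", "ProfileMatrix", function(x) x@values)
#' @rdname accessors
setMethod("divisionDomains", "ProfileMatrix", function(x) x@domains)
#' @rdname accessors
setMethod("proteomes", "ProteomeSet", function(x) x@proteins)
#' @rdname accessors
setMethod("taxonomyMap", "ProteomeSet", function(x) x@taxonomy)
#' @rdname accessors
setMethod("alignmentRows", "ProgressiveAlignment", function(x) x@rows)

setMethod("show", "RegulonNetwork", function(object) {
  crl <- sum(object@edges$regulator == object@regulator)
  cat("RegulonNetwork:", nrow(object@genes), "genes,",
      nrow(object@tus), "transcription units,",
      nrow(object@edges), "edges (", crl, "Crl,",
      nrow(object@edges) - crl, "co-regulator )\n")
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme:", nrow(object@matrix), "x", ncol(object@matrix),
      "matrix; gap", object@gapOpen, "/", object@gapExtend,
      "; lambda =", object@lambda, ", K =", object@K,
      ", db length =", format(object@dbLength, scientific = TRUE), "\n")
})

setMethod("show", "PairAlignment", function(object) {
  cat(sprintf("PairAlignment %s vs %s: score %g, identity %.1f%%, query %d-%d, subject %d-%d\n",
              object@queryId, object@subjectId, object@rawScore,
              100 * object@identity, object@qStart, object@qEnd,
              object@sStart, object@sEnd))
})

setMethod("show", "ProteomeSet", function(object) {
  cat("ProteomeSet:", length(object@proteins), "genomes,",
      length(unique(object@taxonomy$division)), "divisions,",
      sum(vapply(object@proteins, length, 1L)), "proteins\n")
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  p <- object@presence
  cat("PresenceAbsenceMatrix:", nrow(p), "genes x", ncol(p), "genomes;",
      sprintf("%.1f%% present\n", 100 * mean(p)))
})

setMethod("show", "ProfileMatrix", function(object) {
  v <- object@values
  cat("ProfileMatrix:", nrow(v), "divisions x", ncol(v), "genes;",
      sprintf("mean relative abundance %.3f\n", mean(v)))
})

setMethod("show", "LinkageDendrogram", function(object) {
  cat("LinkageDendrogram:", length(object@labels), "leaves,",
      object@linkage, "linkage,", object@distance, "distance\n")
})

setMethod("show", "ProgressiveAlignment", function(object) {
  cat("ProgressiveAlignment:", length(object@rows), "sequences x",
      nchar(object@rows[1]), "columns\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nArchaealDivisions, "archaeal +",
      object@nBacterialDivisions, "bacterial divisions x",
      object@genomesPerDivision, "genomes;", object@nFamilies,
      "families; divergence", object@divergence,
      "; seed", object@seed, "\n")
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", nrow(object@presence@presence), "families x",
      ncol(object@presence@presence), "genomes;",
      nrow(object@pairs), "planted ortholog pairs\n")
})
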
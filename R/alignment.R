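#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format distributed with BLAST (comment
#' lines starting with \code{#}, a header row of residue letters, then one
#' labelled row of integers per residue).
#'
#' @param path path to the matrix file.
#' @return numeric matrix with residue dimnames.
#' @export
readScoreMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(cols))))
  dimnames(m) <- list(vapply(rows, `[`, "", 1L), cols)
  m[cols, cols, drop = FALSE]
}

.matrix_cache <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Reads the packaged BLOSUM62 matrix (NCBI text format) once and caches it.
#'
#' @return 25 x 25 numeric matrix (20 amino acids plus B, J, Z, X, *).
#' @export
blosum62 <- function() {
  if (is.null(.matrix_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "regulonTracer")
    .matrix_cache$blosum62 <- readScoreMatrix(path)
  }
  .matrix_cache$blosum62
}

#' Simple nucleotide substitution matrix
#'
#' Match/mismatch matrix over A, C, G, T (plus N scoring 0 against
#' everything), with the BLAST megablast-style defaults +5/-4.
#'
#' @param match,mismatch scores for identical and differing bases.
#' @return 5 x 5 numeric matrix.
#' @export
nucleotideMatrix <- function(match = 5, mismatch = -4) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Construct a scoring scheme
#'
#' @param matrix substitution matrix (default \code{\link{blosum62}()}).
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   \code{gapOpen + L * gapExtend}.
#' @param lambda,K Karlin-Altschul parameters (defaults are the standard
#'   gapped BLOSUM62/11,1 constants).
#' @param dbLength fixed effective database length for E-values.
#' @return a \linkS4class{ScoringScheme}.
#' @examples
#' scheme <- scoringScheme()
#' scheme
#' @export
scoringScheme <- function(matrix = blosum62(), gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041, dbLength = 5e8) {
  new("ScoringScheme", matrix = matrix, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K, dbLength = dbLength)
}

#' Scoring scheme for nucleotide sequences
#'
#' \code{\link{scoringScheme}} preset with the +5/-4 nucleotide matrix and
#' BLAST-like nucleotide gap penalties.
#'
#' @param ... overrides passed on to \code{\link{scoringScheme}}.
#' @export
nucleotideScheme <- function(...) {
  args <- list(...)
  defaults <- list(matrix = nucleotideMatrix(), gapOpen = 10, gapExtend = 2,
                   lambda = 0.267, K = 0.041, dbLength = 5e8)
  do.call(scoringScheme, utils::modifyList(defaults, args))
}

# encode a sequence string as 0-based indices into the scheme's matrix
encodeSeq <- function(x, scheme) {
  chars <- strsplit(toupper(x), "")[[1]]
  idx <- match(chars, rownames(scheme@matrix))
  if (anyNA(idx))
    stop("residue(s) not covered by the substitution matrix: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

.as_seq_string <- function(x) {
  if (is(x, "XString") || is(x, "XStringSet")) as.character(x) else
    as.character(x)
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman alignment under the Gotoh three-state recurrence: the
#' returned score is the maximum over all local alignments, and an empty
#' alignment (score 0) is returned when no residue pair scores positive.
#' Ties between equal-scoring optima are broken deterministically towards
#' the left-most (smallest query start, then subject start) alignment.
#'
#' @param query,subject sequences (character or Biostrings XString).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param queryId,subjectId identifiers recorded on the result.
#' @return a \linkS4class{PairAlignment}.
#' @examples
#' localAlign("MKV", "MKV", scoringScheme())  # score 5 + 5 + 4 = 14
#' @export
localAlign <- function(query, subject, scheme = scoringScheme(),
                       queryId = "query", subjectId = "subject") {
  qs <- .as_seq_string(query); ss <- .as_seq_string(subject)
  if (!nzchar(qs) || !nzchar(ss)) stop("sequences must be non-empty")
  res <- .gotoh_local(encodeSeq(qs, scheme), encodeSeq(ss, scheme),
                      scheme@matrix, scheme@gapOpen, scheme@gapExtend)
  qc <- strsplit(toupper(qs), "")[[1]]
  sc <- strsplit(toupper(ss), "")[[1]]
  aq <- ifelse(res$q_idx > 0, qc[pmax(res$q_idx, 1L)], "-")
  as_ <- ifelse(res$s_idx > 0, sc[pmax(res$s_idx, 1L)], "-")
  ncols <- length(aq)
  ident <- if (ncols) mean(aq == as_ & aq != "-") else 0
  qcov <- if (res$q_end >= res$q_start && res$q_end > 0)
    (res$q_end - res$q_start + 1) / nchar(qs) else 0
  scov <- if (res$s_end >= res$s_start && res$s_end > 0)
    (res$s_end - res$s_start + 1) / nchar(ss) else 0
  new("PairAlignment", queryId = queryId, subjectId = subjectId,
      alignedQuery = paste(aq, collapse = ""),
      alignedSubject = paste(as_, collapse = ""),
      rawScore = res$score,
      qStart = as.integer(res$q_start), qEnd = as.integer(res$q_end),
      sStart = as.integer(res$s_start), sEnd = as.integer(res$s_end),
      identity = ident, qCoverage = qcov, sCoverage = scov)
}

#' Optimal global alignment with affine gaps
#'
#' Needleman-Wunsch alignment of two sequences (or, internally, two
#' alignment profiles, where the column score is the mean residue-pair
#' score) under the same affine gap model as \code{\link{localAlign}}.
#'
#' @inheritParams localAlign
#' @return a \linkS4class{PairAlignment} spanning both sequences fully.
#' @export
globalAlign <- function(query, subject, scheme = scoringScheme(),
                        queryId = "query", subjectId = "subject") {
  qs <- .as_seq_string(query); ss <- .as_seq_string(subject)
  if (!nzchar(qs) || !nzchar(ss)) stop("sequences must be non-empty")
  A <- matrix(encodeSeq(qs, scheme), nrow = 1)
  B <- matrix(encodeSeq(ss, scheme), nrow = 1)
  res <- .gotoh_global_profile(A, B, scheme@matrix,
                               scheme@gapOpen, scheme@gapExtend)
  qc <- strsplit(toupper(qs), "")[[1]]
  sc <- strsplit(toupper(ss), "")[[1]]
  aq <- ifelse(res$a_idx > 0, qc[pmax(res$a_idx, 1L)], "-")
  as_ <- ifelse(res$b_idx > 0, sc[pmax(res$b_idx, 1L)], "-")
  ident <- mean(aq == as_ & aq != "-")
  new("PairAlignment", queryId = queryId, subjectId = subjectId,
      alignedQuery = paste(aq, collapse = ""),
      alignedSubject = paste(as_, collapse = ""),
      rawScore = res$score,
      qStart = 1L, qEnd = nchar(qs), sStart = 1L, sEnd = nchar(ss),
      identity = ident, qCoverage = 1, sCoverage = 1)
}

#' Re-score a reported alignment under a scheme
#'
#' Sums substitution scores over aligned columns and charges each gap run
#' \code{gapOpen + L * gapExtend}. Used to verify that reported alignment
#' strings reproduce their raw score.
#'
#' @param aln a \linkS4class{PairAlignment}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return numeric score.
#' @export
rescoreAlignment <- function(aln, scheme = scoringScheme()) {
  a <- strsplit(aln@alignedQuery, "")[[1]]
  b <- strsplit(aln@alignedSubject, "")[[1]]
  if (!length(a)) return(0)
  score <- 0; in_gap <- FALSE
  for (i in seq_along(a)) {
    if (a[i] == "-" || b[i] == "-") {
      score <- score - scheme@gapExtend - (!in_gap) * scheme@gapOpen
      in_gap <- TRUE
    } else {
      score <- score + scheme@matrix[a[i], b[i]]
      in_gap <- FALSE
    }
  }
  score
}

#' Karlin-Altschul E-value at a fixed database size
#'
#' Expected number of chance local alignments with score at least S:
#' \deqn{E = K m n e^{-\lambda S}} with query length \eqn{m} and the fixed
#' database length \eqn{n} of the scheme. E is strictly decreasing in the
#' score and proportional to the query length.
#'
#' @param rawScore non-negative alignment score.
#' @param queryLen query length \eqn{m}.
#' @param scheme a \linkS4class{ScoringScheme} supplying \eqn{\lambda},
#'   \eqn{K} and \eqn{n}.
#' @return non-negative E-value.
#' @examples
#' evalue(50, 100, scoringScheme())
#' @export
evalue <- function(rawScore, queryLen, scheme = scoringScheme()) {
  stopifnot(rawScore >= 0, queryLen > 0)
  scheme@K * queryLen * scheme@dbLength * exp(-scheme@lambda * rawScore)
}

#' Query coverage of an alignment
#'
#' Fraction of the query spanned by the aligned region,
#' \code{(qEnd - qStart + 1) / queryLen}; 0 for an empty alignment.
#'
#' @param aln a \linkS4class{PairAlignment}.
#' @param queryLen ungapped query length.
#' @return fraction in \[0, 1\].
#' @export
queryCoverage <- function(aln, queryLen) {
  if (aln@qEnd < aln@qStart || aln@qEnd == 0L) return(0)
  (aln@qEnd - aln@qStart + 1) / queryLen
}
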
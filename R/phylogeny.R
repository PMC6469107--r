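#' Tamura-Nei (TN93) pairwise distance
#'
#' Closed-form TN93 distance between two aligned nucleotide sequences,
#' from the observed proportions of purine transitions (A<->G), pyrimidine
#' transitions (C<->T) and transversions, with empirical base frequencies
#' taken over the comparable sites of the pair. Sites where either
#' sequence has a non-ACGT symbol (gap, ambiguity) are skipped pairwise.
#' When a logarithm argument is non-positive the distance is saturated:
#' \code{NaN} is returned with attribute \code{saturated = TRUE}.
#'
#' @param a,b equal-length character strings or \code{DNAString}s.
#' @return numeric distance (substitutions per site), possibly \code{NaN}.
#' @examples
#' tn93Distance("ACGTACGT", "ACGTACGT")  # 0
#' @export
tn93Distance <- function(a, b) {
  av <- strsplit(toupper(.as_seq_string(a)), "")[[1]]
  bv <- strsplit(toupper(.as_seq_string(b)), "")[[1]]
  if (length(av) != length(bv))
    stop("sequences must be pre-aligned to equal length")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites between the two sequences")
  av <- av[ok]; bv <- bv[ok]
  L <- length(av)
  counts <- table(factor(c(av, bv), levels = c("A", "C", "G", "T")))
  g <- as.numeric(counts) / sum(counts)
  names(g) <- c("A", "C", "G", "T")
  gR <- g["A"] + g["G"]; gY <- g["C"] + g["T"]
  diff <- av != bv
  pur <- diff & ((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  pyr <- diff & ((av == "C" & bv == "T") | (av == "T" & bv == "C"))
  P1 <- sum(pur) / L; P2 <- sum(pyr) / L
  Q <- sum(diff & !pur & !pyr) / L
  if (P1 + P2 + Q == 0) return(structure(0, saturated = FALSE))
  k1 <- 2 * g["A"] * g["G"] / gR
  k2 <- 2 * g["C"] * g["T"] / gY
  k3 <- 2 * (gR * gY - g["A"] * g["G"] * gY / gR - g["C"] * g["T"] * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0 || !is.finite(w1) || !is.finite(w2))
    return(structure(NaN, saturated = TRUE))
  d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  structure(unname(d), saturated = FALSE)
}

#' TN93 distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector (or \code{DNAStringSet}) of aligned,
#'   equal-length sequences.
#' @param fallback what to do with saturated pairs: \code{"none"} keeps
#'   \code{NaN}; \code{"pdistance"} substitutes the raw mismatch
#'   proportion (used by the bootstrap so that extreme resamples remain
#'   usable).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
tn93DistanceMatrix <- function(seqs, fallback = c("none", "pdistance")) {
  fallback <- match.arg(fallback)
  s <- if (is(seqs, "XStringSet")) as.character(seqs) else seqs
  n <- length(s)
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tn93Distance(s[i], s[j])
      if (is.nan(d) && fallback == "pdistance") {
        ai <- strsplit(toupper(s[i]), "")[[1]]
        bj <- strsplit(toupper(s[j]), "")[[1]]
        ok <- ai %in% c("A", "C", "G", "T") & bj %in% c("A", "C", "G", "T")
        d <- mean(ai[ok] != bj[ok])
      }
      D[i, j] <- D[j, i] <- as.numeric(d)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (exact on additive matrices).
#' Negative branch lengths are clamped to zero; the total clamped deficit
#' is recorded in the \code{"clamped"} attribute.
#'
#' @param D symmetric distance matrix (>= 3 taxa, finite entries).
#' @return unrooted \code{phylo} tree.
#' @export
njTree <- function(D) {
  if (nrow(D) < 3) stop("neighbor joining needs >= 3 taxa")
  bad <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("saturated/non-finite distance for pair(s): ",
         paste(apply(bad, 1, function(ij)
           paste0(rownames(D)[ij[1]], "-", colnames(D)[ij[2]])),
           collapse = ", "))
  tr <- ape::nj(stats::as.dist(D))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- deficit
  tr
}

#' Construct TN93 model parameters
#'
#' @param baseFreqs numeric of length 4 (A, C, G, T), positive, summing
#'   to 1.
#' @param alpha1 purine transition rate (A<->G).
#' @param alpha2 pyrimidine transition rate (C<->T).
#' @param beta transversion rate.
#' @return a \linkS4class{TN93Params}.
#' @export
tn93Params <- function(baseFreqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       alpha1 = 2, alpha2 = 2, beta = 1) {
  f <- as.numeric(baseFreqs)
  names(f) <- c("A", "C", "G", "T")
  new("TN93Params", baseFreqs = f / sum(f), alpha1 = alpha1,
      alpha2 = alpha2, beta = beta)
}

#' TN93 instantaneous rate matrix
#'
#' Rate matrix with rows/cols A, C, G, T, normalised so that branch
#' lengths are expected substitutions per site.
#'
#' @param params a \linkS4class{TN93Params}.
#' @return 4 x 4 rate matrix with zero row sums.
#' @export
tn93RateMatrix <- function(params) {
  f <- params@baseFreqs
  a1 <- params@alpha1; a2 <- params@alpha2; b <- params@beta
  Q <- matrix(0, 4, 4, dimnames = list(names(f), names(f)))
  for (i in names(f)) for (j in names(f)) {
    if (i == j) next
    transition <- (i %in% c("A", "G") && j %in% c("A", "G")) ||
      (i %in% c("C", "T") && j %in% c("C", "T"))
    rate <- if (!transition) b else if (i %in% c("A", "G")) a1 else a2
    Q[i, j] <- rate * f[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  Q / mu
}

#' TN93 transition probability matrix
#'
#' \eqn{P(t) = e^{Qt}} computed through the eigendecomposition of the
#' frequency-symmetrised rate matrix (TN93 is time-reversible).
#'
#' @param params a \linkS4class{TN93Params}.
#' @param t branch length (expected substitutions per site).
#' @return 4 x 4 stochastic matrix.
#' @export
tn93TransitionProb <- function(params, t) {
  stopifnot(t >= 0)
  f <- params@baseFreqs
  Q <- tn93RateMatrix(params)
  sq <- sqrt(f)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sq)
  dimnames(P) <- dimnames(Q)
  P[P < 0] <- 0
  P
}

#' Log-likelihood of an alignment on a tree under TN93
#'
#' Felsenstein pruning over alignment columns with TN93 transition
#' probabilities. Gap and ambiguity characters contribute a partial
#' likelihood of 1 for every state (missing data). The likelihood of an
#' unrooted tree is independent of the rooting used for the computation
#' (pulley principle).
#'
#' @param tree a \code{phylo} whose tip labels match the alignment rows.
#' @param aln named character vector of equal-length gapped sequences, or
#'   a \linkS4class{ProgressiveAlignment}.
#' @param params a \linkS4class{TN93Params}.
#' @return total log-likelihood.
#' @export
tn93Loglik <- function(tree, aln, params = tn93Params()) {
  rows <- if (is(aln, "ProgressiveAlignment")) alignmentRows(aln) else aln
  if (!setequal(tree$tip.label, names(rows)))
    stop("tree leaves and alignment rows must carry the same names")
  chars <- do.call(rbind, strsplit(toupper(rows[tree$tip.label]), ""))
  ncol_aln <- ncol(chars)
  # compress to unique column patterns
  pat <- apply(chars, 2, paste, collapse = "")
  upat <- unique(pat)
  wt <- as.numeric(table(pat)[upat])
  cols <- do.call(cbind, strsplit(upat, ""))
  bases <- c("A", "C", "G", "T")
  f <- params@baseFreqs
  tre <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tre$tip.label)
  nNode <- tre$Nnode
  P <- lapply(tre$edge.length, function(t) tn93TransitionProb(params, t))
  nPat <- length(upat)
  # partial likelihoods: node x state x pattern
  L <- array(1, dim = c(nTip + nNode, 4, nPat))
  for (i in seq_len(nTip)) {
    for (p in seq_len(nPat)) {
      ch <- cols[i, p]
      if (ch %in% bases) {
        L[i, , p] <- 0
        L[i, match(ch, bases), p] <- 1
      }                                  # else missing: all ones
    }
  }
  done <- logical(nTip + nNode)
  for (k in seq_len(nrow(tre$edge))) {
    parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
    contrib <- matrix(0, 4, nPat)
    for (s in 1:4) contrib[s, ] <- P[[k]][s, ] %*% L[child, , ]
    if (!done[parent]) {
      L[parent, , ] <- contrib
      done[parent] <- TRUE
    } else {
      L[parent, , ] <- L[parent, , ] * contrib
    }
  }
  root <- tre$edge[nrow(tre$edge), 1]
  site_lik <- as.numeric(f %*% L[root, , ])
  sum(wt * log(site_lik))
}

#' Progressive multiple alignment
#'
#' Basic progressive aligner: pairwise global alignments give identity
#' distances, a complete-linkage guide tree orders the merges, and
#' profile-profile global alignment (column score = mean residue-pair
#' score) assembles the multiple alignment up the guide tree.
#'
#' @param seqs named character vector (or XStringSet) of >= 2 sequences.
#' @param scheme a \linkS4class{ScoringScheme}; use
#'   \code{\link{nucleotideScheme}()} for nucleotide input (the default
#'   here) or \code{\link{scoringScheme}()} for proteins.
#' @return a \linkS4class{ProgressiveAlignment} with rows in input order.
#' @export
progressiveAlign <- function(seqs, scheme = nucleotideScheme()) {
  s <- if (is(seqs, "XStringSet")) as.character(seqs) else seqs
  if (length(s) < 2) stop("need >= 2 sequences to align")
  if (any(!nzchar(s))) stop("empty sequence in input")
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("seq", seq_along(s))
  n <- length(s)
  if (n == 2) {
    pa <- globalAlign(s[1], s[2], scheme)
    rows <- stats::setNames(c(pa@alignedQuery, pa@alignedSubject), ids)
    return(new("ProgressiveAlignment", rows = rows))
  }
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pa <- globalAlign(s[i], s[j], scheme)
      D[i, j] <- D[j, i] <- 1 - pa@identity
    }
  }
  guide <- .agglomerate(D, "complete", ids)
  # profiles as character matrices, keyed by hclust merge ids
  profiles <- list()
  singletons <- lapply(s, function(x) matrix(strsplit(toupper(x), "")[[1]],
                                             nrow = 1))
  getProfile <- function(id) {
    if (id < 0) singletons[[-id]] else profiles[[id]]
  }
  memberIds <- list()
  getMembers <- function(id) if (id < 0) -id else memberIds[[id]]
  encodeProfile <- function(prof) {
    codes <- match(prof, rownames(scheme@matrix)) - 1L
    codes[prof == "-"] <- -1L
    if (anyNA(codes))
      stop("residue(s) not covered by the substitution matrix: ",
           paste(unique(prof[is.na(codes) & prof != "-"]), collapse = ", "))
    matrix(codes, nrow = nrow(prof))
  }
  for (step in seq_len(nrow(guide@merge))) {
    a <- guide@merge[step, 1]; b <- guide@merge[step, 2]
    pa <- getProfile(a); pb <- getProfile(b)
    res <- .gotoh_global_profile(encodeProfile(pa), encodeProfile(pb),
                                 scheme@matrix, scheme@gapOpen,
                                 scheme@gapExtend)
    ncols <- length(res$a_idx)
    newA <- matrix("-", nrow(pa), ncols)
    newB <- matrix("-", nrow(pb), ncols)
    newA[, res$a_idx > 0] <- pa[, res$a_idx[res$a_idx > 0], drop = FALSE]
    newB[, res$b_idx > 0] <- pb[, res$b_idx[res$b_idx > 0], drop = FALSE]
    profiles[[step]] <- rbind(newA, newB)
    memberIds[[step]] <- c(getMembers(a), getMembers(b))
  }
  final <- profiles[[nrow(guide@merge)]]
  members <- memberIds[[nrow(guide@merge)]]
  rows <- apply(final, 1, paste, collapse = "")
  rows <- stats::setNames(rows[order(members)], ids[sort(members)])
  rows <- rows[ids]
  new("ProgressiveAlignment", rows = rows)
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Mean-free sum over all sequence pairs and columns of the substitution
#' score, charging each gap run \code{gapOpen + L * gapExtend} per pair.
#' Used to check local optimality of the progressive aligner.
#'
#' @param aln a \linkS4class{ProgressiveAlignment}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return numeric score.
#' @export
sumOfPairsScore <- function(aln, scheme = nucleotideScheme()) {
  rows <- alignmentRows(aln)
  n <- length(rows)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pa <- new("PairAlignment", queryId = "a", subjectId = "b",
                alignedQuery = rows[i], alignedSubject = rows[j],
                rawScore = 0, qStart = 1L, qEnd = 1L, sStart = 1L,
                sEnd = 1L, identity = 0, qCoverage = 0, sCoverage = 0)
      # drop columns gapped in both rows before scoring the pair
      a <- strsplit(rows[i], "")[[1]]; b <- strsplit(rows[j], "")[[1]]
      keep <- !(a == "-" & b == "-")
      pa@alignedQuery <- paste(a[keep], collapse = "")
      pa@alignedSubject <- paste(b[keep], collapse = "")
      total <- total + rescoreAlignment(pa, scheme)
    }
  }
  total
}

#' Bootstrap support for a neighbor-joining TN93 tree
#'
#' Builds the tree from the full alignment (TN93 distances, neighbor
#' joining, zero-length internal branches collapsed as unresolved), then
#' resamples alignment columns with replacement B times, rebuilds the tree
#' for each replicate and reports, for every internal edge of the main
#' tree, the percentage of replicates containing the same bipartition.
#' All supports are retained in the result; rendering with
#' \code{\link{writeSupportTree}} masks values below the display
#' threshold.
#'
#' @param aln a \linkS4class{ProgressiveAlignment} or named character
#'   vector of >= 4 aligned sequences.
#' @param B number of bootstrap replicates (>= 1; 1000 for a full run).
#' @param displayThreshold support percentage below which labels are
#'   masked when rendering (default 60).
#' @return a \code{phylo} with node labels holding support percentages;
#'   attribute \code{"supports"} holds the numeric supports of the
#'   non-root internal nodes and \code{"displayThreshold"} the threshold.
#' @export
bootstrapSupport <- function(aln, B = 1000, displayThreshold = 60) {
  rows <- if (is(aln, "ProgressiveAlignment")) alignmentRows(aln) else aln
  if (length(rows) < 4) stop("bootstrap needs >= 4 sequences")
  stopifnot(B >= 1)
  chars <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(chars) <- names(rows)
  build <- function(cols) {
    sub <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    njTree(tn93DistanceMatrix(sub, fallback = "pdistance"))
  }
  nc <- ncol(chars)
  main <- build(seq_len(nc))
  main <- ape::di2multi(main, tol = 1e-10)   # zero-length edges: unresolved
  reps <- lapply(seq_len(B), function(b)
    build(sample.int(nc, nc, replace = TRUE)))
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / B
  main$node.label <- formatC(support, format = "fg")
  supports <- support[-1]                    # drop the trivial root "clade"
  attr(main, "supports") <- supports
  attr(main, "displayThreshold") <- displayThreshold
  main
}

#' Write a support-annotated tree as Newick, masking weak supports
#'
#' Internal-node labels with bootstrap support below the display threshold
#' are blanked in the written file; the tree object keeps all values.
#'
#' @param tree result of \code{\link{bootstrapSupport}}.
#' @param path output file.
#' @param displayThreshold override the threshold stored on the tree.
#' @export
writeSupportTree <- function(tree, path,
                             displayThreshold = attr(tree, "displayThreshold")) {
  if (is.null(displayThreshold)) displayThreshold <- 60
  out <- tree
  sup <- suppressWarnings(as.numeric(out$node.label))
  out$node.label[!is.na(sup) & sup < displayThreshold] <- ""
  ape::write.tree(out, file = path)
  invisible(path)
}
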
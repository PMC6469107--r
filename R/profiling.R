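#' Collapse presence/absence to per-division relative abundances
#'
#' For each taxonomic division d and gene g, computes the fraction of
#' genomes of d that carry an ortholog of g: (number of genomes in the
#' division with an ortholog) / (number of genomes in the division). A
#' value of 1 is 100% presence; 0 marks a division without any ortholog.
#'
#' @param pam a \linkS4class{PresenceAbsenceMatrix} (genes x genomes).
#' @param taxonomy data.frame with columns \code{genome_id},
#'   \code{division}; every genome of the matrix must be assigned and
#'   every division must contain at least one genome.
#' @param domains optional data.frame (\code{division}, \code{domain})
#'   carried through as row tags.
#' @return a \linkS4class{ProfileMatrix} (divisions x genes).
#' @export
relativeAbundance <- function(pam, taxonomy,
                              domains = data.frame(division = character(),
                                                   domain = character())) {
  p <- presence(pam)
  genomes <- colnames(p)
  div <- taxonomy$division[match(genomes, taxonomy$genome_id)]
  if (anyNA(div))
    stop("genome(s) without a division: ",
         paste(genomes[is.na(div)], collapse = ", "))
  divs <- unique(taxonomy$division)
  counts <- table(factor(taxonomy$division, levels = divs))
  if (any(counts == 0))
    stop("division(s) with zero genomes: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  vals <- do.call(rbind, lapply(divs, function(d) {
    cols <- genomes[div == d]
    n_total <- sum(taxonomy$division == d)
    rowSums(p[, cols, drop = FALSE]) / n_total
  }))
  dimnames(vals) <- list(divs, rownames(p))
  dom <- stats::setNames(domains$domain[match(divs, domains$division)], divs)
  dom <- dom[!is.na(dom)]
  new("ProfileMatrix", values = vals, domains = dom)
}

#' Uncentered-correlation distance
#'
#' One minus the cosine-like similarity without mean-centering:
#' \deqn{d(x, y) = 1 - \frac{\sum x_i y_i}{\sqrt{\sum x_i^2 \sum y_i^2}}}
#' Ranges over \[0, 2\]; 0 for proportional vectors, 1 for orthogonal ones.
#'
#' @param x,y numeric vectors of equal length; neither may be all-zero.
#' @return distance in \[0, 2\].
#' @export
uncenteredCorrelationDistance <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("uncentered correlation undefined for an all-zero vector")
  1 - sum(x * y) / (nx * ny)
}

#' Pearson-correlation distance
#'
#' One minus the sample correlation coefficient; ranges over \[0, 2\].
#'
#' @param x,y numeric vectors of equal length, each with nonzero variance.
#' @return distance in \[0, 2\].
#' @export
pearsonDistance <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for a zero-variance vector")
  1 - stats::cor(x, y)
}

# full pairwise distance matrix over the rows of m, naming offending pairs
profileDistanceMatrix <- function(m, distance = c("uncentered", "pearson")) {
  distance <- match.arg(distance)
  f <- switch(distance, uncentered = uncenteredCorrelationDistance,
              pearson = pearsonDistance)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tryCatch(f(m[i, ], m[j, ]), error = function(err)
        stop("distance undefined for pair (", rownames(m)[i], ", ",
             rownames(m)[j], "): ", conditionMessage(err), call. = FALSE))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Agglomerative hierarchical clustering of profile rows or columns
#'
#' Single- or complete-linkage clustering under the uncentered-correlation
#' or Pearson distance. No leaf-order optimization is performed: the leaf
#' order is the merge-induced order. Ties between equal minimal distances
#' are broken towards the pair whose (smallest member index, other smallest
#' member index) is lexicographically least, which makes the merge sequence
#' deterministic.
#'
#' The default combination (complete linkage, uncentered correlation) is
#' the one used for the published division-by-gene profile; single linkage
#' with the Pearson distance, the combination quoted for the rendered
#' figure, is available through the arguments.
#'
#' @param x a \linkS4class{ProfileMatrix} or numeric matrix.
#' @param axis cluster \code{"rows"} or \code{"cols"}.
#' @param linkage \code{"complete"} (default) or \code{"single"}.
#' @param distance \code{"uncentered"} (default) or \code{"pearson"}.
#' @return a \linkS4class{LinkageDendrogram}.
#' @export
hcluster <- function(x, axis = c("rows", "cols"),
                     linkage = c("complete", "single"),
                     distance = c("uncentered", "pearson")) {
  axis <- match.arg(axis); linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  m <- if (is(x, "ProfileMatrix")) profileValues(x) else x
  if (axis == "cols") m <- t(m)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 items on the chosen axis")
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(n))
  D <- profileDistanceMatrix(m, distance)
  .agglomerate(D, linkage, rownames(m), distance)
}

# core agglomeration on a precomputed symmetric distance matrix
.agglomerate <- function(D, linkage, labels, distance = "precomputed") {
  n <- nrow(D)
  # active clusters: list of member index vectors; id: hclust encoding
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  reps <- seq_len(n)          # smallest original member index per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  trees <- vector("list", n)  # nested structure for leaf ordering

  cluster_dist <- function(a, b) {
    vals <- D[members[[a]], members[[b]], drop = FALSE]
    if (linkage == "complete") max(vals) else min(vals)
  }

  for (step in seq_len(n - 1)) {
    k <- length(members)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- cluster_dist(i, j)
        lo <- min(reps[i], reps[j]); hi <- max(reps[i], reps[j])
        if (is.null(best) || d < best$d - 1e-15 ||
            (abs(d - best$d) <= 1e-15 &&
             (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best <- list(d = d, i = i, j = j, lo = lo, hi = hi)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    merged_members <- c(members[[i]], members[[j]])
    # merge-induced order: left subtree is the cluster with the smaller
    # representative index
    left <- if (reps[i] <= reps[j]) i else j
    right <- if (left == i) j else i
    subtree <- list(getTree(trees, members, left), getTree(trees, members, right))
    members[[i]] <- merged_members
    reps[i] <- min(reps[i], reps[j])
    ids[i] <- step
    trees[[i]] <- subtree
    members[[j]] <- NULL
    reps <- reps[-j]; ids <- ids[-j]; trees[[j]] <- NULL
  }
  order <- unlist(trees[[1]])
  new("LinkageDendrogram", merge = merge, height = height,
      order = as.integer(order), labels = labels,
      linkage = linkage, distance = distance)
}

getTree <- function(trees, members, idx) {
  if (is.null(trees[[idx]])) members[[idx]] else trees[[idx]]
}

#' Convert a LinkageDendrogram to an hclust object
#'
#' @param x a \linkS4class{LinkageDendrogram}.
#' @param ... ignored.
#' @return a \code{\link[stats]{hclust}} object.
#' @export
as.hclust.LinkageDendrogram <- function(x, ...) {
  structure(list(merge = x@merge, height = x@height, order = x@order,
                 labels = x@labels,
                 method = x@linkage,
                 dist.method = x@distance,
                 call = match.call()),
            class = "hclust")
}

#' Serialize a dendrogram to Newick with merge heights as branch lengths
#'
#' @param x a \linkS4class{LinkageDendrogram}.
#' @return Newick string.
#' @export
dendrogramNewick <- function(x) {
  ph <- ape::as.phylo(stats::as.hclust(x))
  ape::write.tree(ph)
}

#' Write a profile matrix as TSV
#'
#' Division rows, gene columns; the division's domain tag (archaeal or
#' bacterial) is carried in a second column when known.
#'
#' @param pm a \linkS4class{ProfileMatrix}.
#' @param path output file.
#' @param provenance optional character vector written as leading
#'   \code{#} comment lines (parameters used to produce the profile).
#' @export
writeProfileMatrix <- function(pm, path, provenance = NULL) {
  v <- profileValues(pm)
  dom <- divisionDomains(pm)[rownames(v)]
  dom[is.na(dom)] <- ""
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("division", "domain", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], dom[i],
                       format(v[i, ], trim = TRUE)), collapse = "\t"), con)
  invisible(path)
}
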
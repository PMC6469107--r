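# shared fixtures and independent oracles, built in code

packagedTable <- function() {
  system.file("extdata", "crl_regulon.tsv", package = "regulonTracer")
}

loadPackagedNetwork <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(loadRegulonTable(packagedTable()))
    cache
  }
})

# write a small regulon table from a data.frame of row lists
writeToyTable <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(c("gene", "bnumber", "tus", "co_regulators", "crl_effect",
                    "evidence", "references", "go_terms"), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

# a tiny 4-letter alphabet scoring scheme for the brute-force oracle;
# gap penalties are small so gapped optima actually occur at length <= 5
toyScheme <- function(gapOpen = 3, gapExtend = 1) {
  b <- c("A", "B", "C", "D")
  m <- matrix(-2, 4, 4, dimnames = list(b, b))
  diag(m) <- c(3, 4, 2, 3)
  m["A", "C"] <- m["C", "A"] <- 1
  scoringScheme(matrix = m, gapOpen = gapOpen, gapExtend = gapExtend,
                lambda = 0.5, K = 0.1, dbLength = 1e4)
}

randomToySeq <- function(n) {
  paste(sample(c("A", "B", "C", "D"), n, replace = TRUE), collapse = "")
}

# brute-force global alignment score by recursive enumeration of all
# monotone alignments under affine gaps (gap of length L costs
# open + L * ext); exponential, for lengths <= 5 only
bruteGlobalScore <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  go <- scheme@gapOpen; ge <- scheme@gapExtend
  m <- scheme@matrix
  rec <- function(i, j, state) {
    # state: 0 none/match, 1 gap-in-b (consuming a), 2 gap-in-a
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv))
      best <- max(best, m[av[i], bv[j]] + rec(i + 1, j + 1, 0))
    if (i <= length(av)) {
      pen <- ge + if (state == 1) 0 else go
      best <- max(best, -pen + rec(i + 1, j, 1))
    }
    if (j <= length(bv)) {
      pen <- ge + if (state == 2) 0 else go
      best <- max(best, -pen + rec(i, j + 1, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# brute-force local score: best global score over all substring pairs, or 0
bruteLocalScore <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv)) {
      s <- bruteGlobalScore(paste(av[i1:i2], collapse = ""),
                            paste(bv[j1:j2], collapse = ""), scheme)
      best <- max(best, s)
    }
  best
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
bruteEnrichmentP <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K are the category members
  mean(hits >= k)
}

# naive agglomeration reference: recompute cluster distances from the raw
# pairwise matrix at every step (no Lance-Williams updates)
naiveAgglomerate <- function(D, linkage) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      vals <- D[clusters[[i]], clusters[[j]], drop = FALSE]
      d <- if (linkage == "complete") max(vals) else min(vals)
      lo <- min(clusters[[i]][1], clusters[[j]][1])
      hi <- max(clusters[[i]][1], clusters[[j]][1])
      # same deterministic tie rule as the implementation, but applied to
      # distances recomputed from scratch
      if (is.null(best) || d < best$d - 1e-15 ||
          (abs(d - best$d) <= 1e-15 &&
           (lo < best$lo || (lo == best$lo && hi < best$hi))))
        best <- list(d = d, i = i, j = j, lo = lo, hi = hi)
    }
    merges[step, ] <- sort(c(ids[best$i], ids[best$j]))
    heights[step] <- best$d
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    ids[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(merge = merges, height = heights)
}

# small simulated panel shared across orthology tests
scaledPanel <- local({
  cache <- new.env(parent = emptyenv())
  function(divergence, seed = 42, retention = 0.5) {
    key <- paste(divergence, seed, retention)
    if (is.null(cache[[key]])) {
      cfg <- simConfig(nArchaealDivisions = 1, nBacterialDivisions = 4,
                       genomesPerDivision = 4, nFamilies = 6,
                       retention = retention, divergence = divergence,
                       decoysPerGenome = 8, seed = seed)
      cache[[key]] <- c(simulateProteomes(cfg), list(config = cfg))
    }
    cache[[key]]
  }
})

bdbhAgainstTruth <- function(sim, maxEvalue = 1e-6, minCoverage = 0.6) {
  ref <- proteomes(sim$proteomes)[[sim$reference]]
  seeds <- grep("^fam", names(ref), value = TRUE)
  assign <- bdbhAll(seeds, sim$proteomes, ref,
                    maxEvalue = maxEvalue, minCoverage = minCoverage)
  truth <- presence(sim$truth@presence)
  pam <- presenceMatrix(assign, rownames(truth), colnames(truth))
  pred <- presence(pam)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  list(assignments = assign, pred = pred, truth = truth,
       precision = if (tp + fp) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn) tp / (tp + fn) else NA_real_)
}

# random two-clade alignment with many diagnostic columns
twoCladeAlignment <- function(nPerClade = 4, nDiag = 60, nNoise = 40) {
  bases <- c("A", "C", "G", "T")
  cladeA <- sample(bases, nDiag, TRUE)
  cladeB <- vapply(cladeA, function(b) sample(setdiff(bases, b), 1), "")
  shared <- sample(bases, nNoise, TRUE)
  mk <- function(core) {
    v <- c(core, shared)
    flip <- sample(length(v), 3)   # light within-clade noise
    v[flip] <- vapply(v[flip], function(b) sample(setdiff(bases, b), 1), "")
    paste(v, collapse = "")
  }
  s <- c(vapply(seq_len(nPerClade), function(i) mk(cladeA), ""),
         vapply(seq_len(nPerClade), function(i) mk(cladeB), ""))
  stats::setNames(s, c(paste0("a", seq_len(nPerClade)),
                       paste0("b", seq_len(nPerClade))))
}
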
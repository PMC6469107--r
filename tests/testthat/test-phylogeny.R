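randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

mutateSites <- function(s, idx, kind = c("any", "transversion")) {
  kind <- match.arg(kind)
  v <- strsplit(s, "")[[1]]
  # complement-style swaps are transversions that conserve base frequencies
  swap <- c(A = "T", T = "A", C = "G", G = "C")
  for (i in idx) {
    v[i] <- if (kind == "transversion") swap[[v[i]]] else
      sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}

test_that("TN93 distance is zero on identical sequences and symmetric", {
  s <- randomDna(120)
  expect_equal(as.numeric(tn93Distance(s, s)), 0)
  set.seed(2)
  t <- mutateSites(s, sample(120, 20))
  expect_equal(tn93Distance(s, t), tn93Distance(t, s))
})

test_that("with only transversions the TN93 distance reduces to the K2P formula", {
  set.seed(3)
  # equal base frequencies; complement-swap transversions applied to the
  # same number of sites of each base, so the frequencies stay equal
  s <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  idx <- unlist(lapply(0:3, function(o) sample(seq(1 + o, 200, by = 4), 7)))
  t <- mutateSites(s, idx, kind = "transversion")
  Q <- 28 / 200
  k2p <- -0.5 * log(1 - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(as.numeric(tn93Distance(s, t)), k2p, tolerance = 1e-9)
})

test_that("TN93 matches an independent closed-form evaluation to 1e-9", {
  set.seed(4)
  for (rep in 1:5) {
    s <- randomDna(100)
    t <- mutateSites(s, sample(100, sample(10:30, 1)))
    ours <- as.numeric(tn93Distance(s, t))
    bin <- ape::as.DNAbin(matrix(c(strsplit(tolower(s), "")[[1]],
                                   strsplit(tolower(t), "")[[1]]),
                                 2, byrow = TRUE))
    ref <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("TN93 grows monotonically with added substitutions and flags saturation", {
  set.seed(6)
  s <- randomDna(300)
  idx <- sample(300)
  ds <- vapply(c(10, 30, 60, 90), function(k)
    as.numeric(tn93Distance(s, mutateSites(s, idx[seq_len(k)]))), 1)
  expect_true(all(diff(ds) > 0))
  # saturation: near-complementary pair has no valid log argument
  sat <- tn93Distance(paste(rep("A", 60), collapse = ""),
                      paste(rep(c("G", "C"), 30), collapse = ""))
  expect_true(is.nan(sat))
  expect_true(attr(sat, "saturated"))
  # gaps are skipped pairwise; an all-gap pair has no comparable sites
  expect_error(tn93Distance("----", "ACGT"), "no comparable sites")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(8)
  for (rep in 1:4) {
    tr <- ape::rtree(sample(4:7, 1))
    D <- stats::cophenetic(tr)
    got <- njTree(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), got)), 0)
    expect_equal(stats::cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("three taxa resolve with closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  lens <- stats::setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                          tr$tip.label)
  expect_equal(lens[["a"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["b"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["c"]], (4 + 5 - 3) / 2)
})

test_that("small perturbations of an additive matrix keep the topology", {
  set.seed(12)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length + 0.5   # keep internal edges long
  D <- stats::cophenetic(tr)
  for (rep in 1:5) {
    E <- D + matrix(stats::runif(36, -1e-3, 1e-3), 6)
    E <- (E + t(E)) / 2; diag(E) <- 0
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), njTree(E))), 0)
  }
})

test_that("non-finite distances are rejected with the offending pair named", {
  D <- matrix(c(0, NaN, NaN, 0), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  D3 <- rbind(cbind(D, z = c(1, 1)), z = c(1, 1, 0))
  dimnames(D3) <- list(c("x", "y", "z"), c("x", "y", "z"))
  expect_error(njTree(D3), "x-y")
})

test_that("two-leaf pruning equals the analytic pairwise TN93 likelihood", {
  p <- tn93Params(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                  alpha1 = 2, alpha2 = 3, beta = 1)
  tr <- ape::read.tree(text = "(a:0.04,b:0.09);")
  set.seed(14)
  sa <- randomDna(150)
  sb <- mutateSites(sa, sample(150, 15))
  ll <- tn93Loglik(tr, c(a = sa, b = sb), p)
  P <- tn93TransitionProb(p, 0.13)      # pulley principle: t = 0.04 + 0.09
  f <- p@baseFreqs
  av <- strsplit(sa, "")[[1]]; bv <- strsplit(sb, "")[[1]]
  analytic <- sum(log(mapply(function(x, y) f[x] * P[x, y], av, bv)))
  expect_equal(ll, analytic, tolerance = 1e-9)
})

test_that("at t -> 0 a two-leaf identical column approaches log pi(state)", {
  p <- tn93Params()
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  ll <- tn93Loglik(tr, c(a = "A", b = "A"), p)
  expect_equal(ll, log(0.25), tolerance = 1e-6)
})

test_that("the pruning likelihood is invariant under re-rooting", {
  p <- tn93Params(c(A = 0.35, C = 0.15, G = 0.2, T = 0.3))
  set.seed(16)
  tr <- ape::rtree(6)
  anc <- randomDna(90)
  seqs <- stats::setNames(vapply(seq_len(6), function(i)
    mutateSites(anc, sample(90, sample(5:15, 1))), ""), tr$tip.label)
  ll1 <- tn93Loglik(tr, seqs, p)
  tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                   resolve.root = TRUE)
  ll2 <- tn93Loglik(tr2, seqs, p)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("TN93 transition probabilities are stochastic and satisfy detailed balance", {
  p <- tn93Params(c(A = 0.4, C = 0.1, G = 0.3, T = 0.2), 2.5, 1.5, 1)
  P <- tn93TransitionProb(p, 0.3)
  expect_equal(rowSums(P), c(A = 1, C = 1, G = 1, T = 1), tolerance = 1e-12)
  f <- p@baseFreqs
  for (i in 1:4) for (j in 1:4)
    expect_equal(f[i] * P[i, j], f[j] * P[j, i], tolerance = 1e-12,
                 ignore_attr = TRUE)
  expect_equal(tn93TransitionProb(p, 0), diag(4), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("progressive alignment reduces to pairwise for two sequences and is gap-free for identical inputs", {
  s <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "ACGTACGTAC")
  al <- progressiveAlign(s)
  expect_equal(unname(alignmentRows(al)), unname(s))  # no gaps introduced
  two <- c(a = "ACGTTTACGT", b = "ACGTACGT")
  al2 <- progressiveAlign(two)
  pw <- globalAlign(two[1], two[2], nucleotideScheme())
  expect_equal(unname(alignmentRows(al2)[["a"]]), pw@alignedQuery)
  expect_equal(unname(alignmentRows(al2)[["b"]]), pw@alignedSubject)
})

test_that("the progressive alignment is locally optimal on sum-of-pairs", {
  # independent linear-gap sum-of-pairs scorer: substitution score per
  # residue column pair, -gapExtend per residue-against-gap column
  spLinear <- function(rows, scheme = nucleotideScheme()) {
    mat <- do.call(rbind, strsplit(unname(rows), ""))
    total <- 0
    n <- nrow(mat)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- mat[i, ]; b <- mat[j, ]
      both <- a != "-" & b != "-"
      one <- xor(a == "-", b == "-")
      total <- total +
        sum(scheme@matrix[cbind(a[both], b[both])]) -
        scheme@gapExtend * sum(one)
    }
    total
  }
  set.seed(21)
  s <- c(a = "ACGTACGTACGGT", b = "ACGTACGACGGT", c = "ACGTACCGTACGT")
  al <- progressiveAlign(s)
  rows <- alignmentRows(al)
  sp <- spLinear(rows)
  ncol_aln <- nchar(rows[1])
  for (rep in 1:10) {
    # a joint column shuffle preserves every column, hence the score:
    # the produced alignment is never beaten by one
    perm <- sample(ncol_aln)
    shuffled <- vapply(rows, function(r)
      paste(strsplit(r, "")[[1]][perm], collapse = ""), "")
    expect_gte(sp, spLinear(shuffled))
    # scrambling gap placements independently per row destroys the
    # residue pairings and must score strictly worse
    scrambled <- vapply(rows, function(r) {
      v <- strsplit(r, "")[[1]]
      res <- v[v != "-"]
      pos <- sample(length(v), length(res))
      out <- rep("-", length(v))
      out[sort(pos)] <- res
      paste(out, collapse = "")
    }, "")
    expect_gt(sp, spLinear(scrambled))
  }
})

test_that("deleting gaps from the progressive alignment recovers the inputs", {
  set.seed(22)
  s <- stats::setNames(vapply(1:5, function(i) randomDna(40 + 3 * i), ""),
                       paste0("s", 1:5))
  al <- progressiveAlign(s)
  expect_equal(vapply(alignmentRows(al), function(r) gsub("-", "", r), ""),
               s)
})

test_that("bootstrap supports are 0/100 at B = 1 and empty for identical sequences", {
  set.seed(25)
  aln <- twoCladeAlignment()
  b1 <- bootstrapSupport(aln, B = 1)
  expect_true(all(attr(b1, "supports") %in% c(0, 100)))
  same <- stats::setNames(rep(paste(rep("ACGT", 20), collapse = ""), 4),
                          paste0("s", 1:4))
  b0 <- bootstrapSupport(same, B = 5)
  expect_length(attr(b0, "supports"), 0)
})

test_that("a strongly structured two-clade alignment is supported at >= 95%", {
  set.seed(26)
  aln <- twoCladeAlignment(nPerClade = 4, nDiag = 60, nNoise = 40)
  tree <- bootstrapSupport(aln, B = 100)
  # the a-clade bipartition is an edge of the main tree with high support
  expect_true(any(attr(tree, "supports") >= 95))
})

test_that("supports are invariant to leaf-label permutation up to resampling", {
  set.seed(27)
  aln <- twoCladeAlignment()
  set.seed(99); t1 <- bootstrapSupport(aln, B = 25)
  perm <- sample(names(aln))
  set.seed(99); t2 <- bootstrapSupport(aln[perm], B = 25)
  expect_setequal(attr(t1, "supports"), attr(t2, "supports"))
})

test_that("rendering masks supports below the display threshold but keeps the data", {
  set.seed(28)
  aln <- twoCladeAlignment()
  tree <- bootstrapSupport(aln, B = 20, displayThreshold = 60)
  out <- tempfile(fileext = ".nwk")
  writeSupportTree(tree, out, displayThreshold = 101)  # mask everything
  txt <- readLines(out)
  expect_false(grepl("\\)1?[0-9]+:", txt))             # no support labels left
  expect_true(length(attr(tree, "supports")) >= 1)     # data retained
})
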
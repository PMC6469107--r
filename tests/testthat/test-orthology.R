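toyProteome <- function(seqs) Biostrings::AAStringSet(seqs)

test_that("a verbatim copy of the query is its own best hit", {
  prot <- toyProteome(c(p1 = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQ",
                        p2 = "GGSSGGSSGGSSGGSSGGSSGGSSGGSSGGSSGGG"))
  hit <- bestHit(c(q = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQ"), prot,
                 maxEvalue = 1e-3, minCoverage = 0.6)
  expect_equal(hit$subject, "p1")
  expect_equal(hit$coverage, 1)
})

test_that("unrelated short peptides fall below the threshold", {
  prot <- toyProteome(c(p1 = "GGGGGGGG", p2 = "PPPPPPPP"))
  hit <- bestHit(c(q = "MKVLWAALLVTFLAGCQAKVEQAVETEPEPELRQQ"), prot,
                 maxEvalue = 1e-6, minCoverage = 0.6)
  expect_null(hit)
})

test_that("best hit equals the brute-force argmax over a 10-protein proteome", {
  set.seed(5)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mkprot <- function(n) paste(sample(aas, n, TRUE), collapse = "")
  base <- mkprot(60)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- sample(aas, k, TRUE)
    paste(v, collapse = "")
  }
  prot <- toyProteome(stats::setNames(
    vapply(c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50),
           function(k) mutate(base, k), ""),
    paste0("p", 1:10)))
  sch <- scoringScheme()
  # oracle: exhaustive all-vs-one scoring with the same thresholds
  scores <- vapply(seq_along(prot), function(i)
    localAlign(base, as.character(prot[[i]]), sch)@rawScore, 1)
  covs <- vapply(seq_along(prot), function(i)
    localAlign(base, as.character(prot[[i]]), sch)@qCoverage, 1)
  es <- vapply(scores, evalue, 1, queryLen = 60, scheme = sch)
  pass <- es <= 1e-6 & covs >= 0.6
  expect_true(any(pass))
  oracle <- names(prot)[pass][which.max(scores[pass])]
  hit <- bestHit(c(q = base), prot, sch)
  expect_equal(hit$subject, oracle)
})

test_that("BDBH maps every seed to its own copy in an identical genome", {
  sim <- scaledPanel(divergence = 0)
  ref <- proteomes(sim$proteomes)[[sim$reference]]
  # target genome = exact copy of the reference
  pset2 <- proteomeSet(
    list(refcopy = ref, orig = ref),
    data.frame(genome_id = c("refcopy", "orig"), division = c("d", "d")))
  for (s in grep("^fam", names(ref), value = TRUE)[1:3]) {
    a <- bdbh(s, "refcopy", pset2, ref)
    expect_true(a$present)
    expect_equal(a$subject_id, s)
  }
})

test_that("a paralog trap breaks reciprocity and yields no assignment", {
  set.seed(9)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p1 <- paste(sample(aas, 80, TRUE), collapse = "")
  v <- strsplit(p1, "")[[1]]
  i <- sample(80, 16); v[i] <- sample(aas, 16, TRUE)
  p2 <- paste(v, collapse = "")                      # paralog of p1
  # target protein: p2 with slight extra noise -> closest to p2, not p1
  w <- strsplit(p2, "")[[1]]
  j <- sample(80, 4); w[j] <- sample(aas, 4, TRUE)
  tgt <- paste(w, collapse = "")
  ref <- Biostrings::AAStringSet(c(P1 = p1, P2 = p2))
  pset <- proteomeSet(
    list(t = Biostrings::AAStringSet(c(tp = tgt)), r = ref),
    data.frame(genome_id = c("t", "r"), division = c("d", "d")))
  a <- bdbh("P1", "t", pset, ref)
  expect_false(a$present)
  # sanity: the same search seeded from P2 succeeds
  b <- bdbh("P2", "t", pset, ref)
  expect_true(b$present)
})

test_that("at divergence zero BDBH recovers the planted truth exactly", {
  sim <- scaledPanel(divergence = 0)
  res <- bdbhAgainstTruth(sim)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
})

test_that("threshold tightening never adds an ortholog", {
  sim <- scaledPanel(divergence = 0.05)
  loose <- bdbhAgainstTruth(sim, maxEvalue = 1e-6, minCoverage = 0.6)
  tightE <- bdbhAgainstTruth(sim, maxEvalue = 1e-30, minCoverage = 0.6)
  tightC <- bdbhAgainstTruth(sim, maxEvalue = 1e-6, minCoverage = 0.95)
  expect_true(all(tightE$pred <= loose$pred))
  expect_true(all(tightC$pred <= loose$pred))
})

test_that("homolog scan finds the self hit first and respects empty panels", {
  sim <- scaledPanel(divergence = 0.05)
  ref <- proteomes(sim$proteomes)[[sim$reference]]
  seed <- stats::setNames(as.character(ref[["fam01"]]), "fam01")
  hits <- homologScan(seed, sim$proteomes)
  self <- hits[hits$genome == sim$reference & hits$subject == "fam01", ]
  expect_equal(nrow(self), 1)
  expect_equal(min(hits$evalue), self$evalue)
  empty <- proteomeSet(list(), data.frame(genome_id = character(),
                                          division = character()))
  expect_equal(nrow(homologScan(seed, empty)), 0)
})

test_that("presence matrix handles the empty, full and conflicting cases", {
  empty <- data.frame(seed_gene = character(), genome_id = character(),
                      subject_id = character(), forward_evalue = numeric(),
                      reverse_evalue = numeric(), present = logical())
  m0 <- presenceMatrix(empty, genes = c("f1", "f2"), genomes = c("g1", "g2"))
  expect_false(any(presence(m0)))
  full <- data.frame(seed_gene = rep(c("f1", "f2"), 2),
                     genome_id = rep(c("g1", "g2"), each = 2),
                     subject_id = "x", forward_evalue = 0,
                     reverse_evalue = 0, present = TRUE)
  m1 <- presenceMatrix(full, c("f1", "f2"), c("g1", "g2"))
  expect_true(all(presence(m1)))
  conflict <- data.frame(seed_gene = c("f1", "f1"), genome_id = c("g1", "g1"),
                         subject_id = c("x", "y"), forward_evalue = 0,
                         reverse_evalue = 0, present = TRUE)
  expect_error(presenceMatrix(conflict, "f1", "g1"), "conflicting subjects")
})

test_that("the exact-duplicate genome filter removes only true duplicates", {
  a <- Biostrings::AAStringSet(c(x = "MKV", y = "WWW"))
  b <- Biostrings::AAStringSet(c(u = "WWW", v = "MKV"))  # same set, other ids
  c_ <- Biostrings::AAStringSet(c(z = "MKVH"))
  pset <- proteomeSet(list(g1 = a, g2 = b, g3 = c_),
                      data.frame(genome_id = c("g1", "g2", "g3"),
                                 division = "d"))
  out <- dedupeGenomes(pset)
  expect_setequal(names(proteomes(out)), c("g1", "g3"))
  expect_equal(attr(out, "removed"), "g2")
})
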
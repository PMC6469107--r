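test_that("the packaged compendium loads with 86 genes and flags the shared locus tag", {
  expect_warning(net <- loadRegulonTable(packagedTable()),
                 "duplicate bnumber.*b0885")
  expect_s4_class(net, "RegulonNetwork")
  expect_equal(nrow(regulonGenes(net)), 86)
  expect_equal(sum(regulonGenes(net)$dup_bnumber), 2)  # aat and ymfE
})

test_that("an empty table yields an empty network and schema errors name the column", {
  p <- writeToyTable(character())
  net <- loadRegulonTable(p)
  expect_equal(nrow(regulonGenes(net)), 0)
  expect_equal(nrow(regulonEdges(net)), 0)
  bad <- tempfile()
  writeLines("gene\tbnumber\ttus", bad)
  expect_error(loadRegulonTable(bad), "missing required column.*co_regulators")
})

test_that("a toy row produces one gene and one edge per regulator", {
  p <- writeToyTable(
    "yaaX\tb0001\tyaaX\tCRP(+);ArcA(-)\t+\tGEA\tCR1\tsome process")
  net <- loadRegulonTable(p)
  expect_equal(nrow(regulonGenes(net)), 1)
  expect_equal(nrow(regulonEdges(net)), 3)     # 1 Crl + 2 co-regulators
  expect_setequal(regulonEdges(net)$regulator, c("Crl", "CRP", "ArcA"))
})

test_that("unknown effect symbols are parse errors carrying the row number", {
  p <- writeToyTable(
    "yaaX\tb0001\tyaaX\t\t?\tGEA\tCR1\t")
  expect_error(loadRegulonTable(p), "row 1.*unknown effect symbol")
})

test_that("dual-sign co-regulators collapse to a single +/- edge", {
  p <- writeToyTable(
    "gadA\tb3517\tgadAX\tGadW(+/-)\t+\tMSI\tCR10\t")
  net <- loadRegulonTable(p)
  co <- regulonEdges(net)[regulonEdges(net)$regulator == "GadW", ]
  expect_equal(nrow(co), 1)
  expect_equal(co$effect, "+/-")
})

test_that("sign tally matches the published 73 activated / 12 repressed split", {
  net <- loadPackagedNetwork()
  tally <- effectSignTally(net)
  expect_equal(tally[["+"]], 73)
  expect_equal(tally[["-"]], 12)
  # tallies deduplicate by locus tag: they sum to the distinct-locus count
  expect_equal(sum(tally), length(unique(regulonGenes(net)$bnumber)))
})

test_that("sign tally on a single-gene network counts one activation", {
  p <- writeToyTable("yaaX\tb0001\tyaaX\t\t+\tGEA\tCR1\t")
  tally <- effectSignTally(loadRegulonTable(p))
  expect_equal(tally[["+"]], 1)
  expect_equal(tally[["-"]], 0)
})

test_that("exclusive/co-regulated partition is 24/62 and covers all genes", {
  net <- loadPackagedNetwork()
  part <- exclusiveGenePartition(net)
  expect_length(part$crl_only, 24)
  expect_length(part$co_regulated, 62)
  expect_length(intersect(part$crl_only, part$co_regulated), 0)
  expect_setequal(c(part$crl_only, part$co_regulated),
                  regulonGenes(net)$gene)
})

test_that("partition degenerates correctly without co-regulators", {
  p <- writeToyTable(c(
    "aaaA\tb0001\taaaA\t\t+\tGEA\tCR1\t",
    "bbbB\tb0002\tbbbB\tCRP(+)\t-\tMSI\tCR2\t"))
  net <- loadRegulonTable(p)
  part <- exclusiveGenePartition(net)
  expect_equal(part$crl_only, "aaaA")
  expect_equal(part$co_regulated, "bbbB")
})

test_that("TF-degree histogram reproduces 19/11/14 for one/two/three TFs", {
  h <- tfDegreeHistogram(loadPackagedNetwork())
  expect_equal(h[["1"]], 19)
  expect_equal(h[["2"]], 11)
  expect_equal(h[["3"]], 14)
  # conservation: histogram totals the co-regulated genes
  expect_equal(sum(h),
               length(exclusiveGenePartition(loadPackagedNetwork())$co_regulated))
})

test_that("a regulator appearing with two signs counts once in the degree", {
  p <- writeToyTable("yaaX\tb0001\tyaaX\tAda(+);Ada(-)\t+\tGEA\tCR1\t")
  h <- tfDegreeHistogram(loadRegulonTable(p))
  expect_equal(h, c(`1` = 1L))
})

test_that("TU summary gives 77 units with 52% monogenic, and TU names expand correctly", {
  net <- loadPackagedNetwork()
  tu <- tuSummary(net)
  expect_equal(tu$n_tus, 77)
  expect_equal(tu$pct_monogenic, 52)
  expect_equal(parseTuName("csgBAC"), c("csgB", "csgA", "csgC"))
  expect_equal(parseTuName("fliAZ-tcyJ"), c("fliA", "fliZ", "tcyJ"))
  expect_equal(parseTuName("sdhCDAB-sucABCD"),
               c("sdhC", "sdhD", "sdhA", "sdhB",
                 "sucA", "sucB", "sucC", "sucD"))
  expect_equal(parseTuName("ada-alkB"), c("ada", "alkB"))
  expect_equal(parseTuName("uof"), "uof")
})

test_that("TU summary handles tiny networks", {
  p1 <- writeToyTable("aaaA\tb0001\taaaA\t\t+\tGEA\tCR1\t")
  expect_equal(tuSummary(loadRegulonTable(p1)),
               list(n_tus = 1, pct_monogenic = 100))
  p2 <- writeToyTable(c(
    "aaaA\tb0001\taaaA\t\t+\tGEA\tCR1\t",
    "bbbB\tb0002\tbbbBC\t\t+\tGEA\tCR1\t"))
  expect_equal(tuSummary(loadRegulonTable(p2))$pct_monogenic, 50)
})

test_that("edge-list export is deterministic and round-trips the edge multiset", {
  net <- loadPackagedNetwork()
  p <- tempfile(fileext = ".tsv")
  exportEdgeList(net, p)
  rows <- utils::read.delim(p, header = FALSE,
                            col.names = c("regulator", "target", "sign"))
  expect_equal(nrow(rows), nrow(regulonEdges(net)))
  got <- sort(paste(rows$regulator, rows$target, rows$sign))
  want <- sort(paste(regulonEdges(net)$regulator, regulonEdges(net)$target,
                     regulonEdges(net)$effect))
  expect_equal(got, want)
  # deterministic bytes on re-export
  p2 <- tempfile(fileext = ".tsv")
  exportEdgeList(net, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("single-edge export writes one data row plus optional header", {
  p <- writeToyTable("aaaA\tb0001\taaaA\t\t+\tGEA\tCR1\t")
  net <- loadRegulonTable(p)
  out <- tempfile()
  exportEdgeList(net, out, header = TRUE)
  expect_length(readLines(out), 2)
})

test_that("enrichment p-values match exhaustive enumeration for small cases", {
  # the worked example: N=10, K=5, n=4, k=4 -> 5/210
  genes <- paste0("g", 1:10)
  cats <- stats::setNames(rep(list(character()), 10), genes)
  for (g in genes[1:5]) cats[[g]] <- "X"
  res <- enrichmentTest(genes[1:4], genes, cats)
  expect_equal(res$p[res$category == "X"], 5 / 210, tolerance = 1e-12)
  # property: equality with enumeration over all C(N, n) draws
  set.seed(11)
  for (rep in 1:10) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    genes <- paste0("g", seq_len(N))
    cats <- stats::setNames(rep(list(character()), N), genes)
    for (g in genes[seq_len(K)]) cats[[g]] <- "X"
    query <- sample(genes, n)
    k <- sum(query %in% genes[seq_len(K)])
    res <- enrichmentTest(query, genes, cats)
    expect_equal(res$p[res$category == "X"], bruteEnrichmentP(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("enrichment degenerate cases: full query and empty overlap", {
  genes <- paste0("g", 1:8)
  cats <- stats::setNames(as.list(rep("X", 8)), genes)
  cats[["g8"]] <- "Y"
  res <- enrichmentTest(genes, genes, cats)
  expect_true(all(res$p == 1))                     # query == background
  cats0 <- stats::setNames(as.list(rep("Z", 8)), genes)
  res0 <- enrichmentTest("g1", genes, cats0)
  expect_true(all(res0$p <= 1))
  expect_error(enrichmentTest("nope", genes, cats), "absent from background")
})
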
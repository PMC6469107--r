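#' Run the regulon-tracing pipeline end to end
#'
#' Orchestrates curate -> simulate -> orthologs -> profile -> tree with
#' deterministic plain-text outputs (TSV / FASTA / Newick). Every written
#' artifact that supports comments carries a provenance header with the
#' package version and the parameters used. Stage outputs are valid
#' inputs to the next stage by construction.
#'
#' Stages:
#' \describe{
#'   \item{curate}{load the regulon table, print/write the summary
#'     statistics block and export the edge list.}
#'   \item{simulate}{generate the synthetic proteome panel and write it.}
#'   \item{orthologs}{BDBH assignment of every family seed across the
#'     panel; writes the assignments and the presence/absence matrix.}
#'   \item{profile}{per-division relative abundance + hierarchical
#'     clustering; writes the profile matrix and the row dendrogram.}
#'   \item{tree}{progressive alignment of the first family with >= 4
#'     carriers, bootstrap NJ tree; writes the support-annotated Newick.}
#' }
#'
#' @param outDir output directory (created).
#' @param tablePath regulon table for the curate stage (default: the
#'   packaged compendium).
#' @param config \linkS4class{SimConfig} for the simulation stages.
#' @param stages character vector of stages to run, in order.
#' @param homologEvalue,orthologEvalue,minCoverage,dbLength,bootstrapB,displayThreshold
#'   pipeline thresholds (defaults: 1e-3, 1e-6, 0.6, 5e8, 1000, 60).
#' @param linkage,distance clustering options for the profile stage.
#' @param quiet suppress the per-stage count log.
#' @return invisible list with the artifact paths and per-stage counts.
#' @export
runPipeline <- function(outDir,
                        tablePath = system.file("extdata", "crl_regulon.tsv",
                                                package = "regulonTracer"),
                        config = simConfig(nArchaealDivisions = 1,
                                           nBacterialDivisions = 4,
                                           genomesPerDivision = 4,
                                           nFamilies = 6, retention = 0.7,
                                           decoysPerGenome = 8, seed = 42),
                        stages = c("curate", "simulate", "orthologs",
                                   "profile", "tree"),
                        homologEvalue = 1e-3, orthologEvalue = 1e-6,
                        minCoverage = 0.6, dbLength = 5e8,
                        bootstrapB = 1000, displayThreshold = 60,
                        linkage = "complete", distance = "uncentered",
                        quiet = FALSE) {
  stopifnot(homologEvalue > 0, orthologEvalue > 0,
            minCoverage >= 0, minCoverage <= 1, dbLength > 0,
            bootstrapB >= 1, displayThreshold >= 0, displayThreshold <= 100)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()
  artifacts <- list()
  say <- function(...) if (!quiet) message(...)
  prov <- function(extra = character()) c(
    paste0("regulonTracer ",
           as.character(utils::packageVersion("regulonTracer"))),
    extra)
  scheme <- scoringScheme(dbLength = dbLength)
  sim <- NULL; pam <- NULL

  if ("curate" %in% stages) {
    if (!file.exists(tablePath))
      stop("missing input: regulon table not found at ", tablePath)
    net <- loadRegulonTable(tablePath)
    tally <- effectSignTally(net)
    part <- exclusiveGenePartition(net)
    tu <- tuSummary(net)
    stats_lines <- c(
      paste0("# ", prov(paste0("table: ", basename(tablePath)))),
      paste0("genes\t", nrow(regulonGenes(net))),
      paste0("tus\t", tu$n_tus),
      paste0("pct_monogenic_tus\t", tu$pct_monogenic),
      paste0("edges\t", nrow(regulonEdges(net))),
      paste0("positive\t", tally[["+"]]),
      paste0("negative\t", tally[["-"]]),
      paste0("crl_only\t", length(part$crl_only)),
      paste0("co_regulated\t", length(part$co_regulated)))
    statsPath <- file.path(outDir, "curate_stats.tsv")
    writeLines(stats_lines, statsPath)
    edgePath <- file.path(outDir, "edges.tsv")
    exportEdgeList(net, edgePath, header = TRUE)
    artifacts$curate <- c(statsPath, edgePath)
    log_counts$curate <- c(genes = nrow(regulonGenes(net)),
                           edges = nrow(regulonEdges(net)))
    say("curate: ", nrow(regulonGenes(net)), " genes, ",
        nrow(regulonEdges(net)), " edges")
  }

  if ("simulate" %in% stages) {
    sim <- simulateProteomes(config)
    simDir <- file.path(outDir, "panel")
    writeSimulation(sim, simDir, config)
    artifacts$simulate <- simDir
    log_counts$simulate <- c(genomes = length(proteomes(sim$proteomes)),
                             families = config@nFamilies)
    say("simulate: ", length(proteomes(sim$proteomes)), " genomes")
  }

  if ("orthologs" %in% stages) {
    if (is.null(sim)) stop("missing input: the orthologs stage needs the ",
                           "simulate stage (or a loaded panel)")
    ref <- proteomes(sim$proteomes)[[sim$reference]]
    seeds <- grep("^fam", names(ref), value = TRUE)
    assign <- bdbhAll(seeds, sim$proteomes, ref, scheme,
                      maxEvalue = orthologEvalue, minCoverage = minCoverage)
    assignPath <- file.path(outDir, "assignments.tsv")
    utils::write.table(assign, assignPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pam <- presenceMatrix(assign, seeds, names(proteomes(sim$proteomes)))
    p <- presence(pam)
    presPath <- file.path(outDir, "presence.tsv")
    utils::write.table(data.frame(gene = rownames(p), p,
                                  check.names = FALSE),
                       presPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$orthologs <- c(assignPath, presPath)
    log_counts$orthologs <- c(assignments = sum(assign$present))
    say("orthologs: ", sum(assign$present), " assignments present")
  }

  if ("profile" %in% stages) {
    if (is.null(pam)) stop("missing input: the profile stage needs the ",
                           "orthologs stage")
    prof <- relativeAbundance(pam, taxonomyMap(sim$proteomes),
                              sim$proteomes@domains)
    profPath <- file.path(outDir, "profile.tsv")
    writeProfileMatrix(prof, profPath,
                       provenance = prov(c(paste0("linkage: ", linkage),
                                           paste0("distance: ", distance))))
    dend <- hcluster(prof, "rows", linkage, distance)
    dendPath <- file.path(outDir, "divisions.nwk")
    writeLines(dendrogramNewick(dend), dendPath)
    artifacts$profile <- c(profPath, dendPath)
    log_counts$profile <- c(divisions = nrow(profileValues(prof)))
    say("profile: ", nrow(profileValues(prof)), " division rows")
  }

  if ("tree" %in% stages) {
    if (is.null(sim)) stop("missing input: the tree stage needs the ",
                           "simulate stage")
    fam_sizes <- rowSums(presence(sim$truth@presence))
    fam <- names(fam_sizes)[fam_sizes >= 4][1]
    if (is.na(fam)) stop("no family with >= 4 carriers to build a tree from")
    carriers <- colnames(presence(sim$truth@presence))[
      presence(sim$truth@presence)[fam, ]]
    nt <- vapply(carriers, function(g)
      as.character(sim$proteomes@nucleotides[[g]][[fam]]), "")
    aln <- progressiveAlign(nt, nucleotideScheme())
    tree <- bootstrapSupport(aln, B = bootstrapB,
                             displayThreshold = displayThreshold)
    treePath <- file.path(outDir, "family_tree.nwk")
    writeSupportTree(tree, treePath)
    artifacts$tree <- treePath
    log_counts$tree <- c(leaves = length(carriers), bootstrap = bootstrapB)
    say("tree: ", length(carriers), " leaves, B = ", bootstrapB)
  }

  invisible(list(artifacts = artifacts, counts = log_counts))
}
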
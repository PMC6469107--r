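#' Configuration of the synthetic proteome panel
#'
#' The default division counts (18 archaeal + 69 bacterial) match the
#' taxonomic panel the pipeline is designed to emulate; the default 61
#' genomes per division gives a panel of the same order as a few thousand
#' genomes. Tests and examples use a much smaller explicit configuration.
#'
#' @param nArchaealDivisions,nBacterialDivisions numbers of divisions.
#' @param genomesPerDivision genomes per division.
#' @param nFamilies number of seeded gene families (default 86, the size
#'   of the regulon being traced).
#' @param retention scalar or (divisions x families) matrix of
#'   per-(division, family) retention probabilities.
#' @param seqLength ancestral coding-sequence length in nt (multiple of
#'   3; default 300, i.e. a 100-residue protein).
#' @param divergence expected substitutions per site on each tree branch.
#' @param decoysPerGenome unrelated decoy proteins appended per genome.
#' @param seed integer RNG seed; a fixed seed makes outputs
#'   byte-identical.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' simConfig(nArchaealDivisions = 1, nBacterialDivisions = 4,
#'           genomesPerDivision = 4, nFamilies = 6, seed = 42)
#' @export
simConfig <- function(nArchaealDivisions = 18, nBacterialDivisions = 69,
                      genomesPerDivision = 61, nFamilies = 86,
                      retention = 0.7, seqLength = 300, divergence = 0.05,
                      decoysPerGenome = 10, seed = 1) {
  new("SimConfig",
      nArchaealDivisions = as.integer(nArchaealDivisions),
      nBacterialDivisions = as.integer(nBacterialDivisions),
      genomesPerDivision = as.integer(genomesPerDivision),
      nFamilies = as.integer(nFamilies), retention = retention,
      seqLength = as.integer(seqLength), divergence = divergence,
      decoysPerGenome = as.integer(decoysPerGenome), seed = as.integer(seed))
}

.stop_codons <- c("TAA", "TAG", "TGA")
.bases <- c("A", "C", "G", "T")

# random coding sequence without stop codons
.randomCodingSeq <- function(n_nt) {
  codons <- apply(expand.grid(.bases, .bases, .bases), 1, paste, collapse = "")
  codons <- setdiff(codons, .stop_codons)
  paste(sample(codons, n_nt / 3, replace = TRUE), collapse = "")
}

# evolve a coding sequence along one branch under TN93; stop codons are
# excluded by redrawing any mutated codon that lands on a stop
.evolveBranch <- function(seq, P) {
  v <- strsplit(seq, "")[[1]]
  n_codons <- length(v) / 3
  out <- v
  for (c in seq_len(n_codons)) {
    idx <- (3 * (c - 1) + 1):(3 * c)
    repeat {
      newc <- vapply(v[idx], function(b)
        sample(.bases, 1, prob = P[b, ]), "")
      cod <- paste(newc, collapse = "")
      if (!cod %in% .stop_codons) { out[idx] <- newc; break }
    }
  }
  paste(out, collapse = "")
}

# evolve an ancestral sequence down a tree; returns named tip sequences
.evolveTree <- function(ancestor, tree, params) {
  tre <- ape::reorder.phylo(tree, "cladewise")
  P <- lapply(tre$edge.length, function(t) tn93TransitionProb(params, t))
  nTip <- length(tre$tip.label)
  seqs <- vector("list", nTip + tre$Nnode)
  root <- tre$edge[1, 1]
  seqs[[root]] <- ancestor
  for (k in seq_len(nrow(tre$edge))) {
    parent <- tre$edge[k, 1]; child <- tre$edge[k, 2]
    seqs[[child]] <- .evolveBranch(seqs[[parent]], P[[k]])
  }
  stats::setNames(unlist(seqs[seq_len(nTip)]), tre$tip.label)
}

.translate <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

#' Simulate a proteome panel with planted ortholog families
#'
#' Generates, per gene family, a random ancestral coding sequence, a
#' random tree over the genomes that retain the family (presence sampled
#' per (division, family) from the retention probability) with all branch
#' lengths equal to the configured divergence, and tip sequences evolved
#' under TN93 with stop codons excluded. A designated reference genome
#' (the first genome of the first bacterial division, or of the first
#' division if there are no bacterial ones) retains every family so that
#' every family has a seed. Decoy proteins drawn from the shuffled pooled
#' residue composition of the family proteins are appended to every
#' genome. Amino-acid FASTA content is obtained by translation; the
#' nucleotide sequences are retained for phylogenetic use.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{proteomes}
#'   (\linkS4class{ProteomeSet}), \code{reference} (the reference genome
#'   id) and \code{truth} (\linkS4class{SimulationTruth}).
#' @export
simulateProteomes <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  nd_a <- config@nArchaealDivisions; nd_b <- config@nBacterialDivisions
  divisions <- c(if (nd_a) sprintf("arc%02d", seq_len(nd_a)),
                 if (nd_b) sprintf("bac%02d", seq_len(nd_b)))
  domains <- data.frame(
    division = divisions,
    domain = rep(c("archaeal", "bacterial"), c(nd_a, nd_b)),
    stringsAsFactors = FALSE)
  genomes <- unlist(lapply(divisions, function(d)
    sprintf("%s_g%d", d, seq_len(config@genomesPerDivision))))
  taxonomy <- data.frame(
    genome_id = genomes,
    division = rep(divisions, each = config@genomesPerDivision),
    stringsAsFactors = FALSE)
  reference <- if (nd_b) sprintf("bac%02d_g1", 1L) else genomes[1]

  fams <- sprintf("fam%02d", seq_len(config@nFamilies))
  R <- config@retention
  if (!is.matrix(R))
    R <- matrix(R, length(divisions), config@nFamilies)
  dimnames(R) <- list(divisions, fams)

  params <- tn93Params(baseFreqs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  pres <- matrix(FALSE, length(fams), length(genomes),
                 dimnames = list(fams, genomes))
  nt_by_genome <- stats::setNames(
    replicate(length(genomes), character(), simplify = FALSE), genomes)
  aa_by_genome <- nt_by_genome
  trees <- list()
  pairs <- list()

  for (f in fams) {
    anc <- .randomCodingSeq(config@seqLength)
    carry <- stats::runif(length(genomes)) <
      R[cbind(taxonomy$division, rep(f, length(genomes)))]
    names(carry) <- genomes
    carry[reference] <- TRUE
    carriers <- genomes[carry]
    pres[f, carriers] <- TRUE
    if (length(carriers) == 1) {
      tip_nt <- stats::setNames(
        .evolveBranch(anc, tn93TransitionProb(params, config@divergence)),
        carriers)
      trees[[f]] <- NULL
    } else {
      tr <- ape::rtree(length(carriers), rooted = TRUE, tip.label = carriers)
      tr$edge.length <- rep(config@divergence, nrow(tr$edge))
      trees[[f]] <- tr
      tip_nt <- .evolveTree(anc, tr, params)
    }
    for (g in carriers) {
      nt_by_genome[[g]][f] <- tip_nt[[g]]
      pairs[[length(pairs) + 1L]] <-
        data.frame(seed_gene = f, genome_id = g, protein_id = f,
                   stringsAsFactors = FALSE)
    }
  }

  for (g in genomes) {
    if (length(nt_by_genome[[g]]))
      aa_by_genome[[g]] <- stats::setNames(
        .translate(nt_by_genome[[g]]), names(nt_by_genome[[g]]))
  }
  # decoys: draw from the shuffled pooled residue composition of the
  # family proteins, so composition is protein-like but order is random
  pool <- strsplit(paste(unlist(aa_by_genome), collapse = ""), "")[[1]]
  if (!length(pool)) pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (g in genomes) {
    if (config@decoysPerGenome > 0) {
      dec <- vapply(seq_len(config@decoysPerGenome), function(k)
        paste(sample(pool, config@seqLength / 3, replace = TRUE),
              collapse = ""), "")
      names(dec) <- sprintf("decoy%02d", seq_len(config@decoysPerGenome))
      aa_by_genome[[g]] <- c(aa_by_genome[[g]], dec)
    }
  }

  proteins <- lapply(aa_by_genome, Biostrings::AAStringSet)
  nucleotides <- lapply(nt_by_genome[lengths(nt_by_genome) > 0],
                        Biostrings::DNAStringSet)
  pset <- proteomeSet(proteins, taxonomy, domains, nucleotides)
  truth <- new("SimulationTruth",
               presence = new("PresenceAbsenceMatrix", presence = pres),
               pairs = do.call(rbind, pairs),
               trees = trees)
  list(proteomes = pset, reference = reference, truth = truth)
}

#' Simulate a single-copy family restricted to designated divisions
#'
#' Plants one single-copy gene family in every genome of the designated
#' divisions and nowhere else, on a panel otherwise consisting of decoy
#' proteins. Emulates a regulator that is conserved but taxonomically
#' constrained to one part of the panel: a homolog scan of the seed
#' should yield exactly one hit per carrier genome and none elsewhere.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param designatedDivisions division names carrying the family (default:
#'   the first bacterial division). May be empty.
#' @return list with \code{proteomes} (\linkS4class{ProteomeSet}),
#'   \code{nucleotides} (named character of the family's coding
#'   sequences), \code{seed} (named character: the seed protein from the
#'   first carrier genome, or from the panel reference when there are no
#'   carriers), \code{carriers} (genome ids carrying the family) and
#'   \code{familyId}.
#' @export
crlLikeFamily <- function(config, designatedDivisions = NULL) {
  stopifnot(is(config, "SimConfig"))
  ndiv <- config@nArchaealDivisions + config@nBacterialDivisions
  R <- matrix(0, ndiv, 1)
  cfg1 <- simConfig(nArchaealDivisions = config@nArchaealDivisions,
                    nBacterialDivisions = config@nBacterialDivisions,
                    genomesPerDivision = config@genomesPerDivision,
                    nFamilies = 1, retention = R,
                    seqLength = config@seqLength,
                    divergence = config@divergence,
                    decoysPerGenome = config@decoysPerGenome,
                    seed = config@seed)
  if (is.null(designatedDivisions))
    designatedDivisions <- if (config@nBacterialDivisions) "bac01" else
      character()
  divisions <- c(if (config@nArchaealDivisions)
    sprintf("arc%02d", seq_len(config@nArchaealDivisions)),
    if (config@nBacterialDivisions)
      sprintf("bac%02d", seq_len(config@nBacterialDivisions)))
  unknown <- setdiff(designatedDivisions, divisions)
  if (length(unknown))
    stop("unknown division(s): ", paste(unknown, collapse = ", "))
  R[match(designatedDivisions, divisions), 1] <- 1
  cfg1@retention <- R
  sim <- simulateProteomes(cfg1)
  pset <- sim$proteomes
  tax <- taxonomyMap(pset)
  carriers <- tax$genome_id[tax$division %in% designatedDivisions]
  # the reference genome always carries the family in the generator;
  # when it is not designated, strip the family from it
  fam <- "fam01"
  if (!sim$reference %in% carriers) {
    prot <- proteomes(pset)
    prot[[sim$reference]] <-
      prot[[sim$reference]][names(prot[[sim$reference]]) != fam]
    nucs <- pset@nucleotides
    if (!is.null(nucs[[sim$reference]]))
      nucs[[sim$reference]] <-
        nucs[[sim$reference]][names(nucs[[sim$reference]]) != fam]
    pset <- proteomeSet(prot, tax, pset@domains, nucs)
  }
  nt <- unlist(lapply(carriers, function(g) {
    x <- pset@nucleotides[[g]]
    if (is.null(x) || !fam %in% names(x)) return(NULL)
    stats::setNames(as.character(x[fam]), g)
  }))
  seed_from <- if (length(carriers)) carriers[1] else sim$reference
  seed_prot <- proteomes(sim$proteomes)[[seed_from]]
  seed <- stats::setNames(as.character(seed_prot[[fam]]), "crl_like")
  list(proteomes = pset, nucleotides = nt, seed = seed,
       carriers = carriers, familyId = fam)
}

#' Write a simulated panel to plain-text files
#'
#' Per-genome \code{.faa} (and \code{.fna} where nucleotide sequences
#' exist) FASTA files wrapped at 60 columns, taxonomy and domain TSVs,
#' truth tables, and a YAML-style echo of the configuration.
#'
#' @param sim result of \code{\link{simulateProteomes}}.
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{SimConfig} used (echoed to
#'   \code{config.yaml}).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pset <- sim$proteomes
  for (g in names(proteomes(pset))) {
    Biostrings::writeXStringSet(proteomes(pset)[[g]],
                                file.path(dir, paste0(g, ".faa")), width = 60)
    if (!is.null(pset@nucleotides[[g]]))
      Biostrings::writeXStringSet(pset@nucleotides[[g]],
                                  file.path(dir, paste0(g, ".fna")),
                                  width = 60)
  }
  utils::write.table(taxonomyMap(pset), file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(pset@domains, file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  p <- presence(sim$truth@presence)
  utils::write.table(data.frame(gene = rownames(p), p, check.names = FALSE),
                     file.path(dir, "truth_presence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth@pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    lines <- c(
      paste0("n_archaeal_divisions: ", config@nArchaealDivisions),
      paste0("n_bacterial_divisions: ", config@nBacterialDivisions),
      paste0("genomes_per_division: ", config@genomesPerDivision),
      paste0("n_families: ", config@nFamilies),
      paste0("retention: ", if (is.matrix(config@retention)) "matrix"
             else config@retention),
      paste0("seq_length: ", config@seqLength),
      paste0("divergence: ", config@divergence),
      paste0("decoys_per_genome: ", config@decoysPerGenome),
      paste0("seed: ", config@seed))
    writeLines(lines, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
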
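#' Construct a ProteomeSet
#'
#' @param proteins named list of \code{AAStringSet} objects, one per genome.
#' @param taxonomy data.frame with columns \code{genome_id}, \code{division}.
#' @param domains data.frame with columns \code{division}, \code{domain}
#'   (\code{"archaeal"} or \code{"bacterial"}); optional.
#' @param nucleotides optional named list of \code{DNAStringSet} coding
#'   sequences matching the proteins.
#' @return a \linkS4class{ProteomeSet}.
#' @export
proteomeSet <- function(proteins, taxonomy,
                        domains = data.frame(division = character(),
                                             domain = character()),
                        nucleotides = list()) {
  new("ProteomeSet", proteins = proteins, nucleotides = nucleotides,
      taxonomy = taxonomy, domains = domains)
}

#' Read per-genome proteomes from a directory of FASTA files
#'
#' Each \code{.faa} file is one genome; the genome id is the file stem and
#' protein ids are FASTA ids up to the first whitespace.
#'
#' @param dir directory of multi-FASTA protein files.
#' @param taxonomyPath 2-column TSV (genome_id, division).
#' @param domainsPath 2-column TSV (division, domain); optional.
#' @return a \linkS4class{ProteomeSet}.
#' @export
readProteomes <- function(dir, taxonomyPath, domainsPath = NULL) {
  files <- sort(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
  if (!length(files)) stop("no .faa files found in ", dir)
  proteins <- lapply(files, function(f) {
    s <- Biostrings::readAAStringSet(f)
    names(s) <- sub("\\s.*$", "", names(s))
    s
  })
  names(proteins) <- sub("\\.faa$", "", basename(files))
  taxonomy <- utils::read.delim(taxonomyPath, header = FALSE,
                                col.names = c("genome_id", "division"),
                                stringsAsFactors = FALSE)
  domains <- if (is.null(domainsPath))
    data.frame(division = character(), domain = character())
  else utils::read.delim(domainsPath, header = FALSE,
                         col.names = c("division", "domain"),
                         stringsAsFactors = FALSE)
  proteomeSet(proteins, taxonomy, domains)
}

#' Best hit of a query in one proteome
#'
#' Scores the query against every subject with the exact Smith-Waterman
#' aligner and returns the highest-raw-score subject passing the E-value
#' and query-coverage thresholds, or \code{NULL} when none passes. Ranking
#' is by raw score (E-values are monotone in the score at fixed lengths);
#' ties break by smaller E-value, then lexicographic subject id.
#'
#' @param query named character of length 1 (or an \code{AAString} with
#'   \code{queryId} given): the query protein.
#' @param proteome an \code{AAStringSet} of candidate subjects.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param maxEvalue,minCoverage acceptance thresholds.
#' @param queryId,genomeId identifiers recorded on the hit.
#' @return one-row data.frame (query, subject, genome, score, evalue,
#'   coverage) or \code{NULL}.
#' @export
bestHit <- function(query, proteome, scheme = scoringScheme(),
                    maxEvalue = 1e-6, minCoverage = 0.6,
                    queryId = NULL, genomeId = NA_character_) {
  if (!length(proteome)) stop("proteome must be non-empty")
  qs <- .as_seq_string(query)
  if (is.null(queryId))
    queryId <- if (!is.null(names(query))) names(query)[1] else "query"
  hits <- scanProteome(qs, queryId, proteome, genomeId, scheme,
                       maxEvalue, minCoverage)
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(-hits$score, hits$evalue, hits$subject,
                     method = "radix"), , drop = FALSE]
  hits[1, , drop = FALSE]
}

# score one query against every subject of one proteome; returns passing hits
scanProteome <- function(qs, queryId, proteome, genomeId, scheme,
                         maxEvalue, minCoverage) {
  m <- nchar(qs)
  qenc <- encodeSeq(qs, scheme)
  rows <- lapply(seq_along(proteome), function(i) {
    senc <- encodeSeq(as.character(proteome[[i]]), scheme)
    res <- .gotoh_local(qenc, senc, scheme@matrix,
                        scheme@gapOpen, scheme@gapExtend)
    cov <- if (res$q_end > 0) (res$q_end - res$q_start + 1) / m else 0
    e <- evalue(res$score, m, scheme)
    if (e <= maxEvalue && cov >= minCoverage)
      data.frame(query = queryId, subject = names(proteome)[i],
                 genome = genomeId, score = res$score, evalue = e,
                 coverage = cov, stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    data.frame(query = character(), subject = character(),
               genome = character(), score = numeric(), evalue = numeric(),
               coverage = numeric(), stringsAsFactors = FALSE)
  else out
}

#' Scan all proteomes for homologs of a seed protein
#'
#' Returns every subject in every genome passing the (permissive) homolog
#' thresholds, not only the best per genome, sorted by E-value. The
#' defaults (E <= 1e-3, coverage >= 60%) are the survey thresholds used to
#' chart where a protein family occurs at all.
#'
#' @param seed named character of length 1: the seed protein sequence.
#' @param pset a \linkS4class{ProteomeSet}.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param maxEvalue,minCoverage thresholds.
#' @return data.frame of hits (query, subject, genome, score, evalue,
#'   coverage).
#' @export
homologScan <- function(seed, pset, scheme = scoringScheme(),
                        maxEvalue = 1e-3, minCoverage = 0.6) {
  qs <- .as_seq_string(seed)
  queryId <- if (!is.null(names(seed))) names(seed)[1] else "seed"
  all <- lapply(names(proteomes(pset)), function(g) {
    prot <- proteomes(pset)[[g]]
    if (!length(prot)) return(NULL)
    scanProteome(qs, queryId, prot, g, scheme, maxEvalue, minCoverage)
  })
  out <- do.call(rbind, all)
  if (is.null(out) || !nrow(out))
    return(data.frame(query = character(), subject = character(),
                      genome = character(), score = numeric(),
                      evalue = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$evalue, out$genome, out$subject,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bidirectional-best-hit ortholog assignment for one seed in one genome
#'
#' Finds the best hit of the seed in the target genome (forward search),
#' then the best hit of that protein back in the reference proteome
#' (reverse search). The assignment is present iff the reverse best hit is
#' the seed itself. Both directions enforce the E-value and coverage
#' thresholds; coverage is computed on the query of each direction.
#'
#' @param seedId protein id of the seed within the reference proteome.
#' @param targetGenomeId genome searched for the ortholog.
#' @param pset a \linkS4class{ProteomeSet} containing the target genome.
#' @param referenceProteome \code{AAStringSet} the seed belongs to.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @param maxEvalue,minCoverage thresholds applied in both directions
#'   (defaults E <= 1e-6, coverage >= 60%).
#' @return one-row data.frame (seed_gene, genome_id, subject_id,
#'   forward_evalue, reverse_evalue, present); subject_id is NA when no
#'   reciprocal pair exists.
#' @export
bdbh <- function(seedId, targetGenomeId, pset, referenceProteome,
                 scheme = scoringScheme(), maxEvalue = 1e-6,
                 minCoverage = 0.6) {
  if (!seedId %in% names(referenceProteome))
    stop("seed '", seedId, "' not found in the reference proteome")
  target <- proteomes(pset)[[targetGenomeId]]
  if (is.null(target)) stop("unknown target genome: ", targetGenomeId)
  absent <- data.frame(seed_gene = seedId, genome_id = targetGenomeId,
                       subject_id = NA_character_, forward_evalue = NA_real_,
                       reverse_evalue = NA_real_, present = FALSE,
                       stringsAsFactors = FALSE)
  if (!length(target)) return(absent)
  seed_seq <- as.character(referenceProteome[[seedId]])
  fwd <- bestHit(seed_seq, target, scheme, maxEvalue, minCoverage,
                 queryId = seedId, genomeId = targetGenomeId)
  if (is.null(fwd)) return(absent)
  cand_seq <- as.character(target[[fwd$subject]])
  rev <- bestHit(cand_seq, referenceProteome, scheme, maxEvalue, minCoverage,
                 queryId = fwd$subject)
  if (is.null(rev) || rev$subject != seedId) return(absent)
  data.frame(seed_gene = seedId, genome_id = targetGenomeId,
             subject_id = fwd$subject, forward_evalue = fwd$evalue,
             reverse_evalue = rev$evalue, present = TRUE,
             stringsAsFactors = FALSE)
}

#' BDBH assignments for many seeds across all genomes
#'
#' Runs \code{\link{bdbh}} for every (seed, genome) combination.
#'
#' @param seedIds protein ids within the reference proteome.
#' @param pset a \linkS4class{ProteomeSet}.
#' @param referenceProteome \code{AAStringSet} containing the seeds.
#' @param scheme,maxEvalue,minCoverage as in \code{\link{bdbh}}.
#' @param genomeIds genomes to search (default: all in \code{pset}).
#' @return data.frame of assignments, one row per (seed, genome).
#' @export
bdbhAll <- function(seedIds, pset, referenceProteome,
                    scheme = scoringScheme(), maxEvalue = 1e-6,
                    minCoverage = 0.6, genomeIds = names(proteomes(pset))) {
  rows <- lapply(seedIds, function(s)
    do.call(rbind, lapply(genomeIds, function(g)
      bdbh(s, g, pset, referenceProteome, scheme, maxEvalue, minCoverage))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the gene-by-genome presence/absence matrix
#'
#' @param assignments data.frame as returned by \code{\link{bdbhAll}}.
#' @param genes,genomes row and column orders.
#' @return a \linkS4class{PresenceAbsenceMatrix}; cell TRUE iff an
#'   assignment with a subject exists.
#' @export
presenceMatrix <- function(assignments,
                           genes = unique(assignments$seed_gene),
                           genomes = unique(assignments$genome_id)) {
  m <- matrix(FALSE, length(genes), length(genomes),
              dimnames = list(genes, genomes))
  pres <- assignments[assignments$present, , drop = FALSE]
  if (nrow(pres)) {
    key <- paste(pres$seed_gene, pres$genome_id)
    conflict <- tapply(pres$subject_id, key,
                       function(s) length(unique(s)) > 1)
    if (any(conflict))
      stop("conflicting subjects for (gene, genome) pair(s): ",
           paste(names(conflict)[conflict], collapse = ", "))
    pres <- pres[!duplicated(key), , drop = FALSE]
    unknown <- !(pres$seed_gene %in% genes) | !(pres$genome_id %in% genomes)
    if (any(unknown))
      stop("assignment references unknown gene/genome: ",
           paste(paste(pres$seed_gene, pres$genome_id)[unknown],
                 collapse = ", "))
    m[cbind(pres$seed_gene, pres$genome_id)] <- TRUE
  }
  new("PresenceAbsenceMatrix", presence = m)
}

#' Drop genomes with exactly duplicated protein sets
#'
#' Synthetic stand-in for similarity-based genome de-duplication: removes
#' any genome whose multiset of protein sequences is identical to that of
#' an earlier (alphabetically first) genome. Real panels would use a
#' genome-similarity score; this filter only removes exact duplicates.
#'
#' @param pset a \linkS4class{ProteomeSet}.
#' @return the filtered \linkS4class{ProteomeSet}, with the removed genome
#'   ids in the \code{"removed"} attribute.
#' @export
dedupeGenomes <- function(pset) {
  ids <- sort(names(proteomes(pset)))
  sig <- vapply(ids, function(g)
    paste(sort(as.character(proteomes(pset)[[g]])), collapse = "|"), "")
  keep <- ids[!duplicated(sig)]
  removed <- setdiff(ids, keep)
  out <- proteomeSet(proteomes(pset)[keep],
                     taxonomyMap(pset)[taxonomyMap(pset)$genome_id %in% keep, ,
                                       drop = FALSE],
                     pset@domains,
                     pset@nucleotides[intersect(names(pset@nucleotides), keep)])
  attr(out, "removed") <- removed
  out
}

#' Write a hits table as TSV
#'
#' @param hits data.frame from \code{\link{homologScan}} or
#'   \code{\link{bestHit}}.
#' @param path output file.
#' @export
exportHitsTable <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
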
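#' Load a curated regulon table
#'
#' Reads a tab-separated regulon table (one row per regulated gene, with
#' locus tag, transcription units, co-regulating TFs with signs, the sign
#' of the master-regulator effect, evidence codes, references and GO
#' terms) and builds a validated \linkS4class{RegulonNetwork}. Lines
#' starting with \code{#} are curation comments and are skipped.
#' Multi-valued cells use \code{";"} separators; co-regulators are written
#' \code{Name(+)}, \code{Name(-)} or \code{Name(+/-)}; a hyphenated complex
#' name such as \code{GadE-RcsB} is a single regulator entity.
#'
#' Duplicate locus tags across rows are permitted (distinct genes can share
#' a bnumber in the source table) but are flagged with a warning and in the
#' \code{dup_bnumber} column.
#'
#' @param path path to the table. The packaged compendium of the 86
#'   Crl-controlled genes of \emph{E. coli} K-12 is at
#'   \code{system.file("extdata", "crl_regulon.tsv", package = "regulonTracer")}.
#' @param regulator name of the master regulator (default \code{"Crl"}).
#' @return a \linkS4class{RegulonNetwork}.
#' @examples
#' net <- loadRegulonTable(system.file("extdata", "crl_regulon.tsv",
#'                                     package = "regulonTracer"))
#' net
#' @export
loadRegulonTable <- function(path, regulator = "Crl") {
  if (!file.exists(path)) stop("regulon table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("regulon table is empty (no header)")
  required <- c("gene", "bnumber", "tus", "co_regulators", "crl_effect",
                "evidence", "references", "go_terms")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing))
    stop("regulon table schema error: missing required column(s) ",
         paste(missing, collapse = ", "))

  splitMulti <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) character() else
      trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  }

  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(f) <- length(header)            # pad short rows (empty trailing cells)
    stats::setNames(as.list(f), header)
  })

  genes <- data.frame(gene = character(), bnumber = character(),
                      stringsAsFactors = FALSE)
  gene_tus <- list(); gene_go <- list()
  edges <- list()

  for (i in seq_along(rows)) {
    r <- rows[[i]]
    gene <- trimws(r$gene)
    if (!nzchar(gene)) stop("row ", i, ": empty gene name")
    eff <- trimws(r$crl_effect)
    if (is.na(eff) || !eff %in% c("+", "-", "+/-"))
      stop("row ", i, ": unknown effect symbol '", eff, "'")
    tus <- splitMulti(r$tus)
    if (!length(tus)) stop("row ", i, ": gene must belong to >= 1 TU")
    ev <- splitMulti(r$evidence)
    unknown_ev <- setdiff(ev, c("APPH", "GEA", "MSI", "IMP"))
    if (length(unknown_ev))
      stop("row ", i, ": unknown evidence code(s) ",
           paste(unknown_ev, collapse = ", "))
    refs <- splitMulti(r$references)
    genes <- rbind(genes, data.frame(gene = gene, bnumber = trimws(r$bnumber),
                                     stringsAsFactors = FALSE))
    gene_tus[[gene]] <- tus
    gene_go[[gene]] <- splitMulti(r$go_terms)
    edges[[length(edges) + 1L]] <-
      list(regulator = regulator, target = gene, effect = eff,
           evidence = ev, references = refs)
    for (co in splitMulti(r$co_regulators)) {
      m <- regmatches(co, regexec("^(.*)\\(([+-]|\\+/?-)\\)$", co))[[1]]
      if (length(m) != 3)
        stop("row ", i, ": cannot parse co-regulator '", co, "'")
      sign <- if (m[3] %in% c("+-", "+/-")) "+/-" else m[3]
      edges[[length(edges) + 1L]] <-
        list(regulator = trimws(m[2]), target = gene, effect = sign,
             evidence = character(), references = character())
    }
  }

  bad <- grep("^b\\d{4}$", genes$bnumber, invert = TRUE)
  if (length(bad))
    warning("bnumber(s) not matching b\\d{4}: ",
            paste(genes$bnumber[bad], collapse = ", "))
  dup <- duplicated(genes$bnumber) | duplicated(genes$bnumber, fromLast = TRUE)
  if (any(dup))
    warning("duplicate bnumber(s) across rows: ",
            paste(unique(genes$bnumber[dup]), collapse = ", "))
  genes$tus <- unname(gene_tus[genes$gene])
  genes$go_terms <- unname(gene_go[genes$gene])
  genes$dup_bnumber <- dup

  tu_names <- unique(unlist(genes$tus))
  tu_genes <- lapply(tu_names, parseTuName)
  tu_context <- lapply(tu_genes, function(g) setdiff(g, genes$gene))
  tus <- data.frame(name = tu_names, stringsAsFactors = FALSE)
  tus$genes <- tu_genes
  tus$context <- tu_context

  edges_df <- data.frame(
    regulator = vapply(edges, `[[`, "", "regulator"),
    target = vapply(edges, `[[`, "", "target"),
    effect = vapply(edges, `[[`, "", "effect"),
    stringsAsFactors = FALSE)
  edges_df$evidence <- lapply(edges, `[[`, "evidence")
  edges_df$references <- lapply(edges, `[[`, "references")

  new("RegulonNetwork", genes = genes, tus = tus, edges = edges_df,
      regulator = regulator)
}

#' Expand an operon-style transcription-unit name into its gene list
#'
#' TU names follow E. coli operon nomenclature: hyphen-separated segments,
#' each a lowercase gene stem followed by zero or more uppercase suffix
#' letters, one gene per suffix (\code{csgBAC} -> csgB, csgA, csgC;
#' \code{fliAZ-tcyJ} -> fliA, fliZ, tcyJ). A segment without uppercase
#' letters is a single gene.
#'
#' @param name TU name string.
#' @return character vector of member genes, in operon order.
#' @export
parseTuName <- function(name) {
  segs <- strsplit(name, "-", fixed = TRUE)[[1]]
  out <- character()
  for (s in segs) {
    stem <- sub("([A-Z].*)?$", "", s)
    caps <- substring(s, nchar(stem) + 1L)
    if (!nzchar(caps)) {
      out <- c(out, s)
    } else if (nchar(caps) == 1L) {
      out <- c(out, s)                       # e.g. alkB: stem + single suffix
    } else {
      out <- c(out, paste0(stem, strsplit(caps, "")[[1]]))
    }
  }
  if (anyDuplicated(out))
    stop("TU '", name, "' expands to a duplicated gene list")
  out
}

#' Tally the master-regulator effect signs over distinct loci
#'
#' Counts the genes activated (+), repressed (-) or dually controlled
#' (+/-) by the master regulator. Genes are deduplicated by locus tag
#' (bnumber), so two table rows sharing a bnumber count once; rows sharing
#' a locus tag with conflicting signs count once per sign.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @return named integer vector with elements \code{"+"}, \code{"-"} and
#'   \code{"+/-"}.
#' @export
effectSignTally <- function(net) {
  e <- regulonEdges(net)
  crl <- e[e$regulator == masterRegulator(net), , drop = FALSE]
  bn <- regulonGenes(net)$bnumber[match(crl$target, regulonGenes(net)$gene)]
  u <- !duplicated(paste(bn, crl$effect))
  tab <- table(factor(crl$effect[u], levels = c("+", "-", "+/-")))
  stats::setNames(as.integer(tab), names(tab))
}

masterRegulator <- function(net) net@regulator

#' Partition genes by exclusive versus shared control
#'
#' Splits the gene set into genes controlled only by the master regulator
#' and genes that additionally carry at least one co-regulator edge. The
#' two sets are disjoint and jointly cover all genes.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @return list with character vectors \code{crl_only} and
#'   \code{co_regulated}.
#' @export
exclusiveGenePartition <- function(net) {
  g <- regulonGenes(net)$gene
  e <- regulonEdges(net)
  co <- unique(e$target[e$regulator != masterRegulator(net)])
  list(crl_only = setdiff(g, co), co_regulated = intersect(g, co))
}

#' Histogram of co-regulator counts per gene
#'
#' For each co-regulated gene, counts the number of distinct non-master
#' regulator names on its edges (a named complex such as \code{GadE-RcsB}
#' is one regulator; a regulator appearing with two signs still counts
#' once) and tabulates genes by that count.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @return named integer vector, names are regulator counts k >= 1.
#' @export
tfDegreeHistogram <- function(net) {
  e <- regulonEdges(net)
  co <- e[e$regulator != masterRegulator(net), , drop = FALSE]
  if (!nrow(co)) return(stats::setNames(integer(), character()))
  k <- vapply(split(co$regulator, co$target), function(r) length(unique(r)), 1L)
  tab <- table(k)
  stats::setNames(as.integer(tab), names(tab))
}

#' Transcription-unit summary
#'
#' Number of distinct transcription units and the percentage (rounded to
#' the nearest integer) that contain exactly one gene. TU gene content is
#' the full operon complement expanded from the TU name, not only the
#' regulon members.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @return list with \code{n_tus} and \code{pct_monogenic}.
#' @export
tuSummary <- function(net) {
  tus <- regulonTUs(net)
  sizes <- lengths(tus$genes)
  list(n_tus = nrow(tus),
       pct_monogenic = if (nrow(tus)) round(100 * mean(sizes == 1)) else NA_real_)
}

#' Export the network as a tab-separated edge list
#'
#' Writes a 3-column (regulator, target, sign) TSV readable by standard
#' graph viewers, in deterministic lexicographic row order.
#'
#' @param net a \linkS4class{RegulonNetwork}.
#' @param path output file.
#' @param header write a header row (default FALSE).
#' @return the path, invisibly.
#' @export
exportEdgeList <- function(net, path, header = FALSE) {
  e <- regulonEdges(net)[, c("regulator", "target", "effect")]
  e <- e[order(e$regulator, e$target, e$effect, method = "radix"), , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(err)
    stop("cannot write edge list to '", path, "': ", conditionMessage(err)))
  on.exit(close(con))
  if (header) writeLines("regulator\ttarget\tsign", con)
  if (nrow(e))
    writeLines(paste(e$regulator, e$target, e$effect, sep = "\t"), con)
  invisible(path)
}

#' Hypergeometric enrichment of functional categories
#'
#' One-sided (upper tail) hypergeometric test for over-representation of
#' each category among a query gene set drawn from a background: with
#' \eqn{k} query hits, \eqn{K} background hits, query size \eqn{n} and
#' background size \eqn{N}, the p-value is \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}. Benjamini-Hochberg adjusted
#' values are included. Genes without any category are tallied in the
#' \code{n_uncategorized} attribute.
#'
#' @param query character vector of query genes (must be a subset of
#'   \code{background}).
#' @param background character vector of background genes.
#' @param categories named list mapping each gene to a character vector of
#'   its categories.
#' @return data.frame with columns \code{category}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_adj}, sorted by p.
#' @examples
#' cats <- list(g1 = "A", g2 = "A", g3 = "B", g4 = c("A", "B"))
#' enrichmentTest(c("g1", "g2"), c("g1", "g2", "g3", "g4"), cats)
#' @export
enrichmentTest <- function(query, background, categories) {
  offenders <- setdiff(query, background)
  if (length(offenders))
    stop("query gene(s) absent from background: ",
         paste(offenders, collapse = ", "))
  background <- unique(background)
  query <- unique(query)
  N <- length(background); n <- length(query)
  catlist <- categories[intersect(names(categories), background)]
  all_cats <- sort(unique(unlist(catlist)))
  n_uncat <- sum(!background %in% names(catlist)[lengths(catlist) > 0])
  res <- lapply(all_cats, function(cc) {
    members <- names(catlist)[vapply(catlist, function(v) cc %in% v, TRUE)]
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cc, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  else {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out <- out[order(out$p, out$category), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_uncategorized") <- n_uncat
  out
}
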
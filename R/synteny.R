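# orthology by reciprocal best hits (local protein alignment scoring)
# and gene-order (synteny) support

#' Validate a gene-order table
#'
#' A gene-order table records the marker genes around a locus: one row per
#' gene per species with its genomic unit (chromosome or scaffold), 1-based
#' ordinal position within the unit and strand.
#'
#' @param df data.frame with columns `species`, `unit`, `gene`, `position`,
#'   `strand` (a missing `unit` column defaults to one unit, a missing
#'   `strand` to `+`).
#' @return The validated data.frame.
#' @export
geneOrderTable <- function(df) {
  if (!"unit" %in% names(df)) df$unit <- "locus_1"
  if (!"strand" %in% names(df)) df$strand <- "+"
  need <- c("species", "unit", "gene", "position", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene-order table lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need, drop = FALSE]
  key <- split(df, df$species)
  for (sp in names(key)) {
    sub <- key[[sp]]
    if (anyDuplicated(paste(sub$unit, sub$position)))
      stop(sprintf("duplicate ordinal position within species '%s'", sp))
    if (anyDuplicated(paste(sub$unit, sub$gene)))
      stop(sprintf("duplicate gene within species '%s'", sp))
  }
  df
}

#' Read a gene-order TSV
#'
#' @param path TSV with columns `species`, `unit`, `gene`, `position`,
#'   `strand`.
#' @return Validated gene-order data.frame.
#' @export
readGeneOrders <- function(path) {
  geneOrderTable(read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

# local protein alignment score (BLAST-like scoring of candidate hits)
.proteinScore <- function(a, b, gapOpening = 11, gapExtension = 1,
                          matrixName = "BLOSUM62") {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(as.character(a)),
    subject = Biostrings::AAString(as.character(b)),
    type = "local", substitutionMatrix = .substMatrix(matrixName),
    gapOpening = gapOpening, gapExtension = gapExtension,
    scoreOnly = TRUE)
}

#' Best hit of every query protein in a target set
#'
#' Scores every query/target pair by local affine-gap protein alignment
#' (BLOSUM62, gap open 11 / extend 1 — local scoring because homologs of
#' very different length should still pair through their shared region)
#' and reports the best-scoring target per query, ties broken by
#' lexicographic target id.
#'
#' @param query,target named [Biostrings::AAStringSet] (or named character
#'   vectors) of proteins.
#' @param gapOpening,gapExtension,matrixName scoring parameters.
#' @return data.frame `query`, `target`, `score` with the full score
#'   matrix in attribute `scores` (queries in rows).
#' @export
bestHits <- function(query, target, gapOpening = 11, gapExtension = 1,
                     matrixName = "BLOSUM62") {
  query <- Biostrings::AAStringSet(query)
  target <- Biostrings::AAStringSet(target)
  if (!length(query) || !length(target)) stop("empty protein set")
  if (is.null(names(query)) || is.null(names(target)))
    stop("protein sets must be named")
  scores <- matrix(NA_real_, length(query), length(target),
                   dimnames = list(names(query), names(target)))
  for (i in seq_along(query)) {
    scores[i, ] <- vapply(seq_along(target), function(j)
      .proteinScore(query[[i]], target[[j]], gapOpening, gapExtension,
                    matrixName), numeric(1))
  }
  ord <- order(colnames(scores))  # lexicographic tie-break
  bestIdx <- apply(scores[, ord, drop = FALSE], 1L, which.max)
  out <- data.frame(query = rownames(scores),
                    target = colnames(scores)[ord][bestIdx],
                    score = scores[cbind(seq_len(nrow(scores)),
                                         ord[bestIdx])],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scores") <- scores
  out
}

#' Reciprocal best hits
#'
#' A pair (a, b) is a reciprocal best hit (RBH) — the standard orthology
#' criterion — when b is a's best hit and a is b's best hit.
#'
#' @param bhAB best hits of set A against set B ([bestHits()]).
#' @param bhBA best hits of set B against set A, computed with the same
#'   scoring.
#' @return data.frame `geneA`, `geneB`, `forwardScore`, `reverseScore`,
#'   `isRbh`.
#' @export
reciprocalBestHits <- function(bhAB, bhBA) {
  back <- setNames(bhBA$target, bhBA$query)
  revScore <- setNames(bhBA$score, bhBA$query)
  out <- data.frame(
    geneA = bhAB$query,
    geneB = bhAB$target,
    forwardScore = bhAB$score,
    reverseScore = unname(revScore[bhAB$target]),
    isRbh = unname(back[bhAB$target] == bhAB$query),
    stringsAsFactors = FALSE)
  out$isRbh[is.na(out$isRbh)] <- FALSE
  out
}

#' Gene-order (synteny) support for a focal gene pair
#'
#' Counts the genes within `k` positions of the focal gene in species A
#' whose ortholog lies within `k` positions of the focal gene's partner in
#' species B. Only genes on the focal gene's genomic unit contribute (a
#' gene on an unplaced scaffold cannot support synteny). Strand is ignored
#' for counting and reported in the details attribute.
#'
#' @param tableA,tableB gene-order data.frames ([geneOrderTable()]).
#' @param focalA focal gene in A.
#' @param focalB focal gene in B (defaults to the same name).
#' @param k window half-width in gene positions.
#' @param orthologs optional data.frame `geneA`, `geneB` mapping genes of A
#'   to genes of B (e.g. RBH pairs from [reciprocalBestHits()]); by default
#'   genes pair by name.
#' @return Integer support count (at most `2 * k`), with a data.frame of
#'   the supporting gene pairs (and strands) in attribute `details`.
#' @export
syntenySupport <- function(tableA, tableB, focalA, focalB = focalA, k = 2L,
                           orthologs = NULL) {
  tableA <- geneOrderTable(tableA)
  tableB <- geneOrderTable(tableB)
  rowA <- tableA[tableA$gene == focalA, , drop = FALSE]
  rowB <- tableB[tableB$gene == focalB, , drop = FALSE]
  if (nrow(rowA) != 1L)
    stop(sprintf("focal gene '%s' absent (or duplicated) in table A", focalA))
  if (nrow(rowB) != 1L)
    stop(sprintf("focal gene '%s' absent (or duplicated) in table B", focalB))
  mapAB <- if (is.null(orthologs)) NULL else
    setNames(orthologs$geneB, orthologs$geneA)

  neighA <- tableA[tableA$unit == rowA$unit & tableA$gene != focalA &
                     abs(tableA$position - rowA$position) <= k, ,
                   drop = FALSE]
  unitB <- tableB[tableB$unit == rowB$unit, , drop = FALSE]
  details <- list()
  for (i in seq_len(nrow(neighA))) {
    gA <- neighA$gene[i]
    gB <- if (is.null(mapAB)) gA else unname(mapAB[gA])
    if (is.na(gB) || is.null(gB)) next
    hit <- unitB[unitB$gene == gB &
                   abs(unitB$position - rowB$position) <= k, , drop = FALSE]
    if (nrow(hit) == 1L) {
      details[[length(details) + 1L]] <- data.frame(
        geneA = gA, geneB = gB,
        strandA = neighA$strand[i], strandB = hit$strand,
        stringsAsFactors = FALSE)
    }
  }
  details <- if (length(details)) do.call(rbind, details) else
    data.frame(geneA = character(), geneB = character(),
               strandA = character(), strandB = character(),
               stringsAsFactors = FALSE)
  support <- nrow(details)
  attr(support, "details") <- details
  support
}
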
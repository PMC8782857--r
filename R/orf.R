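# theoretical-protein prediction: translate a locus from the conserved
# start codon to the first in-frame stop codon

#' Translate a nucleotide sequence
#'
#' Standard genetic code, frame 1; trailing 1-2 nucleotides are ignored.
#' Stop codons are rendered as `*`. Codons containing ambiguity symbols are
#' translated to the unique residue they encode when all resolutions agree,
#' and to `X` otherwise (an ambiguous codon is never rendered as a stop).
#'
#' @param cds nucleotide sequence ([Biostrings::DNAString] or string) over
#'   the IUPAC alphabet; at least one complete codon.
#' @return Amino-acid string (may contain `*` and `X`).
#' @export
#' @examples
#' translateCds("ATGTAA")    # "M*"
#' translateCds("ATGGCCAAT") # "MAN"
translateCds <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) == 0L) stop("empty input sequence")
  .checkAlphabet(s, .IUPAC_DNA, what = "nucleotide sequence")
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "solve"))
}

#' Predict the theoretical protein from a locus
#'
#' Translates from the ATG at `startOffset` until the first in-frame stop
#' codon (literal TAA/TAG/TGA only; codons containing N never terminate the
#' scan, so sequencing ambiguity cannot create a false truncation). Returns
#' the residues strictly before the stop.
#'
#' @param locus nucleotide sequence ([Biostrings::DNAString] or string).
#' @param startOffset 0-based offset of the start codon; must be an ATG.
#' @param species,gene identifiers carried into the result.
#' @param nonOrthologousStart logical flag carried into the result (set by
#'   [locateConservedStart()]).
#' @return A [CodingPrediction-class].
#' @export
#' @examples
#' p <- predictTheoreticalProtein("ATGGCCGCCTAAGG", 0L)
#' lengthAa(p)  # 3
predictTheoreticalProtein <- function(locus, startOffset, species = "query",
                                      gene = "gene",
                                      nonOrthologousStart = FALSE) {
  s <- toupper(as.character(locus))
  startOffset <- as.integer(startOffset)
  if (startOffset < 0L || startOffset + 3L > nchar(s))
    stop("startOffset out of range")
  if (substr(s, startOffset + 1L, startOffset + 3L) != "ATG")
    stop(sprintf("no ATG at offset %d", startOffset))
  frame <- substr(s, startOffset + 1L, nchar(s))
  ncod <- nchar(frame) %/% 3L
  starts <- (seq_len(ncod) - 1L) * 3L + 1L
  codons <- substring(frame, starts, starts + 2L)
  stopIdx <- which(codons %in% .STOP_CODONS)
  if (length(stopIdx)) {
    k <- stopIdx[1]
    lengthAa <- k - 1L
    stopFound <- TRUE
    stopOffset <- startOffset + 3L * lengthAa
    coding <- codons[seq_len(lengthAa)]
  } else {
    lengthAa <- ncod
    stopFound <- FALSE
    stopOffset <- NA_integer_
    coding <- codons
  }
  protein <- if (lengthAa > 0L)
    translateCds(paste(coding, collapse = "")) else ""
  new("CodingPrediction",
      species = species, gene = gene,
      startOffset = startOffset, protein = protein,
      lengthAa = lengthAa, stopFound = stopFound,
      stopOffset = stopOffset,
      nonOrthologousStart = nonOrthologousStart)
}

#' Locate the conserved start codon in a locus
#'
#' Anchors the locus to the reference by aligning the reference's first 90
#' nucleotides against the locus (the reference 5' region globally, the
#' locus locally) and takes the ATG at the anchored reference-start
#' position, or the nearest ATG 3' of it within 30 nt. When neither exists
#' the nearest ATG 3' of the anchor anywhere in the locus (falling back to
#' the nearest 5' ATG) is used and flagged as a non-orthologous start. Ties
#' resolve to the 5'-most candidate.
#'
#' @param locus nucleotide sequence containing the candidate gene.
#' @param referenceCds intact reference CDS (must begin with ATG).
#' @param anchorWidth how much reference 5' sequence to anchor with.
#' @param slack how far 3' of the anchor an ATG still counts as the
#'   conserved start.
#' @return list with `startOffset` (0-based), `anchorOffset` and
#'   `nonOrthologousStart`.
#' @export
locateConservedStart <- function(locus, referenceCds, anchorWidth = 90L,
                                 slack = 30L) {
  loc <- Biostrings::DNAString(toupper(as.character(locus)))
  ref <- toupper(as.character(referenceCds))
  if (substr(ref, 1, 3) != "ATG") stop("reference CDS must begin with ATG")
  head5 <- Biostrings::DNAString(substr(ref, 1L, min(anchorWidth, nchar(ref))))
  aln <- Biostrings::pairwiseAlignment(
    pattern = head5, subject = loc, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 5, mismatch = -4, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 0.5)
  anchor <- BiocGenerics::start(Biostrings::subject(aln)) - 1L  # 0-based
  hits <- Biostrings::matchPattern("ATG", loc)
  atg <- BiocGenerics::start(hits) - 1L
  if (!length(atg)) stop("no ATG found in locus")
  if (anchor %in% atg)
    return(list(startOffset = anchor, anchorOffset = anchor,
                nonOrthologousStart = FALSE))
  down <- atg[atg > anchor]
  near <- down[down - anchor <= slack]
  if (length(near))
    return(list(startOffset = near[1], anchorOffset = anchor,
                nonOrthologousStart = FALSE))
  chosen <- if (length(down)) down[1] else atg[length(atg)]
  list(startOffset = chosen, anchorOffset = anchor,
       nonOrthologousStart = TRUE)
}

#' Scan loci for theoretical proteins
#'
#' Runs [locateConservedStart()] and [predictTheoreticalProtein()] on every
#' locus of a set and tabulates the predictions (the table written by the
#' pipeline's ORF-scan stage).
#'
#' @param loci named [Biostrings::DNAStringSet] (or named character
#'   vector) of genomic loci; names are taken as species.
#' @param referenceCds intact reference CDS.
#' @param gene gene identifier for the report.
#' @return list with `predictions` (list of [CodingPrediction-class]) and
#'   `table` (data.frame: species, gene, startOffset, lengthAa, stopOffset,
#'   stopFound, nonOrthologousStart).
#' @export
orfScan <- function(loci, referenceCds, gene = "gene") {
  loci <- Biostrings::DNAStringSet(loci)
  if (is.null(names(loci))) stop("loci must be named by species")
  preds <- lapply(names(loci), function(sp) {
    st <- locateConservedStart(loci[[sp]], referenceCds)
    predictTheoreticalProtein(loci[[sp]], st$startOffset, species = sp,
                              gene = gene,
                              nonOrthologousStart = st$nonOrthologousStart)
  })
  names(preds) <- names(loci)
  tab <- data.frame(
    species = names(loci),
    gene = gene,
    startOffset = vapply(preds, startOffset, integer(1)),
    lengthAa = vapply(preds, lengthAa, integer(1)),
    stopOffset = vapply(preds, stopOffset, integer(1)),
    stopFound = vapply(preds, stopFound, logical(1)),
    nonOrthologousStart = vapply(preds, function(p) p@nonOrthologousStart,
                                 logical(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(predictions = preds, table = tab)
}
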
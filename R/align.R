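# pairwise affine-gap alignment with deterministic, left-normalized gaps

# shift every gap run in `gapRow` as far left as possible without changing
# the induced sequences or the score; `baseRow` is the other row.
# Returns list(gapRow, baseRow) as character vectors.
.leftShiftGaps <- function(gapRow, baseRow) {
  n <- length(gapRow)
  i <- 1L
  while (i <= n) {
    if (gapRow[i] == .GAP) {
      a <- i
      b <- i
      while (b < n && gapRow[b + 1L] == .GAP) b <- b + 1L
      # slide the run [a, b] left while the flanking characters in the
      # ungapped row match (same induced sequences, same score)
      while (a > 1L && gapRow[a - 1L] != .GAP &&
             baseRow[a - 1L] == baseRow[b]) {
        gapRow[b] <- gapRow[a - 1L]
        gapRow[a - 1L] <- .GAP
        a <- a - 1L
        b <- b - 1L
      }
      i <- b + 1L
      # skip over any run we may have merged into
      while (i <= n && gapRow[i] == .GAP) i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  gapRow
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (or anchored global-local) alignment of two nucleotide
#' sequences under match/mismatch scoring with affine gap penalties
#' (a gap of length L costs `gapOpening + L * gapExtension`). Gap runs in
#' the returned alignment are left-shifted to their 5'-most equivalent
#' position so that indel coordinates are canonical (the convention used
#' for variant normalization).
#'
#' @param reference,query nucleotide sequences (strings or
#'   [Biostrings::DNAString]); at most 50,000 nt each.
#' @param match,mismatch match score and mismatch penalty.
#' @param gapOpening,gapExtension affine gap parameters.
#' @param type `"global"` (both sequences end to end) or `"global-local"`
#'   (reference end to end within a longer query, e.g. a locus with
#'   flanks).
#' @param refId,queryId identifiers stored in the result.
#' @return An [AffineAlignment-class].
#' @export
#' @examples
#' aln <- alignGlobal("ACGT", "AGT")
#' alignedQuery(aln)  # "A-GT"
alignGlobal <- function(reference, query, match = 5, mismatch = -4,
                        gapOpening = 10, gapExtension = 0.5,
                        type = c("global", "global-local"),
                        refId = "reference", queryId = "query") {
  type <- match.arg(type)
  r <- toupper(as.character(reference))
  q <- toupper(as.character(query))
  if (!nchar(r) || !nchar(q)) stop("sequences must be non-empty")
  if (nchar(r) > 50000L || nchar(q) > 50000L)
    stop("sequence exceeds the 50,000-nt cap; align an anchored subregion instead")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(r), subject = Biostrings::DNAString(q),
    type = type, substitutionMatrix = mat,
    gapOpening = gapOpening, gapExtension = gapExtension)
  ar <- .chars(Biostrings::alignedPattern(aln))
  aq <- .chars(Biostrings::alignedSubject(aln))
  # canonicalize gap placement row by row
  aq2 <- .leftShiftGaps(aq, ar)
  ar2 <- .leftShiftGaps(ar, aq2)
  new("AffineAlignment",
      refId = refId, queryId = queryId,
      alignedRef = paste(ar2, collapse = ""),
      alignedQuery = paste(aq2, collapse = ""),
      score = BiocGenerics::score(aln),
      params = list(match = match, mismatch = mismatch,
                    gapOpening = gapOpening, gapExtension = gapExtension,
                    type = type))
}
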
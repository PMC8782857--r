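# tandem repeat-domain detection by self-comparison dot plot
# (windowed un-normalized substitution-matrix score, Dotmatcher semantics)

# BLOSUM62 lazily loaded from Biostrings' data sets
.substMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Self-comparison dot plot of a protein
#'
#' Marks every position pair (i, j) whose substitution-matrix score summed
#' over a `window`-long stretch along the diagonal starting at (i, j)
#' reaches `threshold`, and merges marked windows that overlap by at least
#' one cell into maximal diagonal segments. With the defaults (window 10,
#' threshold 23, BLOSUM62) tandem repeat units appear as off-diagonal
#' lines whose offsets are multiples of the unit length.
#'
#' @param protein amino-acid sequence ([Biostrings::AAString] or string).
#' @param window window size in residues.
#' @param threshold un-normalized window score threshold.
#' @param matrixName substitution matrix to use (a Biostrings data set
#'   name, e.g. `"BLOSUM62"`).
#' @param seqId identifier stored in the result.
#' @return A [DotPlot-class]; segment coordinates are 0-based.
#' @export
#' @examples
#' dp <- selfDotplot(strrep("MEVLKQAHTDGRWS", 3))
#' matchSegments(dp)
selfDotplot <- function(protein, window = 10L, threshold = 23,
                        matrixName = "BLOSUM62", seqId = "protein") {
  s <- toupper(as.character(protein))
  n <- nchar(s)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window exceeds sequence length")
  mat <- .substMatrix(matrixName)
  ch <- .chars(s)
  idx <- match(ch, rownames(mat))
  if (anyNA(idx))
    stop(sprintf("residue '%s' not covered by matrix %s",
                 ch[which(is.na(idx))[1]], matrixName))

  segs <- list()
  for (d in 0:(n - window)) {
    m <- n - d                               # diagonal length in cells
    v <- mat[cbind(idx[seq_len(m)], idx[seq_len(m) + d])]
    if (m < window) next
    cs <- cumsum(v)
    wsum <- if (m == window) cs[window] else
      c(cs[window], cs[(window + 1L):m] - cs[1:(m - window)])
    marked <- which(wsum >= threshold)       # 1-based window starts
    if (!length(marked)) next
    brk <- which(diff(marked) > window - 1L)
    starts <- marked[c(1L, brk + 1L)]
    ends <- marked[c(brk, length(marked))]
    for (k in seq_along(starts)) {
      s1 <- starts[k] - 1L                   # 0-based
      len <- ends[k] - starts[k] + window
      segs[[length(segs) + 1L]] <-
        data.frame(start1 = s1, start2 = s1 + d, length = len)
      if (d > 0L)
        segs[[length(segs) + 1L]] <-
          data.frame(start1 = s1 + d, start2 = s1, length = len)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start1 = integer(), start2 = integer(), length = integer())
  segments <- segments[order(segments$start1, segments$start2), ,
                       drop = FALSE]
  rownames(segments) <- NULL
  new("DotPlot", seqId = seqId, seqLength = as.integer(n),
      window = window, threshold = as.numeric(threshold),
      matrixName = matrixName, segments = segments)
}

#' Estimate repeat unit length and copy number from a dot plot
#'
#' The repeat unit length is taken as the smallest off-diagonal offset
#' whose total supported segment length is at least half of the maximum
#' across offsets; the copy number is one plus the longest chain of
#' offsets at consecutive multiples of the unit length (with 10% jitter
#' tolerated, since diverged repeat units drift). A plot with no
#' off-diagonal segment is flagged as repeat-free (copy number 1, unit
#' length = sequence length).
#'
#' @param dp a [DotPlot-class] from [selfDotplot()].
#' @param minSupportFrac fraction of the maximal offset support required
#'   for an offset to be considered the unit length.
#' @param jitter relative tolerance when matching offsets to multiples of
#'   the unit length.
#' @return A [RepeatProfile-class].
#' @export
profileRepeats <- function(dp, minSupportFrac = 0.5, jitter = 0.1) {
  stopifnot(is(dp, "DotPlot"))
  seg <- dp@segments
  off <- seg[seg$start2 > seg$start1, , drop = FALSE]  # each pair once
  if (!nrow(off)) {
    return(new("RepeatProfile", seqId = dp@seqId,
               unitLengthAa = dp@seqLength, copyNumber = 1L,
               evidence = data.frame(offset = integer(),
                                     support = integer()),
               noRepeat = TRUE))
  }
  offset <- off$start2 - off$start1
  support <- tapply(off$length, offset, sum)
  evidence <- data.frame(offset = as.integer(names(support)),
                         support = as.integer(support))
  evidence <- evidence[order(evidence$offset), , drop = FALSE]
  rownames(evidence) <- NULL
  strong <- evidence$offset[evidence$support >=
                              minSupportFrac * max(evidence$support)]
  unit <- min(strong)
  # chain consecutive multiples of the unit; each offset supports its
  # nearest multiple only, with 10% jitter tolerated (diverged units drift)
  kcand <- round(evidence$offset / unit)
  okk <- kcand >= 1 & abs(evidence$offset - kcand * unit) <=
    pmax(1, jitter * kcand * unit)
  ks <- sort(unique(kcand[okk]))
  chain <- 0L
  if (length(ks)) {
    grp <- cumsum(c(TRUE, diff(ks) != 1L))
    chain <- max(tabulate(grp))
  }
  new("RepeatProfile", seqId = dp@seqId,
      unitLengthAa = as.integer(unit),
      copyNumber = as.integer(1L + chain),
      evidence = evidence, noRepeat = FALSE)
}
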
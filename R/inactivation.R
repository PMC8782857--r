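# inactivating-mutation calling against an intact reference CDS:
# frameshift indels and premature stop codons, shared-mutation merging,
# gene-status classification

#' Call inactivating mutations from a pairwise alignment
#'
#' Scans a reference-anchored alignment for (a) indel events whose net
#' length is not a multiple of 3 (frameshifts) and (b) in-frame stop codons
#' of the query occurring before the reference's terminal stop (premature
#' stops). Indel runs separated by fewer than `minSeparation` aligned
#' columns are merged into one event before the mod-3 test, since alignment
#' ambiguity otherwise splits single biological events. Premature stops are
#' detected in the query's own running frame (codons counted from the query
#' start), i.e. in the frame in which the mutated locus would actually be
#' translated. Coordinates are 0-based offsets into the ungapped reference
#' CDS.
#'
#' Between diverged orthologs the optimal alignment occasionally re-pairs
#' a few mismatched bases through a complementary insertion/deletion pair
#' of equal length a handful of columns apart; such a pair changes no
#' reading frame overall and is an alignment artifact, not a biological
#' event. Complementary equal-length frameshift pairs closer than
#' `slippageWindowNt` are therefore removed; genuinely compensated
#' frameshift pairs at larger distances are still reported individually
#' (the attribute `netFrameRestored` flags overall frame restoration).
#'
#' @param aln an [AffineAlignment-class] whose reference row, gap-stripped,
#'   is a valid CDS (starts with ATG, whole codons, stop-terminated, no
#'   internal in-frame stop).
#' @param referenceIsCds set FALSE to skip the reference CDS validation.
#' @param minSeparation merge indel runs closer than this many aligned
#'   columns.
#' @param slippageWindowNt drop complementary equal-length
#'   insertion/deletion pairs whose coordinates are within this many
#'   nucleotides.
#' @return data.frame with columns `kind` (`frameshift_deletion`,
#'   `frameshift_insertion`, `premature_stop`), `refCoord`, `lengthNt`
#'   (net indel length; 3 for stops), `carrier` (the query id), sorted by
#'   `refCoord`. Attribute `reference` holds the reference id and
#'   `netFrameRestored` whether the cumulative indel length is a multiple
#'   of 3.
#' @export
callMutations <- function(aln, referenceIsCds = TRUE, minSeparation = 3L,
                          slippageWindowNt = 30L) {
  stopifnot(is(aln, "AffineAlignment"))
  r <- .chars(aln@alignedRef)
  q <- .chars(aln@alignedQuery)
  refSeq <- paste(r[r != .GAP], collapse = "")
  refLen <- nchar(refSeq)
  if (referenceIsCds) {
    ok <- substr(refSeq, 1, 3) == "ATG" && refLen %% 3L == 0L
    if (ok) {
      aa <- translateCds(refSeq)
      ok <- substr(aa, nchar(aa), nchar(aa)) == "*" &&
        !grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE)
    }
    if (!ok) stop("reference row, gap-stripped, is not a valid CDS")
  }

  n <- length(r)
  # 0-based reference coordinate assigned to each column: for reference
  # characters their own offset, for insertion columns the offset of the
  # next reference character
  refIdx <- cumsum(r != .GAP)          # 1-based index of ref char at/next
  coordAt <- ifelse(r != .GAP, refIdx - 1L, pmin(refIdx, refLen - 1L))

  # --- indel runs ---------------------------------------------------------
  colType <- ifelse(q == .GAP, "del", ifelse(r == .GAP, "ins", "aln"))
  rl <- rle(colType)
  ends <- cumsum(rl$lengths)
  startsCol <- ends - rl$lengths + 1L
  runs <- data.frame(type = rl$values, start = startsCol, end = ends,
                     stringsAsFactors = FALSE)
  indels <- runs[runs$type != "aln", , drop = FALSE]
  callRows <- list()
  if (nrow(indels)) {
    signed <- ifelse(indels$type == "ins", 1L, -1L) *
      (indels$end - indels$start + 1L)
    coord <- coordAt[indels$start]
    # merge runs separated by < minSeparation aligned columns
    grp <- integer(nrow(indels))
    g <- 1L
    grp[1] <- g
    if (nrow(indels) > 1L) {
      for (i in 2:nrow(indels)) {
        sep <- indels$start[i] - indels$end[i - 1L] - 1L
        if (sep < minSeparation) grp[i] <- g else { g <- g + 1L; grp[i] <- g }
      }
    }
    for (gi in unique(grp)) {
      net <- sum(signed[grp == gi])
      if (net %% 3L != 0L) {
        callRows[[length(callRows) + 1L]] <- data.frame(
          kind = if (net < 0L) "frameshift_deletion" else "frameshift_insertion",
          refCoord = coord[grp == gi][1],
          lengthNt = abs(net),
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- premature stops in the query's own running frame -------------------
  qCols <- which(q != .GAP)
  nq <- length(qCols)
  ncodq <- nq %/% 3L
  if (ncodq > 0L) {
    qpos <- matrix(qCols[seq_len(ncodq * 3L)], ncol = 3L, byrow = TRUE)
    codons <- paste0(q[qpos[, 1]], q[qpos[, 2]], q[qpos[, 3]])
    isStop <- codons %in% .STOP_CODONS
    if (any(isStop)) {
      stopCoord <- coordAt[qpos[isStop, 1]]
      premature <- stopCoord < refLen - 3L
      if (any(premature)) {
        callRows[[length(callRows) + 1L]] <- data.frame(
          kind = "premature_stop",
          refCoord = stopCoord[premature],
          lengthNt = 3L,
          stringsAsFactors = FALSE)
      }
    }
  }

  calls <- if (length(callRows)) do.call(rbind, callRows) else
    data.frame(kind = character(), refCoord = integer(),
               lengthNt = integer(), stringsAsFactors = FALSE)

  # drop alignment-slippage artifacts: complementary equal-length
  # insertion/deletion pairs within slippageWindowNt (greedy, left to right)
  fs <- which(calls$kind %in% c("frameshift_deletion", "frameshift_insertion"))
  if (length(fs) > 1L) {
    fsRows <- calls[fs, , drop = FALSE]
    drop <- rep(FALSE, nrow(fsRows))
    for (i in seq_len(nrow(fsRows) - 1L)) {
      if (drop[i]) next
      j <- which(!drop & seq_len(nrow(fsRows)) > i &
                   fsRows$kind != fsRows$kind[i] &
                   fsRows$lengthNt == fsRows$lengthNt[i] &
                   abs(fsRows$refCoord - fsRows$refCoord[i]) <= slippageWindowNt)
      if (length(j)) drop[c(i, j[1])] <- TRUE
    }
    if (any(drop)) calls <- calls[-fs[drop], , drop = FALSE]
  }
  calls$carrier <- rep(aln@queryId, nrow(calls))
  calls <- calls[order(calls$refCoord, calls$kind), , drop = FALSE]
  rownames(calls) <- NULL
  totIns <- sum((runs$end - runs$start + 1L)[runs$type == "ins"])
  totDel <- sum((runs$end - runs$start + 1L)[runs$type == "del"])
  attr(calls, "reference") <- aln@refId
  attr(calls, "netFrameRestored") <- ((totIns - totDel) %% 3L) == 0L
  calls
}

#' Merge mutation calls shared across species
#'
#' Calls of identical kind and length whose reference coordinates differ by
#' at most `toleranceNt` (after left-normalized alignment) are merged into
#' one event carried by the union of species — the evidence that an
#' inactivating mutation was inherited from a common ancestor. The default
#' window of 9 nt (three codons) absorbs the placement jitter of one
#' inherited indel across species: a substitution next to the gap shifts
#' its optimal position by 1-2 nt, and when the indel sits in a
#' short homopolymer run whose reference copy has itself mutated, the
#' canonical left-aligned position can migrate by up to the run length.
#' Two independent same-length frameshifts within 9 nt of each other in
#' different species are far less likely than one inherited event.
#'
#' @param calls list of per-species call data.frames from
#'   [callMutations()] (all against the same reference), or one combined
#'   data.frame.
#' @param toleranceNt coordinate tolerance for merging.
#' @return data.frame with columns `kind`, `refCoord` (left-most
#'   coordinate of the merged event), `lengthNt`, `nCarriers` and
#'   `carriers` (comma-separated species), sorted by `refCoord`; list
#'   column `carrierSpecies` holds the species character vectors.
#' @export
findSharedMutations <- function(calls, toleranceNt = 9L) {
  if (is.data.frame(calls)) calls <- list(calls)
  refs <- unique(unlist(lapply(calls, attr, "reference")))
  if (length(refs) > 1L)
    stop("calls were made against different references: ",
         paste(refs, collapse = ", "))
  all <- do.call(rbind, lapply(calls, function(x)
    x[, c("kind", "refCoord", "lengthNt", "carrier"), drop = FALSE]))
  if (is.null(all) || !nrow(all)) {
    out <- data.frame(kind = character(), refCoord = integer(),
                      lengthNt = integer(), nCarriers = integer(),
                      carriers = character(), stringsAsFactors = FALSE)
    out$carrierSpecies <- list()
    return(out)
  }
  out <- list()
  for (key in unique(paste(all$kind, all$lengthNt))) {
    sub <- all[paste(all$kind, all$lengthNt) == key, , drop = FALSE]
    sub <- sub[order(sub$refCoord), , drop = FALSE]
    grp <- cumsum(c(1L, diff(sub$refCoord) > toleranceNt))
    for (gi in unique(grp)) {
      s <- sub[grp == gi, , drop = FALSE]
      carriers <- sort(unique(s$carrier))
      row <- data.frame(kind = s$kind[1], refCoord = min(s$refCoord),
                        lengthNt = s$lengthNt[1],
                        nCarriers = length(carriers),
                        carriers = paste(carriers, collapse = ","),
                        stringsAsFactors = FALSE)
      row$carrierSpecies <- list(carriers)
      out[[length(out) + 1L]] <- row
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$refCoord, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- refs
  out
}

#' Classify a gene as intact or pseudogene
#'
#' A gene is called a pseudogene when it carries at least one frameshift or
#' premature stop, or when its theoretical protein is shorter than
#' `truncationThreshold` of the intact reference (strict inequality: a
#' prediction exactly at the threshold with no mutation calls is intact).
#'
#' @param prediction a [CodingPrediction-class] for the species/gene.
#' @param calls mutation-call data.frame from [callMutations()] for the
#'   same species/gene.
#' @param referenceLengthAa length of the intact reference protein.
#' @param truncationThreshold fraction of the reference length below which
#'   a call-free prediction is still considered inactivated.
#' @return A [GeneStatus-class].
#' @export
classifyStatus <- function(prediction, calls, referenceLengthAa,
                           truncationThreshold = 0.5) {
  stopifnot(is(prediction, "CodingPrediction"))
  fraction <- prediction@lengthAa / referenceLengthAa
  inactivating <- calls[calls$kind %in% c("frameshift_deletion",
                                          "frameshift_insertion",
                                          "premature_stop"), , drop = FALSE]
  status <- if (nrow(inactivating) > 0L || fraction < truncationThreshold)
    "pseudogene" else "intact"
  new("GeneStatus",
      species = prediction@species, gene = prediction@gene,
      status = status, evidence = inactivating,
      predictedFraction = fraction,
      copies = 1L)
}
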
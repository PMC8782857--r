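#' Simulation configuration for a repeat-rich single-exon gene family
#'
#' Describes the ground-truth scenario the simulator generates: a tandem
#' repeat-rich ancestral coding sequence, a species tree along which it
#' evolves by per-site substitutions, and inactivating events (frameshift
#' indels, nonsense codons) injected on chosen branches and inherited by all
#' descendants. Construct with [simulationConfig()].
#'
#' @slot seed integer; seeds every random draw, identical configs give
#'   byte-identical outputs.
#' @slot repeatUnitLengthAa integer; length of the repeat unit in residues.
#' @slot repeatCopies integer; number of tandem copies in the ancestral
#'   protein.
#' @slot unitDivergence numeric; per-residue probability that a tandem copy
#'   differs from the master unit (near-identical copies).
#' @slot subRate numeric; per-site substitution probability per unit branch
#'   length.
#' @slot flankLengthNt integer; untranslated random flank added on each side
#'   of every tip locus.
#' @slot flankingGenes character; marker genes surrounding the focal gene in
#'   the emitted gene-order tables.
#' @slot geneName character; name of the focal gene.
#' @slot tree character; rooted Newick with branch lengths (and optionally
#'   internal node labels used as branch identifiers).
#' @slot events data.frame with columns `branch`, `kind`
#'   (`deletion`/`insertion`/`nonsense`), `offsetNt` (0-based offset into
#'   the ancestral CDS) and `lengthNt`.
#' @slot dropGenes named list, species -> marker genes absent from that
#'   species' locus ("*" applies to every species).
#' @slot insertGenes data.frame with columns `species`, `gene`, `after`;
#'   extra marker genes inserted after an existing one.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  repeatUnitLengthAa = "integer",
  repeatCopies = "integer",
  unitDivergence = "numeric",
  subRate = "numeric",
  flankLengthNt = "integer",
  flankingGenes = "character",
  geneName = "character",
  tree = "character",
  events = "data.frame",
  dropGenes = "list",
  insertGenes = "data.frame"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@repeatUnitLengthAa < 1L) msg <- c(msg, "repeatUnitLengthAa must be >= 1")
  if (object@repeatCopies < 1L) msg <- c(msg, "repeatCopies must be >= 1")
  if (object@unitDivergence < 0 || object@unitDivergence > 1)
    msg <- c(msg, "unitDivergence must be in [0, 1]")
  if (object@subRate < 0 || object@subRate > 1)
    msg <- c(msg, "subRate must be in [0, 1]")
  cdsLen <- 3L * object@repeatUnitLengthAa * object@repeatCopies + 6L
  if (cdsLen %% 3L != 0L) msg <- c(msg, "CDS length must be divisible by 3")
  ev <- object@events
  if (nrow(ev)) {
    need <- c("branch", "kind", "offsetNt", "lengthNt")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, sprintf("events must have columns %s", paste(need, collapse = ", ")))
    } else {
      if (!all(ev$kind %in% c("deletion", "insertion", "nonsense")))
        msg <- c(msg, "event kind must be deletion, insertion or nonsense")
      if (any(ev$offsetNt < 0L) || any(ev$offsetNt >= cdsLen))
        msg <- c(msg, sprintf("event offsetNt must lie within the CDS [0, %d)", cdsLen))
      if (any(ev$lengthNt < 1L)) msg <- c(msg, "event lengthNt must be >= 1")
      bad <- ev$kind == "nonsense" & (ev$offsetNt %% 3L != 0L)
      if (any(bad)) msg <- c(msg, "nonsense events must start on a codon boundary")
      # overlap check in ancestral coordinates (insertions occupy a point)
      if (nrow(ev) > 1L) {
        lo <- ev$offsetNt
        hi <- ev$offsetNt + ifelse(ev$kind == "insertion", 1L, ev$lengthNt) - 1L
        ord <- order(lo)
        if (any(lo[ord][-1L] <= hi[ord][-length(ord)]))
          msg <- c(msg, "injected events overlap in ancestral CDS coordinates")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulated gene-loss dataset with ground truth
#'
#' Result of [simulateGeneLoss()]: per-tip genomic loci (CDS embedded in
#' untranslated flanks), per-tip evolved CDS regions, the ancestral gene,
#' per-species gene-order tables and a truth table recording the injected
#' events and each tip's intact/pseudogene status.
#'
#' @slot config the [SimulationConfig-class] that produced the dataset.
#' @slot tree `phylo`; the labeled species tree.
#' @slot ancestralCds,ancestralProtein ancestral gene as
#'   [Biostrings::DNAString] / [Biostrings::AAString].
#' @slot genomic [Biostrings::DNAStringSet]; one locus per tip, flanks
#'   included.
#' @slot cds [Biostrings::DNAStringSet]; evolved homologous CDS region per
#'   tip (no flanks; for pseudogene tips this is not a valid CDS).
#' @slot geneOrders data.frame; species, unit, gene, position, strand.
#' @slot truth list with elements `tips` (data.frame species/status),
#'   `events` (data.frame branch/kind/offsetNt/lengthNt/descendants) and
#'   `lossBranch`.
#' @export
setClass("GeneLossSim", representation(
  config = "SimulationConfig",
  tree = "ANY",
  ancestralCds = "ANY",
  ancestralProtein = "ANY",
  genomic = "ANY",
  cds = "ANY",
  geneOrders = "data.frame",
  truth = "list"
))

#' Theoretical protein predicted from a genomic locus
#'
#' Translation of a locus from a start codon to the first in-frame stop
#' codon (TAA/TAG/TGA). Codons containing ambiguity never terminate the
#' scan, so sequencing ambiguity cannot create a false truncation.
#'
#' @slot species,gene identifiers.
#' @slot startOffset 0-based nucleotide offset of the ATG used.
#' @slot protein character; predicted residues (initiator Met included,
#'   no stop symbol).
#' @slot lengthAa integer; number of residues before the stop.
#' @slot stopFound logical; FALSE when the sequence ends before any
#'   in-frame stop codon.
#' @slot stopOffset integer; 0-based offset of the first in-frame stop
#'   triplet (NA when `stopFound` is FALSE).
#' @slot nonOrthologousStart logical; TRUE when the start codon used is not
#'   at the position the reference start aligns to.
#' @export
setClass("CodingPrediction", representation(
  species = "character",
  gene = "character",
  startOffset = "integer",
  protein = "character",
  lengthAa = "integer",
  stopFound = "logical",
  stopOffset = "integer",
  nonOrthologousStart = "logical"
))

setValidity("CodingPrediction", function(object) {
  msg <- character()
  if (object@lengthAa != nchar(object@protein))
    msg <- c(msg, "lengthAa must equal the number of predicted residues")
  if (grepl("*", object@protein, fixed = TRUE))
    msg <- c(msg, "predicted protein must not contain a stop symbol")
  if (object@stopFound && !is.na(object@stopOffset) &&
      (object@stopOffset - object@startOffset) != 3L * object@lengthAa)
    msg <- c(msg, "stopOffset - startOffset must equal 3 * lengthAa")
  if (length(msg)) msg else TRUE
})

#' Pairwise affine-gap alignment
#'
#' Two equal-length aligned rows with `-` as the gap symbol, plus the
#' alignment score and scoring parameters. Gap runs are left-normalized to a
#' canonical position (the convention used for variant normalization), so
#' mutation coordinates are deterministic.
#'
#' @slot refId,queryId sequence identifiers.
#' @slot alignedRef,alignedQuery aligned rows (equal length).
#' @slot score numeric alignment score.
#' @slot params list; scoring parameters (match/mismatch or matrix, gap
#'   open, gap extend, alignment type).
#' @export
setClass("AffineAlignment", representation(
  refId = "character",
  queryId = "character",
  alignedRef = "character",
  alignedQuery = "character",
  score = "numeric",
  params = "list"
))

setValidity("AffineAlignment", function(object) {
  msg <- character()
  if (nchar(object@alignedRef) != nchar(object@alignedQuery))
    msg <- c(msg, "aligned rows must have equal length")
  r <- strsplit(object@alignedRef, "")[[1]]
  q <- strsplit(object@alignedQuery, "")[[1]]
  if (any(r == .GAP & q == .GAP))
    msg <- c(msg, "no alignment column may be gap in both rows")
  if (length(msg)) msg else TRUE
})

#' Per-species gene status call
#'
#' Classification of one gene in one species as intact, pseudogene or
#' absent, with the inactivating-mutation evidence and the predicted
#' protein's length as a fraction of the intact reference.
#'
#' @slot species,gene identifiers.
#' @slot status one of `intact`, `pseudogene`, `absent`.
#' @slot evidence data.frame of inactivating-mutation calls
#'   (kind/refCoord/lengthNt/carrier).
#' @slot predictedFraction numeric in \[0, 1\]; predicted length over
#'   reference length.
#' @slot copies integer; gene copy number (0 when absent).
#' @export
setClass("GeneStatus", representation(
  species = "character",
  gene = "character",
  status = "character",
  evidence = "data.frame",
  predictedFraction = "numeric",
  copies = "integer"
))

setValidity("GeneStatus", function(object) {
  msg <- character()
  if (!object@status %in% c("intact", "pseudogene", "absent"))
    msg <- c(msg, "status must be intact, pseudogene or absent")
  if (object@status == "absent" && object@copies != 0L)
    msg <- c(msg, "absent genes must have 0 copies")
  if (length(msg)) msg else TRUE
})

#' Self-comparison dot plot
#'
#' Windowed self-comparison of a protein: a cell (i, j) is marked when the
#' substitution-matrix score summed over a window starting at (i, j) along
#' the diagonal reaches the threshold; marked windows are merged into
#' maximal diagonal segments. Coordinates are 0-based.
#'
#' @slot seqId sequence identifier.
#' @slot seqLength integer; protein length in residues.
#' @slot window integer window size.
#' @slot threshold numeric; un-normalized window score threshold.
#' @slot matrixName substitution matrix identifier.
#' @slot segments data.frame with columns `start1`, `start2`, `length`
#'   (0-based diagonal runs; symmetric under swapping start1/start2).
#' @export
setClass("DotPlot", representation(
  seqId = "character",
  seqLength = "integer",
  window = "integer",
  threshold = "numeric",
  matrixName = "character",
  segments = "data.frame"
))

setValidity("DotPlot", function(object) {
  seg <- object@segments
  msg <- character()
  if (nrow(seg)) {
    off <- seg$start1 != seg$start2
    a <- paste(seg$start1[off], seg$start2[off], seg$length[off])
    b <- paste(seg$start2[off], seg$start1[off], seg$length[off])
    if (!setequal(a, b)) msg <- c(msg, "segments must be symmetric under (i,j) -> (j,i)")
    if (any(seg$start1 < 0L) || any(seg$start2 < 0L))
      msg <- c(msg, "segment starts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Tandem repeat profile of a protein
#'
#' Repeat unit length and copy number estimated from the off-diagonal
#' periodicity of a self dot plot.
#'
#' @slot seqId sequence identifier.
#' @slot unitLengthAa integer; estimated repeat unit length (the whole
#'   sequence length when no repeat is detected).
#' @slot copyNumber integer; estimated tandem copy count (1 when no repeat
#'   is detected).
#' @slot evidence data.frame with columns `offset`, `support` (total
#'   diagonal segment length at each off-diagonal offset).
#' @slot noRepeat logical; TRUE when no off-diagonal periodicity was found.
#' @export
setClass("RepeatProfile", representation(
  seqId = "character",
  unitLengthAa = "integer",
  copyNumber = "integer",
  evidence = "data.frame",
  noRepeat = "logical"
))

setValidity("RepeatProfile", function(object) {
  msg <- character()
  if (object@copyNumber < 1L) msg <- c(msg, "copyNumber must be >= 1")
  if (object@unitLengthAa < 1L) msg <- c(msg, "unitLengthAa must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Maximum-parsimony gain/loss reconstruction
#'
#' Ancestral presence/absence (or copy-number) states on a rooted species
#' tree under unordered-state maximum parsimony, the minimal number of state
#' changes, and the changes assigned to branches.
#'
#' @slot character_ character; name of the character (gene) reconstructed.
#' @slot tree `phylo`; the labeled input tree.
#' @slot stateSets named list; per-node candidate state sets from the
#'   bottom-up pass.
#' @slot states named character; the chosen state per node (tips included).
#' @slot eventCount integer; minimal number of state changes.
#' @slot events data.frame with columns `branch` (child node label of the
#'   branch), `from`, `to`.
#' @slot ambiguous logical; TRUE when more than one minimal labeling exists
#'   (the reported labeling prefers ancestral presence).
#' @export
setClass("GainLossFit", representation(
  character_ = "character",
  tree = "ANY",
  stateSets = "list",
  states = "character",
  eventCount = "integer",
  events = "data.frame",
  ambiguous = "logical"
))

setValidity("GainLossFit", function(object) {
  if (object@eventCount != nrow(object@events))
    "eventCount must equal the number of branch events"
  else TRUE
})
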
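#' @rdname geneDecay-accessors
#' @export
setMethod("speciesName", "CodingPrediction", function(x) x@species)
#' @rdname geneDecay-accessors
#' @export
setMethod("speciesName", "GeneStatus", function(x) x@species)
#' @rdname geneDecay-accessors
#' @export
setMethod("geneName", "CodingPrediction", function(x) x@gene)
#' @rdname geneDecay-accessors
#' @export
setMethod("geneName", "GeneStatus", function(x) x@gene)
#' @rdname geneDecay-accessors
#' @export
setMethod("proteinSeq", "CodingPrediction", function(x) x@protein)
#' @rdname geneDecay-accessors
#' @export
setMethod("lengthAa", "CodingPrediction", function(x) x@lengthAa)
#' @rdname geneDecay-accessors
#' @export
setMethod("startOffset", "CodingPrediction", function(x) x@startOffset)
#' @rdname geneDecay-accessors
#' @export
setMethod("stopFound", "CodingPrediction", function(x) x@stopFound)
#' @rdname geneDecay-accessors
#' @export
setMethod("stopOffset", "CodingPrediction", function(x) x@stopOffset)

#' @rdname geneDecay-accessors
#' @export
setMethod("alignedRef", "AffineAlignment", function(x) x@alignedRef)
#' @rdname geneDecay-accessors
#' @export
setMethod("alignedQuery", "AffineAlignment", function(x) x@alignedQuery)
#' @rdname geneDecay-accessors
#' @export
setMethod("score", "AffineAlignment", function(x, ...) x@score)

#' @rdname geneDecay-accessors
#' @export
setMethod("statusCall", "GeneStatus", function(x) x@status)
#' @rdname geneDecay-accessors
#' @export
setMethod("evidence", "GeneStatus", function(x) x@evidence)
#' @rdname geneDecay-accessors
#' @export
setMethod("predictedFraction", "GeneStatus", function(x) x@predictedFraction)

#' @rdname geneDecay-accessors
#' @export
setMethod("matchSegments", "DotPlot", function(x) x@segments)
#' @rdname geneDecay-accessors
#' @export
setMethod("unitLength", "RepeatProfile", function(x) x@unitLengthAa)
#' @rdname geneDecay-accessors
#' @export
setMethod("copyNumber", "RepeatProfile", function(x) x@copyNumber)

#' @rdname geneDecay-accessors
#' @export
setMethod("eventCount", "GainLossFit", function(x) x@eventCount)
#' @rdname geneDecay-accessors
#' @export
setMethod("events", "GainLossFit", function(x) x@events)
#' @rdname geneDecay-accessors
#' @export
setMethod("nodeStates", "GainLossFit", function(x) x@states)
#' @rdname geneDecay-accessors
#' @export
setMethod("isAmbiguous", "GainLossFit", function(x) x@ambiguous)

#' @rdname geneDecay-accessors
#' @export
setMethod("truthTable", "GeneLossSim", function(x) x@truth)
#' @rdname geneDecay-accessors
#' @export
setMethod("speciesTree", "GeneLossSim", function(x) x@tree)

setMethod("show", "SimulationConfig", function(object) {
  cdsLen <- 3L * object@repeatUnitLengthAa * object@repeatCopies + 6L
  cat("SimulationConfig\n")
  cat(sprintf("  gene: %s | unit %d aa x %d copies -> CDS %d nt\n",
              object@geneName, object@repeatUnitLengthAa,
              object@repeatCopies, cdsLen))
  cat(sprintf("  seed %d | subRate %.3g | flank %d nt | %d injected event(s)\n",
              object@seed, object@subRate, object@flankLengthNt,
              nrow(object@events)))
})

setMethod("show", "GeneLossSim", function(object) {
  st <- object@truth$tips
  cat("GeneLossSim\n")
  cat(sprintf("  %d tips (%d intact, %d pseudogene) | ancestral CDS %d nt\n",
              nrow(st), sum(st$status == "intact"),
              sum(st$status == "pseudogene"), length(object@ancestralCds)))
  cat(sprintf("  loss branch: %s | %d injected event(s)\n",
              object@truth$lossBranch, nrow(object@truth$events)))
})

setMethod("show", "CodingPrediction", function(object) {
  cat(sprintf("CodingPrediction %s/%s: %d aa, start @%d, stop %s%s\n",
              object@species, object@gene, object@lengthAa,
              object@startOffset,
              if (object@stopFound) sprintf("@%d", object@stopOffset) else "not found",
              if (object@nonOrthologousStart) " [non-orthologous start]" else ""))
})

setMethod("show", "AffineAlignment", function(object) {
  cat(sprintf("AffineAlignment %s vs %s: %d columns, score %.1f\n",
              object@refId, object@queryId, nchar(object@alignedRef),
              object@score))
})

setMethod("show", "GeneStatus", function(object) {
  cat(sprintf("GeneStatus %s/%s: %s (%.1f%% of reference, %d mutation call(s))\n",
              object@species, object@gene, object@status,
              100 * object@predictedFraction, nrow(object@evidence)))
})

setMethod("show", "DotPlot", function(object) {
  cat(sprintf("DotPlot %s (%d aa): window %d, threshold %g, %d segment(s)\n",
              object@seqId, object@seqLength, object@window,
              object@threshold, nrow(object@segments)))
})

setMethod("show", "RepeatProfile", function(object) {
  if (object@noRepeat) {
    cat(sprintf("RepeatProfile %s: no repeat detected\n", object@seqId))
  } else {
    cat(sprintf("RepeatProfile %s: unit %d aa x %d copies\n",
                object@seqId, object@unitLengthAa, object@copyNumber))
  }
})

setMethod("show", "GainLossFit", function(object) {
  cat(sprintf("GainLossFit '%s': %d event(s)%s\n", object@character_,
              object@eventCount,
              if (object@ambiguous) " [ambiguous labeling]" else ""))
  if (nrow(object@events)) {
    for (i in seq_len(nrow(object@events))) {
      cat(sprintf("  %s: %s -> %s\n", object@events$branch[i],
                  object@events$from[i], object@events$to[i]))
    }
  }
})
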
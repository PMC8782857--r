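# end-to-end pipeline: simulate/load -> orf scan -> mutation calling ->
# repeat profiling -> synteny -> gain/loss parsimony -> report bundle

# defaults merged under user config
.defaultRunConfig <- function() {
  list(
    gene = "EPPK1",
    reference_species = "human",
    thresholds = list(truncation_fraction = 0.5,
                      shared_tolerance_nt = 9L,
                      dotplot_window = 10L,
                      dotplot_threshold = 23,
                      synteny_k = 2L),
    calibrations = NULL,
    simulate = NULL,
    inputs = NULL
  )
}

.validateRunConfig <- function(config) {
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config must contain either a 'simulate' block or an 'inputs' block")
  if (!is.null(config$inputs)) {
    need <- c("genomic_fasta", "cds_fasta", "tree")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      stop("inputs block lacks: ", paste(miss, collapse = ", "))
    for (p in unlist(config$inputs[need]))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  invisible(config)
}

# build a SimulationConfig from the config list's simulate block
.simConfigFromList <- function(block, seed = NULL) {
  args <- block
  if (!is.null(args$events)) {
    ev <- do.call(rbind, lapply(args$events, as.data.frame,
                                stringsAsFactors = FALSE))
    ev$offsetNt <- as.integer(ev$offsetNt)
    ev$lengthNt <- as.integer(ev$lengthNt)
    args$events <- ev
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(simulationConfig, args)
}

#' Run the full gene-loss inference pipeline
#'
#' Orchestrates all stages over a single configuration: data simulation
#' (or loading), theoretical-protein prediction per species, inactivating
#' mutation calling against the reference species, shared-mutation
#' detection, repeat-domain profiling, gene-order synteny support,
#' maximum-parsimony gain/loss reconstruction and (when calibrations are
#' given) dating of the loss. Writes per-stage TSV tables and a
#' machine-readable JSON summary; re-running with the same config and seed
#' reproduces all outputs byte for byte.
#'
#' @param config path to a YAML config or an equivalent named list. Keys:
#'   `simulate` (arguments of [simulationConfig()]) or `inputs`
#'   (`genomic_fasta`, `cds_fasta`, `tree`, optional `gene_orders`),
#'   `gene`, `reference_species`, `thresholds`
#'   (`truncation_fraction`, `shared_tolerance_nt`, `dotplot_window`,
#'   `dotplot_threshold`, `synteny_k`), `calibrations` (list/data.frame of
#'   `tipA`, `tipB`, `ageMya`).
#' @param outdir output directory for the report bundle.
#' @param seed overrides the simulation seed from the config.
#' @return Invisibly, a list with every stage result (`sim`, `orf`,
#'   `calls`, `shared`, `status`, `repeats`, `synteny`, `gainloss`,
#'   `dating`, `summary`).
#' @export
runPipeline <- function(config, outdir = tempfile("genedecay_run_"),
                        seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(.defaultRunConfig(), config)
  .validateRunConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  gene <- config$gene
  refSp <- config$reference_species
  stage <- "setup"
  log <- function(s, msg) message(sprintf("[genedecay] %-10s %s", s, msg))

  result <- tryCatch({
    # --- data ------------------------------------------------------------
    stage <- "simulate"
    if (!is.null(config$simulate)) {
      simCfg <- .simConfigFromList(config$simulate, seed = seed)
      sim <- simulateGeneLoss(simCfg)
      genomic <- sim@genomic
      cds <- sim@cds
      tree <- sim@tree
      orders <- sim@geneOrders
      usedSeed <- simCfg@seed
      log(stage, sprintf("%d tips, CDS %d nt, seed %d",
                         length(genomic), length(sim@ancestralCds), usedSeed))
    } else {
      sim <- NULL
      genomic <- Biostrings::readDNAStringSet(config$inputs$genomic_fasta)
      cds <- Biostrings::readDNAStringSet(config$inputs$cds_fasta)
      tree <- readSpeciesTree(file = config$inputs$tree)
      orders <- if (!is.null(config$inputs$gene_orders))
        readGeneOrders(config$inputs$gene_orders) else NULL
      usedSeed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
      log(stage, sprintf("loaded %d loci", length(genomic)))
    }
    if (!length(genomic)) stop("no query loci")
    if (!refSp %in% names(cds))
      stop(sprintf("reference species '%s' not among the sequences", refSp))
    refCds <- as.character(cds[[refSp]])

    # --- theoretical proteins --------------------------------------------
    stage <- "orf-scan"
    orf <- orfScan(genomic, refCds, gene = gene)
    write.table(orf$table, file.path(outdir, "protein_lengths.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    refLenAa <- orf$table$lengthAa[orf$table$species == refSp]
    log(stage, sprintf("reference protein %d aa", refLenAa))

    # --- mutation calling -------------------------------------------------
    stage <- "call"
    others <- setdiff(names(cds), refSp)
    calls <- lapply(others, function(sp) {
      aln <- alignGlobal(refCds, as.character(cds[[sp]]),
                         refId = refSp, queryId = sp)
      callMutations(aln)
    })
    names(calls) <- others
    callTab <- do.call(rbind, c(calls, make.row.names = FALSE))
    if (is.null(callTab)) callTab <- .emptyCalls()
    write.table(callTab, file.path(outdir, "mutation_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    shared <- findSharedMutations(calls,
                                  toleranceNt = th$shared_tolerance_nt)
    write.table(shared[, setdiff(names(shared), "carrierSpecies")],
                file.path(outdir, "shared_mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log(stage, sprintf("%d calls, %d shared events",
                       nrow(callTab), nrow(shared)))

    # --- status ----------------------------------------------------------
    stage <- "status"
    statusList <- lapply(names(genomic), function(sp) {
      cl <- if (sp %in% names(calls)) calls[[sp]] else .emptyCalls()
      classifyStatus(orf$predictions[[sp]], cl, refLenAa,
                     truncationThreshold = th$truncation_fraction)
    })
    names(statusList) <- names(genomic)
    statusTab <- data.frame(
      species = names(statusList),
      gene = gene,
      status = vapply(statusList, statusCall, character(1)),
      predictedFraction = vapply(statusList, predictedFraction, numeric(1)),
      nMutations = vapply(statusList, function(s) nrow(evidence(s)),
                          integer(1)),
      stringsAsFactors = FALSE)
    rownames(statusTab) <- NULL
    write.table(statusTab, file.path(outdir, "gene_status.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log(stage, sprintf("%d pseudogene tip(s)",
                       sum(statusTab$status == "pseudogene")))

    # --- repeat profiling -------------------------------------------------
    stage <- "repeats"
    repeats <- lapply(names(genomic), function(sp) {
      p <- orf$predictions[[sp]]
      if (p@lengthAa < th$dotplot_window) {
        return(new("RepeatProfile", seqId = sp,
                   unitLengthAa = max(1L, p@lengthAa), copyNumber = 1L,
                   evidence = data.frame(offset = integer(),
                                         support = integer()),
                   noRepeat = TRUE))
      }
      profileRepeats(selfDotplot(p@protein, window = th$dotplot_window,
                                 threshold = th$dotplot_threshold,
                                 seqId = sp))
    })
    names(repeats) <- names(genomic)
    repTab <- data.frame(
      species = names(repeats),
      unitLengthAa = vapply(repeats, unitLength, integer(1)),
      copyNumber = vapply(repeats, copyNumber, integer(1)),
      noRepeat = vapply(repeats, function(r) r@noRepeat, logical(1)),
      stringsAsFactors = FALSE)
    rownames(repTab) <- NULL
    write.table(repTab, file.path(outdir, "repeat_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log(stage, sprintf("reference: %d copies of a %d-aa unit",
                       repTab$copyNumber[repTab$species == refSp],
                       repTab$unitLengthAa[repTab$species == refSp]))

    # --- synteny ----------------------------------------------------------
    stage <- "synteny"
    synTab <- NULL
    if (!is.null(orders)) {
      refTab <- orders[orders$species == refSp, , drop = FALSE]
      synTab <- data.frame(
        species = setdiff(unique(orders$species), refSp),
        stringsAsFactors = FALSE)
      synTab$syntenySupport <- vapply(synTab$species, function(sp) {
        as.integer(syntenySupport(refTab,
                                  orders[orders$species == sp, , drop = FALSE],
                                  focalA = gene, k = th$synteny_k))
      }, integer(1))
      rownames(synTab) <- NULL
      write.table(synTab, file.path(outdir, "synteny_support.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log(stage, sprintf("support computed for %d species pair(s)",
                         nrow(synTab)))
    }

    # --- gain/loss parsimony ---------------------------------------------
    stage <- "gainloss"
    tipStates <- setNames(ifelse(statusTab$status == "intact", "1", "0"),
                          statusTab$species)
    fit <- fitchParsimony(tree, tipStates, characterId = gene)
    losses <- fit@events[fit@events$from == "1" & fit@events$to == "0", ,
                         drop = FALSE]
    write.table(fit@events, file.path(outdir, "gain_loss_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log(stage, sprintf("%d event(s), %d loss(es)", eventCount(fit),
                       nrow(losses)))

    stage <- "dating"
    cal <- config$calibrations
    dating <- NULL
    if (!is.null(cal) && nrow(losses)) {
      if (!is.data.frame(cal))
        cal <- do.call(rbind, lapply(cal, as.data.frame,
                                     stringsAsFactors = FALSE))
      dating <- lapply(losses$branch, function(b)
        dateEvent(tree, b, cal, sharedMutations = shared))
      names(dating) <- losses$branch
    }

    # --- summary ----------------------------------------------------------
    stage <- "summary"
    summary <- list(
      seed = usedSeed,
      gene = gene,
      referenceSpecies = refSp,
      nSpecies = length(genomic),
      orfLengthsAa = setNames(as.list(orf$table$lengthAa),
                              orf$table$species),
      status = setNames(as.list(statusTab$status), statusTab$species),
      sharedMutations = shared[, c("kind", "refCoord", "lengthNt",
                                   "nCarriers", "carriers")],
      eventCount = eventCount(fit),
      events = fit@events,
      lossBranches = losses$branch,
      dating = if (is.null(dating)) NULL else lapply(dating, function(d)
        d[c("branch", "lowerMya", "upperMya")]),
      syntenySupport = if (is.null(synTab)) NULL else
        setNames(as.list(synTab$syntenySupport), synTab$species),
      repeatProfiles = setNames(
        lapply(names(repeats), function(sp)
          list(unitLengthAa = unitLength(repeats[[sp]]),
               copyNumber = copyNumber(repeats[[sp]]),
               noRepeat = repeats[[sp]]@noRepeat)),
        names(repeats))
    )
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    list(sim = sim, orf = orf, calls = calls, shared = shared,
         status = statusList, statusTable = statusTab, repeats = repeats,
         synteny = synTab, gainloss = fit, dating = dating,
         summary = summary, outdir = outdir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
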
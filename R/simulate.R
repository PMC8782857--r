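# ground-truth simulator: a repeat-rich single-exon gene evolved along a
# species tree with injected inactivating mutations

#' Default species tree for simulations
#'
#' A 15-taxon rooted tree (Newick, branch lengths in units of 100 My)
#' emulating the study system: three terrestrial outgroups (human, cattle,
#' hippo) and a 12-tip cetacean clade split into baleen whales and toothed
#' whales. Internal nodes are labeled so branches can be addressed by the
#' label of the node below them (e.g. `"cetacea"` is the cetacean stem
#' branch).
#'
#' @return A single Newick string.
#' @export
#' @examples
#' tr <- ape::read.tree(text = defaultTree())
#' ape::Ntip(tr)
defaultTree <- function() {
  paste0(
    "((cattle:0.60,(((blue_whale:0.10,minke_whale:0.10)mysticeti:0.23,(sp",
    "erm_whale:0.30,(baiji:0.25,((narwhal:0.12,beluga:0.12)monodontidae:0",
    ".08,((vaquita:0.14,finless_porpoise:0.14)phocoenidae:0.04,(white_sid",
    "ed_dolphin:0.16,(pilot_whale:0.12,(orca:0.10,bottlenose_dolphin:0.10",
    ")orcinae:0.02)globicephalinae:0.04)delphinidae:0.02)delphinoidea_cor",
    "e:0.02)delphinoidea:0.05)odontoceti_crown:0.05)odontoceti:0.03)cetac",
    "ea:0.21,hippo:0.54)whippomorpha:0.06)cetruminantia:0.36,human:0.96)r",
    "oot;"
  )
}

# default injected events: a nonsense codon and a 1-nt deletion on the
# cetacean stem (shared by all 12 cetacean tips) plus, when the CDS is
# long enough, two tip-private frameshifts. At default size the nonsense
# sits at codon 70, truncating the theoretical protein to 69 residues;
# for short CDS configurations the offsets scale down.
.defaultEvents <- function(cdsLen = 7206L) {
  ncod <- cdsLen %/% 3L
  stopCodon <- max(3L, min(70L, ncod - 4L))  # 1-based codon of injected stop
  nonsense <- 3L * (stopCodon - 1L)
  del1 <- nonsense + 93L
  if (del1 >= cdsLen) del1 <- nonsense + 5L
  ev <- data.frame(
    branch = c("cetacea", "cetacea"),
    kind = c("nonsense", "deletion"),
    offsetNt = c(nonsense, del1),
    lengthNt = c(3L, 1L),
    stringsAsFactors = FALSE)
  if (cdsLen > 2100L) {
    ev <- rbind(ev, data.frame(
      branch = c("blue_whale", "bottlenose_dolphin"),
      kind = c("deletion", "insertion"),
      offsetNt = c(2001L, 1501L),
      lengthNt = c(2L, 1L),
      stringsAsFactors = FALSE))
  }
  ev
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study system: a single-exon gene whose
#' protein is a tandem array of ~60-residue plakin-like repeat units
#' (default 40 copies, giving a 7,206-nt CDS, within the 6,000-12,000-nt
#' range typical of such genes), evolved along [defaultTree()] with i.i.d.
#' per-site substitutions, and inactivated on the cetacean stem branch by a
#' nonsense codon plus a 1-nt frameshift deletion inherited by all 12
#' cetacean tips.
#'
#' @param seed integer seed; identical configs produce byte-identical
#'   output files.
#' @param repeatUnitLengthAa repeat unit length in residues.
#' @param repeatCopies number of tandem copies.
#' @param unitDivergence per-residue divergence among tandem copies.
#' @param subRate per-site substitution probability per unit branch length.
#' @param flankLengthNt length of random untranslated flank on each side of
#'   a tip locus.
#' @param flankingGenes marker genes for the gene-order tables.
#' @param geneName focal gene name.
#' @param tree rooted Newick string with branch lengths.
#' @param events data.frame of injected events (`branch`, `kind`,
#'   `offsetNt`, `lengthNt`); see [SimulationConfig-class]. When `NULL`
#'   and the tree is [defaultTree()], the default cetacean-stem events
#'   (scaled to the CDS length) are used; with a custom tree the default
#'   is no events.
#' @param dropGenes named list: species -> marker genes missing from its
#'   locus; the name `"*"` applies to every species. The default drops
#'   `MACF1CTL` everywhere, mirroring its loss in placental mammals.
#' @param insertGenes data.frame (`species`, `gene`, `after`) of extra
#'   marker genes.
#' @return A validated [SimulationConfig-class] object.
#' @export
#' @examples
#' cfg <- simulationConfig(seed = 1L, repeatUnitLengthAa = 20L,
#'                         repeatCopies = 10L)
#' cfg
simulationConfig <- function(seed = 1L,
                             repeatUnitLengthAa = 60L,
                             repeatCopies = 40L,
                             unitDivergence = 0.02,
                             subRate = 0.05,
                             flankLengthNt = 200L,
                             flankingGenes = c("PARP10", "PLEC", "MACF1CTL",
                                               "NRBP2", "PUF60"),
                             geneName = "EPPK1",
                             tree = defaultTree(),
                             events = NULL,
                             dropGenes = list("*" = "MACF1CTL"),
                             insertGenes = data.frame(species = character(),
                                                      gene = character(),
                                                      after = character())) {
  if (is.null(events)) {
    cdsLen <- 3L * as.integer(repeatUnitLengthAa) * as.integer(repeatCopies) + 6L
    events <- if (identical(tree, defaultTree())) .defaultEvents(cdsLen) else
      .defaultEvents(cdsLen)[0, , drop = FALSE]
  }
  new("SimulationConfig",
      seed = as.integer(seed),
      repeatUnitLengthAa = as.integer(repeatUnitLengthAa),
      repeatCopies = as.integer(repeatCopies),
      unitDivergence = unitDivergence,
      subRate = subRate,
      flankLengthNt = as.integer(flankLengthNt),
      flankingGenes = flankingGenes,
      geneName = geneName,
      tree = tree,
      events = events,
      dropGenes = dropGenes,
      insertGenes = insertGenes)
}

# amino acids and a codon choice table derived from the standard code
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

.codonsFor <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Build the intact ancestral gene
#'
#' Generates the ancestral repeat-rich gene: a random repeat unit of
#' `repeatUnitLengthAa` canonical residues, tandem-arrayed `repeatCopies`
#' times with light per-copy divergence, back-translated codon by codon
#' (sense codons only, so the CDS contains no internal in-frame stop),
#' prefixed with ATG and terminated by a single stop codon.
#'
#' @param config a [SimulationConfig-class].
#' @return A list with elements `cds` ([Biostrings::DNAString]), `protein`
#'   ([Biostrings::AAString]) and `unit` (character; the master repeat
#'   unit).
#' @export
#' @examples
#' g <- buildIntactGene(simulationConfig(repeatUnitLengthAa = 20L,
#'                                       repeatCopies = 5L))
#' length(g$cds)  # 3 * (20 * 5) + 6
buildIntactGene <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  unit <- sample(.AA20, config@repeatUnitLengthAa, replace = TRUE)
  copies <- lapply(seq_len(config@repeatCopies), function(i) {
    u <- unit
    hit <- runif(length(u)) < config@unitDivergence
    if (any(hit)) {
      u[hit] <- vapply(u[hit], function(a)
        sample(setdiff(.AA20, a), 1L), character(1))
    }
    u
  })
  aa <- c("M", unlist(copies))
  tab <- .codonsFor()
  codons <- vapply(aa, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1))
  codons[1] <- "ATG"  # fixed initiator codon
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  protein <- paste(aa, collapse = "")
  expectLen <- 3L * config@repeatUnitLengthAa * config@repeatCopies + 6L
  stopifnot(nchar(cds) == expectLen)
  list(cds = Biostrings::DNAString(cds),
       protein = Biostrings::AAString(protein),
       unit = paste(unit, collapse = ""))
}

# is the 3-character codon (vector of single chars) a stop codon?
.isStop <- function(codon) paste(codon, collapse = "") %in% .STOP_CODONS

#' Evolve the ancestral gene along the species tree
#'
#' Applies i.i.d. per-site substitutions on every branch (probability
#' `subRate * branch length`, uniform over the three alternative
#' nucleotides) and the configured inactivating events on their branches;
#' both are inherited by all descendants. Substitutions never touch
#' injected-event sites or the start codon, and on branches leading to at
#' least one intact tip a substitution that would create an in-frame stop
#' (or destroy the terminal stop) is redrawn, so stochastic noise cannot
#' mimic a declared inactivating event.
#'
#' @param ancestralCds [Biostrings::DNAString] (or string) ancestral CDS.
#' @param config a [SimulationConfig-class]; its `tree` and `events` drive
#'   the evolution.
#' @return A list with elements `genomic` (per-tip loci with random
#'   untranslated flanks, [Biostrings::DNAStringSet]), `cds` (per-tip
#'   evolved CDS region, no flanks), `tree` (labeled `phylo`) and `truth`
#'   (the ground-truth table; see [GeneLossSim-class]).
#' @export
evolveOnTree <- function(ancestralCds, config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed + 1L)
  tree <- .labelTree(ape::read.tree(text = config@tree))
  if (anyDuplicated(tree$tip.label)) stop("tree tips must be uniquely named")
  L <- nchar(as.character(ancestralCds))
  ev <- config@events
  if (nrow(ev)) {
    labs <- .nodeLabels(tree)
    bad <- setdiff(ev$branch, labs)
    if (length(bad))
      stop(sprintf("event branch '%s' does not exist in the tree", bad[1]))
    if (any(ev$offsetNt + ifelse(ev$kind == "insertion", 0L, ev$lengthNt) > L))
      stop("event extends beyond the CDS end")
  }

  # frozen ancestral positions: start codon and all event footprints
  frozen <- rep(FALSE, L)
  frozen[1:3] <- TRUE
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "insertion") {
        frozen[ev$offsetNt[i] + 1L] <- TRUE
      } else {
        frozen[(ev$offsetNt[i] + 1L):(ev$offsetNt[i] + ev$lengthNt[i])] <- TRUE
      }
    }
  }

  # pseudogene tips = tips below any event branch
  eventDesc <- list()
  pseudoTips <- character()
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      d <- .descendantTips(tree, .nodeNumber(tree, ev$branch[i]))
      eventDesc[[i]] <- d
      pseudoTips <- union(pseudoTips, d)
    }
  }
  intactTips <- setdiff(tree$tip.label, pseudoTips)

  nt <- ape::Ntip(tree)
  labels <- .nodeLabels(tree)
  # per-node sequence as a character vector in ancestral coordinates:
  # "" = deleted position, multi-character = insertion before that base
  seqs <- vector("list", nt + tree$Nnode)
  seqs[[.rootNode(tree)]] <- .chars(ancestralCds)

  preEdges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(preEdges))) {
    parent <- preEdges[k, 1]; child <- preEdges[k, 2]
    blen <- tree$edge.length[which(tree$edge[, 1] == parent &
                                     tree$edge[, 2] == child)]
    s <- seqs[[parent]]
    childTips <- .descendantTips(tree, child)
    protectFrame <- any(childTips %in% intactTips)

    # substitutions on this branch
    p <- config@subRate * blen
    elig <- which(nchar(s) == 1L & !frozen)
    if (p > 0 && length(elig)) {
      hit <- elig[runif(length(elig)) < p]
      for (pos in hit) {
        alts <- sample(setdiff(.NUCS, s[pos]))
        if (protectFrame) {
          # keep intact lineages free of spurious in-frame stops and keep
          # their terminal stop a stop
          codon0 <- (pos - 1L) %/% 3L
          idx <- (codon0 * 3L + 1L):(codon0 * 3L + 3L)
          terminal <- codon0 == (L %/% 3L - 1L)
          chosen <- NA_character_
          for (a in alts) {
            cand <- s[idx]
            cand[pos - codon0 * 3L] <- a
            ok <- if (terminal) .isStop(cand) else !.isStop(cand)
            if (ok) { chosen <- a; break }
          }
          if (!is.na(chosen)) s[pos] <- chosen
        } else {
          s[pos] <- alts[1]
        }
      }
    }

    # injected events assigned to this branch
    if (nrow(ev)) {
      here <- which(ev$branch == labels[child])
      for (i in here) {
        off <- ev$offsetNt[i]; len <- ev$lengthNt[i]
        if (ev$kind[i] == "deletion") {
          s[(off + 1L):(off + len)] <- ""
        } else if (ev$kind[i] == "insertion") {
          ins <- paste(sample(.NUCS, len, replace = TRUE), collapse = "")
          s[off + 1L] <- paste0(ins, s[off + 1L])
        } else {  # nonsense: overwrite the codon with TAA
          s[(off + 1L):(off + 3L)] <- c("T", "A", "A")
        }
      }
    }
    seqs[[child]] <- s
  }

  tipCds <- vapply(seq_len(nt), function(i) paste(seqs[[i]], collapse = ""),
                   character(1))
  names(tipCds) <- tree$tip.label
  flk <- config@flankLengthNt
  genomic <- vapply(tree$tip.label, function(tp) {
    up <- paste(sample(.NUCS, flk, replace = TRUE), collapse = "")
    dn <- paste(sample(.NUCS, flk, replace = TRUE), collapse = "")
    paste0(up, tipCds[[tp]], dn)
  }, character(1))

  truth <- list(
    tips = data.frame(
      species = tree$tip.label,
      status = ifelse(tree$tip.label %in% pseudoTips, "pseudogene", "intact"),
      stringsAsFactors = FALSE),
    events = if (nrow(ev)) {
      data.frame(ev,
                 descendants = vapply(eventDesc, paste, character(1),
                                      collapse = ","),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(branch = character(), kind = character(),
                 offsetNt = integer(), lengthNt = integer(),
                 descendants = character(), stringsAsFactors = FALSE)
    },
    lossBranch = if (nrow(ev)) {
      # the most ancestral event branch (largest descendant set)
      ev$branch[which.max(lengths(eventDesc))]
    } else NA_character_
  )

  list(genomic = Biostrings::DNAStringSet(genomic),
       cds = Biostrings::DNAStringSet(tipCds),
       tree = tree,
       truth = truth)
}

#' Emit per-species gene-order tables
#'
#' Builds the marker-gene order around the focal gene for every tip of the
#' configured tree: the flanking genes with the focal gene inserted between
#' the upstream block (`PARP10`, `PLEC`, `MACF1CTL`) and the downstream
#' block (`NRBP2`, `PUF60`), minus per-species dropped genes, plus
#' per-species inserted genes.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame with columns `species`, `unit`, `gene`, `position`
#'   (1-based ordinal), `strand`.
#' @export
#' @examples
#' head(emitLocusTables(simulationConfig()), 5)
emitLocusTables <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  tree <- .labelTree(ape::read.tree(text = config@tree))
  downstream <- intersect(c("NRBP2", "PUF60"), config@flankingGenes)
  upstream <- setdiff(config@flankingGenes, downstream)
  template <- c(upstream, config@geneName, downstream)
  strands <- setNames(rep("+", length(template)), template)
  strands[intersect(c("PARP10", "NRBP2"), template)] <- "-"

  rows <- lapply(tree$tip.label, function(sp) {
    genes <- template
    drop <- c(config@dropGenes[["*"]], config@dropGenes[[sp]])
    genes <- setdiff(genes, drop)
    ins <- config@insertGenes
    if (nrow(ins)) {
      ins <- ins[ins$species == sp, , drop = FALSE]
      for (i in seq_len(nrow(ins))) {
        at <- match(ins$after[i], genes)
        if (is.na(at)) stop(sprintf(
          "insertGenes: anchor gene '%s' absent in species '%s'",
          ins$after[i], sp))
        genes <- append(genes, ins$gene[i], after = at)
      }
    }
    data.frame(species = sp, unit = "locus_1", gene = genes,
               position = seq_along(genes),
               strand = ifelse(genes %in% names(strands),
                               strands[genes], "+"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  geneOrderTable(tab)  # validates (duplicate ordinals etc.)
}

#' Run the full simulation
#'
#' Builds the ancestral gene, evolves it along the tree, emits gene-order
#' tables and assembles the ground truth. With `outdir` set, writes
#' `genomic.fasta`, `cds.fasta`, `protein.fasta`, `tree.nwk`,
#' `gene_orders.tsv` and `truth.json`; identical configs (including the
#' seed) give byte-identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param outdir optional output directory.
#' @return A [GeneLossSim-class] object (invisibly when writing).
#' @export
#' @examples
#' sim <- simulateGeneLoss(simulationConfig(repeatUnitLengthAa = 15L,
#'                                          repeatCopies = 10L))
#' truthTable(sim)$lossBranch
simulateGeneLoss <- function(config = simulationConfig(), outdir = NULL) {
  gene <- buildIntactGene(config)
  evo <- evolveOnTree(gene$cds, config)
  orders <- emitLocusTables(config)
  sim <- new("GeneLossSim",
             config = config,
             tree = evo$tree,
             ancestralCds = gene$cds,
             ancestralProtein = gene$protein,
             genomic = evo$genomic,
             cds = evo$cds,
             geneOrders = orders,
             truth = evo$truth)
  if (!is.null(outdir)) {
    writeSimulation(sim, outdir)
    return(invisible(sim))
  }
  sim
}

#' Write a simulated dataset to disk
#'
#' @param sim a [GeneLossSim-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "GeneLossSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim@genomic, file.path(dir, "genomic.fasta"))
  Biostrings::writeXStringSet(sim@cds, file.path(dir, "cds.fasta"))
  prot <- Biostrings::AAStringSet(setNames(as.character(sim@ancestralProtein),
                                           "ancestral"))
  Biostrings::writeXStringSet(prot, file.path(dir, "protein.fasta"))
  writeLines(ape::write.tree(sim@tree), file.path(dir, "tree.nwk"))
  write.table(sim@geneOrders, file.path(dir, "gene_orders.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(dir)
}
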
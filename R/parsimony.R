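# maximum-parsimony gain/loss reconstruction on a rooted species tree
# (unordered states, polytomies allowed) and calibration-based dating

#' Read and validate a rooted species tree
#'
#' Parses Newick via \pkg{ape}, checks tip uniqueness and labels every
#' internal node (existing labels are kept, unlabeled nodes get
#' `N<number>`), so branches can be addressed by the label of the node
#' below them.
#'
#' @param text Newick string (use `file` for a path instead).
#' @param file path to a Newick file.
#' @return A labeled `phylo` object.
#' @export
#' @examples
#' tr <- readSpeciesTree("((A,B),C);")
#' tr$node.label
readSpeciesTree <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file) else
    ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  .labelTree(tree)
}

#' Maximum-parsimony ancestral states for an unordered character
#'
#' Bottom-up pass over the rooted tree computing per-node candidate state
#' sets and the minimal number of state changes (unordered states; at a
#' polytomy the states kept are those shared by the largest number of
#' children, and the change count grows by the number of children not
#' sharing them — the n-ary generalization of the intersection/union
#' rule). A top-down pass then fixes one minimal labeling; when several
#' exist the reported labeling prefers ancestral presence (state `"1"`)
#' and the ambiguity flag is set.
#'
#' @param tree labeled `phylo` (see [readSpeciesTree()]) or Newick string.
#' @param tipStates named vector of tip states (e.g. `0` absent, `1`
#'   present, `2` two copies); coerced to character. A missing or `"?"`
#'   state is treated as any state with a warning (error when
#'   `strict = TRUE`).
#' @param characterId name of the character, for reporting.
#' @param preferState state preferred when a choice among minimal
#'   labelings exists.
#' @param strict error (instead of warn) on missing tip states.
#' @return A [GainLossFit-class].
#' @export
#' @examples
#' fit <- fitchParsimony("((A,B)ab,(C,D)cd)r;",
#'                       c(A = 1, B = 1, C = 0, D = 0))
#' eventCount(fit)
#' events(fit)
fitchParsimony <- function(tree, tipStates, characterId = "gene",
                           preferState = "1", strict = FALSE) {
  if (is.character(tree)) tree <- readSpeciesTree(tree)
  tree <- .labelTree(tree)
  nt <- ape::Ntip(tree)
  labels <- .nodeLabels(tree)
  tipStates <- setNames(as.character(tipStates), names(tipStates))
  missing <- setdiff(tree$tip.label, names(tipStates))
  unknown <- union(missing,
                   names(tipStates)[is.na(tipStates) | tipStates == "?"])
  unknown <- intersect(unknown, tree$tip.label)
  if (length(unknown)) {
    if (strict) stop("missing state for tip(s): ",
                     paste(unknown, collapse = ", "))
    warning("tip(s) with unknown state treated as any state: ",
            paste(unknown, collapse = ", "))
  }
  alphabet <- sort(unique(stats::na.omit(
    tipStates[tipStates != "?" & names(tipStates) %in% tree$tip.label])))
  if (!length(alphabet)) stop("no informative tip states")

  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) {
    tp <- tree$tip.label[i]
    sets[[i]] <- if (tp %in% unknown) alphabet else tipStates[[tp]]
  }

  # bottom-up: keep states with the maximal child vote count
  changes <- 0L
  for (node in .postorderNodes(tree)) {
    kids <- .children(tree, node)
    votes <- table(unlist(lapply(kids, function(k) sets[[k]])))
    kmax <- max(votes)
    sets[[node]] <- sort(names(votes)[votes == kmax])
    changes <- changes + (length(kids) - kmax)
  }

  # top-down: parent state when possible, else the preferred state
  pick <- function(set, parentState) {
    if (!is.null(parentState) && parentState %in% set) return(parentState)
    if (preferState %in% set) preferState else set[1]
  }
  states <- character(nt + tree$Nnode)
  root <- .rootNode(tree)
  ambiguous <- length(sets[[root]]) > 1L
  states[root] <- pick(sets[[root]], NULL)
  preEdges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (k in seq_len(nrow(preEdges))) {
    parent <- preEdges[k, 1]; child <- preEdges[k, 2]
    if (!(states[parent] %in% sets[[child]]) && length(sets[[child]]) > 1L)
      ambiguous <- TRUE
    states[child] <- pick(sets[[child]], states[parent])
  }
  names(states) <- labels
  names(sets) <- labels

  ev <- list()
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c2 <- tree$edge[k, 2]
    if (states[p] != states[c2])
      ev[[length(ev) + 1L]] <- data.frame(branch = labels[c2],
                                          from = unname(states[p]),
                                          to = unname(states[c2]),
                                          stringsAsFactors = FALSE)
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(branch = character(), from = character(), to = character(),
               stringsAsFactors = FALSE)
  if (nrow(ev) != changes)
    stop("internal error: labeling does not achieve the minimal change count")
  new("GainLossFit", character_ = characterId, tree = tree,
      stateSets = sets, states = states,
      eventCount = as.integer(changes), events = ev,
      ambiguous = ambiguous)
}

#' Map the origin branch of a character
#'
#' The origin is placed on the stem branch of the smallest clade containing
#' every species carrying the character, provided that clade contains no
#' species lacking it; otherwise the presence pattern is not consistent
#' with a single gain and a conflict is reported (use [fitchParsimony()]
#' for the multi-event reconstruction).
#'
#' @param tree labeled `phylo` or Newick string.
#' @param presentTips species carrying the character (absence is assumed
#'   for all other tips, including outgroups).
#' @return list with `branch` (label of the node below the origin branch,
#'   `NA` on conflict), `cladeTips`, and `conflict`.
#' @export
mapOrigin <- function(tree, presentTips) {
  if (is.character(tree)) tree <- readSpeciesTree(tree)
  tree <- .labelTree(tree)
  bad <- setdiff(presentTips, tree$tip.label)
  if (length(bad)) stop("unknown tip(s): ", paste(bad, collapse = ", "))
  if (!length(presentTips)) stop("no presence tips given")
  labels <- .nodeLabels(tree)
  if (length(presentTips) == 1L) {
    return(list(branch = presentTips, cladeTips = presentTips,
                conflict = FALSE))
  }
  mrca <- ape::getMRCA(tree, presentTips)
  clade <- .descendantTips(tree, mrca)
  if (!setequal(clade, presentTips)) {
    return(list(branch = NA_character_, cladeTips = clade, conflict = TRUE))
  }
  list(branch = labels[mrca], cladeTips = clade, conflict = FALSE)
}

# node ages from a calibration table (tipA, tipB, ageMya): the MRCA of each
# pair gets the stated age; tips have age 0
.nodeAges <- function(tree, calibrations) {
  ages <- setNames(rep(NA_real_, ape::Ntip(tree) + tree$Nnode),
                   .nodeLabels(tree))
  ages[tree$tip.label] <- 0
  for (i in seq_len(nrow(calibrations))) {
    node <- ape::getMRCA(tree, c(calibrations$tipA[i], calibrations$tipB[i]))
    ages[.nodeLabels(tree)[node]] <- calibrations$ageMya[i]
  }
  ages
}

#' Date an event branch from node-age calibrations
#'
#' An event on a branch happened between the age of the node below the
#' branch (e.g. the crown divergence of the affected clade) and the age of
#' the node above it (the divergence from the sister lineage). Ages come
#' from a calibration table and are never computed from sequences. Shared
#' mutations whose carrier set equals the tips below the branch are listed
#' as supporting evidence.
#'
#' @param tree labeled `phylo` or Newick string.
#' @param branch label of the node below the event branch.
#' @param calibrations data.frame `tipA`, `tipB`, `ageMya`: the most recent
#'   common ancestor of each pair has the given age (in million years).
#' @param sharedMutations optional data.frame from
#'   [findSharedMutations()].
#' @return list with `branch`, `lowerMya` (age of the node below; 0 for a
#'   tip), `upperMya` (age of the node above), and `support` (rows of
#'   `sharedMutations` carried by exactly the tips below the branch).
#'   An uncalibrated endpoint yields `NA` on that side.
#' @export
#' @examples
#' cal <- data.frame(tipA = c("hippo", "whale"),
#'                   tipB = c("whale", "dolphin"),
#'                   ageMya = c(54, 33))
#' dateEvent("(((whale,dolphin)cet,hippo)whip,cattle)r;", "cet", cal)
dateEvent <- function(tree, branch, calibrations, sharedMutations = NULL) {
  if (is.character(tree)) tree <- readSpeciesTree(tree)
  tree <- .labelTree(tree)
  node <- .nodeNumber(tree, branch)
  parent <- .parent(tree, node)
  if (is.na(parent)) stop("the root has no branch above it to date")
  ages <- .nodeAges(tree, calibrations)
  lower <- unname(ages[.nodeLabels(tree)[node]])
  upper <- unname(ages[.nodeLabels(tree)[parent]])
  if (!is.na(lower) && !is.na(upper) && lower > upper)
    stop("calibrations are inconsistent: node below older than node above")
  support <- NULL
  if (!is.null(sharedMutations) && nrow(sharedMutations)) {
    below <- sort(.descendantTips(tree, node))
    keep <- vapply(sharedMutations$carrierSpecies, function(cs)
      setequal(cs, below), logical(1))
    support <- sharedMutations[keep, , drop = FALSE]
  }
  list(branch = branch, lowerMya = lower, upperMya = upper,
       support = support)
}
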
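# shared internal helpers (tree bookkeeping, small validators)

# split a sequence-like object into single characters
.chars <- function(x) strsplit(as.character(x), "")[[1]]

# label every node of a phylo tree uniquely: tips keep their names,
# internal nodes keep existing labels, unlabeled ones get "N<number>"
.labelTree <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", nn)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("N", which(empty) + nt)
  if (anyDuplicated(c(tree$tip.label, lab)))
    stop("node labels must be unique across tips and internal nodes")
  tree$node.label <- lab
  tree
}

# all node labels indexed by ape node number (tips first)
.nodeLabels <- function(tree) c(tree$tip.label, tree$node.label)

# ape node number for a label (tip or internal); error when absent
.nodeNumber <- function(tree, label) {
  idx <- match(label, .nodeLabels(tree))
  if (is.na(idx)) stop(sprintf("node '%s' not found in tree", label))
  idx
}

# tip labels descending from (and including, if tip) a node number
.descendantTips <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .descendantTips, tree = tree), use.names = FALSE)
}

# children node numbers of a node
.children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# parent node number of a node (NA for the root)
.parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p)) p else NA_integer_
}

# internal nodes in postorder (children before parents)
.postorderNodes <- function(tree) {
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  unique(edges[, 1])
}

.rootNode <- function(tree) ape::Ntip(tree) + 1L

# stop() with position info when x contains characters outside `allowed`
.checkAlphabet <- function(x, allowed, what = "sequence") {
  ch <- .chars(toupper(x))
  bad <- which(!ch %in% allowed)
  if (length(bad))
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, ch[bad[1]], bad[1]))
  invisible(ch)
}

.IUPAC_DNA <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V")

# empty mutation-call data.frame with the canonical columns
.emptyCalls <- function() {
  data.frame(kind = character(), refCoord = integer(),
             lengthNt = integer(), carrier = character(),
             stringsAsFactors = FALSE)
}
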
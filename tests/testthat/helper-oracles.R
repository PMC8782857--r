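# independent oracles and small fixtures used across the test files

# hand-typed standard genetic code (independent of the implementation path)
.ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleTranslate <- function(s) {
  n <- nchar(s) %/% 3L
  starts <- (seq_len(n) - 1L) * 3L + 1L
  paste(unname(.ORACLE_CODE[substring(s, starts, starts + 2L)]),
        collapse = "")
}

# brute-force affine-gap global alignment score (Gotoh, quadratic space);
# gap of length L costs open + L * ext
oracleGlobalScore <- function(a, b, match = 5, mismatch = -4,
                              open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consume a)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consume b)
  M[1, 1] <- 0
  if (n) Ix[2:(n + 1L), 1] <- -(open + ext * seq_len(n))
  if (m) Iy[1, 2:(m + 1L)] <- -(open + ext * seq_len(m))
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                     Iy[i - 1L, j - 1L]) + s
      Ix[i, j] <- max(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext,
                      Iy[i - 1L, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext,
                      Ix[i, j - 1L] - open - ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

# naive O(n^2) dot-plot marks: marks[i, j] (1-based window starts) TRUE iff
# the window sum of matrix scores along the diagonal reaches the threshold
oracleDotplotMarks <- function(s, window = 10L, threshold = 23,
                               mat = NULL) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- get("BLOSUM62", envir = e)
  }
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  lim <- n - window + 1L
  marks <- matrix(FALSE, lim, lim)
  for (i in seq_len(lim)) {
    for (j in seq_len(lim)) {
      sc <- 0
      for (k in 0:(window - 1L)) sc <- sc + mat[ch[i + k], ch[j + k]]
      marks[i, j] <- sc >= threshold
    }
  }
  marks
}

# convert a DotPlot's segments back into the marked-window matrix
dotplotSegmentsToMarks <- function(dp) {
  n <- dp@seqLength
  w <- dp@window
  lim <- n - w + 1L
  marks <- matrix(FALSE, lim, lim)
  seg <- matchSegments(dp)
  for (r in seq_len(nrow(seg))) {
    span <- seg$length[r] - w          # window starts: start .. start+span
    i <- seg$start1[r] + 1L + 0:span
    j <- seg$start2[r] + 1L + 0:span
    marks[cbind(i, j)] <- TRUE
  }
  marks
}

# exhaustive minimal change count over all internal labelings
oracleMinChanges <- function(tree, tipStates) {
  tipStates <- as.character(tipStates[tree$tip.label])
  alphabet <- sort(unique(tipStates))
  nn <- tree$Nnode
  nt <- ape::Ntip(tree)
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), nn), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tipStates, unlist(grid[r, ], use.names = FALSE))
    best <- min(best, sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]]))
  }
  best
}

# scaled-down simulation used throughout the suite: same 15-taxon tree and
# stem events as the default scenario, shorter repeat array for speed
testSimConfig <- function(seed = 1L, ...) {
  simulationConfig(seed = seed, repeatUnitLengthAa = 15L,
                   repeatCopies = 20L, ...)
}

cetaceanTips <- function() {
  c("blue_whale", "minke_whale", "sperm_whale", "baiji", "narwhal",
    "beluga", "vaquita", "finless_porpoise", "white_sided_dolphin",
    "pilot_whale", "orca", "bottlenose_dolphin")
}

# random DNA / protein helpers
randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
randProtein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}

emptyEvents <- function() {
  data.frame(branch = character(), kind = character(),
             offsetNt = integer(), lengthNt = integer(),
             stringsAsFactors = FALSE)
}
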
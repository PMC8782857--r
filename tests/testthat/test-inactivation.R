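test_that("global alignment handles identity and a single gap", {
  a <- alignGlobal("ACGTACGT", "ACGTACGT")
  expect_equal(score(a), 5 * 8)
  expect_false(grepl("-", alignedRef(a), fixed = TRUE))
  expect_false(grepl("-", alignedQuery(a), fixed = TRUE))
  b <- alignGlobal("ACGT", "AGT")
  expect_equal(alignedRef(b), "ACGT")
  expect_equal(alignedQuery(b), "A-GT")
  expect_equal(score(b), 3 * 5 - (10 + 0.5))
  expect_error(alignGlobal("", "ACGT"), "non-empty")
  expect_error(alignGlobal(strrep("A", 50001), "ACGT"), "cap")
})

test_that("alignment scores match the brute-force affine-gap oracle", {
  set.seed(13)
  for (rep in 1:12) {
    n <- sample(30:120, 1)
    a <- randDna(n)
    b <- if (rep %% 2 == 0) randDna(sample(30:120, 1)) else {
      # homologous pair: mutate and indel the first sequence
      v <- strsplit(a, "")[[1]]
      hit <- runif(n) < 0.1
      v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), TRUE)
      cut <- sort(sample(n, 2))
      paste(v[-(cut[1]:(cut[1] + 1))], collapse = "")
    }
    expect_equal(score(alignGlobal(a, b)), oracleGlobalScore(a, b),
                 label = sprintf("replicate %d", rep))
  }
})

test_that("gap runs are left-normalized to canonical coordinates", {
  # deletion inside a homopolymer must report the 5'-most position
  ref <- "ATGCAAAAATTTGCGTTTTAA"
  qry <- "ATGCAAAATTTGCGTTTTAA"   # one A of the run removed
  aln <- alignGlobal(ref, qry)
  calls <- callMutations(aln)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$kind, "frameshift_deletion")
  expect_equal(calls$refCoord, 4L)  # first A of the run
})

test_that("frameshifts and premature stops are called at reference coordinates", {
  g <- buildIntactGene(simulationConfig(seed = 31L, repeatUnitLengthAa = 15L,
                                        repeatCopies = 20L))
  ref <- as.character(g$cds)
  # identical sequences: no calls
  expect_equal(nrow(callMutations(alignGlobal(ref, ref))), 0L)
  # single 1-nt deletion at offset 300
  qry <- paste0(substr(ref, 1, 300), substr(ref, 302, nchar(ref)))
  calls <- callMutations(alignGlobal(ref, qry, queryId = "whale"))
  fs <- calls[calls$kind == "frameshift_deletion", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$lengthNt, 1L)
  expect_lte(abs(fs$refCoord - 300L), 3L)  # left-shift within one codon
  expect_equal(fs$carrier, "whale")
  # in-frame 3-nt deletion is not a frameshift
  qry3 <- paste0(substr(ref, 1, 300), substr(ref, 304, nchar(ref)))
  calls3 <- callMutations(alignGlobal(ref, qry3))
  expect_equal(nrow(calls3[grepl("frameshift", calls3$kind), ]), 0L)
  # nonsense substitution: premature stop in the query's own frame
  qry4 <- paste0(substr(ref, 1, 207), "TGA", substr(ref, 211, nchar(ref)))
  calls4 <- callMutations(alignGlobal(ref, qry4))
  expect_equal(calls4$kind, "premature_stop")
  expect_equal(calls4$refCoord, 207L)
  # the reference must be a valid CDS
  expect_error(callMutations(alignGlobal("CCCTTTAAA", "CCCTTTAAA")),
               "valid CDS")
})

test_that("premature stops follow the query frame after upstream indels", {
  g <- buildIntactGene(simulationConfig(seed = 32L, repeatUnitLengthAa = 15L,
                                        repeatCopies = 20L))
  ref <- as.character(g$cds)
  # 1-nt deletion at 150 shifts the query frame; place a stop that is
  # in-frame only in the shifted query frame: query positions 300..302
  qry <- paste0(substr(ref, 1, 150), substr(ref, 152, 301), "TAA",
                substr(ref, 305, nchar(ref)))
  calls <- callMutations(alignGlobal(ref, qry))
  stops <- calls[calls$kind == "premature_stop", ]
  expect_gte(nrow(stops), 1L)
  expect_true(any(abs(stops$refCoord - 301L) <= 3L))
})

test_that("frame bookkeeping balances calls against net indel length", {
  g <- buildIntactGene(simulationConfig(seed = 33L, repeatUnitLengthAa = 15L,
                                        repeatCopies = 20L))
  ref <- as.character(g$cds)
  # deletion of 1 at 120 and insertion of 1 at 400: distant compensated
  # pair, both reported individually, net frame restored
  qry <- paste0(substr(ref, 1, 120), substr(ref, 122, 400), "G",
                substr(ref, 401, nchar(ref)))
  calls <- callMutations(alignGlobal(ref, qry))
  fs <- calls[grepl("frameshift", calls$kind), ]
  expect_equal(nrow(fs), 2L)
  expect_setequal(fs$kind, c("frameshift_deletion", "frameshift_insertion"))
  signed <- ifelse(fs$kind == "frameshift_insertion", 1L, -1L) * fs$lengthNt
  expect_true(attr(calls, "netFrameRestored"))
  expect_equal(sum(signed) %% 3L, 0L)
})

test_that("alignment slippage between intact orthologs yields no calls", {
  for (seed in 1:5) {
    sim <- simulateGeneLoss(testSimConfig(seed = seed))
    ref <- as.character(sim@cds[["human"]])
    for (sp in c("cattle", "hippo")) {
      aln <- alignGlobal(ref, as.character(sim@cds[[sp]]),
                         refId = "human", queryId = sp)
      expect_equal(nrow(callMutations(aln)), 0L,
                   label = sprintf("seed %d, %s", seed, sp))
    }
  }
})

test_that("shared mutations merge by kind, length and position", {
  mk <- function(sp, coord, kind = "frameshift_deletion", len = 1L) {
    d <- data.frame(kind = kind, refCoord = coord, lengthNt = len,
                    carrier = sp, stringsAsFactors = FALSE)
    attr(d, "reference") <- "refgene"
    d
  }
  clade <- paste0("sp", 1:12)
  calls <- c(lapply(clade, mk, coord = 300L),
             list(mk("out1", 500L), mk("out2", 910L, kind = "premature_stop",
                                       len = 3L)))
  sh <- findSharedMutations(calls)
  main <- sh[sh$refCoord == 300L, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$nCarriers, 12L)
  expect_setequal(main$carrierSpecies[[1]], clade)
  # disjoint coordinates under tolerance 0 are never merged
  sh2 <- findSharedMutations(list(mk("a", 100L), mk("b", 101L)),
                             toleranceNt = 0L)
  expect_equal(nrow(sh2), 2L)
  # tolerance 1 merges them at the left-most coordinate
  sh3 <- findSharedMutations(list(mk("a", 100L), mk("b", 101L)),
                             toleranceNt = 1L)
  expect_equal(nrow(sh3), 1L)
  expect_equal(sh3$refCoord, 100L)
  # mixed references are rejected
  bad <- mk("c", 100L)
  attr(bad, "reference") <- "other"
  expect_error(findSharedMutations(list(mk("a", 100L), bad)),
               "different references")
})

test_that("carrier sets of injected events equal the truth descendant sets", {
  sim <- simulateGeneLoss(testSimConfig(seed = 8L))
  ref <- as.character(sim@cds[["human"]])
  others <- setdiff(names(sim@cds), "human")
  calls <- lapply(others, function(sp)
    callMutations(alignGlobal(ref, as.character(sim@cds[[sp]]),
                              refId = "human", queryId = sp)))
  sh <- findSharedMutations(calls)
  tt <- truthTable(sim)
  del <- tt$events[tt$events$kind == "deletion", ]
  hit <- sh[sh$kind == "frameshift_deletion" & sh$lengthNt == del$lengthNt &
              abs(sh$refCoord - del$offsetNt) <= 3L, ]
  expect_equal(nrow(hit), 1L)
  expect_setequal(hit$carrierSpecies[[1]],
                  strsplit(del$descendants, ",")[[1]])
})

test_that("status classification applies the truncation rule strictly", {
  p <- new("CodingPrediction", species = "whale", gene = "EPPK1",
           startOffset = 0L, protein = strrep("A", 69), lengthAa = 69L,
           stopFound = TRUE, stopOffset = 207L, nonOrthologousStart = FALSE)
  calls <- data.frame(kind = "frameshift_deletion", refCoord = 300L,
                      lengthNt = 1L, carrier = "whale")
  st <- classifyStatus(p, calls, referenceLengthAa = 5088L)
  expect_equal(statusCall(st), "pseudogene")
  expect_equal(predictedFraction(st), 69 / 5088, tolerance = 1e-12)
  # full length, no calls: intact
  pFull <- new("CodingPrediction", species = "h", gene = "g",
               startOffset = 0L, protein = strrep("A", 100), lengthAa = 100L,
               stopFound = TRUE, stopOffset = 300L,
               nonOrthologousStart = FALSE)
  none <- calls[0, ]
  expect_equal(statusCall(classifyStatus(pFull, none, 100L)), "intact")
  # exactly at the threshold with no calls: intact (strict inequality)
  pHalf <- new("CodingPrediction", species = "h", gene = "g",
               startOffset = 0L, protein = strrep("A", 50), lengthAa = 50L,
               stopFound = TRUE, stopOffset = 150L,
               nonOrthologousStart = FALSE)
  expect_equal(statusCall(classifyStatus(pHalf, none, 100L)), "intact")
  # just below: pseudogene
  pLess <- new("CodingPrediction", species = "h", gene = "g",
               startOffset = 0L, protein = strrep("A", 49), lengthAa = 49L,
               stopFound = TRUE, stopOffset = 147L,
               nonOrthologousStart = FALSE)
  expect_equal(statusCall(classifyStatus(pLess, none, 100L)), "pseudogene")
})
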
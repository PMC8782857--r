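test_that("species trees parse, validate and round-trip", {
  tr <- readSpeciesTree("((A,B),C);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 2L)
  expect_true(all(nchar(tr$node.label) > 0))
  # canonical round-trip
  tr2 <- readSpeciesTree(ape::write.tree(tr))
  expect_equal(ape::write.tree(tr2), ape::write.tree(tr))
  expect_error(readSpeciesTree("((A,A),B);"), "duplicate tip")
  expect_error(readSpeciesTree("((A,B,C);"))
})

test_that("a single cetacean-stem loss explains the 15-taxon pattern", {
  tips <- readSpeciesTree(defaultTree())$tip.label
  states <- setNames(rep("0", length(tips)), tips)
  states[c("human", "cattle", "hippo")] <- "1"
  fit <- fitchParsimony(defaultTree(), states, characterId = "EPPK1")
  expect_equal(eventCount(fit), 1L)
  expect_equal(events(fit)$branch, "cetacea")
  expect_equal(events(fit)$from, "1")
  expect_equal(events(fit)$to, "0")
  # uniform states need no event at all
  allOne <- setNames(rep("1", length(tips)), tips)
  expect_equal(eventCount(fitchParsimony(defaultTree(), allOne)), 0L)
})

test_that("event counts equal the exhaustive minimum on random trees", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    states <- setNames(sample(c("0", "1", "2"), n, TRUE), tr$tip.label)
    fit <- fitchParsimony(tr, states)
    expect_equal(eventCount(fit), oracleMinChanges(tr, states),
                 label = sprintf("replicate %d", rep))
    # the reported labeling realizes the count it claims
    expect_equal(nrow(events(fit)), eventCount(fit))
  }
})

test_that("polytomies are handled by the n-ary vote rule", {
  tr <- readSpeciesTree("(A,B,C,D,E)r;")
  fit <- fitchParsimony(tr, c(A = "1", B = "1", C = "1", D = "0", E = "0"))
  expect_equal(eventCount(fit),
               oracleMinChanges(tr, c(A = "1", B = "1", C = "1",
                                      D = "0", E = "0")))
  expect_equal(eventCount(fit), 2L)
})

test_that("event counts are invariant under tip reordering", {
  set.seed(100)
  tr <- ape::rtree(6, rooted = TRUE)
  states <- setNames(sample(c("0", "1"), 6, TRUE), tr$tip.label)
  base <- eventCount(fitchParsimony(tr, states))
  for (i in 1:5)
    expect_equal(eventCount(fitchParsimony(tr, sample(states))), base)
})

test_that("unknown tip states widen to any state with a warning", {
  tr <- readSpeciesTree("((A,B)ab,(C,D)cd)r;")
  expect_warning(fit <- fitchParsimony(tr, c(A = "1", B = "1", C = "0")),
                 "unknown state")
  expect_equal(eventCount(fit), 1L)
  expect_error(fitchParsimony(tr, c(A = "1", B = "1", C = "0"),
                              strict = TRUE), "missing state")
})

test_that("ambiguous reconstructions prefer ancestral presence", {
  tr <- readSpeciesTree("((A,B)ab,(C,D)cd)r;")
  fit <- fitchParsimony(tr, c(A = "1", B = "0", C = "1", D = "0"))
  expect_true(isAmbiguous(fit))
  expect_equal(unname(nodeStates(fit)["r"]), "1")
  expect_equal(eventCount(fit), 2L)
})

test_that("origin maps to the stem of the smallest clade of carriers", {
  tr <- readSpeciesTree(file = system.file("extdata", "vertebrate_tree.nwk",
                                           package = "geneDecay"))
  gnath <- setdiff(tr$tip.label, c("lamprey", "sea_squirt"))
  orig <- mapOrigin(tr, gnath)
  expect_false(orig$conflict)
  expect_equal(orig$branch, "gnathostomata")
  expect_setequal(orig$cladeTips, gnath)
  # single carrier: origin on its terminal branch
  expect_equal(mapOrigin(tr, "human")$branch, "human")
  # two non-sister carriers with absent species in between: conflict
  conf <- mapOrigin(tr, c("human", "zebrafish"))
  expect_true(conf$conflict)
  expect_true(is.na(conf$branch))
  expect_error(mapOrigin(tr, "not_a_tip"), "unknown tip")
})

test_that("event dating brackets the loss between calibrated nodes", {
  tr <- readSpeciesTree(defaultTree())
  cal <- read.table(system.file("extdata", "calibrations.tsv",
                                package = "geneDecay"),
                    header = TRUE, sep = "\t")
  d <- dateEvent(tr, "cetacea", cal)
  expect_equal(d$lowerMya, 33)
  expect_equal(d$upperMya, 54)
  # terminal-branch event: [0, parent age]
  d2 <- dateEvent(tr, "blue_whale", cal)
  expect_equal(d2$lowerMya, 0)
  expect_equal(d2$upperMya, 10)
  # an uncalibrated endpoint is reported as unknown
  d3 <- dateEvent(tr, "delphinidae", cal)
  expect_true(is.na(d3$lowerMya) || is.na(d3$upperMya))
  # shared mutations carried by exactly the clade below support the event
  sh <- data.frame(kind = "frameshift_deletion", refCoord = 300L,
                   lengthNt = 1L, nCarriers = 12L,
                   carriers = paste(cetaceanTips(), collapse = ","))
  sh$carrierSpecies <- list(cetaceanTips())
  d4 <- dateEvent(tr, "cetacea", cal, sharedMutations = sh)
  expect_equal(nrow(d4$support), 1L)
  d5 <- dateEvent(tr, "mysticeti", cal, sharedMutations = sh)
  expect_equal(nrow(d5$support), 0L)
})
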
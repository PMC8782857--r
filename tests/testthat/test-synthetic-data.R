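test_that("intact gene geometry, round-trip translation and determinism", {
  cfg <- simulationConfig(seed = 7L, repeatUnitLengthAa = 60L,
                          repeatCopies = 30L)
  g <- buildIntactGene(cfg)
  expect_equal(length(g$cds), 3L * 60L * 30L + 6L)  # 5406 nt
  expect_equal(nchar(as.character(g$protein)), 1801L)
  # translation of the CDS reproduces the protein exactly (plus stop)
  aa <- translateCds(g$cds)
  expect_equal(substr(aa, 1, nchar(aa) - 1L), as.character(g$protein))
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
  # same seed, byte-identical; different seed differs
  g2 <- buildIntactGene(simulationConfig(seed = 7L, repeatUnitLengthAa = 60L,
                                         repeatCopies = 30L))
  expect_identical(as.character(g$cds), as.character(g2$cds))
  g3 <- buildIntactGene(simulationConfig(seed = 8L, repeatUnitLengthAa = 60L,
                                         repeatCopies = 30L))
  expect_false(identical(as.character(g$cds), as.character(g3$cds)))
})

test_that("default configuration keeps the CDS in the 6-12 kb range", {
  cfg <- simulationConfig()
  len <- 3L * cfg@repeatUnitLengthAa * cfg@repeatCopies + 6L
  expect_gte(len, 6000L)
  expect_lte(len, 12000L)
})

test_that("zero rate and zero events reproduce the ancestor at every tip", {
  cfg <- simulationConfig(seed = 2L, repeatUnitLengthAa = 15L,
                          repeatCopies = 10L, subRate = 0,
                          events = emptyEvents())
  sim <- simulateGeneLoss(cfg)
  anc <- as.character(sim@ancestralCds)
  for (tp in speciesTree(sim)$tip.label)
    expect_identical(as.character(sim@cds[[tp]]), anc)
  expect_true(all(truthTable(sim)$tips$status == "intact"))
})

test_that("stem-branch events are inherited by exactly the clade tips", {
  sim <- simulateGeneLoss(testSimConfig(seed = 3L))
  tt <- truthTable(sim)
  clade <- cetaceanTips()
  for (i in seq_len(nrow(tt$events))) {
    desc <- strsplit(tt$events$descendants[i], ",")[[1]]
    expect_setequal(desc, clade)
  }
  expect_setequal(tt$tips$species[tt$tips$status == "pseudogene"], clade)
  expect_equal(tt$lossBranch, "cetacea")
  # the 1-nt stem deletion shortens every cetacean CDS region by one base
  L <- length(sim@ancestralCds)
  for (tp in clade) expect_equal(nchar(as.character(sim@cds[[tp]])), L - 1L)
  for (tp in setdiff(speciesTree(sim)$tip.label, clade))
    expect_equal(nchar(as.character(sim@cds[[tp]])), L)
})

test_that("intact tips keep full-length open reading frames", {
  sim <- simulateGeneLoss(testSimConfig(seed = 4L))
  ancLen <- nchar(as.character(sim@ancestralProtein))
  o <- orfScan(sim@genomic, as.character(sim@ancestralCds))
  tt <- truthTable(sim)
  for (tp in tt$tips$species[tt$tips$status == "intact"])
    expect_equal(o$table$lengthAa[o$table$species == tp], ancLen)
})

test_that("a terminal-branch nonsense event truncates that tip only", {
  ev <- data.frame(branch = "hippo", kind = "nonsense",
                   offsetNt = 207L, lengthNt = 3L)
  cfg <- simulationConfig(seed = 5L, repeatUnitLengthAa = 15L,
                          repeatCopies = 20L, subRate = 0, events = ev)
  sim <- simulateGeneLoss(cfg)
  o <- orfScan(sim@genomic, as.character(sim@ancestralCds))
  expect_equal(o$table$lengthAa[o$table$species == "hippo"], 69L)
  expect_true(all(o$table$lengthAa[o$table$species != "hippo"] == 301L))
})

test_that("invalid event configurations are rejected", {
  expect_error(simulationConfig(repeatUnitLengthAa = 15L, repeatCopies = 20L,
                                events = data.frame(branch = "cetacea",
                                                    kind = "deletion",
                                                    offsetNt = 2000L,
                                                    lengthNt = 1L)),
               "within the CDS")
  expect_error(simulationConfig(
    repeatUnitLengthAa = 15L, repeatCopies = 20L,
    events = data.frame(branch = c("cetacea", "cetacea"),
                        kind = c("deletion", "deletion"),
                        offsetNt = c(300L, 301L),
                        lengthNt = c(3L, 1L))),
    "overlap")
  expect_error(simulationConfig(events = data.frame(branch = "cetacea",
                                                    kind = "nonsense",
                                                    offsetNt = 208L,
                                                    lengthNt = 3L)),
               "codon boundary")
  # unknown branch is caught at evolution time
  cfg <- simulationConfig(repeatUnitLengthAa = 15L, repeatCopies = 20L,
                          events = data.frame(branch = "no_such_clade",
                                              kind = "deletion",
                                              offsetNt = 10L,
                                              lengthNt = 1L))
  expect_error(simulateGeneLoss(cfg), "does not exist")
})

test_that("gene-order tables follow the configured locus structure", {
  ord <- emitLocusTables(simulationConfig())
  hum <- ord[ord$species == "human", ]
  expect_equal(hum$gene[order(hum$position)],
               c("PARP10", "PLEC", "EPPK1", "NRBP2", "PUF60"))
  # no drops: every species shows the identical full arrangement
  ord2 <- emitLocusTables(simulationConfig(dropGenes = list()))
  orders <- split(ord2$gene[order(ord2$species, ord2$position)],
                  sort(ord2$species))
  expect_equal(length(unique(orders)), 1L)
  expect_true("MACF1CTL" %in% ord2$gene)
  # duplicate ordinal rejected
  bad <- data.frame(species = "x", unit = "u", gene = c("a", "b"),
                    position = c(1L, 1L), strand = "+")
  expect_error(geneOrderTable(bad), "duplicate ordinal")
})

test_that("simulation output files are byte-identical for identical configs", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- simulationConfig(seed = 11L, repeatUnitLengthAa = 15L,
                          repeatCopies = 10L,
                          events = data.frame(branch = "cetacea",
                                              kind = "deletion",
                                              offsetNt = 99L, lengthNt = 1L))
  simulateGeneLoss(cfg, outdir = d1)
  simulateGeneLoss(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = paste("bytes of", f))
  }
})
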
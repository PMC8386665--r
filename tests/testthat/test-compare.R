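test_that("identical molecules give a single full-length block and no events", {
  m <- randMolecule(8000, 1, "a")
  b <- MitoMolecule("b", as.character(m), circular = TRUE)
  bl <- anchorBlocks(m, b)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$width, 8000L)
  expect_identical(bl$strand, "+")
  su <- sharedUnique(bl, 8000L, 8000L)
  expect_identical(su$uniqueA, 0L)
  expect_identical(su$uniqueB, 0L)
  expect_identical(nrow(detectRearrangements(bl, m, b)), 0L)
})

test_that("a molecule versus its reverse complement is one minus-strand block", {
  m <- randMolecule(8000, 2, "a")
  rc <- MitoMolecule("rc", as.character(
    Biostrings::reverseComplement(molSeq(m))), circular = TRUE)
  bl <- anchorBlocks(m, rc)
  expect_identical(nrow(bl), 1L)
  expect_identical(bl$strand, "-")
  expect_identical(bl$width, 8000L)
  ## global orientation flip, not an inversion event
  expect_identical(nrow(detectRearrangements(bl, m, rc)), 0L)
})

test_that("disjoint random molecules share nothing", {
  a <- randMolecule(6000, 3, "a")
  b <- randMolecule(6000, 4, "b")
  bl <- anchorBlocks(a, b)
  su <- sharedUnique(bl, 6000L, 6000L)
  expect_lt(su$shared, 100L)
})

test_that("group A molecules 1a/1b reproduce the shared/unique structure", {
  g <- realizeGenome(mitoProfile("groupA", scale = 0.1), seed = 21)
  m1a <- g$molecules[["molecule 1a"]]
  m1b <- g$molecules[["molecule 1b"]]
  bl <- anchorBlocks(m1a, m1b)
  su <- sharedUnique(bl, length(m1a), length(m1b))
  sharedTruth <- length(m1b) - 980L       # unique-1b spacer at this scale
  expect_lt(abs(su$shared - sharedTruth) / sharedTruth, 0.01)
  expect_lt(abs(su$uniqueA - (length(m1a) - sharedTruth)) / sharedTruth, 0.01)
  ## conservation identities are exact by construction
  expect_identical(su$shared + su$uniqueA, length(m1a))
  expect_identical(su$shared + su$uniqueB, length(m1b))
})

test_that("the translocation fixture yields one event of the planted size", {
  tp <- makeTranslocationPair(seed = 7)
  bl <- anchorBlocks(tp$molA, tp$molB)
  ev <- detectRearrangements(bl, tp$molA, tp$molB)
  tr <- ev[ev$type == "translocation", ]
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$blockLength, 774L)
  expect_identical(tr$flankLen, 40L)
  ## breakpoint flank discovery returns the 40 bp pair
  fl <- breakpointFlanks(tr, tp$molA, tp$molB)
  expect_identical(fl$length, 40L)
  expect_identical(fl$orientation, "direct")
})

test_that("a larger flank is recovered at its own size", {
  tp <- makeTranslocationPair(flankLen = 60L, totalLen = 20000L, seed = 8)
  bl <- anchorBlocks(tp$molA, tp$molB)
  ev <- detectRearrangements(bl, tp$molA, tp$molB)
  tr <- ev[ev$type == "translocation", ]
  expect_identical(tr$blockLength, 774L)
  expect_identical(tr$flankLen, 60L)
})

test_that("an insertion is called on the molecule-2 style fixture", {
  ip <- makeInsertionPair(totalLen = 30000, seed = 8)
  bl <- anchorBlocks(ip$molA, ip$molB)
  ev <- detectRearrangements(bl, ip$molA, ip$molB)
  expect_identical(ev$type, "insertion")
  expect_identical(ev$blockLength, 774L)
  expect_identical(ev$flankLen, 40L)
  ## event with no planted flank: plain insert without repeats
  set.seed(9)
  bg <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  ins <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  a <- MitoMolecule("a", bg, circular = TRUE)
  b <- MitoMolecule("b", paste0(substr(bg, 1, 4000), ins,
                                substr(bg, 4001, 10000)), circular = TRUE)
  ev2 <- detectRearrangements(anchorBlocks(a, b), a, b)
  expect_identical(ev2$type, "insertion")
  expect_true(is.na(ev2$flankLen))
  expect_lte(abs(ev2$blockLength - 600L), 60L)  # anchor resolution
  expect_null(breakpointFlanks(ev2, a, b))
})

test_that("event calls are symmetric up to insertion/deletion duality", {
  ip <- makeInsertionPair(totalLen = 30000, seed = 10)
  evAB <- detectRearrangements(anchorBlocks(ip$molA, ip$molB),
                               ip$molA, ip$molB)
  evBA <- detectRearrangements(anchorBlocks(ip$molB, ip$molA),
                               ip$molB, ip$molA)
  expect_identical(evAB$type, "insertion")
  expect_identical(evBA$type, "deletion")
  expect_identical(evAB$blockLength, evBA$blockLength)
  expect_identical(evAB$flankLen, evBA$flankLen)

  tp <- makeTranslocationPair(totalLen = 20000, seed = 11)
  evT <- detectRearrangements(anchorBlocks(tp$molA, tp$molB),
                              tp$molA, tp$molB)
  evTs <- detectRearrangements(anchorBlocks(tp$molB, tp$molA),
                               tp$molB, tp$molA)
  expect_identical(evT$type, "translocation")
  expect_identical(evTs$type, "translocation")
  expect_identical(evT$blockLength, evTs$blockLength)
})

test_that("rotation of either input changes no event type or length", {
  tp <- makeTranslocationPair(totalLen = 20000, seed = 12)
  ref <- detectRearrangements(anchorBlocks(tp$molA, tp$molB),
                              tp$molA, tp$molB)
  rotA <- rotateMolecule(tp$molA, 9000)
  rotB <- rotateMolecule(tp$molB, 4000)
  for (pair in list(list(rotA, tp$molB), list(tp$molA, rotB),
                    list(rotA, rotB))) {
    ev <- detectRearrangements(anchorBlocks(pair[[1]], pair[[2]]),
                               pair[[1]], pair[[2]])
    tr <- ev[ev$type == "translocation", ]
    expect_identical(tr$blockLength, ref$blockLength[ref$type == "translocation"])
    expect_identical(tr$flankLen, ref$flankLen[ref$type == "translocation"])
  }
})

test_that("an inverted segment is reported as an inversion", {
  set.seed(13)
  bg <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  inv <- paste0(substr(bg, 1, 4000), rc(substr(bg, 4001, 6500)),
                substr(bg, 6501, 12000))
  a <- MitoMolecule("a", bg, circular = TRUE)
  b <- MitoMolecule("b", inv, circular = TRUE)
  ev <- detectRearrangements(anchorBlocks(a, b), a, b)
  expect_true("inversion" %in% ev$type)
  evi <- ev[ev$type == "inversion", ]
  expect_lte(abs(evi$blockLength - 2500L), 60L)
})

test_that("intergenic distances are reported from annotations", {
  ann <- data.frame(
    molecule = "m2",
    geneId = c("Ψrps14", "Ψcob", "rps10"),
    start = c(100L, 700L, 2038L),
    end = c(400L, 1400L, 2500L),
    strand = "+",
    pseudo = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  expect_identical(reportIntergenic(ann, "Ψcob", "rps10"), 637L)
  ann$start[3] <- 2039L
  expect_identical(reportIntergenic(ann, "Ψcob", "rps10"), 638L)
  expect_error(reportIntergenic(ann, "cob", "rps10"), "not found")
  expect_error(reportIntergenic(ann, "rps10", "Ψrps14"), "ordered")
})
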
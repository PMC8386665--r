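test_that("named profiles reproduce the published architectures", {
  pB <- mitoProfile("groupB")
  expect_identical(profileMoleculeLength(pB, "molecule 2"), 113443L)
  expect_identical(profileMoleculeLength(pB, "molecule 1"), 284385L)
  f1 <- profileFamilies(pB, "molecule 1")
  expect_setequal(f1$family, c("R1", "R3"))
  expect_true(all(f1$orientation == "direct"))
  expect_identical(f1$length[f1$family == "R1"], 11916L)
  expect_identical(f1$length[f1$family == "R3"], 4513L)

  pA <- mitoProfile("groupA")
  expect_identical(profileMoleculeLength(pA, "molecule 1a"), 297036L)
  expect_identical(profileMoleculeLength(pA, "molecule 1b"), 229589L)
  f1a <- profileFamilies(pA, "molecule 1a")
  expect_identical(f1a$orientation[f1a$family == "R1"], "inverted")
  expect_identical(f1a$orientation[f1a$family == "R2"], "direct")
  ## 1b carries the R2 pair but only a single R1 copy
  f1b <- profileFamilies(pA, "molecule 1b")
  expect_identical(f1b$copies[f1b$family == "R2"], 2L)
  expect_false("R1" %in% f1b$family[f1b$copies == 2L])

  pO <- mitoProfile("oka15")
  expect_identical(nrow(profileFamilies(pO, "molecule 2")), 0L)  # no R4
  f1o <- profileFamilies(pO, "molecule 1")
  expect_identical(f1o$length[f1o$family == "R1"], 13435L)

  expect_error(mitoProfile("groupC"), "arg")
  expect_error(mitoProfile("groupA", scale = 0), "scale")
})

test_that("scaling shrinks spacers but never planted features", {
  p <- mitoProfile("groupB", scale = 0.15)
  f <- profileFamilies(p, "molecule 1")
  expect_identical(f$length[f$family == "R1"], 11916L)
  expect_lt(profileMoleculeLength(p, "molecule 1"), 284385L * 0.4)
})

test_that("realized genomes are deterministic and match their truth", {
  p <- mitoProfile("groupB", scale = 0.1)
  g1 <- realizeGenome(p, seed = 42)
  g2 <- realizeGenome(p, seed = 42)
  expect_identical(lapply(g1$molecules, as.character),
                   lapply(g2$molecules, as.character))
  g3 <- realizeGenome(p, seed = 43)
  expect_false(identical(as.character(g1$molecules[[1]]),
                         as.character(g3$molecules[[1]])))

  ## byte-identical FASTA under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  writeMitoFasta(g1$molecules, f1)
  writeMitoFasta(g2$molecules, f2)
  expect_identical(readLines(f1), readLines(f2))

  ## planted copies recovered verbatim at truth coordinates
  tr <- g1$truth$repeats
  m1 <- g1$truth$features[g1$truth$features$molecule == "molecule 1", ]
  expect_identical(sum(m1$family == "R1"), 2L)
  expect_identical(sum(m1$family == "R3"), 2L)
  for (r in seq_len(nrow(tr))) {
    mol <- g1$molecules[[tr$molecule[r]]]
    c1 <- circularSubseq(mol, tr$start1[r], tr$length[r], tr$strand1[r])
    c2 <- circularSubseq(mol, tr$start2[r], tr$length[r], tr$strand2[r])
    expect_identical(c1, c2)
  }
})

test_that("the group A shared core is identical between molecules 1a and 1b", {
  g <- realizeGenome(mitoProfile("groupA", scale = 0.1), seed = 7)
  sharedLen <- length(g$molecules[["molecule 1b"]]) - 980L
  expect_identical(substr(as.character(g$molecules[["molecule 1a"]]), 1, sharedLen),
                   substr(as.character(g$molecules[["molecule 1b"]]), 1, sharedLen))
})

test_that("divergence plants the stated substitution load in copy 2", {
  g <- realizeGenome(mitoProfile("groupB", scale = 0.1), seed = 5,
                     divergence = 0.02)
  tr <- g$truth$repeats[g$truth$repeats$family == "R4", ]
  mol <- g$molecules[[tr$molecule]]
  c1 <- strsplit(circularSubseq(mol, tr$start1, tr$length), "")[[1]]
  c2 <- strsplit(circularSubseq(mol, tr$start2, tr$length), "")[[1]]
  mismatches <- sum(c1 != c2)
  expect_identical(mismatches, as.integer(round(0.02 * tr$length)))
  expect_equal(1 - mismatches / tr$length, 0.98, tolerance = 1e-3)
})

test_that("translocation pair plants the block between maximal flanks", {
  tp <- makeTranslocationPair(seed = 3)
  expect_identical(tp$truth$blockLen, 774L)
  expect_identical(tp$truth$flankLen, 40L)
  expect_identical(length(tp$molA), length(tp$molB))  # conserves length
  expect_identical(length(tp$molA), 49239L)
  ## the flank copies really bracket the block in both molecules
  for (mol in list(tp$molA, tp$molB)) {
    st <- if (identical(moleculeId(mol), "transloc_A"))
      tp$truth$flankStartsA else tp$truth$flankStartsB
    f1 <- circularSubseq(mol, st[1], 40)
    f2 <- circularSubseq(mol, st[2], 40)
    expect_identical(f1, tp$truth$flank)
    expect_identical(f2, tp$truth$flank)
  }
})

test_that("read simulation is uniform over sources and lengths behave", {
  src <- list(a = randMolecule(6000, 1, "a"), b = randMolecule(6000, 2, "b"))
  sim <- simulateReads(src, c(0.5, 0.5),
                       readSimParams(nReads = 1000, meanLength = 800,
                                     minLength = 300, maxLength = 3000),
                       seed = 9)
  nA <- sum(sim$truth$source == "a")
  ## binomial 99% bounds for n=1000, p=0.5
  expect_gt(nA, qbinom(0.005, 1000, 0.5))
  expect_lt(nA, qbinom(0.995, 1000, 0.5))

  ## error-free reads are exact substrings of the doubled source
  d <- paste0(as.character(src$a), as.character(src$a))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  idx <- which(sim$truth$source == "a")[1:25]
  for (i in idx) {
    r <- as.character(sim$reads[[i]])
    if (sim$truth$strand[i] == "-") r <- rc(r)
    expect_true(grepl(r, d, fixed = TRUE))
  }
})

test_that("coverage requests the expected number of reads", {
  m <- randMolecule(49239, 11, "m3")
  sim <- simulateReads(list(m), 1,
                       readSimParams(coverage = 40, meanLength = 10000,
                                     minLength = 2000, maxLength = 40000),
                       seed = 2)
  expect_identical(nrow(sim$truth), 197L)   # 40 * 49239 / 10000
})

test_that("read simulation validates its parameters", {
  m <- randMolecule(1000, 1)
  expect_error(readSimParams(coverage = 10, subRate = 0.5), "rates")
  expect_error(readSimParams(), "exactly one")
  expect_error(
    simulateReads(list(m), 1, readSimParams(nReads = 5, minLength = 2000),
                  seed = 1),
    "exceeds the shortest molecule")
  expect_error(simulateReads(list(m), c(0.5, 0.6),
                             readSimParams(nReads = 5, minLength = 100),
                             seed = 1),
               "sum to 1|one abundance")
})

test_that("FASTQ output round trips through Biostrings", {
  m <- randMolecule(5000, 3)
  fq <- tempfile(fileext = ".fastq")
  sim <- simulateReads(list(m), 1,
                       readSimParams(nReads = 20, meanLength = 900,
                                     minLength = 400, maxLength = 2000),
                       seed = 4, fastq = fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(as.character(back), as.character(sim$reads))
})
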
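## shared fixture: a 20 kb circle with a 500 bp direct pair, its two
## sub-genomic circles, and junction constructs at w = 800
.valFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(4)
    bg <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
    rp <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    s <- plantPair(bg, rp, 5001, 13501)
    mm <- MitoMolecule("mm", s, circular = TRUE)
    pairs <- findRepeats(mm, repeatParams(minLen = 400))
    prods <- enumerateAllProducts(mm, pairs)
    prods <- lapply(prods, predictJunctions, parent = mm, w = 800)
    juncs <- unlist(lapply(prods, productJunctions))
    cons <- Biostrings::DNAStringSet(vapply(juncs, junctionConstruct,
                                            character(1)))
    names(cons) <- vapply(juncs, junctionId, character(1))
    cache <<- list(mol = mm, prods = prods, juncs = juncs, cons = cons)
    cache
  }
})

test_that("error-free junction-spanning reads map at identity 1", {
  fx <- .valFixture()
  ## one read extracted right across each junction breakpoint
  reads <- Biostrings::DNAStringSet(vapply(
    fx$prods, function(p) {
      pm <- MitoMolecule("p", as.character(productSeq(p)), circular = TRUE)
      bp <- productJunctions(p)[[1]]@breakpoint
      circularSubseq(pm, bp - 1500L, 3000L)
    }, character(1)))
  names(reads) <- paste0("r", seq_along(reads))
  aln <- mapReads(reads, fx$cons, validationParams(minAnchor = 600))
  for (i in seq_along(reads)) {
    hit <- aln[aln$qname == names(reads)[i] &
                 aln$tname == names(fx$cons)[i], ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$identity, 1)
    expect_identical(hit$tstart, 1L)           # full construct covered
    expect_identical(hit$tend, 1600L)
  }
  ## a read from a shuffled decoy never reaches mapping identity
  set.seed(5)
  decoy <- paste(sample(strsplit(as.character(fx$mol), "")[[1]][1:3000]),
                 collapse = "")
  alnD <- mapReads(Biostrings::DNAStringSet(c(d1 = decoy)), fx$cons,
                   validationParams())
  expect_true(nrow(alnD) == 0L || all(alnD$identity < 0.85))
  ## empty read set is not an error
  expect_identical(nrow(mapReads(Biostrings::DNAStringSet(), fx$cons,
                                 validationParams())), 0L)
})

test_that("support counting distinguishes present from absent isoforms", {
  fx <- .valFixture()
  vp <- validationParams(minAnchor = 600, minReads = 3)
  sim <- simulateReads(fx$prods, c(0.5, 0.5),
                       readSimParams(coverage = 25, meanLength = 4000,
                                     minLength = 2500, maxLength = 8000),
                       seed = 11)
  sup <- countSupport(mapReads(sim$reads, fx$cons, vp), fx$juncs, vp)
  expect_true(all(sup$supported))
  expect_true(all(sup$nSpanning >= 3))
  expect_true(all(sup$nSpanning <= sup$nTotal))

  ## negative control: reads from the parent only support nothing
  sim0 <- simulateReads(list(fx$mol), 1,
                        readSimParams(coverage = 25, meanLength = 4000,
                                      minLength = 2500, maxLength = 8000),
                        seed = 12)
  sup0 <- countSupport(mapReads(sim0$reads, fx$cons, vp), fx$juncs, vp)
  expect_true(all(sup0$nSpanning == 0))
  expect_false(any(sup0$supported))

  ## an anchor no read can satisfy zeroes the counts (and over-w errors)
  aln <- mapReads(sim$reads, fx$cons, vp)
  expect_error(countSupport(aln, fx$juncs,
                            validationParams(minAnchor = 900)),
               "exceeds the junction flank")
  ## unknown target ids are an error
  bad <- aln; bad$tname[1] <- "nonsense"
  expect_error(countSupport(bad, fx$juncs, vp), "unknown junction")
})

test_that("support is invariant to read order", {
  fx <- .valFixture()
  vp <- validationParams(minAnchor = 600, minReads = 3)
  sim <- simulateReads(fx$prods, c(0.5, 0.5),
                       readSimParams(coverage = 15, meanLength = 4000,
                                     minLength = 2500, maxLength = 8000),
                       seed = 13)
  a1 <- countSupport(mapReads(sim$reads, fx$cons, vp), fx$juncs, vp)
  a2 <- countSupport(mapReads(rev(sim$reads), fx$cons, vp), fx$juncs, vp)
  expect_identical(a1[order(a1$junction), ], a2[order(a2$junction), ],
                   ignore_attr = TRUE)
})

test_that("sensitivity and specificity hold across seeds with read errors", {
  fx <- .valFixture()
  vp <- validationParams(minAnchor = 600, minReads = 3)
  for (sd in c(21, 22, 23)) {
    sim <- simulateReads(list(fx$prods[[1]], fx$mol), c(0.5, 0.5),
                         readSimParams(coverage = 25, meanLength = 4000,
                                       minLength = 2500, maxLength = 8000,
                                       subRate = 0.03, indelRate = 0.02),
                         seed = sd)
    sup <- countSupport(mapReads(sim$reads, fx$cons, vp), fx$juncs, vp)
    present <- sup$junction == junctionId(productJunctions(fx$prods[[1]])[[1]])
    expect_true(all(sup$supported[present]))     # present isoform found
    expect_true(all(sup$nSpanning[!present] < 3)) # absent isoform not
  }
})

test_that("the PAF import path reproduces the internal mapper's support", {
  fx <- .valFixture()
  vp <- validationParams(minAnchor = 600, minReads = 3)
  sim <- simulateReads(fx$prods, c(0.5, 0.5),
                       readSimParams(coverage = 20, meanLength = 4000,
                                     minLength = 2500, maxLength = 8000),
                       seed = 14)
  aln <- mapReads(sim$reads, fx$cons, vp)
  supI <- countSupport(aln, fx$juncs, vp)

  ## round trip through the PAF format
  paf <- tempfile(fileext = ".paf")
  writePaf(aln, paf)
  supP <- countSupport(pafToAlignments(readPaf(paf)), fx$juncs, vp)
  expect_identical(supI, supP)

  ## external mapper (minimap2) through the same import path
  fa <- tempfile(fileext = ".fa"); rf <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(fx$cons, fa)
  Biostrings::writeXStringSet(sim$reads, rf)
  out <- tempfile(fileext = ".paf")
  status <- system2("minimap2", c("-c", "--secondary=yes", "-N", "10",
                                  "-p", "0.3", fa, rf),
                    stdout = out, stderr = FALSE)
  expect_identical(status, 0L)
  supM <- countSupport(pafToAlignments(readPaf(out)), fx$juncs, vp)
  expect_identical(supM$nSpanning, supI$nSpanning)
  expect_identical(supM$supported, supI$supported)
})

test_that("validateGenome runs the whole pipeline per molecule", {
  ## molecule-2-like fixture, scaled: R4 pair, two sub-circles
  g <- realizeGenome(mitoProfile("groupB", scale = 0.2), seed = 31)
  m2 <- g$molecules[["molecule 2"]]
  prods <- enumerateAllProducts(m2, findRepeats(m2))
  sim <- simulateReads(prods, c(0.5, 0.5),
                       readSimParams(coverage = 20, meanLength = 6000,
                                     minLength = 4000, maxLength = 12000),
                       seed = 32)
  vp <- validationParams(minAnchor = 1000, minReads = 3)
  res <- validateGenome(m2, sim$reads, vp, w = 1200)
  expect_identical(nrow(res$support), 2L)
  expect_true(all(res$support$supported))

  ## a molecule without repeats yields an empty junction table
  gO <- realizeGenome(mitoProfile("oka15", scale = 0.2), seed = 33)
  resO <- validateGenome(gO$molecules[["molecule 2"]], sim$reads, vp,
                         w = 1200)
  expect_identical(nrow(resO$support), 0L)
})
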
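test_that("a direct pair yields two circles that partition the parent", {
  ## toy circle AAAA|R|CCCC|R|GGGG -> circles R+CCCC and R+GGGG+AAAA
  set.seed(1)
  R <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
  toy <- MitoMolecule("toy",
                      paste0(strrep("A", 8), R, strrep("C", 8), R,
                             strrep("G", 8)),
                      circular = TRUE)
  pair <- data.frame(startA = 9, startB = 27, length = 10,
                     orientation = "direct", family = "custom")
  pr <- enumerateProducts(toy, pair)
  expect_length(pr, 2L)
  expect_true(all(vapply(pr, productType, character(1)) ==
                    "subgenomic_circle"))
  expect_identical(as.character(productSeq(pr[[1]])),
                   paste0(R, strrep("C", 8)))
  expect_identical(as.character(productSeq(pr[[2]])),
                   paste0(R, strrep("G", 8), strrep("A", 8)))
  expect_identical(length(pr[[1]]) + length(pr[[2]]), length(toy))
  expect_error(enumerateProducts(MitoMolecule("lin", "ACGTACGT"), pair),
               "linear")
})

test_that("length conservation holds for random placements", {
  set.seed(2)
  for (trial in 1:100) {
    L <- sample(1000:3000, 1)
    rl <- sample(50:200, 1)
    a <- sample(L, 1)
    b <- ((a + rl + sample(100:(L - 2 * rl - 200), 1) - 1) %% L) + 1
    m <- randMolecule(L, seed = trial + 1000)
    pair <- data.frame(startA = a, startB = b, length = rl,
                       orientation = "direct", family = "custom")
    pr <- enumerateProducts(m, pair)
    expect_identical(length(pr[[1]]) + length(pr[[2]]), L)
    ## each product contains one full repeat copy
    copy <- circularSubseq(m, a, rl)
    expect_identical(substr(as.character(productSeq(pr[[1]])), 1, rl),
                     copy)
  }
})

test_that("an inverted pair yields one equal-length isoform; twice restores the parent", {
  set.seed(3)
  bg <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  rp <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  s <- plantPair(bg, rp, 801, 2601, inverted = TRUE)
  m <- MitoMolecule("m", s, circular = TRUE)
  pair <- data.frame(startA = 801, startB = 2601, length = 300,
                     orientation = "inverted", family = "custom")
  iso <- enumerateProducts(m, pair)
  expect_length(iso, 1L)
  expect_identical(productType(iso[[1]]), "inversion_isoform")
  expect_identical(length(iso[[1]]), length(m))
  expect_false(canonicalCircularForm(productSeq(iso[[1]])) ==
                 canonicalCircularForm(m))
  ## the repeat copies stay intact in the product
  p1 <- as.character(productSeq(iso[[1]]))
  expect_identical(substr(p1, 1, 300), rp)

  ## involution: recombine the product at its (re-detected) pair
  m2 <- MitoMolecule("m2", p1, circular = TRUE)
  r2 <- findRepeats(m2, repeatParams(minLen = 250))
  expect_identical(r2$orientation, "inverted")
  iso2 <- enumerateProducts(m2, r2)
  expect_identical(canonicalCircularForm(productSeq(iso2[[1]])),
                   canonicalCircularForm(m))
})

test_that("products are invariant to the copy labelling", {
  m <- randMolecule(3000, 4)
  a <- 301; b <- 1501; rl <- 120
  s <- plantPair(as.character(m), paste(sample(c("A", "C", "G", "T"), rl,
                                               TRUE), collapse = ""), a, b)
  m <- MitoMolecule("m", s, circular = TRUE)
  p1 <- enumerateProducts(m, data.frame(startA = a, startB = b, length = rl,
                                        orientation = "direct",
                                        family = "custom"))
  p2 <- enumerateProducts(m, data.frame(startA = b, startB = a, length = rl,
                                        orientation = "direct",
                                        family = "custom"))
  k1 <- sort(vapply(p1, function(p) canonicalCircularForm(productSeq(p)),
                    character(1)))
  k2 <- sort(vapply(p2, function(p) canonicalCircularForm(productSeq(p)),
                    character(1)))
  expect_identical(k1, k2)
})

test_that("enumerateAllProducts counts products per repeat family", {
  ## two direct pairs on one circle -> four sub-genomic circles
  gB <- realizeGenome(mitoProfile("groupB", scale = 0.12), seed = 5)
  m1 <- gB$molecules[["molecule 1"]]
  pairs <- findRepeats(m1)
  expect_identical(nrow(pairs), 2L)
  prods <- enumerateAllProducts(m1, pairs)
  expect_length(prods, 4L)
  ## one direct pair only (group A molecule 1b, R2) -> two circles
  gA <- realizeGenome(mitoProfile("groupA", scale = 0.12), seed = 6)
  m1b <- gA$molecules[["molecule 1b"]]
  prods1b <- enumerateAllProducts(m1b, findRepeats(m1b))
  expect_length(prods1b, 2L)
  ## zero pairs -> empty
  expect_length(enumerateAllProducts(m1, findRepeats(m1)[0, ]), 0L)
  ## overlapping pairs are rejected
  bad <- data.frame(startA = c(100, 150), startB = c(5000, 5050),
                    length = c(200, 200),
                    orientation = "direct", family = "custom")
  expect_error(enumerateAllProducts(m1, bad), "overlapping")
})

test_that("junction predictions are novel exactly when the oracle says so", {
  set.seed(7)
  bg <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  rp <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  s <- plantPair(bg, rp, 1501, 4001)
  mm <- MitoMolecule("mm", s, circular = TRUE)
  pairs <- findRepeats(mm, repeatParams(minLen = 250))
  prods <- enumerateAllProducts(mm, pairs)
  prods <- lapply(prods, predictJunctions, parent = mm, w = 400)
  for (p in prods) {
    js <- productJunctions(p)
    expect_length(js, 1L)                     # one junction per circle
    expect_true(isNovel(js[[1]]))
    expect_identical(nchar(junctionConstruct(js[[1]])), 800L)
    ## independent oracle: 2w-mer scan of the doubled parent
    expect_false(bruteOccurs(s, junctionConstruct(js[[1]])))
  }

  ## inversion isoform: two junctions, both novel
  si <- plantPair(bg, rp, 1501, 4001, inverted = TRUE)
  mi <- MitoMolecule("mi", si, circular = TRUE)
  pi <- findRepeats(mi, repeatParams(minLen = 250))
  iso <- enumerateProducts(mi, pi)[[1]]
  iso <- predictJunctions(iso, mi, w = 400)
  js <- productJunctions(iso)
  expect_length(js, 2L)
  expect_true(all(vapply(js, isNovel, logical(1))))
  for (j in js) expect_false(bruteOccurs(si, junctionConstruct(j)))

  ## every window of the parent itself is non-novel
  for (st in c(1, 2500, 5900))
    expect_false(isNovelJunction(mm, circularSubseq(mm, st, 800)))

  ## w too small to clear the repeat -> warning, not novel
  expect_warning(pj <- predictJunctions(prods[[1]], mm, w = 120),
                 "cannot be novel")
  expect_false(isNovel(productJunctions(pj)[[1]]))
  expect_error(predictJunctions(prods[[1]], mm, w = 10000), "longer")
})
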
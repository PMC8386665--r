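## ---------------------------------------------------------------------
## Enumeration of single-crossover homologous recombination products at
## detected repeat pairs on circular molecules, and prediction of the
## novel junction constructs used for reverse read mapping.
## ---------------------------------------------------------------------

.pairRow <- function(pair) {
  need <- c("startA", "startB", "length", "orientation")
  if (!all(need %in% names(pair)))
    stop("repeat pair must have columns: ", paste(need, collapse = ", "))
  if (nrow(pair) != 1L) stop("exactly one repeat pair expected")
  pair
}

#' Enumerate recombination products at one repeat pair
#'
#' A single crossover between two *direct* copies splits the circular
#' parent into exactly two sub-genomic circles — one per inter-repeat
#' arc, each retaining one full repeat copy — whose lengths sum to the
#' parent length. A crossover between two *inverted* copies yields one
#' inversion isoform of unchanged length, in which the segment between
#' the copies is reverse-complemented while the copies themselves stay
#' intact.
#'
#' @param x A circular [MitoMolecule-class] (linear molecules are a
#'   topology error).
#' @param pair One row of a [findRepeats()] data.frame.
#' @return List of [IsoformProduct-class] objects (2 for direct pairs, 1
#'   for inverted pairs).
#' @examples
#' g <- realizeGenome(mitoProfile("groupB", scale = 0.15), seed = 1)
#' m2 <- g$molecules[["molecule 2"]]
#' prods <- enumerateProducts(m2, findRepeats(m2))
#' sum(vapply(prods, length, integer(1))) == length(m2)
#' @export
enumerateProducts <- function(x, pair) {
  stopifnot(is(x, "MitoMolecule"))
  if (!isCircular(x))
    stop("recombination products are only enumerated on circular ",
         "molecules; '", moleculeId(x), "' is linear")
  pair <- .pairRow(pair)
  L <- length(x)
  a <- pair$startA; b <- pair$startB; rl <- pair$length
  id <- moleculeId(x)
  if (pair$orientation == "direct") {
    w1 <- (b - a) %% L
    w2 <- L - w1
    if (w1 == 0L) stop("degenerate repeat pair (identical starts)")
    mk <- function(start, wd, which) {
      comp <- data.frame(start = .mod1(start, L), width = wd, strand = "+",
                         stringsAsFactors = FALSE)
      new("IsoformProduct", productType = "subgenomic_circle",
          parentId = id,
          seq = Biostrings::DNAString(circularSubseq(x, start, wd)),
          composition = comp, junctions = list(), repeatPair = pair)
    }
    list(mk(a, w1, 1L), mk(b, w2, 2L))
  } else {
    ## product = copyA + revcomp(inter-copy arc) + copyB + remaining arc
    arc1Start <- a + rl
    arc1Len <- (b - (a + rl)) %% L
    arc2Start <- b + rl
    arc2Len <- (a - (b + rl)) %% L
    segs <- data.frame(
      start = .mod1(c(a, arc1Start, b, arc2Start), L),
      width = c(rl, arc1Len, rl, arc2Len),
      strand = c("+", "-", "+", "+"),
      stringsAsFactors = FALSE)
    segs <- segs[segs$width > 0L, , drop = FALSE]
    pieces <- vapply(seq_len(nrow(segs)), function(i)
      circularSubseq(x, segs$start[i], segs$width[i], segs$strand[i]),
      character(1))
    prod <- paste(pieces, collapse = "")
    stopifnot(nchar(prod) == L)
    list(new("IsoformProduct", productType = "inversion_isoform",
             parentId = id, seq = Biostrings::DNAString(prod),
             composition = segs, junctions = list(), repeatPair = pair))
  }
}

#' Enumerate single-event products over several repeat pairs
#'
#' Products of one crossover at each pair in turn (no chained events:
#' recombination at the large repeats is recurrent and reversible, so
#' single-event sub-genomic circles and isoforms are the observable
#' species). Duplicate products are removed by canonical circular form.
#'
#' @param x A circular [MitoMolecule-class].
#' @param pairs data.frame from [findRepeats()]; pairs must be pairwise
#'   non-overlapping.
#' @return List of [IsoformProduct-class] objects.
#' @export
enumerateAllProducts <- function(x, pairs) {
  stopifnot(is(x, "MitoMolecule"))
  if (is.null(pairs) || nrow(pairs) == 0L) return(list())
  L <- length(x)
  if (nrow(pairs) > 1L) {
    ivs <- rbind(
      data.frame(s = pairs$startA, w = pairs$length, pair = seq_len(nrow(pairs))),
      data.frame(s = pairs$startB, w = pairs$length, pair = seq_len(nrow(pairs))))
    for (i in seq_len(nrow(ivs) - 1L)) for (j in seq.int(i + 1L, nrow(ivs))) {
      if (ivs$pair[i] == ivs$pair[j]) next
      if (.circOverlaps(ivs$s[i], ivs$w[i], ivs$s[j], ivs$w[j], L))
        stop("overlapping repeat pairs are an unsupported configuration")
    }
  }
  prods <- list()
  for (r in seq_len(nrow(pairs)))
    prods <- c(prods, enumerateProducts(x, pairs[r, , drop = FALSE]))
  keys <- vapply(prods, function(p) canonicalCircularForm(productSeq(p)),
                 character(1))
  prods[!duplicated(keys)]
}

## does the 2w-mer occur in the circular parent, either strand?
.occursInParent <- function(parentChar, construct) {
  d <- paste0(parentChar, parentChar)
  grepl(construct, d, fixed = TRUE) ||
    grepl(.rc(construct), d, fixed = TRUE)
}

#' Test whether a junction construct is novel
#'
#' A construct is novel iff it occurs nowhere in the circular parent
#' molecule, on either strand (scanned on the doubled sequence).
#'
#' @param parent The parent [MitoMolecule-class] (or character sequence).
#' @param construct Character; the candidate junction window.
#' @return Logical scalar.
#' @export
isNovelJunction <- function(parent, construct) {
  s <- if (is(parent, "MitoMolecule")) as.character(parent)
       else as.character(parent)
  !.occursInParent(s, as.character(construct))
}

.junctionAt <- function(prodChar, parentChar, center, w, id, repeatLen,
                        provenance) {
  Lp <- nchar(prodChar)
  construct <- .circSubstr(prodChar, center - w + 1L, 2L * w)
  new("Junction", id = id, breakpoint = as.integer(.mod1(center, Lp)),
      construct = construct, w = as.integer(w),
      novel = !.occursInParent(parentChar, construct),
      repeatLen = as.integer(repeatLen), provenance = provenance)
}

#' Predict the novel junctions of a recombination product
#'
#' Junction constructs are windows of `2w` product bases centred on the
#' midpoint of the recombinant repeat copy. With exact repeat copies a
#' window centred anywhere else is always present in the parent, and the
#' construct is novel only when `2w` exceeds the repeat length — the
#' function warns when it cannot be. Each sub-genomic circle yields one
#' junction; an inversion isoform yields two (one per repeat copy).
#'
#' @param product An [IsoformProduct-class] from [enumerateProducts()].
#' @param parent The parent [MitoMolecule-class].
#' @param w Flank width in bp on each side of the breakpoint (default
#'   1,000).
#' @return The product with its `junctions` slot filled; access with
#'   [productJunctions()].
#' @export
predictJunctions <- function(product, parent, w = 1000L) {
  stopifnot(is(product, "IsoformProduct"), is(parent, "MitoMolecule"))
  prodChar <- as.character(productSeq(product))
  parentChar <- as.character(parent)
  Lp <- nchar(prodChar)
  if (2L * w > Lp)
    stop("w = ", w, " requires a construct of ", 2L * w,
         " bp, longer than the ", Lp, " bp product")
  rl <- product@repeatPair$length
  if (2L * w <= rl)
    warning("2w (", 2L * w, ") does not exceed the repeat length (", rl,
            "); junction constructs cannot be novel for exact copies")
  base <- paste0(parentId(product), ":",
                 if (!is.na(product@repeatPair$family) &&
                     product@repeatPair$family != "custom")
                   product@repeatPair$family
                 else paste0("rep", product@repeatPair$startA))
  if (productType(product) == "subgenomic_circle") {
    ## the repeat copy occupies positions 1..rl of the product
    center <- as.integer(ceiling(rl / 2))
    j <- .junctionAt(prodChar, parentChar, center, w,
                     paste0(base, ":circle", product@composition$start[1]),
                     rl,
                     list(parent = parentId(product),
                          productType = "subgenomic_circle",
                          productStart = product@composition$start[1]))
    product@junctions <- list(j)
  } else {
    comp <- product@composition
    centerA <- as.integer(ceiling(rl / 2))
    ## product layout: copyA, inverted arc, copyB, remaining arc
    offB <- rl + comp$width[comp$strand == "-"][1]
    if (is.na(offB)) offB <- rl
    centerB <- as.integer(offB + ceiling(rl / 2))
    jA <- .junctionAt(prodChar, parentChar, centerA, w,
                      paste0(base, ":invA"), rl,
                      list(parent = parentId(product),
                           productType = "inversion_isoform", side = "A"))
    jB <- .junctionAt(prodChar, parentChar, centerB, w,
                      paste0(base, ":invB"), rl,
                      list(parent = parentId(product),
                           productType = "inversion_isoform", side = "B"))
    product@junctions <- list(jA, jB)
  }
  product
}
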
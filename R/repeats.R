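## ---------------------------------------------------------------------
## Intramolecular repeat detection: exact k-mer seeds on the doubled
## sequence (circularity), runs collapsed into maximal exact matches,
## same-diagonal chains merged across small substitution gaps, hits
## deduplicated modulo the molecule length. Identity is computed exactly
## by columnwise comparison of the two copies (gap-free chains).
## ---------------------------------------------------------------------

#' Parameters for large-repeat detection
#'
#' The 1,000 bp default marks the class of large, frequently and
#' reversibly recombining plant-mitochondrial repeats; the 0.98 identity
#' floor reflects that such repeats recombine homologously and are
#' near-identical.
#'
#' @param minLen Minimum repeat length in bp (default 1,000).
#' @param minIdentity Minimum identity fraction in (0, 1] (default 0.98).
#' @param seedK Exact seed k-mer size (default 21).
#' @param maxGap Maximum gap in bp bridged when chaining seeds across
#'   substitutions (default 100).
#' @return A list of class `RepeatParams`.
#' @export
repeatParams <- function(minLen = 1000L, minIdentity = 0.98, seedK = 21L,
                         maxGap = 100L) {
  if (minLen <= seedK) stop("minLen must exceed seedK")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must be in (0, 1]")
  structure(list(minLen = as.integer(minLen), minIdentity = minIdentity,
                 seedK = as.integer(seedK), maxGap = as.integer(maxGap)),
            class = "RepeatParams")
}

.emptyRepeatDf <- function() {
  data.frame(molecule = character(0), family = character(0),
             startA = integer(0), lenA = integer(0), strandA = character(0),
             startB = integer(0), lenB = integer(0), strandB = character(0),
             orientation = character(0), length = integer(0),
             identity = numeric(0), stringsAsFactors = FALSE)
}

## collapse seed pairs that share a diagonal (direct: p2-p1; inverted:
## p1+p2) into maximal exact matches, then chain across gaps <= maxGap
.chainSeeds <- function(p1, p2, k, inverted, maxGap) {
  if (length(p1) == 0L)
    return(data.frame(a = integer(0), b = integer(0), len = integer(0),
                      gapped = integer(0)))
  key <- if (inverted) p1 + p2 else p2 - p1
  o <- order(key, p1)
  key <- key[o]; p1 <- p1[o]; p2 <- p2[o]
  n <- length(p1)
  newRun <- c(TRUE, key[-1L] != key[-n] | p1[-1L] != p1[-n] + 1L)
  runId <- cumsum(newRun)
  a0 <- tapply(p1, runId, min)
  aN <- tapply(p1, runId, max)
  keyR <- key[newRun]
  runs <- data.frame(key = as.integer(keyR),
                     a = as.integer(a0),
                     len = as.integer(aN - a0 + k),
                     stringsAsFactors = FALSE)
  ## merge exact runs separated by small substitution gaps (same diagonal)
  o <- order(runs$key, runs$a)
  runs <- runs[o, , drop = FALSE]
  m <- nrow(runs)
  gap <- c(Inf, ifelse(runs$key[-1L] == runs$key[-m],
                       runs$a[-1L] - (runs$a[-m] + runs$len[-m]), Inf))
  chainId <- cumsum(gap > maxGap)
  aStart <- tapply(runs$a, chainId, min)
  aEnd <- tapply(runs$a + runs$len, chainId, max)
  keyC <- runs$key[!duplicated(chainId)]
  nseg <- tabulate(chainId)
  len <- as.integer(aEnd - aStart)
  a <- as.integer(aStart)
  ## seed (i, j) pairs copyA base x with copyB base (key + k - 1) - x, so
  ## the copy-B start of a chain covering [a, a+len) is key + k - (a+len)
  b <- if (inverted) as.integer(keyC + k - (a + len))
       else as.integer(keyC + a)
  data.frame(a = a, b = b, len = len, gapped = as.integer(nseg > 1L),
             stringsAsFactors = FALSE)
}

## core engine: maximal repeated pairs of a sequence
.findRepeatPairs <- function(s, circular, k, minLen, maxGap) {
  L <- nchar(s)
  if (L < k + 1L || L < minLen) return(NULL)
  d <- if (circular) paste0(s, s) else s
  npos <- nchar(d) - k + 1L
  starts <- seq_len(npos)
  km <- substring(d, starts, starts + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  dtAll <- data.table(kmer = km[ok], pos = starts[ok])
  dtLeft <- dtAll[pos <= L]
  maxDiag <- if (circular) L - 1L else npos

  join <- dtAll[dtLeft, on = "kmer", allow.cartesian = TRUE, nomatch = 0L]
  p1 <- join$i.pos; p2 <- join$pos
  keep <- p2 > p1 & (p2 - p1) <= maxDiag
  dir <- .chainSeeds(p1[keep], p2[keep], k, inverted = FALSE, maxGap = maxGap)

  rkm <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km[ok])))
  dtRc <- data.table(kmer = rkm, pos = dtAll$pos)
  joinI <- dtRc[dtLeft, on = "kmer", allow.cartesian = TRUE, nomatch = 0L]
  p1 <- joinI$i.pos; p2 <- joinI$pos
  keep <- p2 > p1 & (p2 - p1) <= maxDiag
  inv <- .chainSeeds(p1[keep], p2[keep], k, inverted = TRUE, maxGap = maxGap)

  list(direct = dir, inverted = inv, L = L, d = d)
}

.pairIdentity <- function(s, a, b, len, inverted, circular) {
  sA <- if (circular) .circSubstr(s, a, len) else substr(s, a, a + len - 1L)
  sB <- if (circular) .circSubstr(s, b, len) else substr(s, b, b + len - 1L)
  if (inverted) sB <- .rc(sB)
  vA <- utf8ToInt(sA); vB <- utf8ToInt(sB)
  sum(vA == vB) / len
}

.normalizePairs <- function(hits, L, s, circular, inverted, minLen,
                            minIdentity) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  hits <- hits[hits$len >= minLen & hits$len <= L, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  a <- if (circular) .mod1(hits$a, L) else hits$a
  b <- if (circular) .mod1(hits$b, L) else hits$b
  lo <- pmin(a, b); hi <- pmax(a, b)
  o <- order(-hits$len)
  hits <- hits[o, , drop = FALSE]; lo <- lo[o]; hi <- hi[o]
  key <- paste(lo, hi, hits$len, sep = "_")
  dup <- duplicated(key)
  hits <- hits[!dup, , drop = FALSE]; lo <- lo[!dup]; hi <- hi[!dup]
  ## drop self/overlapping copies (palindromes, trivial self-hit)
  keep <- logical(nrow(hits))
  ident <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (circular && .circOverlaps(lo[i], hits$len[i], hi[i], hits$len[i], L)) next
    if (!circular && hi[i] < lo[i] + hits$len[i]) next
    ident[i] <- .pairIdentity(s, lo[i], hi[i], hits$len[i], inverted,
                              circular)
    keep[i] <- ident[i] >= minIdentity
  }
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  data.frame(start1 = lo[keep], start2 = hi[keep],
             len = hits$len, identity = ident[keep],
             orientation = if (inverted) "inverted" else "direct",
             stringsAsFactors = FALSE)
}

## circular containment: is [s2, s2+w2) inside [s1, s1+w1) (mod L)?
.circContains <- function(s1, w1, s2, w2, L) {
  if (w2 > w1) return(FALSE)
  off <- (s2 - s1) %% L
  off + w2 <= w1
}

.suppressContained <- function(df, L, circular) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(-df$len), , drop = FALSE]
  n <- nrow(df)
  keep <- rep(TRUE, n)
  contains <- function(i, sa, wa) {
    if (circular) .circContains(df$start1[i], df$len[i], sa, wa, L) ||
      .circContains(df$start2[i], df$len[i], sa, wa, L)
    else (sa >= df$start1[i] && sa + wa <= df$start1[i] + df$len[i]) ||
      (sa >= df$start2[i] && sa + wa <= df$start2[i] + df$len[i])
  }
  for (j in seq_len(n)[-1L]) {
    for (i in seq_len(j - 1L)) {
      if (!keep[i]) next
      if (contains(i, df$start1[j], df$len[j]) &&
          contains(i, df$start2[j], df$len[j])) { keep[j] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}

## canonical copy order: rotate so the origin falls in the largest
## copy-free arc, then copyA is the first copy encountered
.canonicalOrder <- function(df, L, circular) {
  if (!nrow(df)) return(df)
  for (i in seq_len(nrow(df))) {
    s1 <- df$start1[i]; s2 <- df$start2[i]; w <- df$len[i]
    if (!circular) {
      swap <- s2 < s1
    } else {
      gap12 <- (s2 - (s1 + w)) %% L   # arc after copy1 (to copy2)
      gap21 <- (s1 - (s2 + w)) %% L   # arc after copy2 (to copy1)
      swap <- if (gap21 != gap12) gap21 < gap12 else s2 < s1
    }
    if (swap) {
      df$start1[i] <- s2; df$start2[i] <- s1
    }
  }
  df
}

#' Find large repeated pairs within one molecule
#'
#' Self-comparison of a (typically circular) molecule: both strands are
#' searched, circularity is handled on the doubled sequence with hits
#' deduplicated modulo the length, the trivial whole-sequence self-hit is
#' excluded, and pairs contained within a longer reported pair are
#' suppressed. Pairs are reported in canonical copy order and sorted by
#' length, descending.
#'
#' @param x A [MitoMolecule-class].
#' @param params A [repeatParams()] object.
#' @param lexicon Repeat family lexicon passed to [matchFamilies()];
#'   `NULL` to skip family labelling.
#' @return data.frame with columns `molecule`, `family`, `startA`,
#'   `lenA`, `strandA`, `startB`, `lenB`, `strandB`, `orientation`,
#'   `length`, `identity`. Strand of copy B is `"-"` for inverted pairs.
#' @examples
#' g <- realizeGenome(mitoProfile("groupB", scale = 0.15), seed = 1)
#' findRepeats(g$molecules[["molecule 2"]])$length  # 1589
#' @export
findRepeats <- function(x, params = repeatParams(),
                        lexicon = repeatFamilyLexicon()) {
  stopifnot(is(x, "MitoMolecule"), inherits(params, "RepeatParams"))
  s <- as.character(x)
  L <- nchar(s)
  if (L < 2L * params$minLen) return(.emptyRepeatDf())
  circular <- isCircular(x)
  eng <- .findRepeatPairs(s, circular, params$seedK, params$minLen,
                          params$maxGap)
  if (is.null(eng)) return(.emptyRepeatDf())
  dir <- .normalizePairs(eng$direct, L, s, circular, FALSE,
                         params$minLen, params$minIdentity)
  inv <- .normalizePairs(eng$inverted, L, s, circular, TRUE,
                         params$minLen, params$minIdentity)
  df <- rbind(dir, inv)
  if (is.null(df) || !nrow(df)) return(.emptyRepeatDf())
  df <- .suppressContained(df, L, circular)
  df <- .canonicalOrder(df, L, circular)
  out <- data.frame(
    molecule = moleculeId(x), family = NA_character_,
    startA = df$start1, lenA = df$len, strandA = "+",
    startB = df$start2, lenB = df$len,
    strandB = ifelse(df$orientation == "inverted", "-", "+"),
    orientation = df$orientation, length = df$len,
    identity = df$identity, stringsAsFactors = FALSE)
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(lexicon)) out <- matchFamilies(out, lexicon)
  out
}

#' Find short repeated pairs in a region
#'
#' Exhaustive exact-pair scan restricted to a window of the molecule;
#' used for breakpoint flanking-repeat discovery, where the repeats of
#' interest are tens of bases (the translocated-region flank is 40 bp).
#' The window is treated as a linear excerpt; coordinates in the result
#' are molecule coordinates.
#'
#' @param x A [MitoMolecule-class].
#' @param start 1-based window start (may be any integer on circles).
#' @param width Window width in bp.
#' @param minLen,maxLen Length bounds for reported pairs (defaults 20 and
#'   200).
#' @return data.frame as for [findRepeats()] (family always `NA`).
#' @export
findShortRepeats <- function(x, start, width, minLen = 20L, maxLen = 200L) {
  stopifnot(is(x, "MitoMolecule"))
  L <- length(x)
  width <- min(width, L)
  region <- circularSubseq(x, start, width)
  k <- min(minLen, 15L)
  eng <- .findRepeatPairs(region, circular = FALSE, k = k,
                          minLen = minLen, maxGap = 0L)
  if (is.null(eng)) return(.emptyRepeatDf())
  dir <- .normalizePairs(eng$direct, width, region, FALSE, FALSE, minLen, 1)
  inv <- .normalizePairs(eng$inverted, width, region, FALSE, TRUE, minLen, 1)
  df <- rbind(dir, inv)
  if (is.null(df) || !nrow(df)) return(.emptyRepeatDf())
  df <- df[df$len <= maxLen, , drop = FALSE]
  if (!nrow(df)) return(.emptyRepeatDf())
  df <- .suppressContained(df, width, FALSE)
  df <- .canonicalOrder(df, width, FALSE)
  off <- start - 1L
  mapPos <- function(p) if (isCircular(x)) .mod1(p + off, L) else p + off
  out <- data.frame(
    molecule = moleculeId(x), family = NA_character_,
    startA = mapPos(df$start1), lenA = df$len, strandA = "+",
    startB = mapPos(df$start2), lenB = df$len,
    strandB = ifelse(df$orientation == "inverted", "-", "+"),
    orientation = df$orientation, length = df$len,
    identity = df$identity, stringsAsFactors = FALSE)
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Known repeat family length classes
#'
#' Length lexicon of the four named large-repeat families of potato
#' mitogenomes, including the expanded/reduced OKA15 variants of R1 and
#' R2.
#'
#' @return data.frame with columns `family` and `length` (one row per
#'   known length).
#' @export
repeatFamilyLexicon <- function() {
  data.frame(
    family = c("R1", "R1", "R2", "R2", "R3", "R4"),
    length = c(11916L, 13435L, 7502L, 7076L, 4513L, 1589L),
    stringsAsFactors = FALSE
  )
}

#' Assign repeat family labels by length class
#'
#' A detected pair is labelled with a family when its length lies within
#' `tol` (default ±10%) of a known class length; otherwise `"custom"`.
#' Ties go to the closest class (smallest relative deviation).
#'
#' @param pairs data.frame from [findRepeats()].
#' @param lexicon data.frame with `family` and `length` columns.
#' @param tol Relative length tolerance (default 0.1).
#' @return `pairs` with the `family` column filled.
#' @export
matchFamilies <- function(pairs, lexicon = repeatFamilyLexicon(), tol = 0.1) {
  if (!nrow(pairs)) return(pairs)
  pairs$family <- vapply(pairs$length, function(len) {
    rel <- abs(len - lexicon$length) / lexicon$length
    i <- which.min(rel)
    if (rel[i] <= tol) lexicon$family[i] else "custom"
  }, character(1))
  pairs
}
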
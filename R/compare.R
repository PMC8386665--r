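## ---------------------------------------------------------------------
## Pairwise structural comparison of molecules. Synteny blocks are built
## from k-mers unique in both molecules (both strands), merged into
## gap-free runs, and bridged across locally non-unique stretches
## (repeat copies) when the intervening sequence is identical on both
## sides. Rearrangements are read off the cyclic block order; block
## boundaries of translocations/insertions are refined with the
## breakpoint flanking repeat, which is also reported.
## ---------------------------------------------------------------------

.circKmerPositions <- function(s, k, circular) {
  L <- nchar(s)
  n <- if (circular) L else L - k + 1L
  if (n < 1L) return(NULL)
  list(pos = seq_len(n), km = .kmersAt(s, seq_len(n), k))
}

## merge anchor runs: posA strictly +1 steps; posB +1 ('+') or -1 ('-')
.anchorRuns <- function(pa, pb, strand, k) {
  if (!length(pa))
    return(data.frame(startA = integer(0), startB = integer(0),
                      width = integer(0), strand = character(0)))
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  n <- length(pa)
  step <- if (strand == "+") 1L else -1L
  newRun <- c(TRUE, !(pa[-1L] == pa[-n] + 1L & pb[-1L] == pb[-n] + step))
  runId <- cumsum(newRun)
  aStart <- tapply(pa, runId, min)
  cnt <- tabulate(runId)
  bFirst <- pb[newRun]
  bLast <- tapply(pb, runId, function(x) x[length(x)])
  startB <- if (strand == "+") bFirst else as.integer(bLast)
  data.frame(startA = as.integer(aStart), startB = as.integer(startB),
             width = as.integer(cnt + k - 1L), strand = strand,
             stringsAsFactors = FALSE)
}

## join the run ending at posA = La with the run starting at posA = 1
.wrapJoin <- function(runs, La, Lb, k, circA, circB, strand) {
  if (!circA || nrow(runs) < 2L) return(runs)
  iEnd <- which(runs$startA + (runs$width - k + 1L) - 1L == La)
  iBeg <- which(runs$startA == 1L)
  if (length(iEnd) != 1L || length(iBeg) != 1L || iEnd == iBeg) return(runs)
  nEnd <- runs$width[iEnd] - k + 1L   # anchors in the tail run
  if (strand == "+") {
    bNext <- runs$startB[iEnd] + nEnd
    ok <- circB && .mod1(bNext, Lb) == .mod1(runs$startB[iBeg], Lb)
  } else {
    ## tail run's last anchor B position
    bLastEnd <- runs$startB[iEnd] + runs$width[iEnd] - k
    bNext <- bLastEnd - nEnd
    bBegLast <- runs$startB[iBeg] + runs$width[iBeg] - k
    ok <- circB && .mod1(bNext, Lb) == .mod1(bBegLast, Lb)
  }
  if (!ok) return(runs)
  merged <- runs[iEnd, , drop = FALSE]
  ## tail + head anchors are contiguous across the origin
  merged$width <- runs$width[iEnd] - (k - 1L) + runs$width[iBeg]
  if (strand == "-") merged$startB <- runs$startB[iBeg]
  runs <- runs[-c(iEnd, iBeg), , drop = FALSE]
  rbind(runs, merged)
}

## bridge same-diagonal neighbours across identical non-unique stretches
.bridgeRuns <- function(runs, sA, sB, La, Lb, circA, circB, strand,
                       maxBridge) {
  if (nrow(runs) < 2L) return(runs)
  runs <- runs[order(runs$startA), , drop = FALSE]
  repeat {
    mergedAny <- FALSE
    i <- 1L
    while (i < nrow(runs)) {
      cur <- runs[i, ]; nxt <- runs[i + 1L, ]
      gA <- nxt$startA - (cur$startA + cur$width)
      if (strand == "+") {
        gB <- nxt$startB - (cur$startB + cur$width)
      } else {
        gB <- cur$startB - (nxt$startB + nxt$width)
      }
      if (gA >= 0L && gA == gB && gA <= maxBridge && gA > 0L) {
        gapA <- .circSubstr(sA, cur$startA + cur$width, gA)
        gapB <- if (strand == "+")
          .circSubstr(sB, cur$startB + cur$width, gB)
        else .rc(.circSubstr(sB, nxt$startB + nxt$width, gB))
        if (gapA == gapB) {
          runs$width[i] <- cur$width + gA + nxt$width
          if (strand == "-") runs$startB[i] <- nxt$startB
          runs <- runs[-(i + 1L), , drop = FALSE]
          mergedAny <- TRUE
          next
        }
      } else if (gA == 0L && gB == 0L) {
        runs$width[i] <- cur$width + nxt$width
        if (strand == "-") runs$startB[i] <- nxt$startB
        runs <- runs[-(i + 1L), , drop = FALSE]
        mergedAny <- TRUE
        next
      }
      i <- i + 1L
    }
    if (!mergedAny) break
  }
  runs
}

#' Anchor gap-free synteny blocks between two molecules
#'
#' Anchors are k-mers occurring exactly once in each molecule (counting
#' both strands); consecutive anchors on a common diagonal are merged
#' into maximal gap-free blocks, and blocks separated by an identical
#' non-unique stretch (e.g. a repeat copy inside a shared region) are
#' bridged after verifying the intervening sequences are equal.
#' Circularity is handled with wrap-around k-mers and an origin join.
#'
#' @param a,b [MitoMolecule-class] objects.
#' @param k Anchor k-mer size (default 31; near-unique at the 50-300 kb
#'   scale of mitogenome molecules).
#' @param minBlock Minimum reported block width in bp (default 100).
#' @param maxBridge Maximum bridged stretch in bp (default 25,000; covers
#'   the largest repeat family).
#' @return data.frame of blocks: `startA`, `startB`, `width`, `strand`
#'   (all 1-based; `startB` is the leftmost base of the block on B's
#'   forward strand).
#' @export
anchorBlocks <- function(a, b, k = 31L, minBlock = 100L, maxBridge = 25000L) {
  stopifnot(is(a, "MitoMolecule"), is(b, "MitoMolecule"))
  sA <- as.character(a); sB <- as.character(b)
  La <- nchar(sA); Lb <- nchar(sB)
  empty <- data.frame(startA = integer(0), startB = integer(0),
                      width = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  kA <- .circKmerPositions(sA, k, isCircular(a))
  kB <- .circKmerPositions(sB, k, isCircular(b))
  if (is.null(kA) || is.null(kB)) return(empty)
  rcA <- .rc(kA$km); rcB <- .rc(kB$km)

  cnt <- function(v) {
    dt <- data.table(kmer = v)
    dt[, .N, by = kmer]
  }
  cAf <- cnt(kA$km); cAr <- cnt(rcA)
  cBf <- cnt(kB$km); cBr <- cnt(rcB)

  dtA <- data.table(kmer = kA$km, pos = kA$pos)
  okA <- cAf[N == 1L][!cAr, on = "kmer"]   # unique fwd, absent rc
  dtA <- dtA[okA[, "kmer"], on = "kmer", nomatch = 0L]

  dtBf <- data.table(kmer = kB$km, pos = kB$pos)
  okBf <- cBf[N == 1L][!cBr, on = "kmer"]
  dtBf <- dtBf[okBf[, "kmer"], on = "kmer", nomatch = 0L]

  dtBr <- data.table(kmer = rcB, pos = kB$pos)
  okBr <- cBr[N == 1L][!cBf, on = "kmer"]
  dtBr <- dtBr[okBr[, "kmer"], on = "kmer", nomatch = 0L]

  plus <- dtBf[dtA, on = "kmer", nomatch = 0L]    # pos (B), i.pos (A)
  minus <- dtBr[dtA, on = "kmer", nomatch = 0L]

  runsP <- .anchorRuns(plus$i.pos, plus$pos, "+", k)
  runsM <- .anchorRuns(minus$i.pos, minus$pos, "-", k)
  runsP <- .wrapJoin(runsP, La, Lb, k, isCircular(a), isCircular(b), "+")
  runsM <- .wrapJoin(runsM, La, Lb, k, isCircular(a), isCircular(b), "-")
  runsP <- .bridgeRuns(runsP, sA, sB, La, Lb, isCircular(a), isCircular(b),
                       "+", maxBridge)
  runsM <- .bridgeRuns(runsM, sA, sB, La, Lb, isCircular(a), isCircular(b),
                       "-", maxBridge)
  blocks <- rbind(runsP, runsM)
  if (!nrow(blocks)) return(empty)
  blocks$width <- pmin(blocks$width, min(La, Lb))
  blocks <- blocks[blocks$width >= minBlock, , drop = FALSE]
  if (!nrow(blocks)) return(empty)
  blocks$startA <- .mod1(blocks$startA, La)
  blocks$startB <- .mod1(blocks$startB, Lb)
  blocks <- blocks[order(blocks$startA), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Shared and unique sequence totals from synteny blocks
#'
#' `shared` is the summed block width; unique totals are the
#' complements. On gap-free blocks the identities
#' `shared + uniqueA = length(A)` and `shared + uniqueB = length(B)`
#' hold exactly.
#'
#' @param blocks data.frame from [anchorBlocks()].
#' @param lenA,lenB Molecule lengths in bp.
#' @return data.frame with one row: `shared`, `uniqueA`, `uniqueB`.
#' @export
sharedUnique <- function(blocks, lenA, lenB) {
  if (nrow(blocks) > 1L) {
    o <- order(blocks$startA)
    sA <- blocks$startA[o]; w <- blocks$width[o]
    if (any(sA[-1L] < (sA + w)[-length(sA)]))
      stop("internal error: overlapping synteny blocks")
  }
  shared <- sum(blocks$width)
  data.frame(shared = shared, uniqueA = lenA - shared,
             uniqueB = lenB - shared)
}

## weighted longest cyclically-increasing subsequence of B positions in
## A order; returns indices of the consistent backbone
.cyclicBackbone <- function(startB, width, Lb) {
  m <- length(startB)
  if (m <= 2L) return(seq_len(m))
  best <- NULL; bestW <- -1
  for (r in seq_len(m)) {
    idx <- c(seq.int(r, m), if (r > 1L) seq.int(1L, r - 1L))
    rel <- (startB[idx] - startB[r]) %% Lb
    ## weighted LIS (strictly increasing) over rel
    wts <- width[idx]
    score <- wts; prev <- rep(0L, m)
    for (i in seq_len(m)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (rel[j] < rel[i] && score[j] + wts[i] > score[i]) {
          score[i] <- score[j] + wts[i]
          prev[i] <- j
        }
      }
    }
    i <- which.max(score)
    chain <- integer(0)
    while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
    tot <- sum(wts[chain])
    if (tot > bestW) { bestW <- tot; best <- idx[chain] }
  }
  sort(best)
}

## circular complement of covered intervals, as a data.frame(start, width)
.coverageGaps <- function(starts, widths, L, circular) {
  if (!length(starts))
    return(data.frame(start = 1L, width = L))
  iv <- data.frame(s = .mod1(starts, L), w = pmin(widths, L))
  ## unroll wrap-around intervals
  rows <- list()
  for (i in seq_len(nrow(iv))) {
    e <- iv$s[i] + iv$w[i] - 1L
    if (e <= L) rows[[length(rows) + 1L]] <- c(iv$s[i], e)
    else {
      rows[[length(rows) + 1L]] <- c(iv$s[i], L)
      rows[[length(rows) + 1L]] <- c(1L, e - L)
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1L) for (i in seq.int(2L, nrow(m))) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2] + 1L) {
      merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- m[i, ]
    }
  }
  cov <- do.call(rbind, merged)
  gaps <- list()
  for (i in seq_len(nrow(cov))) {
    e <- cov[i, 2]
    nxtS <- if (i < nrow(cov)) cov[i + 1, 1] else
      (if (circular) cov[1, 1] + L else L + 1L)
    g <- nxtS - e - 1L
    if (g > 0L) gaps[[length(gaps) + 1L]] <- c(.mod1(e + 1L, L), g)
  }
  if (!length(gaps)) return(data.frame(start = integer(0), width = integer(0)))
  g <- do.call(rbind, gaps)
  data.frame(start = as.integer(g[, 1]), width = as.integer(g[, 2]))
}

## flanking-repeat refinement: direct short-repeat pair whose copies
## bracket the raw block. Works in local window coordinates; returns the
## refined block (region strictly between the copies) in molecule
## coordinates, or NULL.
.refineFlanks <- function(mol, rawStart, rawWidth, window, minLen, maxLen) {
  L <- length(mol)
  window <- min(window, max(0L, (L - rawWidth) %/% 2L))
  regionStart <- rawStart - window
  regionWidth <- rawWidth + 2L * window
  if (regionWidth > L || regionWidth < 2L * minLen) return(NULL)
  region <- MitoMolecule("window", circularSubseq(mol, regionStart, regionWidth))
  reps <- findShortRepeats(region, 1L, regionWidth,
                           minLen = minLen, maxLen = maxLen)
  reps <- reps[reps$orientation == "direct", , drop = FALSE]
  if (!nrow(reps)) return(NULL)
  locStart <- window + 1L               # raw block in window coordinates
  locEnd <- window + rawWidth
  slack <- maxLen
  for (i in seq_len(nrow(reps))) {      # sorted longest first
    c1s <- reps$startA[i]; c1e <- c1s + reps$length[i] - 1L
    c2s <- reps$startB[i]; c2e <- c2s + reps$length[i] - 1L
    if (abs(c1s - locStart) > slack) next
    if (abs(c2e - locEnd) > slack) next
    core <- c2s - c1e - 1L
    if (core <= 0L) next
    out <- reps[i, , drop = FALSE]
    out$molecule <- moleculeId(mol)
    out$startA <- .mod1(c1s + regionStart - 1L, L)
    out$startB <- .mod1(c2s + regionStart - 1L, L)
    return(list(start = .mod1(c1e + 1L + regionStart - 1L, L),
                width = as.integer(core),
                flankLen = reps$length[i], flank = out))
  }
  NULL
}

#' Detect rearrangements between two molecules
#'
#' Orders the synteny blocks along molecule A and reads events off the
#' cyclic order: a block whose position in B breaks the cyclic backbone
#' is a translocation; a strand-flipped block is an inversion; sequence
#' covered in only one molecule is an insertion (B only) or deletion (A
#' only). When a direct short-repeat pair brackets a
#' translocated/inserted block, the block boundaries are refined to the
#' region strictly between the two flank copies (the biologically moved
#' unit) and the flank length is reported.
#'
#' @param blocks data.frame from [anchorBlocks()].
#' @param a,b The two [MitoMolecule-class] objects compared.
#' @param minEvent Minimum event size in bp (default 200).
#' @param flankWindow Window for breakpoint flank search (default 500).
#' @return data.frame of events: `type`, `startA`, `endA`, `startB`,
#'   `endB`, `blockLength`, `flankLen` (NA when no flanking repeat is
#'   found).
#' @export
detectRearrangements <- function(blocks, a, b, minEvent = 200L,
                                 flankWindow = 500L) {
  La <- length(a); Lb <- length(b)
  cov <- sum(blocks$width)
  if (cov < 0.5 * min(La, Lb))
    warning("synteny blocks cover less than half of the molecules; ",
            "rearrangement calls are low-confidence")
  empty <- data.frame(type = character(0), startA = integer(0),
                      endA = integer(0), startB = integer(0),
                      endB = integer(0), blockLength = integer(0),
                      flankLen = integer(0), stringsAsFactors = FALSE)
  if (!nrow(blocks)) return(empty)

  ## global orientation: if B is mostly reverse-complemented, flip it
  wMinus <- sum(blocks$width[blocks$strand == "-"])
  flipped <- wMinus > sum(blocks$width) / 2
  if (flipped) {
    blocks$startB <- Lb - (blocks$startB + blocks$width - 1L) + 1L
    blocks$strand <- ifelse(blocks$strand == "-", "+", "-")
  }
  events <- list()
  addEvent <- function(type, sA, eA, sB, eB, len, flankLen) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, startA = sA, endA = eA, startB = sB, endB = eB,
      blockLength = as.integer(len), flankLen = flankLen,
      stringsAsFactors = FALSE)
  }

  ## inversions
  invB <- blocks$strand == "-" & blocks$width >= minEvent
  for (i in which(invB)) {
    addEvent("inversion", blocks$startA[i],
             blocks$startA[i] + blocks$width[i] - 1L,
             blocks$startB[i], blocks$startB[i] + blocks$width[i] - 1L,
             blocks$width[i], NA_integer_)
  }

  ## translocations: blocks off the weighted cyclic backbone
  bl <- blocks[order(blocks$startA), , drop = FALSE]
  backbone <- .cyclicBackbone(bl$startB, bl$width, Lb)
  off <- setdiff(seq_len(nrow(bl)), backbone)
  for (i in off) {
    if (bl$width[i] < minEvent) next
    ref <- .refineFlanks(a, bl$startA[i], bl$width[i], flankWindow,
                         20L, 200L)
    if (!is.null(ref)) {
      addEvent("translocation", ref$start, .mod1(ref$start + ref$width - 1L, La),
               bl$startB[i], bl$startB[i] + bl$width[i] - 1L,
               ref$width, ref$flankLen)
    } else {
      addEvent("translocation", bl$startA[i],
               bl$startA[i] + bl$width[i] - 1L,
               bl$startB[i], bl$startB[i] + bl$width[i] - 1L,
               bl$width[i], NA_integer_)
    }
  }

  ## insertions (B-only sequence) and deletions (A-only sequence)
  gapsA <- .coverageGaps(blocks$startA, blocks$width, La, isCircular(a))
  gapsA <- gapsA[gapsA$width >= minEvent, , drop = FALSE]
  for (i in seq_len(nrow(gapsA))) {
    ref <- .refineFlanks(a, gapsA$start[i], gapsA$width[i], flankWindow,
                         20L, 200L)
    if (!is.null(ref))
      addEvent("deletion", ref$start, .mod1(ref$start + ref$width - 1L, La),
               NA_integer_, NA_integer_, ref$width, ref$flankLen)
    else
      addEvent("deletion", gapsA$start[i],
               .mod1(gapsA$start[i] + gapsA$width[i] - 1L, La),
               NA_integer_, NA_integer_, gapsA$width[i], NA_integer_)
  }
  gapsB <- .coverageGaps(blocks$startB, blocks$width, Lb, isCircular(b))
  gapsB <- gapsB[gapsB$width >= minEvent, , drop = FALSE]
  for (i in seq_len(nrow(gapsB))) {
    ref <- .refineFlanks(b, gapsB$start[i], gapsB$width[i], flankWindow,
                         20L, 200L)
    if (!is.null(ref))
      addEvent("insertion", NA_integer_, NA_integer_, ref$start,
               .mod1(ref$start + ref$width - 1L, Lb), ref$width,
               ref$flankLen)
    else
      addEvent("insertion", NA_integer_, NA_integer_, gapsB$start[i],
               .mod1(gapsB$start[i] + gapsB$width[i] - 1L, Lb),
               gapsB$width[i], NA_integer_)
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Breakpoint flanking-repeat discovery for one event
#'
#' Searches windows around both breakpoints of a translocation or
#' insertion for a direct short-repeat pair whose copies bracket the
#' block, and returns the longest such pair — the candidate substrate of
#' the recombination that moved the block.
#'
#' @param event One row of the [detectRearrangements()] data.frame.
#' @param a,b The compared [MitoMolecule-class] objects.
#' @param window Search window in bp around each breakpoint (default
#'   500).
#' @param minLen,maxLen Flank length bounds (defaults 20 and 200).
#' @return One row of a [findRepeats()]-style data.frame, or `NULL` when
#'   no flanking pair exists.
#' @export
breakpointFlanks <- function(event, a, b, window = 500L, minLen = 20L,
                             maxLen = 200L) {
  stopifnot(nrow(event) == 1L)
  tryOn <- function(mol, s, e) {
    if (is.na(s)) return(NULL)
    wd <- (e - s) %% length(mol) + 1L
    ref <- .refineFlanks(mol, s, wd, window, minLen, maxLen)
    if (is.null(ref)) NULL else ref$flank
  }
  ## prefer the molecule where the block sits in its moved context
  res <- tryOn(b, event$startB, event$endB)
  if (is.null(res)) res <- tryOn(a, event$startA, event$endA)
  res
}

#' Intergenic distance between two named features
#'
#' Reports the length of the intergenic region between two annotated
#' features on the same molecule (bases strictly between the end of the
#' first and the start of the second, in molecule order) — the
#' arrangement report used to compare e.g. the pseudo-cob to rps10
#' spacing across genomes.
#'
#' @param annotations data.frame from [readGff3Annotations()].
#' @param geneX,geneY Feature identifiers.
#' @return Integer distance in bp (0 for abutting features).
#' @export
reportIntergenic <- function(annotations, geneX, geneY) {
  ax <- annotations[annotations$geneId == geneX, , drop = FALSE]
  ay <- annotations[annotations$geneId == geneY, , drop = FALSE]
  if (!nrow(ax)) stop("feature '", geneX, "' not found")
  if (!nrow(ay)) stop("feature '", geneY, "' not found")
  best <- NA_integer_
  for (i in seq_len(nrow(ax))) for (j in seq_len(nrow(ay))) {
    if (ax$molecule[i] != ay$molecule[j]) next
    d <- ay$start[j] - ax$end[i] - 1L
    if (d >= 0L && (is.na(best) || d < best)) best <- d
  }
  if (is.na(best))
    stop("'", geneX, "' and '", geneY,
         "' are not ordered X-then-Y on a common molecule")
  best
}
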
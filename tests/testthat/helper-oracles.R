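## Independent brute-force oracles used to freeze expected values.
## These scan every diagonal / anti-diagonal of the circular sequence
## directly and never share code with the package's seed-and-extend
## implementation.

.oracleComp <- function(v) chartr("ACGT", "TGCA", v)

## maximal repeated pairs (direct + inverted) of a circular sequence by
## exhaustive diagonal scanning; O(L^2), for sequences up to a few kb
bruteRepeats <- function(s, minLen) {
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  res <- list()
  addPair <- function(a, b, len, orientation) {
    lo <- min(a, b); hi <- max(a, b)
    res[[length(res) + 1L]] <<- data.frame(
      startA = lo, startB = hi, length = len, orientation = orientation,
      stringsAsFactors = FALSE)
  }
  circRuns <- function(eq) {
    ## maximal circular runs of TRUE; returns start, len
    if (all(eq)) return(data.frame(start = 1L, len = L))
    d <- c(eq, eq)
    r <- rle(d)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & starts <= L
    data.frame(start = starts[keep], len = pmin(r$lengths[keep], L))
  }
  ## direct: copy at i matches copy at i+d (mod L)
  for (d in seq_len(L - 1L)) {
    shifted <- v[((seq_len(L) - 1L + d) %% L) + 1L]
    runs <- circRuns(v == shifted)
    runs <- runs[runs$len >= minLen, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      a <- runs$start[r]; len <- runs$len[r]
      b <- ((a - 1L + d) %% L) + 1L
      if (len > min(d, L - d)) next   # overlapping copies (tandem)
      addPair(a, b, len, "direct")
    }
  }
  ## inverted: s[x] == comp(s[(C - x) mod L]) along anti-diagonal C
  w <- .oracleComp(v)
  for (C in seq_len(L)) {
    partner <- ((C - seq_len(L)) %% L) + 1L
    runs <- circRuns(v == w[partner])
    runs <- runs[runs$len >= minLen, , drop = FALSE]
    for (r in seq_len(nrow(runs))) {
      a <- runs$start[r]; len <- runs$len[r]
      aEnd <- a + len - 1L
      b <- ((C - aEnd) %% L) + 1L          # partner of the run's last base
      if (a == b && len == L) next
      ## overlap of [a, a+len) and [b, b+len) mod L -> skip palindromic
      offs <- ((b - a) %% L)
      if (offs < len || ((a - b) %% L) < len) next
      addPair(a, b, len, "inverted")
    }
  }
  if (!length(res))
    return(data.frame(startA = integer(0), startB = integer(0),
                      length = integer(0), orientation = character(0)))
  df <- unique(do.call(rbind, res))
  ## suppress pairs contained in longer ones (reporting convention)
  df <- df[order(-df$length), , drop = FALSE]
  within <- function(s2, w2, s1, w1) ((s2 - s1) %% L) + w2 <= w1
  keep <- rep(TRUE, nrow(df))
  for (j in seq_len(nrow(df))) {
    if (j == 1L) next
    for (i in seq_len(j - 1L)) {
      if (!keep[i]) next
      contA <- within(df$startA[j], df$length[j], df$startA[i], df$length[i]) ||
        within(df$startA[j], df$length[j], df$startB[i], df$length[i])
      contB <- within(df$startB[j], df$length[j], df$startA[i], df$length[i]) ||
        within(df$startB[j], df$length[j], df$startB[i], df$length[i])
      if (contA && contB) { keep[j] <- FALSE; break }
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## does a window occur in the circular parent (either strand)?
bruteOccurs <- function(parent, window) {
  d <- paste0(parent, parent)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(window)))
  grepl(window, d, fixed = TRUE) || grepl(rc, d, fixed = TRUE)
}

## six-frame brute-force ORF scan of a circular sequence: returns
## (start, width, strand, lengthCodons) like findOrfs
bruteOrfs <- function(s, minCodons, startCodon = "ATG") {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(s)
  scan <- function(str, strand) {
    n <- nchar(str)
    out <- list()
    for (f in 1:3) {
      cs <- seq.int(f, n - 2L, by = 3L)
      cod <- substring(str, cs, cs + 2L)
      open <- NA_integer_
      for (i in seq_along(cod)) {
        if (cod[i] %in% stops) {
          if (!is.na(open) && (i - open) >= minCodons)
            out[[length(out) + 1L]] <- c(cs[open], cs[i] + 2L, i - open)
          open <- NA_integer_
        } else if (is.na(open) && cod[i] == startCodon) open <- i
      }
    }
    out
  }
  d <- paste0(s, s)
  rows <- list()
  for (hit in scan(d, "+")) {
    wd <- hit[2] - hit[1] + 1L
    if (wd > L) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = ((hit[1] - 1L) %% L) + 1L, width = wd, strand = "+",
      lengthCodons = hit[3], stringsAsFactors = FALSE)
  }
  rd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(d)))
  for (hit in scan(rd, "-")) {
    wd <- hit[2] - hit[1] + 1L
    if (wd > L) next
    fs <- nchar(d) - hit[2] + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      start = ((fs - 1L) %% L) + 1L, width = wd, strand = "-",
      lengthCodons = hit[3], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0), lengthCodons = integer(0)))
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## random circular molecule helper
randMolecule <- function(n, seed, id = "rand", circular = TRUE) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  MitoMolecule(id, s, circular = circular)
}

## plant a repeat pair into a background string; returns the sequence
plantPair <- function(bg, rep1, pos1, pos2, inverted = FALSE) {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  len <- nchar(rep1)
  s <- bg
  substr(s, pos1, pos1 + len - 1L) <- rep1
  substr(s, pos2, pos2 + len - 1L) <- if (inverted) rc(rep1) else rep1
  s
}
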
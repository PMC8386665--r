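#' @importFrom data.table data.table as.data.table setkey setorder :=
#' @import methods
#' @importFrom stats rbinom rlnorm runif median setNames
#' @importFrom utils head tail write.table read.delim
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "kmer", "pos", "i.pos", "N", "grp", "diag", "anti", "strand", "tname",
  "qname", "value", "n", "."
))

## 1-based circular index
.mod1 <- function(pos, L) ((pos - 1L) %% L) + 1L

.BASES <- c("A", "C", "G", "T")

## vectorised reverse complement of character sequences
.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.comp <- function(x) chartr("ACGTN", "TGCAN", x)

## random background sequence at a given GC content
.randSeq <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

## substring of a circular sequence (character), 1-based start, may wrap
.circSubstr <- function(s, start, width) {
  L <- nchar(s)
  stopifnot(width <= L)
  start <- .mod1(start, L)
  end <- start + width - 1L
  if (end <= L) {
    substr(s, start, end)
  } else {
    paste0(substr(s, start, L), substr(s, 1L, end - L))
  }
}

## all k-mers starting at positions `starts` of (possibly wrapped) sequence
.kmersAt <- function(s, starts, k) {
  s2 <- paste0(s, substr(s, 1L, k - 1L))
  substring(s2, starts, starts + k - 1L)
}

## circular interval overlap (1-based starts, widths, modulo L)
.circOverlaps <- function(s1, w1, s2, w2, L) {
  a <- .mod1(s1, L); b <- .mod1(s2, L)
  ia <- c(a, a + L); ib <- c(b, b + L)
  for (x in ia) for (y in ib) {
    if (x < y + w2 && y < x + w1) return(TRUE)
  }
  FALSE
}

## lexicographically least rotation (Booth's algorithm), O(n)
.leastRotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  v <- utf8ToInt(paste0(s, s))
  f <- rep.int(-1L, 2L * n)
  kk <- 0L
  for (j in seq.int(2L, 2L * n)) {
    sj <- v[j]
    i <- f[j - kk - 1L]
    while (i != -1L && sj != v[kk + i + 2L]) {
      if (sj < v[kk + i + 2L]) kk <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != v[kk + i + 2L]) {
      if (sj < v[kk + 1L]) kk <- j - 1L
      f[j - kk] <- -1L
    } else {
      f[j - kk] <- i + 1L
    }
  }
  .circSubstr(s, kk + 1L, n)
}

#' Canonical form of a circular DNA sequence
#'
#' The canonical form is the lexicographically least rotation of the
#' sequence or of its reverse complement, whichever is smaller. Two
#' circular molecules are the same molecule iff their canonical forms are
#' equal, which makes this the deduplication key for recombination
#' products.
#'
#' @param x A character scalar, a [Biostrings::DNAString] or a
#'   [MitoMolecule].
#' @return A character scalar.
#' @export
canonicalCircularForm <- function(x) {
  s <- if (is(x, "MitoMolecule")) as.character(molSeq(x)) else as.character(x)
  m1 <- .leastRotation(s)
  m2 <- .leastRotation(.rc(s))
  if (m1 <= m2) m1 else m2
}

## run boundaries of equal adjacent values in a sorted vector
.groupStarts <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  c(1L, which(x[-1L] != x[-n]) + 1L)
}

#' Write a data frame as a TSV report
#'
#' Thin wrapper used by all report-emitting steps; writes tab-separated
#' values without quoting or row names.
#'
#' @param df A data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeTsvReport <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
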
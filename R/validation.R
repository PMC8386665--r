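## ---------------------------------------------------------------------
## "Reverse read mapping": map long reads onto predicted junction
## constructs (exact k-mer seeds, dominant-diagonal clustering, local
## alignment of the seeded window) and count the reads that span each
## breakpoint with a sufficient anchor on both sides. A PAF import path
## allows an external mapper to be used instead.
## ---------------------------------------------------------------------

#' Parameters for junction validation
#'
#' A junction that lies inside a repeat copy is only confirmable when
#' read anchors extend past the repeat ends into product-specific
#' context; [countSupport()] warns when `minAnchor` is smaller than the
#' repeat length of a junction it is asked to score. Three supporting
#' reads is the conventional long-read floor for structural evidence.
#'
#' @param minAnchor Required aligned bases on each side of the breakpoint
#'   (default 500).
#' @param minReads Spanning reads required to call a junction supported
#'   (default 3).
#' @param minIdentity Minimum alignment identity for a read to count
#'   (default 0.85).
#' @param seedK Seed k-mer size of the internal mapper (default 15).
#' @param band Seed diagonal band half-width in bp (default 100).
#' @param pad Read-window padding passed to the local aligner (default
#'   100).
#' @return A list of class `ValidationParams`.
#' @export
validationParams <- function(minAnchor = 500L, minReads = 3L,
                             minIdentity = 0.85, seedK = 15L,
                             band = 100L, pad = 100L) {
  structure(list(minAnchor = as.integer(minAnchor),
                 minReads = as.integer(minReads),
                 minIdentity = minIdentity, seedK = as.integer(seedK),
                 band = as.integer(band), pad = as.integer(pad)),
            class = "ValidationParams")
}

.asStringSet <- function(x, what) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(x)
    if (is.null(names(out))) names(out) <- paste0(what, seq_along(out))
    return(out)
  }
  if (is.list(x)) {
    chars <- vapply(x, function(e) {
      if (is(e, "MitoMolecule")) as.character(e) else as.character(e)
    }, character(1))
    nm <- names(x)
    if (is.null(nm)) nm <- vapply(seq_along(x), function(i) {
      if (is(x[[i]], "MitoMolecule")) moleculeId(x[[i]])
      else paste0(what, i)
    }, character(1))
    out <- Biostrings::DNAStringSet(chars)
    names(out) <- nm
    return(out)
  }
  stop("cannot interpret ", what)
}

.alnColumns <- function() c("qname", "qlen", "qstart", "qend", "strand",
                            "tname", "tlen", "tstart", "tend", "nmatch",
                            "alnlen", "mapq", "identity")

.emptyAlnDf <- function() {
  df <- data.frame(qname = character(0), qlen = integer(0),
                   qstart = integer(0), qend = integer(0),
                   strand = character(0), tname = character(0),
                   tlen = integer(0), tstart = integer(0), tend = integer(0),
                   nmatch = integer(0), alnlen = integer(0),
                   mapq = integer(0), identity = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Map long reads to junction constructs or molecules
#'
#' A deliberately simple deterministic long-read mapper: exact k-mer
#' seeds, the dominant seed diagonal per read/target/strand, and a local
#' alignment of the seeded read window against the target. The best hit
#' per read and target is reported. For real data an external mapper can
#' be used instead through [readPaf()]/[pafToAlignments()].
#'
#' @param reads Reads as a [Biostrings::DNAStringSet], character vector
#'   or list.
#' @param targets Targets (junction constructs or molecules), same types
#'   accepted.
#' @param params A [validationParams()] object.
#' @return data.frame of alignment records (PAF-compatible columns plus
#'   `identity`): `qname`, `qlen`, `qstart`, `qend`, `strand`, `tname`,
#'   `tlen`, `tstart`, `tend`, `nmatch`, `alnlen`, `mapq`, `identity`.
#'   Read coordinates refer to the original read orientation.
#' @export
mapReads <- function(reads, targets, params = validationParams()) {
  stopifnot(inherits(params, "ValidationParams"))
  reads <- .asStringSet(reads, "read")
  targets <- .asStringSet(targets, "target")
  if (length(reads) == 0L) return(.emptyAlnDf())
  k <- params$seedK

  tchars <- as.character(targets)
  tlens <- nchar(tchars)
  tTab <- data.table(
    kmer = unlist(lapply(tchars, function(s)
      substring(s, seq_len(nchar(s) - k + 1L), seq_len(nchar(s) - k + 1L) + k - 1L)),
      use.names = FALSE),
    tname = rep(names(targets), pmax(tlens - k + 1L, 0L)),
    tpos = unlist(lapply(tlens, function(n) seq_len(max(n - k + 1L, 0L))),
                  use.names = FALSE)
  )
  setkey(tTab, kmer)

  rchars <- as.character(reads)
  rlens <- nchar(rchars)
  qParts <- vector("list", 2L * length(reads))
  for (i in seq_along(rchars)) {
    for (st in c("+", "-")) {
      s <- if (st == "+") rchars[i] else .rc(rchars[i])
      npos <- nchar(s) - k + 1L
      if (npos < 1L) next
      qParts[[2L * (i - 1L) + (st == "-") + 1L]] <- data.table(
        kmer = substring(s, seq_len(npos), seq_len(npos) + k - 1L),
        qname = names(reads)[i], strand = st, qpos = seq_len(npos))
    }
  }
  qTab <- data.table::rbindlist(qParts[!vapply(qParts, is.null, logical(1))])
  if (nrow(qTab) == 0L) return(.emptyAlnDf())
  hits <- tTab[qTab, on = "kmer", allow.cartesian = TRUE, nomatch = 0L]
  if (nrow(hits) == 0L) return(.emptyAlnDf())

  out <- list()
  hits[, grp := paste(qname, tname, strand, sep = "\r")]
  for (h in split(hits, by = "grp")) {
    qn <- h$qname[1]; tn <- h$tname[1]; st <- h$strand[1]
    dg <- h$qpos - h$tpos
    dens <- table(round(dg / params$band))
    center <- as.integer(names(dens)[which.max(dens)]) * params$band
    sel <- abs(dg - center) <= 2L * params$band
    h <- h[sel]
    if (nrow(h) < 3L) next
    rlen <- rlens[[match(qn, names(reads))]]
    rseq <- if (st == "+") rchars[[match(qn, names(reads))]]
            else .rc(rchars[[match(qn, names(reads))]])
    qlo <- max(1L, min(h$qpos) - params$pad)
    qhi <- min(rlen, max(h$qpos) + k - 1L + params$pad)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(substr(rseq, qlo, qhi)),
      subject = targets[[tn]],
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -4),
      gapOpening = 4, gapExtension = 2)
    alnlen <- nchar(as.character(Biostrings::alignedPattern(aln)))
    if (alnlen < k) next
    nm <- Biostrings::nmatch(aln)
    tstart <- IRanges::start(Biostrings::subject(aln))
    tend <- IRanges::end(Biostrings::subject(aln))
    qs <- qlo + IRanges::start(Biostrings::pattern(aln)) - 1L
    qe <- qlo + IRanges::end(Biostrings::pattern(aln)) - 1L
    if (st == "-") { tmp <- qs; qs <- rlen - qe + 1L; qe <- rlen - tmp + 1L }
    out[[length(out) + 1L]] <- data.frame(
      qname = qn, qlen = rlen, qstart = qs, qend = qe, strand = st,
      tname = tn, tlen = tlens[[match(tn, names(targets))]],
      tstart = tstart, tend = tend, nmatch = nm, alnlen = alnlen,
      mapq = 60L, identity = nm / alnlen,
      score = BiocGenerics::score(aln), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyAlnDf())
  df <- do.call(rbind, out)
  ## best hit per read per target (across strands)
  df <- df[order(df$qname, df$tname, -df$score), , drop = FALSE]
  df <- df[!duplicated(df[, c("qname", "tname")]), , drop = FALSE]
  df$score <- NULL
  rownames(df) <- NULL
  df
}

#' Convert an imported PAF table to alignment records
#'
#' Adds the `identity` column (`nmatch/alnlen`) so PAF rows produced by
#' an external mapper can be fed to [countSupport()] in place of
#' [mapReads()] output.
#'
#' @param paf data.frame from [readPaf()].
#' @return Alignment record data.frame.
#' @export
pafToAlignments <- function(paf) {
  paf$identity <- ifelse(paf$alnlen > 0, paf$nmatch / paf$alnlen, 0)
  paf
}

## normalize junction input: list of Junction, or products carrying them
.junctionTable <- function(junctions) {
  if (is(junctions, "Junction")) junctions <- list(junctions)
  jl <- list()
  for (j in junctions) {
    if (is(j, "IsoformProduct")) jl <- c(jl, productJunctions(j))
    else if (is(j, "Junction")) jl <- c(jl, list(j))
    else stop("junctions must be Junction or IsoformProduct objects")
  }
  if (!length(jl))
    return(data.frame(junction = character(0), w = integer(0),
                      repeatLen = integer(0), novel = logical(0),
                      construct = character(0), stringsAsFactors = FALSE))
  data.frame(
    junction = vapply(jl, junctionId, character(1)),
    w = vapply(jl, function(x) x@w, integer(1)),
    repeatLen = vapply(jl, function(x) x@repeatLen, integer(1)),
    novel = vapply(jl, isNovel, logical(1)),
    construct = vapply(jl, junctionConstruct, character(1)),
    stringsAsFactors = FALSE)
}

#' Count read support for predicted junctions
#'
#' A read supports a junction when its alignment to the junction
#' construct covers at least `minAnchor` bases on both sides of the
#' breakpoint (the construct midpoint) at sufficient identity. A
#' junction is `supported` when at least `minReads` reads span it.
#'
#' @param alignments Alignment records from [mapReads()] or
#'   [pafToAlignments()], targeting junction constructs.
#' @param junctions Junctions (list of [Junction-class] or of
#'   [IsoformProduct-class] carrying junctions).
#' @param params A [validationParams()] object; `minAnchor` must not
#'   exceed the junction flank width `w`.
#' @return data.frame: `junction`, `novel`, `nTotal`, `nSpanning`,
#'   `supported`.
#' @export
countSupport <- function(alignments, junctions, params = validationParams()) {
  stopifnot(inherits(params, "ValidationParams"))
  jt <- .junctionTable(junctions)
  if (nrow(jt) && any(params$minAnchor > jt$w))
    stop("minAnchor (", params$minAnchor,
         ") exceeds the junction flank width w")
  ## constructs are centred on the repeat copy, so anchors clear the
  ## copy ends iff minAnchor exceeds half the repeat length
  if (nrow(jt) && any(jt$repeatLen / 2 >= params$minAnchor, na.rm = TRUE))
    warning("minAnchor (", params$minAnchor, ") does not clear the ",
            "repeat half-extent of at least one junction; spanning ",
            "reads may not be isoform-specific")
  if (nrow(alignments)) {
    unknown <- setdiff(unique(alignments$tname), jt$junction)
    if (length(unknown))
      stop("alignments target unknown junction id(s): ",
           paste(unknown, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(jt)), function(i) {
    mid <- jt$w[i]   # last base of the left flank
    a <- alignments[alignments$tname == jt$junction[i] &
                      alignments$identity >= params$minIdentity, ,
                    drop = FALSE]
    spanning <- a$tstart <= mid - params$minAnchor + 1L &
      a$tend >= mid + params$minAnchor
    data.frame(junction = jt$junction[i], novel = jt$novel[i],
               nTotal = nrow(a), nSpanning = sum(spanning),
               supported = sum(spanning) >= params$minReads,
               stringsAsFactors = FALSE)
  })
  if (!length(res))
    return(data.frame(junction = character(0), novel = logical(0),
                      nTotal = integer(0), nSpanning = integer(0),
                      supported = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' End-to-end junction validation for a set of molecules
#'
#' For every circular molecule: detect repeat pairs (unless supplied),
#' enumerate single-event recombination products, predict their novel
#' junction constructs, map the reads, and count spanning support.
#'
#' @param molecules A [MitoMolecule-class] or list of them.
#' @param reads Reads as for [mapReads()].
#' @param params A [validationParams()] object.
#' @param repeats Optional precomputed [findRepeats()] data.frame
#'   (column `molecule` selects rows per molecule).
#' @param w Junction flank width in bp.
#' @param repeatParamsObj Parameters for repeat detection when `repeats`
#'   is not supplied.
#' @return List with `support` (per-junction data.frame with a
#'   `molecule` column) and `products` (per-molecule list of
#'   [IsoformProduct-class]).
#' @export
validateGenome <- function(molecules, reads, params = validationParams(),
                           repeats = NULL, w = 1000L,
                           repeatParamsObj = repeatParams()) {
  if (is(molecules, "MitoMolecule")) molecules <- list(molecules)
  supportAll <- list()
  productsAll <- list()
  for (m in molecules) {
    if (!isCircular(m)) next
    rep_m <- if (is.null(repeats)) findRepeats(m, repeatParamsObj)
             else repeats[repeats$molecule == moleculeId(m), , drop = FALSE]
    prods <- enumerateAllProducts(m, rep_m)
    prods <- lapply(prods, predictJunctions, parent = m, w = w)
    productsAll[[moleculeId(m)]] <- prods
    jt <- .junctionTable(prods)
    jt <- jt[jt$novel, , drop = FALSE]
    if (!nrow(jt)) {
      supportAll[[moleculeId(m)]] <- data.frame(
        molecule = character(0), junction = character(0),
        novel = logical(0), nTotal = integer(0), nSpanning = integer(0),
        supported = logical(0), stringsAsFactors = FALSE)
      next
    }
    constructs <- Biostrings::DNAStringSet(jt$construct)
    names(constructs) <- jt$junction
    aln <- mapReads(reads, constructs, params)
    keepJ <- unlist(lapply(prods, function(p)
      Filter(isNovel, productJunctions(p))), recursive = FALSE)
    sup <- countSupport(aln, keepJ, params)
    sup <- cbind(molecule = moleculeId(m), sup, stringsAsFactors = FALSE)
    supportAll[[moleculeId(m)]] <- sup
  }
  support <- if (length(supportAll)) do.call(rbind, c(supportAll,
                                                      make.row.names = FALSE))
             else data.frame()
  list(support = support, products = productsAll)
}
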
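#' Read mitogenome molecules from FASTA
#'
#' Topology is self-described in the FASTA header through a
#' `circular=true|false` token (any other header word is kept as part of
#' the description); records without the token are linear. A
#' `molecule=<label>` token, when present, fills the molecule display
#' name (underscores are turned into spaces).
#'
#' @param path Path to a FASTA file.
#' @return A named list of [MitoMolecule-class] objects, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">m1 circular=true", "ACGT"), tf)
#' readMitoFasta(tf)[["m1"]]
#' @export
readMitoFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("invalid FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    toks <- strsplit(headers[i], "\\s+")[[1]]
    circ <- any(grepl("^circular=true$", toks, ignore.case = TRUE))
    mn <- grep("^molecule=", toks, value = TRUE)
    mn <- if (length(mn)) gsub("_", " ", sub("^molecule=", "", mn[1])) else NA_character_
    s <- toupper(as.character(set[[i]]))
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("record '", ids[i], "' contains illegal characters: ",
           paste(bad, collapse = ", "))
    out[[i]] <- MitoMolecule(ids[i], s, circular = circ, moleculeName = mn)
  }
  names(out) <- ids
  out
}

#' Write mitogenome molecules to FASTA
#'
#' Emits the `circular=true|false` and (when set) `molecule=<label>`
#' header tokens understood by [readMitoFasta()], so a write/read round
#' trip is the identity.
#'
#' @param molecules A [MitoMolecule-class] or a list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMitoFasta <- function(molecules, path) {
  if (is(molecules, "MitoMolecule")) molecules <- list(molecules)
  seqs <- Biostrings::DNAStringSet(lapply(molecules, molSeq))
  names(seqs) <- vapply(molecules, function(m) {
    h <- paste0(moleculeId(m), " circular=",
                if (isCircular(m)) "true" else "false")
    if (!is.na(moleculeName(m)))
      h <- paste0(h, " molecule=", gsub(" ", "_", moleculeName(m)))
    h
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Extract a (possibly wrapping) subsequence
#'
#' Coordinates are 1-based; `start` may be any integer for circular
#' molecules (interpreted modulo the length). Requests that run past the
#' end of a *linear* molecule are a topology error. With `strand = "-"`
#' the reverse complement of the extracted window is returned.
#'
#' @param x A [MitoMolecule-class].
#' @param start 1-based start position.
#' @param width Number of bases (1..length).
#' @param strand `"+"` or `"-"`.
#' @return Character scalar of `width` bases.
#' @export
circularSubseq <- function(x, start, width, strand = "+") {
  stopifnot(is(x, "MitoMolecule"))
  L <- length(x)
  if (width < 1L || width > L)
    stop("width must be in [1, ", L, "]")
  s <- as.character(x)
  if (isCircular(x)) {
    out <- .circSubstr(s, start, width)
  } else {
    if (start < 1L || start + width - 1L > L)
      stop("subsequence [", start, ", ", start + width - 1L,
           "] runs outside linear molecule '", moleculeId(x),
           "' (wrap-around requires circular topology)")
    out <- substr(s, start, start + width - 1L)
  }
  if (strand == "-") out <- .rc(out)
  out
}

#' Rotate a circular molecule to a new origin
#'
#' Returns the same circular molecule with position `newOrigin` moved to
#' position 1. Rotation never changes molecule length or content; all
#' structural results in this package are invariant under it (the choice
#' of origin on an assembled circular molecule is arbitrary).
#'
#' @param x A circular [MitoMolecule-class].
#' @param newOrigin 1-based position that becomes position 1.
#' @return A [MitoMolecule-class].
#' @export
rotateMolecule <- function(x, newOrigin) {
  stopifnot(is(x, "MitoMolecule"))
  if (!isCircular(x))
    stop("cannot rotate linear molecule '", moleculeId(x), "'")
  L <- length(x)
  MitoMolecule(moleculeId(x), .circSubstr(as.character(x), newOrigin, L),
               circular = TRUE, moleculeName = moleculeName(x))
}

#' Read gene annotations from GFF3
#'
#' Parsed with \pkg{rtracklayer}; coordinates stay in the GFF3/Bioconductor
#' convention (1-based, closed). The feature identifier is taken from the
#' `ID` attribute, falling back to `Name` or `gene`.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `molecule`, `geneId`, `type`,
#'   `start`, `end`, `width`, `strand`, `pseudo`.
#' @export
readGff3Annotations <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% colnames(md)) as.character(md[[col]]) else
    rep(NA_character_, length(gr))
  ids <- pick("ID")
  ids <- ifelse(is.na(ids), pick("Name"), ids)
  ids <- ifelse(is.na(ids), pick("gene"), ids)
  pseudoAttr <- pick("pseudo")
  data.frame(
    molecule = as.character(GenomicRanges::seqnames(gr)),
    geneId = ids,
    type = pick("type"),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    width = GenomicRanges::width(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    pseudo = grepl("^(Ψ|psi-?|pseudo-?)", ids, ignore.case = TRUE) |
      (!is.na(pseudoAttr) & tolower(pseudoAttr) %in% c("true", "1")),
    stringsAsFactors = FALSE
  )
}

#' Write gene annotations to GFF3
#'
#' Inverse of [readGff3Annotations()]; a write/read round trip preserves
#' molecule, id, coordinates and strand.
#'
#' @param annotations data.frame as returned by [readGff3Annotations()]
#'   (columns `molecule`, `geneId`, `start`, `end`, `strand`; `type`
#'   optional).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGff3Annotations <- function(annotations, path) {
  type <- if ("type" %in% names(annotations)) annotations$type else "gene"
  type[is.na(type)] <- "gene"
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$molecule,
    ranges = IRanges::IRanges(start = annotations$start, end = annotations$end),
    strand = annotations$strand
  )
  S4Vectors::mcols(gr)$ID <- annotations$geneId
  S4Vectors::mcols(gr)$type <- type
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
               "tname", "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")

#' Read a PAF alignment file
#'
#' Minimal parser for the 12 mandatory PAF columns (optional SAM-style
#' tags are ignored). PAF uses 0-based half-open coordinates; they are
#' converted to the package's 1-based closed convention.
#'
#' @param path Path to a PAF file.
#' @return A data.frame with the 12 mandatory columns, coordinates
#'   1-based closed.
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(qname = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), tname = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), nmatch = integer(0),
                      alnlen = integer(0), mapq = integer(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12L))
    stop("PAF line ", which(nf < 12L)[1],
         " has fewer than the 12 mandatory columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- data.frame(
    qname = m[, 1], qlen = as.integer(m[, 2]),
    qstart = as.integer(m[, 3]) + 1L, qend = as.integer(m[, 4]),
    strand = m[, 5],
    tname = m[, 6], tlen = as.integer(m[, 7]),
    tstart = as.integer(m[, 8]) + 1L, tend = as.integer(m[, 9]),
    nmatch = as.integer(m[, 10]), alnlen = as.integer(m[, 11]),
    mapq = as.integer(m[, 12]),
    stringsAsFactors = FALSE
  )
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad)) stop("PAF line ", bad[1], ": invalid strand")
  df
}

#' Write alignment records as PAF
#'
#' Inverse of [readPaf()] for the mandatory columns (coordinates are
#' converted back to 0-based half-open).
#'
#' @param alignments data.frame with the [readPaf()] columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePaf <- function(alignments, path) {
  a <- alignments
  for (col in setdiff(.PAF_COLS, names(a))) {
    a[[col]] <- switch(col, mapq = 60L, nmatch = NA_integer_, 0L)
  }
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   a$qname, a$qlen, a$qstart - 1L, a$qend, a$strand,
                   a$tname, a$tlen, a$tstart - 1L, a$tend,
                   a$nmatch, a$alnlen, a$mapq)
  writeLines(lines, path)
  invisible(path)
}
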
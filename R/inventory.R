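## ---------------------------------------------------------------------
## Gene-content accounting: category counts from annotations, ORF
## discovery on circles (six frames, origin-crossing), internal stop
## checks, presence/absence matrices across genomes.
## ---------------------------------------------------------------------

.GENE_CATEGORIES <- c("atp", "nad", "rps_rpl", "ccm", "cox", "sdh", "cob",
                      "matR", "mttB", "rRNA", "tRNA", "orf",
                      "plastid_derived", "pseudo")

.PLASTID_GENES <- c("petA", "petG", "petL", "psbJ", "psbL", "rpl23")

#' The conserved potato mitochondrial gene set
#'
#' The gene complement shared by potato mitogenomes: five ATP synthase
#' subunits, nine NADH dehydrogenase subunits, eleven ribosomal
#' proteins, four cytochrome c biogenesis genes, three cytochrome c
#' oxidase subunits, two succinate dehydrogenase subunits, cob, matR and
#' mttB, plus three rRNAs and the plastid-derived genes commonly found
#' inserted in the mitogenome.
#'
#' @return data.frame with columns `geneId` and `category`.
#' @export
conservedGeneTable <- function() {
  rbind(
    data.frame(geneId = c("atp1", "atp4", "atp6", "atp8", "atp9"),
               category = "atp"),
    data.frame(geneId = c("nad1", "nad2", "nad3", "nad4", "nad4L",
                          "nad5", "nad6", "nad7", "nad9"),
               category = "nad"),
    data.frame(geneId = c("rps1", "rps3", "rps4", "rps10", "rps12",
                          "rps13", "rps19", "rpl2", "rpl5", "rpl10",
                          "rpl16"),
               category = "rps_rpl"),
    data.frame(geneId = c("ccmB", "ccmC", "ccmFC", "ccmFN"),
               category = "ccm"),
    data.frame(geneId = c("cox1", "cox2", "cox3"), category = "cox"),
    data.frame(geneId = c("sdh3", "sdh4"), category = "sdh"),
    data.frame(geneId = "cob", category = "cob"),
    data.frame(geneId = "matR", category = "matR"),
    data.frame(geneId = "mttB", category = "mttB"),
    data.frame(geneId = c("rrn5", "rrn18", "rrn26"), category = "rRNA"),
    data.frame(geneId = .PLASTID_GENES, category = "plastid_derived"),
    stringsAsFactors = FALSE
  )
}

#' The 33-gene phylogeny marker set
#'
#' The common protein-coding genes used for concatenated phylogenies of
#' potato mitogenomes.
#'
#' @return Character vector of 33 gene identifiers.
#' @export
phylogenyGeneSet <- function() {
  c("atp1", "atp4", "atp6", "atp8", "atp9",
    "ccmB", "ccmC", "ccmFc", "ccmFn",
    "cob", "cox1", "cox2", "cox3", "matR", "mttB",
    "nad3", "nad4L", "nad6", "nad7", "nad9",
    "rpl10", "rpl16", "rpl2", "rpl5",
    "rps1", "rps10", "rps12", "rps13", "rps19", "rps3", "rps4",
    "sdh3", "sdh4")
}

#' Classify a gene identifier into the category lexicon
#'
#' @param geneId Character vector of identifiers; a leading `Ψ`/`psi-`/
#'   `pseudo-` marks pseudogenes.
#' @return Character vector of categories; `NA` for unclassifiable ids.
#' @export
categorizeGene <- function(geneId) {
  vapply(geneId, function(g) {
    if (grepl("^(Ψ|psi-?|pseudo-?)", g, ignore.case = FALSE)) return("pseudo")
    base <- g
    if (base %in% .PLASTID_GENES) return("plastid_derived")
    if (grepl("^atp", base)) return("atp")
    if (grepl("^nad", base)) return("nad")
    if (grepl("^(rps|rpl)", base)) return("rps_rpl")
    if (grepl("^ccm", base)) return("ccm")
    if (grepl("^cox", base)) return("cox")
    if (grepl("^sdh", base)) return("sdh")
    if (grepl("^cob", base)) return("cob")
    if (grepl("^matR$", base)) return("matR")
    if (grepl("^mttB$", base)) return("mttB")
    if (grepl("^(rrn|[0-9]+S_?rRNA)", base)) return("rRNA")
    if (grepl("^trn", base)) return("tRNA")
    if (grepl("^orf", base, ignore.case = TRUE)) return("orf")
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}

.STOPS <- c("TAA", "TAG", "TGA")

## ORFs in the three frames of one strand of a (possibly doubled) string
.orfsOneStrand <- function(s, minCodons, startCodons) {
  n <- nchar(s)
  out <- list()
  for (f in 1:3) {
    starts <- seq.int(f, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(s, starts, starts + 2L)
    isStart <- codons %in% startCodons
    isStop <- codons %in% .STOPS
    lastStop <- 0L
    pendingStart <- NA_integer_
    for (i in seq_along(codons)) {
      if (isStop[i]) {
        if (!is.na(pendingStart)) {
          ncod <- i - pendingStart          # codons excluding the stop
          if (ncod >= minCodons)
            out[[length(out) + 1L]] <- c(starts[pendingStart],
                                         starts[i] + 2L, ncod)
        }
        pendingStart <- NA_integer_
      } else if (is.na(pendingStart) && isStart[i]) {
        pendingStart <- i
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      lengthCodons = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], lengthCodons = m[, 3])
}

#' Find open reading frames
#'
#' Six-frame ORF discovery. ORFs are start-codon-initiated and
#' stop-terminated; `lengthCodons` excludes the stop codon, and the
#' reported interval includes it. On circular molecules frames are
#' computed on the doubled sequence and deduplicated modulo the length,
#' so origin-crossing ORFs are found once.
#'
#' @param x A [MitoMolecule-class].
#' @param minCodons Minimum ORF length in codons, excluding the stop
#'   (default 100).
#' @param startCodons Allowed start codons (default `"ATG"`; extensible
#'   to mitochondrial alternatives).
#' @return data.frame: `start`, `width`, `strand`, `lengthCodons`
#'   (molecule coordinates; `start` is the first base of the start codon
#'   on the ORF's strand, reported on forward coordinates).
#' @export
findOrfs <- function(x, minCodons = 100L, startCodons = "ATG") {
  stopifnot(is(x, "MitoMolecule"))
  s <- as.character(x)
  L <- nchar(s)
  circ <- isCircular(x)
  scanFwd <- if (circ) paste0(s, s) else s
  scanRev <- .rc(scanFwd)
  res <- list()
  fw <- .orfsOneStrand(scanFwd, minCodons, startCodons)
  if (nrow(fw)) {
    fw$strand <- "+"
    fw$startFwd <- fw$start
    res[[1L]] <- fw
  }
  rv <- .orfsOneStrand(scanRev, minCodons, startCodons)
  if (nrow(rv)) {
    rv$strand <- "-"
    ## map position on the reverse strand of the doubled sequence back to
    ## forward coordinates: the ORF occupies [n2-end+1, n2-start+1]
    n2 <- nchar(scanFwd)
    s0 <- n2 - rv$end + 1L
    rv$startFwd <- s0
    res[[2L]] <- rv
  }
  if (!length(res))
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0), lengthCodons = integer(0)))
  df <- do.call(rbind, res)
  df$width <- df$end - df$start + 1L
  if (circ) {
    df <- df[df$width <= L, , drop = FALSE]
    df$startMod <- .mod1(df$startFwd, L)
  } else {
    df$startMod <- df$startFwd
  }
  key <- paste(df$startMod, df$width, df$strand)
  df <- df[!duplicated(key), , drop = FALSE]
  out <- data.frame(start = df$startMod, width = df$width,
                    strand = df$strand, lengthCodons = df$lengthCodons,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Check a coding sequence for internal stop codons
#'
#' @param seq In-frame coding sequence (character or DNAString); length
#'   must be a multiple of 3.
#' @return List with `hasInternalStops` (logical; a stop codon occurs
#'   before the final codon) and `positions` (codon indices of internal
#'   stops).
#' @export
checkInternalStops <- function(seq) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("sequence length (", n, ") is not a multiple of 3")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  internal <- which(codons %in% .STOPS)
  internal <- internal[internal < length(codons)]
  list(hasInternalStops = length(internal) > 0L,
       positions = as.integer(internal))
}

#' Summarize gene content by category
#'
#' Counts annotated features per category of the fixed lexicon;
#' pseudogenes (`Ψ`-prefixed) are counted under `pseudo` regardless of
#' their base gene.
#'
#' @param annotations data.frame with at least `geneId` (e.g. from
#'   [readGff3Annotations()]); a logical `pseudo` column is honoured.
#' @return data.frame: `category`, `count` (all lexicon categories, zero
#'   included).
#' @export
summarizeInventory <- function(annotations) {
  counts <- stats::setNames(integer(length(.GENE_CATEGORIES)),
                            .GENE_CATEGORIES)
  if (NROW(annotations)) {
    cats <- categorizeGene(annotations$geneId)
    if ("pseudo" %in% names(annotations))
      cats[which(annotations$pseudo)] <- "pseudo"
    if (anyNA(cats))
      stop("unclassifiable gene id(s): ",
           paste(annotations$geneId[is.na(cats)], collapse = ", "))
    tab <- table(cats)
    counts[names(tab)] <- as.integer(tab)
  }
  data.frame(category = names(counts), count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Presence/absence matrix across genomes
#'
#' @param inventories Named list (one element per genome) of character
#'   vectors of gene/ORF identifiers, or of annotation data.frames with a
#'   `geneId` column.
#' @param groups Optional named character vector mapping genome ids to
#'   group labels; enables the group-specific report.
#' @return List with `matrix` (logical, genes x genomes) and
#'   `groupSpecific` (data.frame `geneId`, `group` of ids present in
#'   exactly one group; empty when `groups` is `NULL` or nothing is
#'   group-specific).
#' @export
presenceAbsence <- function(inventories, groups = NULL) {
  if (is.null(names(inventories)) || anyDuplicated(names(inventories)))
    stop("'inventories' must be uniquely named per genome")
  ids <- lapply(inventories, function(x)
    if (is.data.frame(x)) unique(x$geneId) else unique(as.character(x)))
  all <- sort(unique(unlist(ids)))
  m <- vapply(ids, function(g) all %in% g, logical(length(all)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(all))
  rownames(m) <- all
  colnames(m) <- names(inventories)
  gs <- data.frame(geneId = character(0), group = character(0),
                   stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    if (!all(colnames(m) %in% names(groups)))
      stop("every genome needs a group label")
    glab <- groups[colnames(m)]
    for (g in unique(glab)) {
      inG <- m[, glab == g, drop = FALSE]
      outG <- m[, glab != g, drop = FALSE]
      hit <- rowSums(inG) == ncol(inG) &
        (ncol(outG) == 0L | rowSums(outG) == 0L)
      if (any(hit))
        gs <- rbind(gs, data.frame(geneId = rownames(m)[hit], group = g,
                                   stringsAsFactors = FALSE))
    }
  }
  list(matrix = m, groupSpecific = gs)
}
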
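## ---------------------------------------------------------------------
## In silico PCR on circular templates and the mtDNA type decision rules
## (alpha ~2.4 kb product, beta ~1.6 kb, gamma = no product), plus the
## combined chloroplast/mitochondrial cytoplasm label.
## ---------------------------------------------------------------------

#' Define a primer pair
#'
#' @param name Pair name.
#' @param fwd,rev Primer sequences, 5'->3', 15-35 nt, no Ns.
#' @param maxMismatches Mismatches tolerated per primer site (default 2);
#'   the 3'-terminal base must always match exactly.
#' @param maxProduct Largest reported product in bp (default 5,000).
#' @return A list of class `PrimerPair`.
#' @export
primerPair <- function(name, fwd, rev, maxMismatches = 2L,
                       maxProduct = 5000L) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  for (p in c(fwd, rev)) {
    if (nchar(p) < 15L || nchar(p) > 35L)
      stop("primer length must be 15-35 nt: ", p)
    if (grepl("[^ACGT]", p)) stop("primers must be over A/C/G/T: ", p)
  }
  structure(list(name = name, fwd = fwd, rev = rev,
                 maxMismatches = as.integer(maxMismatches),
                 maxProduct = as.integer(maxProduct)),
            class = "PrimerPair")
}

#' Read primer pairs from a TSV config
#'
#' Columns: `name`, `fwd`, `rev`, and optionally `maxMismatches`,
#' `maxProduct`.
#'
#' @param path TSV file path.
#' @return List of [primerPair()] objects.
#' @export
readPrimerConfig <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "fwd", "rev")
  if (!all(need %in% names(df)))
    stop("primer config needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) primerPair(
    df$name[i], df$fwd[i], df$rev[i],
    maxMismatches = if ("maxMismatches" %in% names(df))
      df$maxMismatches[i] else 2L,
    maxProduct = if ("maxProduct" %in% names(df)) df$maxProduct[i] else 5000L))
}

#' Find primer binding sites on a template
#'
#' Both strands are scanned (with circular wrap-around on circular
#' templates); a site is reported when the primer matches with at most
#' `maxMismatches` mismatches *and* its 3'-terminal base matches exactly
#' (extension realism). Coordinates give the leftmost template base of
#' the site on the forward strand.
#'
#' @param x A [MitoMolecule-class].
#' @param primer Primer sequence, 5'->3'.
#' @param maxMismatches Allowed mismatches (default 2).
#' @return data.frame: `start`, `width`, `strand`, `mismatches`.
#' @export
findPrimerSites <- function(x, primer, maxMismatches = 2L) {
  stopifnot(is(x, "MitoMolecule"))
  primer <- toupper(primer)
  plen <- nchar(primer)
  s <- as.character(x)
  L <- nchar(s)
  scan <- if (isCircular(x)) paste0(s, substr(s, 1L, plen - 1L)) else s
  subj <- Biostrings::DNAString(scan)
  hits <- list()
  for (st in c("+", "-")) {
    pat <- if (st == "+") primer else .rc(primer)
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = maxMismatches,
                                  with.indels = FALSE)
    starts <- IRanges::start(m)
    starts <- starts[starts <= L]
    if (!length(starts)) next
    for (p0 in starts) {
      site <- substr(scan, p0, p0 + plen - 1L)
      ## 3' base: rightmost primer base; on '-', it binds the leftmost
      ## template position of the site
      three <- if (st == "+") substr(site, plen, plen) == substr(primer, plen, plen)
               else substr(site, 1L, 1L) == substr(.rc(primer), 1L, 1L)
      if (!three) next
      mm <- sum(utf8ToInt(site) != utf8ToInt(pat))
      if (mm > maxMismatches) next
      hits[[length(hits) + 1L]] <- data.frame(
        start = p0, width = plen, strand = st, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), width = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Amplify a primer pair on a template
#'
#' All convergent site combinations (a forward-strand site of one primer
#' with a downstream reverse-strand site of the other, distances modulo
#' the length on circular templates) with a product not exceeding
#' `maxProduct` are reported. The product runs from the 5' end of the
#' plus-strand site to the 5' end of the minus-strand site.
#'
#' @param x A [MitoMolecule-class] template.
#' @param pair A [primerPair()] object.
#' @return data.frame: `template`, `fwdStart`, `revStart`, `fwdPrimer`,
#'   `productLength`, `product` (sequence).
#' @export
amplify <- function(x, pair) {
  stopifnot(is(x, "MitoMolecule"), inherits(pair, "PrimerPair"))
  L <- length(x)
  sitesF <- findPrimerSites(x, pair$fwd, pair$maxMismatches)
  sitesR <- findPrimerSites(x, pair$rev, pair$maxMismatches)
  combos <- rbind(
    if (nrow(sitesF) && nrow(sitesR))
      expand.grid(i = which(sitesF$strand == "+"),
                  j = which(sitesR$strand == "-"), which = "FR",
                  stringsAsFactors = FALSE),
    if (nrow(sitesR) && nrow(sitesF))
      expand.grid(i = which(sitesR$strand == "+"),
                  j = which(sitesF$strand == "-"), which = "RF",
                  stringsAsFactors = FALSE))
  out <- list()
  for (r in seq_len(NROW(combos))) {
    if (combos$which[r] == "FR") {
      sp <- sitesF[combos$i[r], ]; sm <- sitesR[combos$j[r], ]
      fwdPrimer <- "fwd"
    } else {
      sp <- sitesR[combos$i[r], ]; sm <- sitesF[combos$j[r], ]
      fwdPrimer <- "rev"
    }
    span <- if (isCircular(x)) (sm$start + sm$width - 1L - sp$start) %% L + 1L
            else sm$start + sm$width - sp$start
    if (is.na(span) || span < sp$width + sm$width) next
    if (span > pair$maxProduct) next
    out[[length(out) + 1L]] <- data.frame(
      template = moleculeId(x), fwdStart = sp$start, revStart = sm$start,
      fwdPrimer = fwdPrimer, productLength = as.integer(span),
      product = circularSubseq(x, sp$start, span),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(template = character(0), fwdStart = integer(0),
                      revStart = integer(0), fwdPrimer = character(0),
                      productLength = integer(0), product = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("fwdStart", "revStart", "productLength")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

.MT_CLASSES <- c(alpha = 2400, beta = 1600)

#' Call the mtDNA type from marker-PCR products
#'
#' Decision rule of the marker locus: no product at all is gamma; a
#' product within `tolerance` of 2,400 bp is alpha; within `tolerance`
#' of 1,600 bp is beta; anything else — including products in two
#' different classes — is unknown (with the evidence reported).
#'
#' @param amplicons data.frame from [amplify()] with the
#'   type-discriminating pair (may be empty).
#' @param tolerance Relative size tolerance around the class centres
#'   (default 0.15; keeps the two classes disjoint).
#' @return List of class `MtDNATypeCall`: `mtType` (`"alpha"`, `"beta"`,
#'   `"gamma"` or `"unknown"`) and `evidence` (product lengths).
#' @export
callMtType <- function(amplicons, tolerance = 0.15) {
  lens <- if (NROW(amplicons)) amplicons$productLength else integer(0)
  if (!length(lens))
    return(structure(list(mtType = "gamma", evidence = integer(0)),
                     class = "MtDNATypeCall"))
  cls <- vapply(lens, function(l) {
    hit <- names(.MT_CLASSES)[abs(l - .MT_CLASSES) <= tolerance * .MT_CLASSES]
    if (length(hit) == 1L) hit else "unknown"
  }, character(1))
  u <- unique(cls)
  mt <- if (length(u) == 1L && u != "unknown") u else "unknown"
  structure(list(mtType = mt, evidence = as.integer(lens)),
            class = "MtDNATypeCall")
}

#' @export
print.MtDNATypeCall <- function(x, ...) {
  cat(sprintf("mtDNA type: %s (products: %s)\n", x$mtType,
              if (length(x$evidence)) paste(x$evidence, collapse = ", ")
              else "none"))
  invisible(x)
}

.GREEK <- c(alpha = "α", beta = "β", gamma = "γ")
.OBSERVED_CYTOPLASMS <- c("T/β", "S/β", "W/α", "W/γ")

#' Combine chloroplast and mtDNA types into a cytoplasm label
#'
#' Produces the conventional `cp/mt` label (e.g. `"W/γ"`, the
#' male-sterility-associated cytoplasm) and flags whether the
#' combination is among those observed in potato germplasm
#' (T/β, S/β, W/α, W/γ).
#'
#' @param mtType `"alpha"`, `"beta"` or `"gamma"` (or an `MtDNATypeCall`).
#' @param cpType Chloroplast type letter (`"T"`, `"S"`, `"W"`, `"A"`,
#'   ...).
#' @return List with `label` and `observed` (logical; `NA` for unknown
#'   inputs).
#' @export
combineCytoplasm <- function(mtType, cpType) {
  if (inherits(mtType, "MtDNATypeCall")) mtType <- mtType$mtType
  if (is.na(mtType) || is.na(cpType) || mtType == "unknown")
    return(list(label = "unknown", observed = NA))
  g <- .GREEK[[mtType]]
  if (is.null(g)) return(list(label = "unknown", observed = NA))
  label <- paste0(toupper(cpType), "/", g)
  list(label = label, observed = label %in% .OBSERVED_CYTOPLASMS)
}
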
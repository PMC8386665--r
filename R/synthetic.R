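## ---------------------------------------------------------------------
## Synthetic multipartite mitogenomes and long-read simulation.
##
## Profiles encode the published molecule sizes and repeat-family
## structure of the four potato mitogenome architectures (two clone
## groups plus two singleton clones). Backgrounds are random at a fixed
## GC; planted repeat copies are exact duplicates unless a divergence is
## requested. Inter-feature spacer lengths are a package choice (the
## source assemblies do not print repeat coordinates) and are recorded in
## the machine-readable truth.
## ---------------------------------------------------------------------

.seg <- function(kind, length, family = NA_character_, strand = "+",
                 copy = NA_integer_, segmentId = NA_character_) {
  data.frame(kind = kind, family = family, strand = strand,
             copy = copy, length = as.integer(length),
             segmentId = segmentId, stringsAsFactors = FALSE)
}

.bg <- function(length, segmentId) .seg("bg", length, segmentId = segmentId)
.feat <- function(family, length, strand = "+", copy = 1L)
  .seg("feature", length, family = family, strand = strand, copy = copy)

## Published repeat family lengths (bp). R1 is inverted in group A;
## OKA15 carries an expanded R1 and a reduced R2, and lacks R4.
.FAMILY_LEN <- list(
  default = c(R1 = 11916L, R2 = 7502L, R3 = 4513L, R4 = 1589L),
  oka15 = c(R1 = 13435L, R2 = 7076L)
)

.profileLayouts <- function(name) {
  switch(name,
    groupA = {
      ## molecules 1a/1b share a common core (~219.8 kb) carrying one R1
      ## copy and the full R2 pair; the second, inverted R1 copy sits in
      ## the 1a-specific segment, so 1b has a single unpaired R1 copy.
      shared <- rbind(
        .bg(50000, "A.S1"),
        .feat("R2", 7502, "+", 1L),
        .bg(40000, "A.S2"),
        .feat("R2", 7502, "+", 2L),
        .bg(50000, "A.S3"),
        .feat("R1", 11916, "+", 1L),
        .bg(52869, "A.S4")
      )
      uniqA <- rbind(
        .bg(30000, "A.U1"),
        .feat("R1", 11916, "-", 2L),
        .bg(35331, "A.U2")
      )
      mol2 <- rbind(
        .bg(20000, "A.M2a"),
        .feat("R4", 1589, "+", 1L),
        .bg(43411, "A.M2b"),   # R4 copy separation 45,000 bp
        .feat("R4", 1589, "+", 2L),
        .bg(46245, "A.M2c")
      )
      list(
        "molecule 1a" = rbind(shared, uniqA),
        "molecule 1b" = rbind(shared, .bg(9800, "A.U3")),
        "molecule 2" = mol2,
        "molecule 3" = .bg(49239, "A.M3")
      )
    },
    groupB = list(
      "molecule 1" = rbind(
        .bg(40000, "B.M1a"),
        .feat("R1", 11916, "+", 1L),
        .bg(78084, "B.M1b"),
        .feat("R1", 11916, "+", 2L),
        .bg(50000, "B.M1c"),
        .feat("R3", 4513, "+", 1L),
        .bg(30487, "B.M1d"),
        .feat("R3", 4513, "+", 2L),
        .bg(52956, "B.M1e")
      ),
      "molecule 2" = rbind(
        .bg(20000, "B.M2a"),
        .feat("R4", 1589, "+", 1L),
        .bg(43411, "B.M2b"),
        .feat("R4", 1589, "+", 2L),
        .bg(46854, "B.M2c")
      ),
      "molecule 3" = .bg(49167, "B.M3")
    ),
    clone10908 = list(
      "molecule 1" = rbind(
        .bg(40000, "C.M1a"),
        .feat("R1", 11916, "+", 1L),
        .bg(70000, "C.M1b"),
        .feat("R1", 11916, "+", 2L),
        .bg(50000, "C.M1c"),
        .feat("R2", 7502, "+", 1L),
        .bg(40000, "C.M1d"),
        .feat("R2", 7502, "+", 2L),
        .bg(56996, "C.M1e")
      ),
      "molecule 2" = rbind(
        .bg(20000, "C.M2a"),
        .feat("R4", 1589, "+", 1L),
        .bg(43411, "C.M2b"),
        .feat("R4", 1589, "+", 2L),
        .bg(45141, "C.M2c")
      ),
      "molecule 3" = .bg(49265, "C.M3")
    ),
    oka15 = list(
      "molecule 1" = rbind(
        .bg(50000, "O.M1a"),
        .feat("R1", 13435, "+", 1L),
        .bg(80000, "O.M1b"),
        .feat("R1", 13435, "+", 2L),
        .bg(60000, "O.M1c"),
        .feat("R2", 7076, "+", 1L),
        .bg(40000, "O.M1d"),
        .feat("R2", 7076, "+", 2L),
        .bg(63867, "O.M1e")
      ),
      "molecule 2" = .bg(54636, "O.M2"),  # OKA15 molecule 2 lacks R4
      "molecule 3" = .bg(49277, "O.M3")
    ),
    stop("unknown profile name: ", name)
  )
}

#' Build a synthetic mitogenome profile
#'
#' The four named profiles mirror the published architectures: group A
#' has four circular molecules (1a/1b with a shared core, R1 inverted in
#' 1a, the R2 pair in both 1a and 1b, R4 in molecule 2); group B has
#' three molecules with direct R1 and R3 pairs in molecule 1 and R4 in
#' molecule 2; clone 10908-06 resembles group A's repeat content on three
#' molecules; OKA15 carries an expanded R1 (13,435 bp), a reduced R2
#' (7,076 bp) and no R4. At `scale = 1` molecule lengths equal the
#' published assembly sizes; smaller scales shrink only the random
#' spacers between planted features, never the features.
#'
#' @param name Profile name: `"groupA"`, `"groupB"`, `"clone10908"` or
#'   `"oka15"`.
#' @param scale Numeric in (0, 1]; spacer scale factor.
#' @param gc Background GC content (default 0.45).
#' @return A [GenomeProfile-class].
#' @examples
#' p <- mitoProfile("groupB")
#' profileMoleculeLength(p, "molecule 2")  # 113443
#' @export
mitoProfile <- function(name = c("groupA", "groupB", "clone10908", "oka15"),
                        scale = 1, gc = 0.45) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1) stop("'scale' must be in (0, 1]")
  layouts <- .profileLayouts(name)
  minSpacer <- 200L
  layouts <- lapply(layouts, function(seg) {
    isBg <- seg$kind == "bg"
    seg$length[isBg] <- pmax(as.integer(round(seg$length[isBg] * scale)),
                             minSpacer)
    seg
  })
  for (nm in names(layouts)) {
    seg <- layouts[[nm]]
    if (any(seg$kind == "bg" & seg$length < minSpacer))
      stop("scale ", scale, " leaves a spacer of molecule '", nm,
           "' shorter than ", minSpacer, " bp")
  }
  new("GenomeProfile", name = name, scale = scale, molecules = layouts,
      gc = gc)
}

#' Tabulate the molecules of a profile
#'
#' @param profile A [GenomeProfile-class].
#' @return data.frame with one row per molecule: `molecule`, `length`,
#'   `nFeatures`.
#' @export
profileMolecules <- function(profile) {
  stopifnot(is(profile, "GenomeProfile"))
  data.frame(
    molecule = names(profile@molecules),
    length = vapply(profile@molecules, function(s) sum(s$length), integer(1)),
    nFeatures = vapply(profile@molecules,
                       function(s) sum(s$kind == "feature"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Length of one profile molecule
#'
#' @param profile A [GenomeProfile-class].
#' @param molecule Molecule name, e.g. `"molecule 2"`.
#' @return Integer length in bp.
#' @export
profileMoleculeLength <- function(profile, molecule) {
  seg <- profile@molecules[[molecule]]
  if (is.null(seg)) stop("no molecule '", molecule, "' in profile")
  sum(seg$length)
}

#' Repeat families planted in one profile molecule
#'
#' @param profile A [GenomeProfile-class].
#' @param molecule Molecule name.
#' @return data.frame with `family`, `length`, `copies`, `orientation`
#'   (orientation of the within-molecule pair; `NA` for single copies).
#' @export
profileFamilies <- function(profile, molecule) {
  seg <- profile@molecules[[molecule]]
  if (is.null(seg)) stop("no molecule '", molecule, "' in profile")
  f <- seg[seg$kind == "feature", , drop = FALSE]
  if (!nrow(f))
    return(data.frame(family = character(0), length = integer(0),
                      copies = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  fams <- unique(f$family)
  data.frame(
    family = fams,
    length = vapply(fams, function(x) f$length[f$family == x][1], integer(1)),
    copies = vapply(fams, function(x) sum(f$family == x), integer(1)),
    orientation = vapply(fams, function(x) {
      st <- f$strand[f$family == x]
      if (length(st) < 2L) NA_character_
      else if (st[1] == st[2]) "direct" else "inverted"
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## Force the planted pair to be *maximal*: break any chance extension of
## the exact match at the copy boundaries by mutating a base adjacent to
## copy 2 (always background in the shipped layouts).
.sealPair <- function(chars, a, b, len, inverted, L) {
  pickNot <- function(bad) setdiff(.BASES, bad)[1]
  if (!inverted) {
    i <- .mod1(a - 1L, L); j <- .mod1(b - 1L, L)
    if (chars[i] == chars[j]) chars[j] <- pickNot(chars[i])
    i <- .mod1(a + len, L); j <- .mod1(b + len, L)
    if (chars[i] == chars[j]) chars[j] <- pickNot(chars[i])
  } else {
    ## inverted match extends while s[a+len+t] == comp(s[b-1-t]) and
    ## s[a-1-t] == comp(s[b+len+t])
    i <- .mod1(a + len, L); j <- .mod1(b - 1L, L)
    if (chars[j] == .comp(chars[i])) chars[j] <- pickNot(.comp(chars[i]))
    i <- .mod1(a - 1L, L); j <- .mod1(b + len, L)
    if (chars[j] == .comp(chars[i])) chars[j] <- pickNot(.comp(chars[i]))
  }
  chars
}

.divergeCopy <- function(s, divergence) {
  len <- nchar(s)
  nmut <- round(divergence * len)
  if (nmut == 0L) return(list(seq = s, nSub = 0L))
  pos <- sample.int(len, nmut)
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(.BASES, b), 1L),
                    character(1))
  list(seq = paste(ch, collapse = ""), nSub = as.integer(nmut))
}

#' Realize a synthetic mitogenome from a profile
#'
#' Generates random backgrounds (shared background segments are generated
#' once, so the group A 1a/1b shared core is byte-identical between the
#' two molecules) and plants the repeat family copies. Copies are exact
#' duplicates unless `divergence > 0`, in which case copy 2 of each pair
#' receives `round(divergence * length)` substitutions. The bases
#' flanking each planted copy are sealed so that the maximal repeat
#' equals the planted length exactly, making the truth well defined.
#' Deterministic under `seed`.
#'
#' @param profile A [GenomeProfile-class].
#' @param seed Integer RNG seed.
#' @param divergence Substitution divergence of copy 2 (0..0.05).
#' @return A list with `molecules` (named list of circular
#'   [MitoMolecule-class]) and `truth`, a list holding `repeats`
#'   (one row per within-molecule pair: `molecule`, `family`,
#'   `orientation`, `length`, `start1`, `strand1`, `start2`, `strand2`,
#'   `nSub`), `features` (every planted copy) and the generator
#'   parameters.
#' @export
realizeGenome <- function(profile, seed = 1L, divergence = 0) {
  stopifnot(is(profile, "GenomeProfile"))
  if (divergence < 0 || divergence > 0.05)
    stop("'divergence' must be in [0, 0.05]")
  set.seed(seed)
  layouts <- profile@molecules

  ## one background per segment id, one sequence pair per family
  bgIds <- unique(unlist(lapply(layouts, function(s) s$segmentId[s$kind == "bg"])))
  bgSeqs <- list()
  for (id in bgIds) {
    len <- NA_integer_
    for (seg in layouts) {
      hit <- seg$kind == "bg" & seg$segmentId == id
      if (any(hit)) { len <- seg$length[which(hit)[1]]; break }
    }
    bgSeqs[[id]] <- .randSeq(len, profile@gc)
  }
  fams <- unique(unlist(lapply(layouts, function(s) s$family[s$kind == "feature"])))
  famSeq <- list()
  for (fm in fams) {
    len <- NA_integer_
    for (seg in layouts) {
      hit <- seg$kind == "feature" & !is.na(seg$family) & seg$family == fm
      if (any(hit)) { len <- seg$length[which(hit)[1]]; break }
    }
    c1 <- .randSeq(len, profile@gc)
    d <- .divergeCopy(c1, divergence)
    famSeq[[fm]] <- list(copy1 = c1, copy2 = d$seq, nSub = d$nSub)
  }

  molecules <- list()
  featRows <- list()
  for (nm in names(layouts)) {
    seg <- layouts[[nm]]
    pieces <- character(nrow(seg))
    offset <- 0L
    for (r in seq_len(nrow(seg))) {
      if (seg$kind[r] == "bg") {
        pieces[r] <- bgSeqs[[seg$segmentId[r]]]
      } else {
        base <- if (seg$copy[r] == 2L) famSeq[[seg$family[r]]]$copy2
                else famSeq[[seg$family[r]]]$copy1
        pieces[r] <- if (seg$strand[r] == "-") .rc(base) else base
        featRows[[length(featRows) + 1L]] <- data.frame(
          molecule = nm, family = seg$family[r], copy = seg$copy[r],
          start = offset + 1L, length = seg$length[r],
          strand = seg$strand[r], stringsAsFactors = FALSE)
      }
      offset <- offset + seg$length[r]
    }
    molecules[[nm]] <- paste(pieces, collapse = "")
  }
  features <- if (length(featRows)) do.call(rbind, featRows) else
    data.frame(molecule = character(0), family = character(0),
               copy = integer(0), start = integer(0), length = integer(0),
               strand = character(0), stringsAsFactors = FALSE)

  ## pair truth + boundary sealing, per molecule
  pairRows <- list()
  for (nm in names(molecules)) {
    fm <- features[features$molecule == nm, , drop = FALSE]
    L <- nchar(molecules[[nm]])
    ch <- NULL
    for (f in unique(fm$family)) {
      cp <- fm[fm$family == f, , drop = FALSE]
      if (nrow(cp) != 2L) next
      cp <- cp[order(cp$copy), , drop = FALSE]
      inv <- cp$strand[1] != cp$strand[2]
      if (is.null(ch)) ch <- strsplit(molecules[[nm]], "")[[1]]
      ch <- .sealPair(ch, cp$start[1], cp$start[2], cp$length[1], inv, L)
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        molecule = nm, family = f,
        orientation = if (inv) "inverted" else "direct",
        length = cp$length[1],
        start1 = cp$start[1], strand1 = cp$strand[1],
        start2 = cp$start[2], strand2 = cp$strand[2],
        nSub = famSeq[[f]]$nSub, stringsAsFactors = FALSE)
    }
    if (!is.null(ch)) molecules[[nm]] <- paste(ch, collapse = "")
  }
  repeats <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(molecule = character(0), family = character(0),
               orientation = character(0), length = integer(0),
               start1 = integer(0), strand1 = character(0),
               start2 = integer(0), strand2 = character(0),
               nSub = integer(0), stringsAsFactors = FALSE)

  mols <- list()
  for (nm in names(molecules)) {
    id <- paste0(profile@name, "_", gsub(" ", "_", nm))
    mols[[nm]] <- MitoMolecule(id, molecules[[nm]], circular = TRUE,
                               moleculeName = nm)
  }
  list(
    molecules = mols,
    truth = list(repeats = repeats, features = features,
                 profile = profile@name, scale = profile@scale,
                 seed = seed, divergence = divergence)
  )
}

## shared machinery for the translocation / insertion fixtures: an
## insert [flank][block][flank] whose block end bases are chosen so the
## flank pair is maximal at exactly flankLen in every context
.makeInsert <- function(blockLen, flankLen, gc, forbidLeft, forbidRight) {
  flank <- .randSeq(flankLen, gc)
  block <- .randSeq(blockLen, gc)
  substr(block, blockLen, blockLen) <- setdiff(.BASES, forbidLeft)[1]
  substr(block, 1L, 1L) <- setdiff(.BASES, forbidRight)[1]
  list(flank = flank, block = block,
       insert = paste0(flank, block, flank))
}

#' Synthetic translocation pair (molecule-3 style)
#'
#' Two circular molecules of equal length that are identical except that
#' a block (default 774 bp), flanked on both sides by a short direct
#' repeat (default 40 bp), sits at a different position in the second
#' molecule — the arrangement observed between the two groups of potato
#' molecule 3, where recombination at the 40 bp repeat is the likely
#' mechanism. The flank pair is maximal at exactly `flankLen` in both
#' molecules.
#'
#' @param blockLen Translocated block length in bp (default 774).
#' @param flankLen Flanking repeat length in bp (default 40).
#' @param totalLen Molecule length in bp (default 49,239, a molecule-3
#'   size).
#' @param seed Integer RNG seed.
#' @param gc Background GC content.
#' @return List with `molA`, `molB` (circular [MitoMolecule-class]) and
#'   `truth` (`blockLen`, `flankLen`, block start positions `blockStartA`
#'   / `blockStartB`, insert start positions, flank copy starts).
#' @export
makeTranslocationPair <- function(blockLen = 774L, flankLen = 40L,
                                  totalLen = 49239L, seed = 1L, gc = 0.45) {
  insertLen <- blockLen + 2L * flankLen
  if (insertLen + 2000L > totalLen)
    stop("totalLen too small for block + flanks")
  set.seed(seed)
  bgLen <- totalLen - insertLen
  bg <- .randSeq(bgLen, gc)
  posA <- floor(bgLen * 0.25)   # insert after this background base
  posB <- floor(bgLen * 0.62)
  ins <- .makeInsert(blockLen, flankLen, gc,
                     forbidLeft = c(substr(bg, posA, posA),
                                    substr(bg, posB, posB)),
                     forbidRight = c(substr(bg, posA + 1L, posA + 1L),
                                     substr(bg, posB + 1L, posB + 1L)))
  mk <- function(pos, id) {
    s <- paste0(substr(bg, 1L, pos), ins$insert,
                substr(bg, pos + 1L, bgLen))
    MitoMolecule(id, s, circular = TRUE, moleculeName = "molecule 3")
  }
  list(
    molA = mk(posA, "transloc_A"),
    molB = mk(posB, "transloc_B"),
    truth = list(
      blockLen = as.integer(blockLen), flankLen = as.integer(flankLen),
      insertStartA = posA + 1L, insertStartB = posB + 1L,
      blockStartA = posA + flankLen + 1L, blockStartB = posB + flankLen + 1L,
      flankStartsA = c(posA + 1L, posA + flankLen + blockLen + 1L),
      flankStartsB = c(posB + 1L, posB + flankLen + blockLen + 1L),
      flank = ins$flank, block = ins$block
    )
  )
}

#' Synthetic insertion pair (10908-06 molecule-2 style)
#'
#' Molecule B carries an extra copy of the flanked block absent from
#' molecule A — the insertion of the translocatable region observed in
#' molecule 2 of one clone. `totalLen` is the length of molecule B; A is
#' shorter by `blockLen + 2*flankLen`.
#'
#' @inheritParams makeTranslocationPair
#' @return List with `molA`, `molB` and `truth` (block/flank lengths and
#'   B-side coordinates).
#' @export
makeInsertionPair <- function(blockLen = 774L, flankLen = 40L,
                              totalLen = 111730L, seed = 1L, gc = 0.45) {
  insertLen <- blockLen + 2L * flankLen
  if (insertLen + 2000L > totalLen)
    stop("totalLen too small for block + flanks")
  set.seed(seed)
  bgLen <- totalLen - insertLen
  bg <- .randSeq(bgLen, gc)
  posB <- floor(bgLen * 0.4)
  ins <- .makeInsert(blockLen, flankLen, gc,
                     forbidLeft = substr(bg, posB, posB),
                     forbidRight = substr(bg, posB + 1L, posB + 1L))
  sB <- paste0(substr(bg, 1L, posB), ins$insert, substr(bg, posB + 1L, bgLen))
  list(
    molA = MitoMolecule("insert_A", bg, circular = TRUE,
                        moleculeName = "molecule 2"),
    molB = MitoMolecule("insert_B", sB, circular = TRUE,
                        moleculeName = "molecule 2"),
    truth = list(blockLen = as.integer(blockLen),
                 flankLen = as.integer(flankLen),
                 insertStartB = posB + 1L,
                 blockStartB = posB + flankLen + 1L)
  )
}

#' Long-read simulation parameters
#'
#' Read lengths are lognormal (parameterised by their mean and the log-sd)
#' and clipped; this emulates a PacBio-like long-read length profile well
#' enough for junction-spanning analysis without modelling the
#' instrument. Errors are uniform substitutions and indels applied after
#' extraction.
#'
#' @param coverage Target mean coverage (mutually exclusive with
#'   `nReads`).
#' @param nReads Exact number of reads.
#' @param meanLength Mean read length in bp (default 10,000).
#' @param sdLog Log-scale standard deviation (default 0.4).
#' @param minLength,maxLength Clipping bounds in bp.
#' @param subRate Per-base substitution rate in `[0, 0.2]`.
#' @param indelRate Per-base indel rate in `[0, 0.2]`.
#' @return A list of class `ReadSimParams`.
#' @export
readSimParams <- function(coverage = NULL, nReads = NULL,
                          meanLength = 10000, sdLog = 0.4,
                          minLength = 2000, maxLength = 40000,
                          subRate = 0, indelRate = 0) {
  if (is.null(coverage) == is.null(nReads))
    stop("give exactly one of 'coverage' or 'nReads'")
  if (subRate < 0 || subRate > 0.2 || indelRate < 0 || indelRate > 0.2)
    stop("error rates must be in [0, 0.2]")
  if (minLength < 1 || minLength > maxLength)
    stop("need 1 <= minLength <= maxLength")
  structure(list(coverage = coverage, nReads = nReads,
                 meanLength = meanLength, sdLog = sdLog,
                 minLength = minLength, maxLength = maxLength,
                 subRate = subRate, indelRate = indelRate),
            class = "ReadSimParams")
}

.applyReadErrors <- function(s, subRate, indelRate) {
  len <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  nSub <- rbinom(1L, len, subRate)
  if (nSub > 0L) {
    pos <- sample.int(len, nSub)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(.BASES, b), 1L),
                      character(1))
  }
  nIndel <- rbinom(1L, len, indelRate)
  nDel <- 0L; nIns <- 0L
  if (nIndel > 0L) {
    pos <- sort(sample.int(len, nIndel))
    isDel <- runif(nIndel) < 0.5
    nDel <- sum(isDel); nIns <- nIndel - nDel
    keep <- rep(TRUE, len)
    keep[pos[isDel]] <- FALSE
    insAt <- pos[!isDel]
    if (nIns > 0L) {
      extra <- sample(.BASES, nIns, replace = TRUE)
      out <- character(0)
      prev <- 1L
      for (t in seq_along(insAt)) {
        out <- c(out, ch[prev:insAt[t]][keep[prev:insAt[t]]], extra[t])
        prev <- insAt[t] + 1L
      }
      if (prev <= len) out <- c(out, ch[prev:len][keep[prev:len]])
      ch <- out
    } else {
      ch <- ch[keep]
    }
  }
  list(seq = paste(ch, collapse = ""), nSub = nSub, nIns = nIns, nDel = nDel)
}

#' Simulate long reads from a mixture of circular molecules
#'
#' Reads start uniformly on the source circle (and may wrap the origin),
#' on a uniform strand, from sources drawn by abundance. The returned
#' truth records the provenance of every read, which allows exact
#' reconstruction of expected junction support at error rate 0.
#'
#' @param sources A list of circular sources: [MitoMolecule-class],
#'   [IsoformProduct-class] or named character sequences.
#' @param abundances Numeric mixture weights, summing to 1.
#' @param params A [readSimParams()] object.
#' @param seed Integer RNG seed.
#' @param fastq Optional path; when given, reads are also written as
#'   FASTQ (constant quality).
#' @return List with `reads` (a named [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame: `read`, `source`, `start`, `strand`, `length`,
#'   `nSub`, `nIns`, `nDel`).
#' @export
simulateReads <- function(sources, abundances, params, seed = 1L,
                          fastq = NULL) {
  stopifnot(inherits(params, "ReadSimParams"))
  seqs <- vapply(sources, function(x) {
    if (is(x, "MitoMolecule")) as.character(x)
    else if (is(x, "IsoformProduct")) as.character(productSeq(x))
    else as.character(x)
  }, character(1))
  nm <- names(sources)
  if (is.null(nm)) nm <- vapply(seq_along(sources), function(i) {
    x <- sources[[i]]
    if (is(x, "MitoMolecule")) moleculeId(x) else paste0("source", i)
  }, character(1))
  names(seqs) <- nm
  lens <- nchar(seqs)
  if (abs(sum(abundances) - 1) > 1e-6) stop("abundances must sum to 1")
  if (length(abundances) != length(seqs))
    stop("one abundance per source required")
  if (params$minLength > min(lens))
    stop("requested minimum read length (", params$minLength,
         ") exceeds the shortest molecule (", min(lens), " bp)")
  set.seed(seed)
  n <- if (!is.null(params$nReads)) params$nReads else
    as.integer(round(params$coverage * sum(abundances * lens) /
                       params$meanLength))
  if (n < 1L) stop("zero reads requested")
  meanlog <- log(params$meanLength) - params$sdLog^2 / 2
  src <- sample.int(length(seqs), n, replace = TRUE, prob = abundances)
  rlen <- pmin(pmax(as.integer(round(rlnorm(n, meanlog, params$sdLog))),
                    params$minLength), params$maxLength)
  rlen <- pmin(rlen, lens[src])
  start <- as.integer(floor(runif(n) * lens[src])) + 1L
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  reads <- character(n)
  nSub <- nIns <- nDel <- integer(n)
  for (i in seq_len(n)) {
    s <- .circSubstr(seqs[src[i]], start[i], rlen[i])
    if (strand[i] == "-") s <- .rc(s)
    if (params$subRate > 0 || params$indelRate > 0) {
      e <- .applyReadErrors(s, params$subRate, params$indelRate)
      s <- e$seq; nSub[i] <- e$nSub; nIns[i] <- e$nIns; nDel[i] <- e$nDel
    }
    reads[i] <- s
  }
  ids <- sprintf("read%05d", seq_len(n))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  truth <- data.frame(read = ids, source = nm[src], start = start,
                      strand = strand, length = rlen,
                      nSub = nSub, nIns = nIns, nDel = nDel,
                      stringsAsFactors = FALSE)
  if (!is.null(fastq)) {
    qual <- vapply(Biostrings::width(out), function(wd) strrep("I", wd),
                   character(1))
    writeLines(as.vector(rbind(paste0("@", ids), as.character(out),
                               "+", qual)), fastq)
  }
  list(reads = out, truth = truth)
}
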
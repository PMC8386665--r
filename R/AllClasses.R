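#' MitoMolecule: one mitochondrial DNA molecule
#'
#' A single mitogenome molecule with an explicit topology flag. Plant
#' mitogenomes are typically multipartite, i.e. they consist of several
#' autonomous molecules, most of them circular; all coordinate arithmetic
#' in this package is 1-based and, for circular molecules, interpreted
#' modulo the molecule length.
#'
#' @slot id Character scalar, the record identifier (FASTA id).
#' @slot moleculeName Character scalar, an optional display label such as
#'   `"molecule 1a"`; `NA` when absent.
#' @slot seq A [Biostrings::DNAString] over `A/C/G/T/N` (uppercase).
#' @slot circular Logical scalar; `TRUE` for circular topology.
#'
#' @seealso [readMitoFasta()], [circularSubseq()], [rotateMolecule()]
#' @export
setClass("MitoMolecule",
  representation(
    id = "character",
    moleculeName = "character",
    seq = "DNAString",
    circular = "logical"
  )
)

setValidity("MitoMolecule", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty character scalar")
  if (length(object@circular) != 1L || is.na(object@circular))
    msg <- c(msg, "'circular' must be TRUE or FALSE")
  if (length(object@seq) < 1L)
    msg <- c(msg, "sequence must have length >= 1")
  bad <- setdiff(Biostrings::uniqueLetters(object@seq), c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence of '", object@id,
                         "' contains disallowed letters: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a MitoMolecule
#'
#' @param id Record identifier.
#' @param seq Character scalar or [Biostrings::DNAString]; lowercase input
#'   is uppercased.
#' @param circular Logical; circular topology (default `FALSE`).
#' @param moleculeName Optional display label (e.g. `"molecule 2"`).
#' @return A [MitoMolecule-class] object.
#' @examples
#' m <- MitoMolecule("m1", "ACGT", circular = TRUE)
#' circularSubseq(m, 4, 2)  # wraps: "TA"
#' @export
MitoMolecule <- function(id, seq, circular = FALSE, moleculeName = NA_character_) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  new("MitoMolecule", id = as.character(id), seq = seq,
      circular = isTRUE(circular), moleculeName = as.character(moleculeName))
}

#' GenomeProfile: blueprint for a synthetic multipartite mitogenome
#'
#' Describes the molecules of a synthetic mitogenome (lengths, planted
#' repeat families with orientation and placement, optional shared-core
#' structure) at a given scale. Profiles named after the study groups
#' reproduce the published molecule and repeat-family lengths; the
#' `scale` parameter shrinks the random spacers between planted features
#' but never the features themselves.
#'
#' @slot name One of `"groupA"`, `"groupB"`, `"clone10908"`, `"oka15"`, or
#'   `"custom"`.
#' @slot scale Numeric in (0, 1]; spacer scale factor.
#' @slot molecules A list of molecule layouts; each layout is a data.frame
#'   of segments (`kind`, `family`, `orientation`, `copy`, `length`,
#'   `segmentId`).
#' @slot gc Background GC content.
#' @export
setClass("GenomeProfile",
  representation(
    name = "character",
    scale = "numeric",
    molecules = "list",
    gc = "numeric"
  )
)

setValidity("GenomeProfile", function(object) {
  if (object@scale <= 0 || object@scale > 1)
    return("'scale' must be in (0, 1]")
  if (object@gc <= 0 || object@gc >= 1)
    return("'gc' must be in (0, 1)")
  TRUE
})

#' Junction: a breakpoint-spanning construct of a recombination product
#'
#' A junction is described by a window of `2w` bases of the product
#' centred on the recombinant repeat copy. It is *novel* iff that window
#' does not occur anywhere in the (doubled) parent molecule, on either
#' strand. With exact repeat copies this requires the window to span the
#' whole repeat copy plus at least one base of product-specific context
#' on each side, which is why junction constructs are centred on the
#' repeat copy midpoint rather than on the crossover itself.
#'
#' @slot id Junction identifier.
#' @slot breakpoint 1-based position of the window centre on the product.
#' @slot construct Character; the `2w`-mer (left flank + right flank).
#' @slot w Flank width in bp.
#' @slot novel Logical; absent from the parent (both strands)?
#' @slot repeatLen Length of the repeat copy the junction crosses (bp);
#'   `NA` for junctions not mediated by a detected repeat.
#' @slot provenance A list recording parent id, product type and the
#'   parent coordinates/strands on each side of the breakpoint.
#' @export
setClass("Junction",
  representation(
    id = "character",
    breakpoint = "integer",
    construct = "character",
    w = "integer",
    novel = "logical",
    repeatLen = "integer",
    provenance = "list"
  )
)

#' IsoformProduct: a product of repeat-mediated recombination
#'
#' Recombination between two *direct* repeat copies on a circular parent
#' splits it into two sub-genomic circles whose lengths sum to the parent
#' length; recombination between two *inverted* copies yields a single
#' equal-length isoform with the inter-repeat segment reverse-complemented.
#'
#' @slot productType `"subgenomic_circle"` or `"inversion_isoform"`.
#' @slot parentId Identifier of the parent molecule.
#' @slot seq [Biostrings::DNAString] of the product (circular).
#' @slot composition data.frame of parent segments (`start`, `width`,
#'   `strand`) in product order.
#' @slot junctions List of [Junction-class] objects (filled by
#'   [predictJunctions()]).
#' @slot repeatPair The repeat pair (one-row data.frame) that mediated the
#'   event.
#' @export
setClass("IsoformProduct",
  representation(
    productType = "character",
    parentId = "character",
    seq = "DNAString",
    composition = "data.frame",
    junctions = "list",
    repeatPair = "data.frame"
  )
)

setValidity("IsoformProduct", function(object) {
  if (!object@productType %in% c("subgenomic_circle", "inversion_isoform"))
    return("productType must be 'subgenomic_circle' or 'inversion_isoform'")
  TRUE
})
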
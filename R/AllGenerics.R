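#' @describeIn MitoMolecule-class record identifier.
#' @param x,object A `MitoMolecule`.
#' @export
setGeneric("moleculeId", function(x) standardGeneric("moleculeId"))

#' @describeIn MitoMolecule-class display label (may be `NA`).
#' @export
setGeneric("moleculeName", function(x) standardGeneric("moleculeName"))

#' @describeIn MitoMolecule-class topology flag.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @describeIn MitoMolecule-class the sequence as a
#'   [Biostrings::DNAString].
#' @export
setGeneric("molSeq", function(x) standardGeneric("molSeq"))

#' @describeIn IsoformProduct-class product type.
#' @export
setGeneric("productType", function(x) standardGeneric("productType"))

#' @describeIn IsoformProduct-class parent molecule id.
#' @export
setGeneric("parentId", function(x) standardGeneric("parentId"))

#' @describeIn IsoformProduct-class product sequence.
#' @export
setGeneric("productSeq", function(x) standardGeneric("productSeq"))

#' @describeIn IsoformProduct-class parent segment composition.
#' @export
setGeneric("productComposition", function(x) standardGeneric("productComposition"))

#' @describeIn IsoformProduct-class list of predicted junctions.
#' @export
setGeneric("productJunctions", function(x) standardGeneric("productJunctions"))

#' @describeIn Junction-class junction identifier.
#' @export
setGeneric("junctionId", function(x) standardGeneric("junctionId"))

#' @describeIn Junction-class the 2w-mer construct sequence.
#' @export
setGeneric("junctionConstruct", function(x) standardGeneric("junctionConstruct"))

#' @describeIn Junction-class is the construct absent from the parent?
#' @export
setGeneric("isNovel", function(x) standardGeneric("isNovel"))

setMethod("moleculeId", "MitoMolecule", function(x) x@id)
setMethod("moleculeName", "MitoMolecule", function(x) x@moleculeName)
setMethod("isCircular", "MitoMolecule", function(x) x@circular)
setMethod("molSeq", "MitoMolecule", function(x) x@seq)

#' @describeIn MitoMolecule-class molecule length in bp.
#' @export
setMethod("length", "MitoMolecule", function(x) length(x@seq))

#' @describeIn MitoMolecule-class the sequence as a character scalar.
#' @export
setMethod("as.character", "MitoMolecule", function(x) as.character(x@seq))

setMethod("show", "MitoMolecule", function(object) {
  cat(sprintf("MitoMolecule '%s'%s: %s bp, %s\n", object@id,
              if (!is.na(object@moleculeName))
                sprintf(" (%s)", object@moleculeName) else "",
              format(length(object@seq), big.mark = ","),
              if (object@circular) "circular" else "linear"))
})

setMethod("productType", "IsoformProduct", function(x) x@productType)
setMethod("parentId", "IsoformProduct", function(x) x@parentId)
setMethod("productSeq", "IsoformProduct", function(x) x@seq)
setMethod("productComposition", "IsoformProduct", function(x) x@composition)
setMethod("productJunctions", "IsoformProduct", function(x) x@junctions)

#' @describeIn IsoformProduct-class product length in bp.
#' @export
setMethod("length", "IsoformProduct", function(x) length(x@seq))

setMethod("show", "IsoformProduct", function(object) {
  cat(sprintf("IsoformProduct (%s) of '%s': %s bp, %d segment(s), %d junction(s)\n",
              object@productType, object@parentId,
              format(length(object@seq), big.mark = ","),
              nrow(object@composition), length(object@junctions)))
})

setMethod("junctionId", "Junction", function(x) x@id)
setMethod("junctionConstruct", "Junction", function(x) x@construct)
setMethod("isNovel", "Junction", function(x) x@novel)

setMethod("show", "Junction", function(object) {
  cat(sprintf("Junction '%s': w=%d, %s\n", object@id, object@w,
              if (object@novel) "novel" else "present in parent"))
})

setMethod("show", "GenomeProfile", function(object) {
  cat(sprintf("GenomeProfile '%s' (scale %.3g): %d molecule(s)\n",
              object@name, object@scale, length(object@molecules)))
  for (nm in names(object@molecules)) {
    seg <- object@molecules[[nm]]
    feats <- seg[seg$kind == "feature", , drop = FALSE]
    cat(sprintf("  %-12s %9s bp  %s\n", nm,
                format(sum(seg$length), big.mark = ","),
                if (nrow(feats)) paste0(feats$family, "(", feats$orientation,
                                        ")", collapse = " ") else "-"))
  }
})
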
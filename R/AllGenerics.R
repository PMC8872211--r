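#' @rdname ReferenceRegion-class
#' @param object,x An object.
#' @export
setGeneric("refName", function(x) standardGeneric("refName"))
#' @rdname ReferenceRegion-class
#' @export
setGeneric("refOffset", function(x) standardGeneric("refOffset"))
#' @rdname ReferenceRegion-class
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname ReferenceRegion-class
#' @export
setGeneric("regionLength", function(x) standardGeneric("regionLength"))

#' @rdname HaplotypeEdit-class
#' @param x An object.
#' @export
setGeneric("delStart", function(x) standardGeneric("delStart"))
#' @rdname HaplotypeEdit-class
#' @export
setGeneric("delEnd", function(x) standardGeneric("delEnd"))
#' @rdname HaplotypeEdit-class
#' @export
setGeneric("insertedSeq", function(x) standardGeneric("insertedSeq"))
#' @rdname HaplotypeEdit-class
#' @export
setGeneric("deletionLength", function(x) standardGeneric("deletionLength"))

#' @rdname VariantTable-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname VariantTable-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname VariantTable-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname VariantTable-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname SVCall-class
#' @export
setGeneric("svType", function(x) standardGeneric("svType"))
#' @rdname SVCall-class
#' @export
setGeneric("netSize", function(x) standardGeneric("netSize"))

## ---- accessors ----

#' @rdname ReferenceRegion-class
#' @export
setMethod("refName", "ReferenceRegion", function(x) x@name)
#' @rdname ReferenceRegion-class
#' @export
setMethod("refOffset", "ReferenceRegion", function(x) x@offset)
#' @rdname ReferenceRegion-class
#' @export
setMethod("refSequence", "ReferenceRegion", function(x) x@sequence)
#' @rdname ReferenceRegion-class
#' @export
setMethod("regionLength", "ReferenceRegion", function(x) length(x@sequence))

#' @rdname HaplotypeEdit-class
#' @export
setMethod("delStart", "HaplotypeEdit", function(x) x@delStart)
#' @rdname HaplotypeEdit-class
#' @export
setMethod("delEnd", "HaplotypeEdit", function(x) x@delEnd)
#' @rdname HaplotypeEdit-class
#' @export
setMethod("insertedSeq", "HaplotypeEdit", function(x) x@insertedSeq)
#' @rdname HaplotypeEdit-class
#' @export
setMethod("deletionLength", "HaplotypeEdit", function(x) x@delEnd - x@delStart)

#' @rdname BreakpointCall-class
#' @export
setMethod("delStart", "BreakpointCall", function(x) x@delStart)
#' @rdname BreakpointCall-class
#' @export
setMethod("delEnd", "BreakpointCall", function(x) x@delEnd)
#' @rdname BreakpointCall-class
#' @export
setMethod("insertedSeq", "BreakpointCall", function(x) x@insertedSeq)
#' @rdname BreakpointCall-class
#' @export
setMethod("deletionLength", "BreakpointCall", function(x) x@deletionLength)

#' @rdname VariantTable-class
#' @export
setMethod("variantInfo", "VariantTable", function(x) x@info)
#' @rdname VariantTable-class
#' @export
setMethod("genotypes", "VariantTable", function(x) x@genotypes)
#' @rdname VariantTable-class
#' @export
setMethod("nVariants", "VariantTable", function(x) nrow(x@info))
#' @rdname VariantTable-class
#' @export
setMethod("nSamples", "VariantTable", function(x) ncol(x@genotypes))

#' @rdname SVCall-class
#' @export
setMethod("svType", "SVCall", function(x) x@type)
#' @rdname SVCall-class
#' @export
setMethod("netSize", "SVCall", function(x) x@netSize)

## ---- show methods ----

setMethod("show", "ReferenceRegion", function(object) {
  cat(sprintf("ReferenceRegion %s: %d bp anchored at %s (spans %s-%s)\n",
              object@name, length(object@sequence),
              format(object@offset, big.mark = ","),
              format(object@offset, big.mark = ","),
              format(object@offset + length(object@sequence) - 1,
                     big.mark = ",")))
})

setMethod("show", "HaplotypeEdit", function(object) {
  cat(sprintf("HaplotypeEdit: del [%s, %s) = %d bp, insertion '%s' (%d bp)\n",
              format(object@delStart, big.mark = ","),
              format(object@delEnd, big.mark = ","),
              as.integer(object@delEnd - object@delStart),
              object@insertedSeq, nchar(object@insertedSeq)))
})

setMethod("show", "CoordinateMap", function(object) {
  cat(sprintf("CoordinateMap: %d block(s), haplotype %d bp -> %s:%s-%s\n",
              nrow(object@blocks), as.integer(object@hapLength),
              object@refName, format(object@refOffset, big.mark = ","),
              format(object@refOffset + object@refLength - 1,
                     big.mark = ",")))
})

setMethod("show", "BreakpointCall", function(object) {
  if (object@status == "resolved") {
    cat(sprintf(
      "BreakpointCall: del %s-%s (%d bp), insertion '%s', support %d\n",
      format(object@delStart, big.mark = ","),
      format(object@delEnd, big.mark = ","),
      as.integer(object@deletionLength),
      object@insertedSeq, as.integer(object@support)))
  } else {
    cat("BreakpointCall: no call --", object@diagnostic, "\n")
  }
})

setMethod("show", "SVCall", function(object) {
  cat(sprintf("SVCall: %s (net size %s bp, %d supporting pairs)\n",
              object@type,
              if (is.na(object@netSize)) "NA" else round(object@netSize),
              as.integer(object@support)))
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variant(s) x %d sample(s)\n",
              nrow(object@info), ncol(object@genotypes)))
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf("PrimerPair: F 5'-%s-3', R 5'-%s-3'\n",
              object@forward, object@reverse))
})
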
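#' @describeIn SparseBinaryVector-class accessor for the active 0-based
#'   indices.
#' @param object,x an object of the documented class.
#' @export
setGeneric("activeIndices", function(x) standardGeneric("activeIndices"))

#' @rdname SparseBinaryVector-class
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' Decompose a pair of binary vectors into intersection and symmetric
#' difference
#'
#' Partitions the union of active features of two vectors over the same
#' universe into the intersecting features (active in both; count I) and the
#' symmetric-difference features (active in exactly one; count D). Only the
#' counts I and D — never the universe size — enter the kernel Shapley
#' computation.
#'
#' @param x,y [SparseBinaryVector-class] objects with equal universe size.
#' @return a [PairDecomposition-class].
#' @examples
#' a <- sparseBinaryVector(c(0, 3), 5)
#' b <- sparseBinaryVector(c(0, 2, 3, 4), 5)
#' d <- decomposePair(a, b)
#' intersectionSize(d)   # I = 2
#' symDifferenceSize(d)  # D = 2
#' @export
setGeneric("decomposePair", function(x, y) standardGeneric("decomposePair"))

#' @rdname PairDecomposition-class
#' @param x a PairDecomposition.
#' @export
setGeneric("intersectionSize",
    function(x) standardGeneric("intersectionSize"))

#' @rdname PairDecomposition-class
#' @export
setGeneric("symDifferenceSize",
    function(x) standardGeneric("symDifferenceSize"))

#' @rdname PairExplanation-class
#' @param x a PairExplanation or ModelExplanation.
#' @export
setGeneric("perFeature", function(x) standardGeneric("perFeature"))

#' @rdname PairExplanation-class
#' @export
setGeneric("kernelValue", function(x) standardGeneric("kernelValue"))

#' @rdname KernelParams-class
#' @param x the object holding kernel parameters.
#' @export
setGeneric("kernelGamma", function(x) standardGeneric("kernelGamma"))
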
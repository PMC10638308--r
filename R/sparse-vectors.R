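#' Construct a sparse binary vector
#'
#' @param activeIndices numeric/integer vector of 0-based positions set to 1;
#'   duplicates are collapsed (set semantics). May be empty.
#' @param universeSize single positive integer, total number of binary
#'   features.
#' @return a [SparseBinaryVector-class].
#' @examples
#' sparseBinaryVector(c(0, 3), universeSize = 5)
#' sparseBinaryVector(integer(0), universeSize = 10)  # all-zero vector
#' @export
sparseBinaryVector <- function(activeIndices, universeSize) {
    idx <- sort(unique(as.integer(activeIndices)))
    new("SparseBinaryVector", activeIndices = idx,
        universeSize = as.integer(universeSize))
}

#' Convert a dense 0/1 vector to sparse form
#'
#' @param bits numeric vector of 0s and 1s.
#' @return a [SparseBinaryVector-class] with `universeSize = length(bits)`.
#' @examples
#' denseToSparse(c(1, 0, 0, 1, 0))
#' @export
denseToSparse <- function(bits) {
    if (!all(bits %in% c(0, 1)))
        stop("dense input must contain only 0s and 1s")
    sparseBinaryVector(which(bits == 1) - 1L, length(bits))
}

#' @rdname SparseBinaryVector-class
#' @export
setMethod("activeIndices", "SparseBinaryVector",
    function(x) x@activeIndices)

#' @rdname SparseBinaryVector-class
#' @export
setMethod("universeSize", "SparseBinaryVector",
    function(x) x@universeSize)

#' @describeIn SparseBinaryVector-class number of active bits.
#' @export
setMethod("length", "SparseBinaryVector",
    function(x) length(x@activeIndices))

setMethod("show", "SparseBinaryVector", function(object) {
    idx <- object@activeIndices
    shown <- if (length(idx) > 8L)
        paste(c(utils::head(idx, 8L), "..."), collapse = " ")
    else paste(idx, collapse = " ")
    cat(sprintf("SparseBinaryVector: %d/%d bits active {%s}\n",
                length(idx), object@universeSize, shown))
})

#' @rdname decomposePair
#' @export
setMethod("decomposePair",
    signature("SparseBinaryVector", "SparseBinaryVector"),
    function(x, y) {
        if (x@universeSize != y@universeSize)
            stop("universe sizes differ (", x@universeSize, " vs ",
                 y@universeSize, ")")
        both <- intersect(x@activeIndices, y@activeIndices)
        either <- union(x@activeIndices, y@activeIndices)
        new("PairDecomposition",
            intersection = sort(both),
            symDifference = sort(setdiff(either, both)),
            universeSize = x@universeSize)
    })

#' @rdname PairDecomposition-class
#' @export
setMethod("intersectionSize", "PairDecomposition",
    function(x) length(x@intersection))

#' @rdname PairDecomposition-class
#' @export
setMethod("symDifferenceSize", "PairDecomposition",
    function(x) length(x@symDifference))

setMethod("show", "PairDecomposition", function(object) {
    cat(sprintf(
        "PairDecomposition: I = %d, D = %d (union %d of universe %d)\n",
        length(object@intersection), length(object@symDifference),
        length(object@intersection) + length(object@symDifference),
        object@universeSize))
})
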
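#' @import methods
NULL

#' SparseBinaryVector: a binary feature vector stored by its active positions
#'
#' Represents one binary feature vector (e.g. a molecular fingerprint) as the
#' set of 0-based indices of its active (1) bits within a fixed feature
#' universe. Sparse storage is essential: Shapley value computation for the
#' RBF kernel only ever touches the union of active features of a pair, whose
#' size is typically orders of magnitude below the universe size.
#'
#' @slot activeIndices integer vector of distinct, sorted 0-based positions
#'   set to 1; may be empty (the all-zero vector).
#' @slot universeSize single positive integer, the total number of binary
#'   features.
#'
#' @seealso [sparseBinaryVector()], [decomposePair()]
#' @export
setClass("SparseBinaryVector",
    representation(activeIndices = "integer", universeSize = "integer"))

setValidity("SparseBinaryVector", function(object) {
    msgs <- character()
    if (length(object@universeSize) != 1L || is.na(object@universeSize) ||
        object@universeSize < 1L)
        msgs <- c(msgs, "universeSize must be a single positive integer")
    idx <- object@activeIndices
    if (anyNA(idx))
        msgs <- c(msgs, "activeIndices must not contain NA")
    else {
        if (anyDuplicated(idx))
            msgs <- c(msgs, "activeIndices must be distinct (set semantics)")
        if (is.unsorted(idx))
            msgs <- c(msgs, "activeIndices must be sorted increasingly")
        if (length(idx) && (min(idx) < 0L ||
                            max(idx) >= object@universeSize))
            msgs <- c(msgs, "activeIndices must lie in [0, universeSize)")
    }
    if (length(msgs)) msgs else TRUE
})

#' PairDecomposition: intersection / symmetric difference of a vector pair
#'
#' The exact partition of the union of active features of two binary vectors
#' into intersecting features (active in both, count I) and symmetric-
#' difference features (active in exactly one, count D). Features inactive in
#' both vectors are excluded entirely; they are dummy players of the kernel
#' game and carry a Shapley value of exactly zero.
#'
#' @slot intersection integer vector of 0-based indices active in both
#'   vectors.
#' @slot symDifference integer vector of 0-based indices active in exactly
#'   one vector.
#' @slot universeSize single integer, the shared feature universe size.
#'
#' @seealso [decomposePair()]
#' @export
setClass("PairDecomposition",
    representation(intersection = "integer", symDifference = "integer",
                   universeSize = "integer"))

setValidity("PairDecomposition", function(object) {
    if (length(intersect(object@intersection, object@symDifference)))
        return("intersection and symDifference must be disjoint")
    TRUE
})

#' KernelParams: Gaussian RBF kernel width
#'
#' Holds the RBF width parameter gamma. The kernel is
#' K(x, x') = exp(-gamma * ||x - x'||^2); the equivalent sigma
#' parameterisation K = exp(-d^2 / (2 sigma^2)) is converted on construction
#' via gamma = 1 / (2 sigma^2) and only gamma is stored.
#'
#' @slot gamma single positive numeric.
#'
#' @seealso [kernelParams()]
#' @export
setClass("KernelParams", representation(gamma = "numeric"))

setValidity("KernelParams", function(object) {
    if (length(object@gamma) != 1L || is.na(object@gamma) ||
        object@gamma <= 0)
        return("gamma must be a single positive number")
    TRUE
})

#' PairExplanation: Shapley values of one RBF kernel evaluation
#'
#' Per-feature Shapley values for a single kernel evaluation K(x, y) between
#' two binary vectors. All intersecting features share one value and all
#' symmetric-difference features share another (exchangeability within each
#' class); features active in neither vector are absent and implicitly zero.
#' When the union is nonempty the per-feature values sum to the kernel value
#' (efficiency). The degenerate pair of two all-zero vectors has kernel value
#' 1 but no players, so no attribution exists; it is flagged instead.
#'
#' @slot phiIntersecting numeric, the Shapley value of each intersecting
#'   feature (NA_real_ when I = 0).
#' @slot phiSymDifference numeric, the Shapley value of each symmetric-
#'   difference feature (NA_real_ when D = 0).
#' @slot perFeature named numeric, feature index (0-based, as name) to
#'   Shapley value, over the union features only.
#' @slot kernelValue numeric, K(x, y) = exp(-gamma * D).
#' @slot decomposition the [PairDecomposition-class] of the pair.
#' @slot degenerate logical, TRUE iff I + D = 0 (no attribution possible).
#'
#' @seealso [explainKernelPair()], [exactShapleyEnumeration()]
#' @export
setClass("PairExplanation",
    representation(phiIntersecting = "numeric",
                   phiSymDifference = "numeric",
                   perFeature = "numeric",
                   kernelValue = "numeric",
                   decomposition = "PairDecomposition",
                   degenerate = "logical"))

#' SVMModelSpec: everything needed to evaluate and explain an RBF-SVM
#'
#' A serialisable specification of a binary-input RBF-kernel SVM decision
#' function dist(x) = b + sum_n w_n K(x, V_n), where the V_n are support
#' vectors and the signed dual weights w_n already contain the class-label
#' sign (y_n * alpha_n). Optional Platt calibration parameters (A, B) define
#' p(x) = 1 / (1 + exp(A * dist(x) + B)).
#'
#' @slot supportVectors list of [SparseBinaryVector-class], all sharing one
#'   universe size.
#' @slot dualWeights numeric vector of signed dual coefficients, one per
#'   support vector.
#' @slot bias single numeric, the intercept b.
#' @slot params a [KernelParams-class].
#' @slot plattA numeric of length 0 or 1.
#' @slot plattB numeric of length 0 or 1 (present iff plattA is).
#'
#' @seealso [svmModelSpec()], [svmDistance()], [explainSvmDistance()]
#' @export
setClass("SVMModelSpec",
    representation(supportVectors = "list", dualWeights = "numeric",
                   bias = "numeric", params = "KernelParams",
                   plattA = "numeric", plattB = "numeric"))

setValidity("SVMModelSpec", function(object) {
    msgs <- character()
    nv <- length(object@supportVectors)
    if (nv < 1L)
        msgs <- c(msgs, "at least one support vector is required")
    if (!all(vapply(object@supportVectors, is, logical(1),
                    "SparseBinaryVector")))
        msgs <- c(msgs, "supportVectors must all be SparseBinaryVector")
    else if (nv >= 1L) {
        us <- vapply(object@supportVectors, function(v) v@universeSize,
                     integer(1))
        if (length(unique(us)) > 1L)
            msgs <- c(msgs, "support vectors must share one universe size")
    }
    if (length(object@dualWeights) != nv)
        msgs <- c(msgs, "dualWeights must match supportVectors in length")
    if (length(object@bias) != 1L || is.na(object@bias))
        msgs <- c(msgs, "bias must be a single number")
    if (length(object@plattA) != length(object@plattB))
        msgs <- c(msgs, "plattA and plattB must both be present or absent")
    if (length(object@plattA) > 1L)
        msgs <- c(msgs, "plattA/plattB must have length 0 or 1")
    if (length(msgs)) msgs else TRUE
})

#' ModelExplanation: Shapley decomposition of one SVM prediction
#'
#' Per-feature Shapley values for the decision-function distance of one test
#' instance and, when Platt parameters are available, for its log-odds. The
#' bias acts as an additional feature whose Shapley value is b itself; on the
#' log-odds scale the corresponding instance-independent term -(A*b + B) is
#' the expected value. Features active neither in the instance nor in any
#' support vector have no entry (zero by construction).
#'
#' @slot perFeatureDistance named numeric, feature index to phi_f for the
#'   distance.
#' @slot biasContribution numeric, phi_b = b.
#' @slot distance numeric, dist(x) computed directly.
#' @slot perFeatureLogodds named numeric (length 0 without Platt
#'   parameters), -A * phi_f.
#' @slot expectedValue numeric of length 0 or 1, -(A*b + B).
#' @slot logodds numeric of length 0 or 1, -A*dist(x) - B.
#' @slot probability numeric of length 0 or 1, 1/(1+exp(A*dist(x)+B)).
#' @slot inInstance named logical, whether each reported feature is active
#'   in the explained instance.
#' @slot degeneratePairs integer, number of (instance, support vector) pairs
#'   with empty union (their kernel value 1 cannot be attributed).
#'
#' @seealso [explainSvmDistance()], [explainSvmLogodds()]
#' @export
setClass("ModelExplanation",
    representation(perFeatureDistance = "numeric",
                   biasContribution = "numeric",
                   distance = "numeric",
                   perFeatureLogodds = "numeric",
                   expectedValue = "numeric",
                   logodds = "numeric",
                   probability = "numeric",
                   inInstance = "logical",
                   degeneratePairs = "integer"))
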
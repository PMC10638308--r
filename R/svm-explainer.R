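#' Construct an SVM model specification
#'
#' @param supportVectors list of [SparseBinaryVector-class] over one
#'   universe.
#' @param dualWeights numeric vector of signed dual coefficients
#'   (y_n * alpha_n), one per support vector.
#' @param bias intercept b of the decision function.
#' @param params a [KernelParams-class].
#' @param plattA,plattB optional Platt calibration parameters of
#'   p(x) = 1 / (1 + exp(A * dist(x) + B)); both or neither.
#' @return an [SVMModelSpec-class].
#' @export
svmModelSpec <- function(supportVectors, dualWeights, bias, params,
                         plattA = numeric(0), plattB = numeric(0)) {
    new("SVMModelSpec", supportVectors = supportVectors,
        dualWeights = as.numeric(dualWeights), bias = as.numeric(bias),
        params = params, plattA = as.numeric(plattA),
        plattB = as.numeric(plattB))
}

#' @rdname SVMModelSpec-class
#' @param x an SVMModelSpec.
#' @export
setMethod("kernelGamma", "SVMModelSpec", function(x) x@params@gamma)

#' @rdname SVMModelSpec-class
#' @export
setMethod("universeSize", "SVMModelSpec",
    function(x) x@supportVectors[[1]]@universeSize)

#' @describeIn SVMModelSpec-class TRUE when Platt parameters are present.
#' @param object an SVMModelSpec.
#' @export
hasPlatt <- function(object) length(object@plattA) == 1L

setMethod("show", "SVMModelSpec", function(object) {
    cat(sprintf(
        "SVMModelSpec: %d support vectors over %d features, gamma = %g\n",
        length(object@supportVectors), universeSize(object),
        kernelGamma(object)))
    cat(sprintf("  bias = %g; Platt calibration: %s\n", object@bias,
                if (hasPlatt(object))
                    sprintf("A = %g, B = %g", object@plattA, object@plattB)
                else "absent"))
})

#' SVM decision-function distance
#'
#' Evaluates dist(x) = b + sum_n w_n K(x, V_n), with K(x, V_n) =
#' exp(-gamma * D_n) where D_n is the symmetric-difference count between x
#' and support vector V_n.
#'
#' @param model an [SVMModelSpec-class].
#' @param x a [SparseBinaryVector-class] with the model's universe size.
#' @return the signed distance from the separating hyperplane.
#' @export
svmDistance <- function(model, x) {
    if (universeSize(x) != universeSize(model))
        stop("instance universe size differs from the model's")
    gamma <- kernelGamma(model)
    ks <- vapply(model@supportVectors, function(v) {
        d <- decomposePair(x, v)
        exp(-gamma * length(d@symDifference))
    }, numeric(1))
    model@bias + sum(model@dualWeights * ks)
}

#' Exact Shapley values for an SVM decision-function distance
#'
#' By additivity of Shapley values over the kernel sum, the distance
#' attribution of feature f is phi_f = sum_n w_n phi_{f,n}, where phi_{f,n}
#' is the exact pair-level Shapley value of f for K(x, V_n) — the
#' intersecting value, the symmetric-difference value, or zero when f is
#' active in neither x nor V_n. The bias is carried as an additional feature
#' whose Shapley value is b itself, so b + sum_f phi_f = dist(x)
#' (efficiency). Features that a support vector activates but the instance
#' does not still receive (generally nonzero) attributions: absent features
#' matter. Pair values are memoised per (I, D) signature, so instances
#' against many support vectors reuse work.
#'
#' @param model an [SVMModelSpec-class].
#' @param x a [SparseBinaryVector-class].
#' @return a [ModelExplanation-class] without log-odds fields (see
#'   [explainSvmLogodds()]).
#' @export
explainSvmDistance <- function(model, x) {
    if (universeSize(x) != universeSize(model))
        stop("instance universe size differs from the model's")
    gamma <- kernelGamma(model)
    featUnion <- sort(Reduce(union, lapply(model@supportVectors,
                                           activeIndices),
                             activeIndices(x)))
    phi <- stats::setNames(numeric(length(featUnion)),
                           as.character(featUnion))
    dist <- model@bias
    nDegen <- 0L
    for (n in seq_along(model@supportVectors)) {
        v <- model@supportVectors[[n]]
        dec <- decomposePair(x, v)
        I <- length(dec@intersection)
        D <- length(dec@symDifference)
        dist <- dist + model@dualWeights[n] * exp(-gamma * D)
        if (I + D == 0L) {
            nDegen <- nDegen + 1L
            next
        }
        pv <- pairPhiValues(I, D, gamma)
        if (I)
            phi[as.character(dec@intersection)] <-
                phi[as.character(dec@intersection)] +
                model@dualWeights[n] * pv[["int"]]
        if (D)
            phi[as.character(dec@symDifference)] <-
                phi[as.character(dec@symDifference)] +
                model@dualWeights[n] * pv[["sym"]]
    }
    inInst <- stats::setNames(featUnion %in% activeIndices(x),
                              as.character(featUnion))
    if (nDegen > 0L)
        warning(nDegen, " instance/support-vector pair(s) have an empty ",
                "union; their kernel value 1 cannot be attributed and the ",
                "efficiency identity will not close")
    new("ModelExplanation", perFeatureDistance = phi,
        biasContribution = model@bias, distance = dist,
        perFeatureLogodds = numeric(0), expectedValue = numeric(0),
        logodds = numeric(0), probability = numeric(0),
        inInstance = inInst, degeneratePairs = nDegen)
}

#' Exact Shapley values for Platt-scaled SVM log-odds
#'
#' Platt scaling maps the distance to a class probability
#' p = 1 / (1 + exp(A * dist + B)), whose logit is linear in the distance:
#' logit(p) = -A * dist - B. Per-feature log-odds attributions are therefore
#' the distance attributions scaled by -A, and the instance-independent term
#' -(A * b + B) plays the role of the expected value. The identity
#' expectedValue + sum_f phi_f^logit = logit(p) holds exactly up to float
#' error.
#'
#' @param model an [SVMModelSpec-class] with Platt parameters.
#' @param x a [SparseBinaryVector-class].
#' @return a [ModelExplanation-class] with log-odds fields populated.
#' @export
explainSvmLogodds <- function(model, x) {
    if (!hasPlatt(model))
        stop("model has no Platt parameters; fit or supply (A, B) first")
    ex <- explainSvmDistance(model, x)
    A <- model@plattA
    B <- model@plattB
    ex@perFeatureLogodds <- -A * ex@perFeatureDistance
    ex@expectedValue <- -(A * ex@biasContribution + B)
    ex@logodds <- -A * ex@distance - B
    ex@probability <- 1 / (1 + exp(A * ex@distance + B))
    ex
}

#' @rdname ModelExplanation-class
#' @param x a ModelExplanation.
#' @export
setMethod("perFeature", "ModelExplanation",
    function(x) x@perFeatureDistance)

setMethod("show", "ModelExplanation", function(object) {
    cat(sprintf(
        "ModelExplanation: %d features, distance = %.6g (bias %.6g)\n",
        length(object@perFeatureDistance), object@distance,
        object@biasContribution))
    if (length(object@logodds))
        cat(sprintf(
            "  logodds = %.6g, probability = %.6g, expected value = %.6g\n",
            object@logodds, object@probability, object@expectedValue))
    if (object@degeneratePairs)
        cat(sprintf("  WARNING: %d degenerate (empty-union) pairs\n",
                    object@degeneratePairs))
})

#' Extract a model specification from a fitted e1071 SVM
#'
#' Pulls support vectors, signed dual coefficients, intercept, gamma and —
#' for probability-calibrated models — the Platt parameters out of an
#' `e1071::svm` (libsvm) binary classifier with an RBF kernel fitted on 0/1
#' inputs, so that [svmDistance()] reproduces the library's decision values
#' exactly. libsvm reports decision values as sum(coefs * K) - rho for the
#' class pair (labels[1], labels[2]), so bias = -rho, and its sigmoid is
#' p = 1 / (1 + exp(probA * dec + probB)) — the same convention the model
#' spec uses, so probA/probB map directly to (A, B).
#'
#' The model must be fitted with `scale = FALSE`: scaling would destroy the
#' binary structure of the inputs.
#'
#' @param trainedModel a fitted `e1071::svm` object.
#' @return an [SVMModelSpec-class] that round-trips losslessly through
#'   [writeModelSpec()]/[readModelSpec()].
#' @export
extractModelSpec <- function(trainedModel) {
    if (!requireNamespace("e1071", quietly = TRUE))
        stop("the e1071 package is required for model extraction")
    if (!inherits(trainedModel, "svm"))
        stop("expected a fitted e1071::svm object")
    # libsvm kernel codes: 0 linear, 1 polynomial, 2 radial, 3 sigmoid
    if (trainedModel$kernel != 2L)
        stop("unsupported model: only the RBF (radial) kernel is handled")
    if (any(unlist(trainedModel$scaled)))
        stop("model was fitted with scaling; refit with scale = FALSE")
    sv <- as.matrix(trainedModel$SV)
    if (!all(sv %in% c(0, 1)))
        stop("support vectors are not binary 0/1 vectors")
    if (length(trainedModel$levels) != 2L)
        stop("only binary classifiers are supported")
    svs <- lapply(seq_len(nrow(sv)), function(i) denseToSparse(sv[i, ]))
    hasProb <- !is.null(trainedModel$probA) &&
        length(trainedModel$probA) == 1L && !is.na(trainedModel$probA)
    svmModelSpec(
        supportVectors = svs,
        dualWeights = as.numeric(trainedModel$coefs),
        bias = -trainedModel$rho,
        params = kernelParams(gamma = trainedModel$gamma),
        plattA = if (hasProb) as.numeric(trainedModel$probA) else numeric(0),
        plattB = if (hasProb) as.numeric(trainedModel$probB) else numeric(0))
}
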
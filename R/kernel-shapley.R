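#' Construct RBF kernel parameters
#'
#' Exactly one of `gamma` or `sigma` must be given; `sigma` is converted
#' immediately via gamma = 1 / (2 sigma^2) and only gamma is stored.
#'
#' @param gamma positive RBF width parameter.
#' @param sigma positive bandwidth of the equivalent
#'   exp(-d^2 / (2 sigma^2)) parameterisation.
#' @return a [KernelParams-class].
#' @examples
#' kernelParams(sigma = 1)   # gamma = 0.5
#' kernelParams(gamma = 0.5)
#' @export
kernelParams <- function(gamma = NULL, sigma = NULL) {
    if (is.null(gamma) == is.null(sigma))
        stop("give exactly one of gamma or sigma")
    if (!is.null(sigma)) {
        if (sigma <= 0) stop("sigma must be positive")
        gamma <- 1 / (2 * sigma^2)
    }
    new("KernelParams", gamma = as.numeric(gamma))
}

#' @rdname KernelParams-class
#' @export
setMethod("kernelGamma", "KernelParams", function(x) x@gamma)

setMethod("show", "KernelParams", function(object) {
    cat(sprintf("KernelParams: gamma = %g (sigma = %g)\n",
                object@gamma, sqrt(1 / (2 * object@gamma))))
})

#' RBF kernel value from the symmetric-difference count
#'
#' On binary vectors the squared Euclidean distance equals the number D of
#' symmetric-difference features, so K(x, y) = exp(-gamma * D). Only D —
#' never the intersection or the universe size — determines the kernel
#' value.
#'
#' @param D non-negative symmetric-difference count.
#' @param params a [KernelParams-class].
#' @return the kernel value exp(-gamma * D).
#' @examples
#' rbfKernelFromCounts(2, kernelParams(sigma = 1))  # exp(-1) = 0.368
#' @export
rbfKernelFromCounts <- function(D, params) {
    if (any(D < 0)) stop("D must be non-negative")
    exp(-kernelGamma(params) * D)
}

#' Exact Shapley value of an intersecting feature
#'
#' An intersecting feature changes the kernel value only when it joins the
#' empty coalition (taking v from 0 to 1), so its Shapley value collapses to
#' the single permutation weight (I+D-1)!/(I+D)! = 1/(I+D). It is exact,
#' independent of gamma, and always positive.
#'
#' @param I intersection count (>= 1; with I = 0 there is no intersecting
#'   feature to score).
#' @param D symmetric-difference count (>= 0).
#' @return 1/(I+D), exactly.
#' @examples
#' phiIntersecting(2, 2)  # 0.25
#' @export
phiIntersecting <- function(I, D) {
    if (I < 1) stop("I must be >= 1: no intersecting feature exists")
    if (D < 0) stop("D must be >= 0")
    1 / (I + D)
}

#' Log Shapley permutation weight of one coalition class
#'
#' Returns the natural logarithm of the product of the coalition
#' multiplicity C_f(N_i, N_d) and the inverse multinomial coefficient
#' (N_i+N_d)! (I+D-N_i-N_d-1)! / (I+D)!, for a coalition with `Ni`
#' intersecting and `Nd` symmetric-difference members joined by a feature of
#' the assessed class. Evaluated with log-gamma (`lchoose`/`lfactorial`) so
#' it never overflows, for union sizes well beyond 1e5.
#'
#' @param Ni,Nd intersecting / symmetric-difference members of the
#'   coalition.
#' @param I,D class sizes of the pair decomposition.
#' @param fromIntersection logical; TRUE when the assessed feature is
#'   intersecting (so Ni ranges over 0..I-1 and Nd over 0..D), FALSE when it
#'   is a symmetric-difference feature (Ni over 0..I, Nd over 0..D-1).
#' @return log of multiplicity times permutation weight.
#' @examples
#' exp(logCoalitionWeight(0, 0, 2, 2, TRUE))   # 1 * 1/4
#' exp(logCoalitionWeight(0, 1, 2, 2, FALSE))  # 1 * 1/12
#' @export
logCoalitionWeight <- function(Ni, Nd, I, D, fromIntersection = TRUE) {
    maxNi <- if (fromIntersection) I - 1L else I
    maxNd <- if (fromIntersection) D else D - 1L
    if (Ni < 0 || Ni > maxNi || Nd < 0 || Nd > maxNd)
        stop("coalition counts out of range for the assessed feature class")
    logMult <- if (fromIntersection)
        lchoose(I - 1, Ni) + lchoose(D, Nd)
    else
        lchoose(I, Ni) + lchoose(D - 1, Nd)
    logMult + lfactorial(Ni + Nd) + lfactorial(I + D - Ni - Nd - 1) -
        lfactorial(I + D)
}

# Three-term closed form for a symmetric-difference feature, un-memoised.
# Terms: (a) joining the empty coalition lifts v from 0 to exp(-gamma);
# (b) joining a nonempty all-intersecting coalition drops v from 1 to
# exp(-gamma); (c) joining a coalition already containing Nd >= 1
# symmetric-difference members changes v by exp(-gamma(Nd+1)) -
# exp(-gamma*Nd). Each summand's combinatorial weight is exponentiated from
# log space; the mixed term is a plain scalar double loop (outer Nd, inner
# Ni), O(I*D) work.
.phiSymRaw <- function(I, D, gamma) {
    eg <- exp(-gamma)
    n <- I + D
    total <- eg / n
    if (I >= 1) {
        accB <- 0
        for (Ni in seq_len(I))
            accB <- accB + exp(lchoose(I, Ni) + lfactorial(Ni) +
                               lfactorial(n - Ni - 1) - lfactorial(n))
        total <- total + (eg - 1) * accB
    }
    if (D >= 2) {
        for (Nd in seq_len(D - 1L)) {
            dv <- exp(-gamma * (Nd + 1)) - exp(-gamma * Nd)
            for (Ni in 0:I) {
                total <- total + dv *
                    exp(lchoose(I, Ni) + lchoose(D - 1, Nd) +
                        lfactorial(Ni + Nd) +
                        lfactorial(n - Ni - Nd - 1) - lfactorial(n))
            }
        }
    }
    total
}

#' Exact Shapley value of a symmetric-difference feature
#'
#' Evaluates the exact three-term closed form: the empty-coalition term
#' exp(-gamma)/(I+D), the intersecting-only-coalition term (in which adding
#' the feature drops the kernel value from 1 to exp(-gamma)), and the mixed
#' double sum over coalitions already containing at least one
#' symmetric-difference feature. All factorial/binomial ratios are taken in
#' log space, so the computation is stable at fingerprint scale. Cost is
#' O(I*D); results are memoised per (I, D, gamma).
#'
#' @param I intersection count (>= 0).
#' @param D symmetric-difference count (>= 1; with D = 0 there is no
#'   symmetric-difference feature to score).
#' @param params a [KernelParams-class].
#' @return the exact Shapley value (typically negative: such features pull
#'   the kernel value below 1).
#' @examples
#' phiSymmetricDifference(2, 2, kernelParams(sigma = 1))  # -0.0661
#' @export
phiSymmetricDifference <- function(I, D, params) {
    if (D < 1) stop("D must be >= 1: no symmetric-difference feature exists")
    if (I < 0) stop("I must be >= 0")
    pairPhiValues(as.integer(I), as.integer(D), kernelGamma(params))[["sym"]]
}

# Memoised per-(I, D, gamma) pair values. An SVM explanation evaluates one
# pair per support vector and many share the same (I, D) signature.
.phiCache <- new.env(parent = emptyenv())

pairPhiValues <- function(I, D, gamma) {
    key <- sprintf("%d|%d|%.17g", I, D, gamma)
    hit <- .phiCache[[key]]
    if (!is.null(hit)) return(hit)
    val <- c(int = if (I >= 1) 1 / (I + D) else NA_real_,
             sym = if (D >= 1) .phiSymRaw(I, D, gamma) else NA_real_)
    .phiCache[[key]] <- val
    val
}

#' Exact Shapley values for one RBF kernel evaluation
#'
#' Attributes the kernel value K(x, y) = exp(-gamma * D) exactly to the
#' union features of the pair: every intersecting feature receives
#' [phiIntersecting()] and every symmetric-difference feature
#' [phiSymmetricDifference()] (features are exchangeable within each class).
#' Features inactive in both vectors are dummy players and are not
#' materialised. The per-feature values sum to the kernel value whenever the
#' union is nonempty (efficiency). If both vectors are all-zero the kernel
#' value is 1 but the game has no players; the explanation is returned empty
#' and flagged degenerate rather than inventing an allocation.
#'
#' @param x,y [SparseBinaryVector-class] objects over the same universe.
#' @param params a [KernelParams-class].
#' @return a [PairExplanation-class].
#' @examples
#' x <- denseToSparse(c(1, 0, 0, 1, 0))
#' y <- denseToSparse(c(1, 0, 1, 1, 1))
#' ex <- explainKernelPair(x, y, kernelParams(sigma = 1))
#' sum(perFeature(ex)) - kernelValue(ex)  # ~0 (efficiency)
#' @export
explainKernelPair <- function(x, y, params) {
    dec <- decomposePair(x, y)
    I <- length(dec@intersection)
    D <- length(dec@symDifference)
    gamma <- kernelGamma(params)
    kval <- exp(-gamma * D)
    if (I + D == 0L) {
        return(new("PairExplanation",
                   phiIntersecting = NA_real_,
                   phiSymDifference = NA_real_,
                   perFeature = stats::setNames(numeric(0), character(0)),
                   kernelValue = kval, decomposition = dec,
                   degenerate = TRUE))
    }
    phi <- pairPhiValues(I, D, gamma)
    per <- c(rep(phi[["int"]], I), rep(phi[["sym"]], D))
    names(per) <- as.character(c(dec@intersection, dec@symDifference))
    ord <- order(as.integer(names(per)))
    new("PairExplanation",
        phiIntersecting = phi[["int"]], phiSymDifference = phi[["sym"]],
        perFeature = per[ord], kernelValue = kval, decomposition = dec,
        degenerate = FALSE)
}

#' @rdname PairExplanation-class
#' @export
setMethod("perFeature", "PairExplanation", function(x) x@perFeature)

#' @rdname PairExplanation-class
#' @export
setMethod("kernelValue", "PairExplanation", function(x) x@kernelValue)

setMethod("show", "PairExplanation", function(object) {
    I <- length(object@decomposition@intersection)
    D <- length(object@decomposition@symDifference)
    cat(sprintf("PairExplanation: I = %d, D = %d, kernel = %.6g\n",
                I, D, object@kernelValue))
    if (object@degenerate) {
        cat("  degenerate: empty union, no attribution possible\n")
    } else {
        if (I) cat(sprintf("  phi per intersecting feature:   %.6g\n",
                           object@phiIntersecting))
        if (D) cat(sprintf("  phi per sym-difference feature: %.6g\n",
                           object@phiSymDifference))
        cat(sprintf("  sum of Shapley values: %.6g\n",
                    sum(object@perFeature)))
    }
})
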
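#' Shapley permutation weight
#'
#' The weight |S|! (n-|S|-1)! / n! applied to the marginal contribution of a
#' feature joining a coalition S out of n players, evaluated stably through
#' log-factorials. Over all subsets S of the n-1 other players the weights
#' sum to 1.
#'
#' @param setSize coalition size |S|, 0 <= |S| <= n-1.
#' @param nPlayers total player count n.
#' @return the weight as a numeric scalar.
#' @examples
#' shapleyWeight(0, 4)  # 1/4
#' shapleyWeight(1, 4)  # 1/12
#' @export
shapleyWeight <- function(setSize, nPlayers) {
    if (setSize < 0 || setSize >= nPlayers)
        stop("need 0 <= setSize <= nPlayers - 1")
    exp(lfactorial(setSize) + lfactorial(nPlayers - setSize - 1) -
        lfactorial(nPlayers))
}

# Coalition value of the kernel game: v(S) = exp(-gamma * Nd(S)) for
# nonempty S, v(empty) = 0 by convention. Depends only on the count of
# symmetric-difference players in S.
.coalitionValue <- function(size, Nd, gamma) {
    ifelse(size == 0, 0, exp(-gamma * Nd))
}

# Count-class enumeration: v depends only on (|S|, Nd), so sum the raw
# Shapley formula over count classes (Ni, Nd) with multiplicity
# choose(.)·choose(.). This is the unsimplified double sum, independent of
# the aggregated three-term closed form it validates.
.enumByCounts <- function(I, D, gamma) {
    n <- I + D
    phiInt <- NA_real_
    phiSym <- NA_real_
    if (I >= 1) {
        acc <- 0
        for (Ni in 0:(I - 1L)) for (Nd in 0:D) {
            vS <- .coalitionValue(Ni + Nd, Nd, gamma)
            vSf <- exp(-gamma * Nd)
            acc <- acc + choose(I - 1, Ni) * choose(D, Nd) *
                shapleyWeight(Ni + Nd, n) * (vSf - vS)
        }
        phiInt <- acc
    }
    if (D >= 1) {
        acc <- 0
        for (Ni in 0:I) for (Nd in 0:(D - 1L)) {
            vS <- .coalitionValue(Ni + Nd, Nd, gamma)
            vSf <- exp(-gamma * (Nd + 1))
            acc <- acc + choose(I, Ni) * choose(D - 1, Nd) *
                shapleyWeight(Ni + Nd, n) * (vSf - vS)
        }
        phiSym <- acc
    }
    c(int = phiInt, sym = phiSym)
}

# Subset-by-subset enumeration over bitmasks, one Shapley sum per
# individual player. Exponential; guarded to <= 15 players. Verifies class
# exchangeability rather than assuming it.
.enumBySubsets <- function(I, D, gamma) {
    n <- I + D
    masks <- 0:(2^n - 1L)
    isSym <- c(rep(FALSE, I), rep(TRUE, D))
    size <- integer(length(masks))
    Nd <- integer(length(masks))
    for (p in seq_len(n)) {
        bit <- bitwShiftL(1L, p - 1L)
        inS <- bitwAnd(masks, bit) > 0L
        size <- size + inS
        if (isSym[p]) Nd <- Nd + inS
    }
    v <- .coalitionValue(size, Nd, gamma)
    w <- exp(lfactorial(0:(n - 1L)) + lfactorial(n - (0:(n - 1L)) - 1L) -
             lfactorial(n))
    phi <- numeric(n)
    for (p in seq_len(n)) {
        bit <- bitwShiftL(1L, p - 1L)
        sel <- bitwAnd(masks, bit) == 0L
        phi[p] <- sum(w[size[sel] + 1L] *
                      (v[bitwOr(masks[sel], bit) + 1L] - v[sel]))
    }
    list(phi = phi, isSym = isSym)
}

#' Brute-force Shapley values by explicit coalition enumeration
#'
#' Computes per-feature Shapley values for the kernel game of a vector pair
#' by direct enumeration, as a validation oracle for the closed forms. Two
#' routes are provided: `"counts"` enumerates coalition count classes
#' (Ni, Nd) with their multiplicities — feasible because the coalition value
#' exp(-gamma * Nd) depends only on counts — and `"subsets"` enumerates
#' every individual subset by bitmask, scoring every player separately so
#' that class exchangeability is verified, not assumed. Both use
#' v(empty) = 0.
#'
#' @param x,y [SparseBinaryVector-class] objects over the same universe.
#' @param params a [KernelParams-class].
#' @param maxUnion refuse pairs whose union exceeds this size (default 20;
#'   the subset route is additionally capped at 15 players).
#' @param mode `"counts"` (default) or `"subsets"`.
#' @return a [PairExplanation-class].
#' @examples
#' x <- denseToSparse(c(1, 0, 0, 1, 0))
#' y <- denseToSparse(c(1, 0, 1, 1, 1))
#' ex <- exactShapleyEnumeration(x, y, kernelParams(sigma = 1))
#' perFeature(ex)  # 0.25 per intersecting, -0.0661 per sym-difference
#' @export
exactShapleyEnumeration <- function(x, y, params, maxUnion = 20L,
                                    mode = c("counts", "subsets")) {
    mode <- match.arg(mode)
    dec <- decomposePair(x, y)
    I <- length(dec@intersection)
    D <- length(dec@symDifference)
    cap <- if (mode == "subsets") min(maxUnion, 15L) else maxUnion
    if (I + D > cap)
        stop("union size ", I + D, " exceeds enumeration capacity ", cap)
    gamma <- kernelGamma(params)
    kval <- exp(-gamma * D)
    if (I + D == 0L) {
        return(new("PairExplanation",
                   phiIntersecting = NA_real_, phiSymDifference = NA_real_,
                   perFeature = stats::setNames(numeric(0), character(0)),
                   kernelValue = kval, decomposition = dec,
                   degenerate = TRUE))
    }
    if (mode == "counts") {
        phi <- .enumByCounts(I, D, gamma)
        per <- c(rep(phi[["int"]], I), rep(phi[["sym"]], D))
        phiInt <- phi[["int"]]
        phiSym <- phi[["sym"]]
    } else {
        res <- .enumBySubsets(I, D, gamma)
        per <- res$phi
        phiInt <- if (I) mean(per[!res$isSym]) else NA_real_
        phiSym <- if (D) mean(per[res$isSym]) else NA_real_
    }
    names(per) <- as.character(c(dec@intersection, dec@symDifference))
    ord <- order(as.integer(names(per)))
    new("PairExplanation",
        phiIntersecting = phiInt, phiSymDifference = phiSym,
        perFeature = per[ord], kernelValue = kval, decomposition = dec,
        degenerate = FALSE)
}
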
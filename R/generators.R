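# Run expr under a private RNG stream so generators are reproducible per
# seed and never disturb the caller's RNG state.
withLocalSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Generate random sparse binary vectors
#'
#' Each of the `universeSize` bits of each vector is active independently
#' with probability `density` (independent Bernoulli bits, no feature
#' correlation). The same seed always reproduces the same vectors, and the
#' caller's RNG state is left untouched.
#'
#' @param n number of vectors (>= 1).
#' @param universeSize number of binary features (>= 1).
#' @param density per-bit activation probability in (0, 1]. The default 0.5
#'   gives uniformly random binary vectors.
#' @param seed integer seed.
#' @return list of `n` [SparseBinaryVector-class] objects.
#' @examples
#' vs <- generateRandomVectors(20, universeSize = 15, seed = 1)
#' lengths <- vapply(vs, length, integer(1))
#' @export
generateRandomVectors <- function(n, universeSize, density = 0.5,
                                  seed = 1L) {
    if (n < 1L || universeSize < 1L)
        stop("n and universeSize must be >= 1")
    if (!is.numeric(density) || length(density) != 1L ||
        density <= 0 || density > 1)
        stop("density must lie in (0, 1]")
    withLocalSeed(seed, {
        lapply(seq_len(n), function(i) {
            bits <- stats::runif(universeSize) < density
            sparseBinaryVector(which(bits) - 1L, universeSize)
        })
    })
}

#' Generate a toy RBF-SVM model specification
#'
#' Produces a syntactically valid, reproducible [SVMModelSpec-class] for
#' testing and demonstration: random support vectors (Bernoulli bits),
#' signed dual weights drawn uniformly from [-2, -0.1] or [0.1, 2], a small
#' random bias, the supplied gamma, and Platt parameters with negative A (so
#' larger distances map to higher probability of the positive class).
#'
#' @param nSupport number of support vectors (>= 1).
#' @param universeSize number of binary features.
#' @param seed integer seed.
#' @param gamma RBF width parameter (default 1).
#' @param density per-bit activation probability for the support vectors.
#' @param platt logical, include Platt calibration parameters (default
#'   TRUE).
#' @return an [SVMModelSpec-class].
#' @examples
#' m <- generateToySvm(5, universeSize = 15, seed = 7)
#' @export
generateToySvm <- function(nSupport, universeSize, seed = 1L, gamma = 1,
                           density = 0.5, platt = TRUE) {
    if (nSupport < 1L)
        stop("nSupport must be >= 1")
    withLocalSeed(seed, {
        svs <- lapply(seq_len(nSupport), function(i) {
            bits <- stats::runif(universeSize) < density
            sparseBinaryVector(which(bits) - 1L, universeSize)
        })
        w <- stats::runif(nSupport, 0.1, 2) *
            sample(c(-1, 1), nSupport, replace = TRUE)
        b <- stats::runif(1, -0.5, 0.5)
        A <- if (platt) -stats::runif(1, 0.5, 3) else numeric(0)
        B <- if (platt) stats::runif(1, -0.5, 0.5) else numeric(0)
        svmModelSpec(supportVectors = svs, dualWeights = w, bias = b,
                     params = kernelParams(gamma = gamma),
                     plattA = A, plattB = B)
    })
}
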
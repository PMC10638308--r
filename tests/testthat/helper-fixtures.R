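# The worked-example pair: two intersecting features, two
# symmetric-difference features, one feature absent from both.
pairX <- denseToSparse(c(1, 0, 0, 1, 0))
pairY <- denseToSparse(c(1, 0, 1, 1, 1))
sigma1 <- kernelParams(sigma = 1)

# Dense evaluation of an SVM decision function, as an algebra route
# independent of the sparse decomposition path.
denseSvmDistance <- function(model, x) {
    u <- universeSize(model)
    toDense <- function(v) {
        z <- numeric(u)
        z[activeIndices(v) + 1L] <- 1
        z
    }
    xd <- toDense(x)
    ks <- vapply(model@supportVectors, function(v)
        exp(-kernelGamma(model) * sum((xd - toDense(v))^2)), numeric(1))
    model@bias + sum(model@dualWeights * ks)
}

writeTempVectors <- function(vectors) {
    tf <- tempfile(fileext = ".txt")
    writeSparseVectors(vectors, tf)
    tf
}
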
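test_that("kernel value depends only on the symmetric-difference count", {
    expect_equal(rbfKernelFromCounts(2, sigma1), exp(-1))
    expect_equal(round(rbfKernelFromCounts(2, sigma1), 3), 0.368)
    expect_equal(rbfKernelFromCounts(0, kernelParams(gamma = 7)), 1)
    expect_equal(rbfKernelFromCounts(1, kernelParams(gamma = 1)), exp(-1))
    expect_error(rbfKernelFromCounts(-1, sigma1), "non-negative")
})

test_that("sigma and gamma parameterisations are exactly equivalent", {
    expect_equal(kernelGamma(kernelParams(sigma = 1)), 0.5)
    expect_equal(kernelGamma(kernelParams(sigma = 2)), 1 / 8)
    expect_error(kernelParams(), "exactly one")
    expect_error(kernelParams(gamma = 1, sigma = 1), "exactly one")
    expect_error(kernelParams(gamma = -1), "positive")
    expect_error(kernelParams(sigma = 0), "positive")
})

test_that("intersecting-feature value is exactly 1/(I+D)", {
    expect_identical(phiIntersecting(2, 2), 0.25)
    expect_identical(phiIntersecting(4, 0), 0.25)
    expect_identical(phiIntersecting(1, 0), 1)
    for (n in 1:200) {
        I <- sample(seq_len(n), 1)
        expect_identical(phiIntersecting(I, n - I), 1 / n)
    }
    expect_error(phiIntersecting(0, 3), "I must be >= 1")
})

test_that("symmetric-difference closed form matches the worked example and forced cases", {
    expect_equal(round(phiSymmetricDifference(2, 2, sigma1), 3), -0.066)
    # single-player game: phi = v({f}) - v(empty) = exp(-gamma)
    for (g in c(0.1, 1, 5))
        expect_equal(phiSymmetricDifference(0, 1, kernelParams(gamma = g)),
                     exp(-g))
    expect_error(phiSymmetricDifference(2, 0, sigma1), "D must be >= 1")
})

test_that("closed form matches exhaustive enumeration over small unions", {
    for (g in c(0.1, 0.5, 1, 2)) {
        p <- kernelParams(gamma = g)
        for (n in 1:15) {
            for (I in 0:n) {
                D <- n - I
                if (D < 1) next
                expected <- .enumByCounts(I, D, g)[["sym"]]
                expect_lt(
                    abs(phiSymmetricDifference(I, D, p) - expected),
                    1e-10,
                    label = sprintf("|closed - enum| at I=%d D=%d gamma=%g",
                                    I, D, g))
            }
        }
    }
})

test_that("efficiency holds over random pairs and gamma sweep", {
    gammas <- c(0.05, 0.5, 1, 5)
    vs <- generateRandomVectors(100, 40, density = 0.25, seed = 2024)
    set.seed(77)
    idx <- matrix(sample.int(100, 2 * 260, replace = TRUE), ncol = 2)
    checked <- 0L
    for (g in gammas) {
        p <- kernelParams(gamma = g)
        for (k in seq_len(nrow(idx))) {
            ex <- explainKernelPair(vs[[idx[k, 1]]], vs[[idx[k, 2]]], p)
            if (ex@degenerate) next
            expect_lte(abs(sum(perFeature(ex)) - kernelValue(ex)),
                       1e-8 * (1 + kernelValue(ex)))
            checked <- checked + 1L
        }
    }
    expect_gte(checked, 1000L)
})

test_that("per-pair explanation assigns class values and omits dummies", {
    ex <- explainKernelPair(pairX, pairY, sigma1)
    pf <- perFeature(ex)
    expect_setequal(names(pf), c("0", "2", "3", "4"))
    expect_false("1" %in% names(pf))  # inactive in both: never materialised
    expect_equal(unname(pf[c("0", "3")]), c(0.25, 0.25))
    expect_equal(sum(pf[c("0", "3")]), 0.5)
    expect_equal(round(sum(pf[c("2", "4")]), 3), -0.132)
    expect_equal(round(kernelValue(ex), 3), 0.368)

    # identical vectors: every active feature gets 1/I, total 1
    v <- sparseBinaryVector(c(1, 4, 7), 10)
    exi <- explainKernelPair(v, v, kernelParams(gamma = 3))
    expect_equal(unname(perFeature(exi)), rep(1 / 3, 3))
    expect_equal(kernelValue(exi), 1)
})

test_that("degenerate all-zero pair is flagged, not allocated", {
    z <- sparseBinaryVector(integer(0), 6)
    ex <- explainKernelPair(z, z, sigma1)
    expect_true(ex@degenerate)
    expect_length(perFeature(ex), 0)
    expect_equal(kernelValue(ex), 1)
})

test_that("gamma -> 0 limit spreads the kernel value uniformly", {
    p <- kernelParams(gamma = 1e-8)
    for (case in list(c(2, 2), c(0, 5), c(3, 1), c(5, 7))) {
        I <- case[1]
        D <- case[2]
        expect_equal(phiSymmetricDifference(I, D, p), 1 / (I + D),
                     tolerance = 1e-6)
    }
})

test_that("log coalition weights match worked-table values and normalise", {
    expect_equal(exp(logCoalitionWeight(0, 0, 2, 2, TRUE)), 0.25)
    expect_equal(exp(logCoalitionWeight(0, 1, 2, 2, FALSE)), 1 / 12)
    expect_error(logCoalitionWeight(2, 0, 2, 2, TRUE), "out of range")
    expect_error(logCoalitionWeight(0, 2, 2, 2, FALSE), "out of range")

    # the weighted permutation measure sums to 1 for the assessed feature
    for (case in list(c(2, 2), c(3, 1), c(1, 4), c(5, 5))) {
        I <- case[1]
        D <- case[2]
        tot <- 0
        for (Ni in 0:(I - 1)) for (Nd in 0:D)
            tot <- tot + exp(logCoalitionWeight(Ni, Nd, I, D, TRUE))
        expect_equal(tot, 1)
        tot <- 0
        for (Ni in 0:I) for (Nd in 0:(D - 1))
            tot <- tot + exp(logCoalitionWeight(Ni, Nd, I, D, FALSE))
        expect_equal(tot, 1)
    }

    # stays finite far beyond naive factorial overflow
    big <- logCoalitionWeight(4e4, 5e4, 5e4, 5e4 + 1, TRUE)
    expect_true(is.finite(big))
})
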
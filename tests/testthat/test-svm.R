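test_that("decision distance matches trivial and dense-algebra routes", {
    x <- sparseBinaryVector(c(1, 3, 5), 10)
    p <- kernelParams(gamma = 0.4)
    # one support vector equal to x: kernel is 1, dist = b + w
    m1 <- svmModelSpec(list(x), dualWeights = 1.7, bias = -0.3, params = p)
    expect_equal(svmDistance(m1, x), -0.3 + 1.7)
    # all-zero weights leave only the bias
    m0 <- svmModelSpec(list(x, sparseBinaryVector(0:2, 10)),
                       dualWeights = c(0, 0), bias = 0.9, params = p)
    expect_equal(svmDistance(m0, x), 0.9)
    # toy models agree with an independent dense evaluation
    for (seed in 1:5) {
        m <- generateToySvm(6, 18, seed = seed, gamma = 0.3)
        z <- generateRandomVectors(1, 18, seed = seed + 100)[[1]]
        expect_equal(svmDistance(m, z), denseSvmDistance(m, z),
                     tolerance = 1e-10)
    }
    expect_error(svmDistance(m1, sparseBinaryVector(0, 4)),
                 "universe size")
})

test_that("distance attribution is efficient across a random sweep", {
    worst <- 0
    n <- 0L
    for (g in c(0.01, 0.1, 1)) {
        for (seed in 1:12) {
            m <- generateToySvm(7, 25, seed = seed, gamma = g)
            xs <- generateRandomVectors(15, 25, seed = 1000 + seed)
            for (x in xs) {
                ex <- explainSvmDistance(m, x)
                gap <- abs(ex@biasContribution +
                           sum(ex@perFeatureDistance) - ex@distance)
                expect_lte(gap, 1e-8 * (1 + abs(ex@distance)))
                worst <- max(worst, gap)
                n <- n + 1L
            }
        }
    }
    expect_gte(n, 500L)
    # attribution-reconstructed sign equals the direct classification
    m <- generateToySvm(9, 20, seed = 4)
    for (x in generateRandomVectors(20, 20, seed = 5)) {
        ex <- explainSvmDistance(m, x)
        expect_identical(sign(ex@biasContribution +
                              sum(ex@perFeatureDistance)),
                         sign(svmDistance(m, x)))
    }
})

test_that("single-support-vector explanation equals the pair explanation", {
    p <- kernelParams(gamma = 0.6)
    v <- sparseBinaryVector(c(0, 2, 7), 12)
    x <- sparseBinaryVector(c(2, 5), 12)
    m <- svmModelSpec(list(v), dualWeights = 1, bias = 0, params = p)
    ex <- explainSvmDistance(m, x)
    pair <- explainKernelPair(x, v, p)
    expect_equal(ex@perFeatureDistance[names(perFeature(pair))],
                 perFeature(pair))
    expect_equal(ex@distance, kernelValue(pair))
})

test_that("model attribution equals dual-weighted sum of oracle pair values", {
    m <- generateToySvm(5, 10, seed = 21, gamma = 0.8, density = 0.4)
    xs <- generateRandomVectors(6, 10, seed = 22, density = 0.4)
    for (x in xs) {
        ex <- explainSvmDistance(m, x)
        expected <- setNames(numeric(length(ex@perFeatureDistance)),
                             names(ex@perFeatureDistance))
        for (n in seq_along(m@supportVectors)) {
            po <- exactShapleyEnumeration(x, m@supportVectors[[n]],
                                          m@params, mode = "subsets")
            if (po@degenerate) next
            pf <- perFeature(po)
            expected[names(pf)] <- expected[names(pf)] +
                m@dualWeights[n] * pf
        }
        expect_equal(ex@perFeatureDistance, expected, tolerance = 1e-9)
    }
})

test_that("attributions scale linearly in the dual weights", {
    m <- generateToySvm(6, 15, seed = 31)
    x <- generateRandomVectors(1, 15, seed = 32)[[1]]
    ex1 <- explainSvmDistance(m, x)
    m2 <- svmModelSpec(m@supportVectors, m@dualWeights * 3.5, m@bias,
                       m@params)
    ex2 <- explainSvmDistance(m2, x)
    expect_equal(ex2@perFeatureDistance, 3.5 * ex1@perFeatureDistance)
    expect_equal(ex2@biasContribution, ex1@biasContribution)
})

test_that("features absent from the instance can carry nonzero attribution", {
    p <- kernelParams(gamma = 0.5)
    v <- sparseBinaryVector(c(0, 1, 2), 6)  # support vector activates 0..2
    x <- sparseBinaryVector(c(0, 1), 6)     # instance lacks feature 2
    m <- svmModelSpec(list(v), dualWeights = 1, bias = 0, params = p)
    ex <- explainSvmDistance(m, x)
    expect_false(ex@inInstance[["2"]])
    expect_true(abs(ex@perFeatureDistance[["2"]]) > 0)
    # jointly inactive features are absent from the report entirely
    expect_false("5" %in% names(ex@perFeatureDistance))
})

test_that("log-odds attribution is the -A scaling with Platt bookkeeping", {
    m <- generateToySvm(6, 20, seed = 41)
    xs <- generateRandomVectors(100, 20, seed = 42)
    gapMax <- 0
    for (x in xs) {
        ex <- explainSvmLogodds(m, x)
        A <- m@plattA
        B <- m@plattB
        expect_equal(ex@perFeatureLogodds, -A * ex@perFeatureDistance)
        expect_equal(ex@expectedValue, -(A * ex@biasContribution + B))
        expect_equal(ex@probability, 1 / (1 + exp(A * ex@distance + B)))
        # reconstructed logit equals log(p/(1-p))
        expect_equal(ex@logodds, log(ex@probability / (1 - ex@probability)),
                     tolerance = 1e-8)
        gap <- abs(ex@expectedValue + sum(ex@perFeatureLogodds) -
                   ex@logodds)
        expect_lte(gap, 1e-8 * (1 + abs(ex@logodds)))
        gapMax <- max(gapMax, gap)
    }
    expect_lte(gapMax, 1e-8)
    # A = -1, B = 0 makes log-odds values equal distance values
    mm <- svmModelSpec(m@supportVectors, m@dualWeights, m@bias, m@params,
                       plattA = -1, plattB = 0)
    exm <- explainSvmLogodds(mm, xs[[1]])
    expect_equal(exm@perFeatureLogodds, exm@perFeatureDistance)
    expect_equal(exm@expectedValue, exm@biasContribution)
    # Platt-less models refuse log-odds explanations
    m0 <- svmModelSpec(m@supportVectors, m@dualWeights, m@bias, m@params)
    expect_error(explainSvmLogodds(m0, xs[[1]]), "Platt")
})

test_that("degenerate empty-union pairs are counted and warned about", {
    p <- kernelParams(gamma = 1)
    z <- sparseBinaryVector(integer(0), 5)
    m <- svmModelSpec(list(z, sparseBinaryVector(0, 5)),
                      dualWeights = c(1, 1), bias = 0, params = p)
    expect_warning(ex <- explainSvmDistance(m, z), "empty union")
    expect_identical(ex@degeneratePairs, 1L)
})

test_that("JSON model specs round-trip bit-exactly", {
    m <- generateToySvm(4, 12, seed = 51)
    tf <- tempfile(fileext = ".json")
    writeModelSpec(m, tf)
    m2 <- readModelSpec(tf)
    expect_identical(m2@bias, m@bias)
    expect_identical(m2@dualWeights, m@dualWeights)
    expect_identical(m2@plattA, m@plattA)
    expect_identical(m2@plattB, m@plattB)
    expect_identical(kernelGamma(m2), kernelGamma(m))
    expect_equal(m2@supportVectors, m@supportVectors)
    # Platt-less round trip
    m0 <- generateToySvm(2, 8, seed = 52, platt = FALSE)
    writeModelSpec(m0, tf)
    expect_false(hasPlatt(readModelSpec(tf)))
    # schema violations are descriptive
    jsonlite::write_json(list(gamma = 1), tf, auto_unbox = TRUE)
    expect_error(readModelSpec(tf), "lacks field")
})

test_that("fitted e1071 models extract to equivalent specifications", {
    skip_if_not_installed("e1071")
    vs <- generateRandomVectors(80, 22, seed = 61)
    X <- t(vapply(vs, function(v) {
        z <- numeric(22)
        z[activeIndices(v) + 1] <- 1
        z
    }, numeric(22)))
    set.seed(62)
    labels <- factor(ifelse(rowSums(X[, 1:6]) + rnorm(80, 0, 0.4) > 3,
                            "pos", "neg"))
    fit <- e1071::svm(X[1:30, ], labels[1:30], kernel = "radial",
                      gamma = 0.15, scale = FALSE, probability = TRUE)
    spec <- extractModelSpec(fit)
    expect_true(hasPlatt(spec))
    # decision values on 50 held-out vectors
    held <- 31:80
    dec <- attr(predict(fit, X[held, ], decision.values = TRUE),
                "decision.values")
    ours <- vapply(vs[held], function(v) svmDistance(spec, v), numeric(1))
    expect_equal(as.numeric(dec), ours, tolerance = 1e-8)
    # Platt probabilities for libsvm's first internal class (the class the
    # decision values are oriented towards, read off the column name)
    posClass <- sub("/.*$", "", colnames(dec))
    pr <- attr(predict(fit, X[held, ], probability = TRUE),
               "probabilities")
    expect_equal(unname(pr[, posClass]),
                 1 / (1 + exp(spec@plattA * ours + spec@plattB)),
                 tolerance = 1e-6)
    # spec round-trips through JSON without changing the distances
    tf <- tempfile(fileext = ".json")
    writeModelSpec(spec, tf)
    spec2 <- readModelSpec(tf)
    expect_identical(vapply(vs[held], function(v) svmDistance(spec2, v),
                            numeric(1)), ours)
    # contract errors
    linFit <- e1071::svm(X[1:30, ], labels[1:30], kernel = "linear",
                         scale = FALSE)
    expect_error(extractModelSpec(linFit), "RBF")
    expect_error(extractModelSpec(lm(rnorm(5) ~ 1)), "e1071::svm")
})
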
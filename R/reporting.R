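# 12 significant digits in machine reports; 3 d.p. in the pretty view.
.fmt <- function(x, pretty = FALSE) {
    if (pretty) sprintf("%.3f", x)
    else formatC(x, digits = 12, format = "g")
}

.reportHeader <- function(command, config, seed = NA) {
    c(sprintf("# rbfshapley %s",
              as.character(utils::packageVersion("rbfshapley"))),
      sprintf("# command: %s", command),
      sprintf("# config: %s", config),
      sprintf("# seed: %s", ifelse(is.na(seed), "none", seed)))
}

.readVectorsAuto <- function(path) {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "#universe_size="))
        readSparseVectors(path)
    else
        readDenseVectors(path)
}

#' Coalition work table for one feature class
#'
#' Enumerates the coalition count classes (Ni, Nd) a feature of the given
#' class can join, with the coalition value before and after joining, the
#' marginal change, the number of such coalitions, the Shapley permutation
#' weight, and their product — the full worked computation whose column sum
#' is the feature's Shapley value.
#'
#' @param I,D class sizes of the pair decomposition.
#' @param params a [KernelParams-class].
#' @param class `"intersecting"` or `"symdiff"`, the class of the assessed
#'   feature.
#' @return a data.frame with columns `N_i`, `N_d`, `v_S`, `v_Sf`,
#'   `delta_v`, `n_coalitions`, `weight`, `product`.
#' @examples
#' tab <- coalitionWorkTable(2, 2, kernelParams(sigma = 1), "symdiff")
#' sum(tab$product)  # the symmetric-difference Shapley value
#' @export
coalitionWorkTable <- function(I, D, params,
                               class = c("intersecting", "symdiff")) {
    class <- match.arg(class)
    gamma <- kernelGamma(params)
    fromInt <- class == "intersecting"
    if (fromInt && I < 1)
        stop("no intersecting feature exists (I = 0)")
    if (!fromInt && D < 1)
        stop("no symmetric-difference feature exists (D = 0)")
    grid <- expand.grid(
        N_d = if (fromInt) 0:D else 0:(D - 1L),
        N_i = if (fromInt) 0:(I - 1L) else 0:I)
    grid <- grid[order(grid$N_i, grid$N_d), c("N_i", "N_d")]
    n <- I + D
    vS <- .coalitionValue(grid$N_i + grid$N_d, grid$N_d, gamma)
    vSf <- if (fromInt) exp(-gamma * grid$N_d)
           else exp(-gamma * (grid$N_d + 1))
    mult <- if (fromInt) choose(I - 1, grid$N_i) * choose(D, grid$N_d)
            else choose(I, grid$N_i) * choose(D - 1, grid$N_d)
    w <- mapply(shapleyWeight, grid$N_i + grid$N_d, n)
    data.frame(N_i = grid$N_i, N_d = grid$N_d, v_S = vS, v_Sf = vSf,
               delta_v = vSf - vS, n_coalitions = mult, weight = w,
               product = (vSf - vS) * mult * w, row.names = NULL)
}

.workSection <- function(I, D, params, class, pretty) {
    tab <- coalitionWorkTable(I, D, params, class)
    rows <- apply(tab, 1L, function(r)
        paste(c(sprintf("%d", r[["N_i"]]), sprintf("%d", r[["N_d"]]),
                .fmt(r[["v_S"]], pretty), .fmt(r[["v_Sf"]], pretty),
                .fmt(r[["delta_v"]], pretty),
                sprintf("%d", r[["n_coalitions"]]),
                .fmt(r[["weight"]], pretty),
                .fmt(r[["product"]], pretty)), collapse = "\t"))
    c(sprintf("# work table: %s feature (I = %d, D = %d)", class, I, D),
      paste(c("N_i", "N_d", "v_S", "v_Sf", "delta_v", "n_coalitions",
              "weight", "product"), collapse = "\t"),
      rows,
      sprintf("# column sum (Shapley value): %s",
              .fmt(sum(tab$product), pretty)))
}

#' Explain the RBF kernel between the first two vectors of a file
#'
#' Reads binary vectors (sparse index-list or dense 0/1 format,
#' auto-detected), computes the exact Shapley decomposition of the kernel
#' value between the first two, and writes a tab-separated report: one row
#' per union feature with its class and Shapley value, `#`-prefixed footer
#' lines for the kernel value and class sums, and optionally (`showWork`)
#' the full coalition work tables for each feature class.
#'
#' @param vectorsPath path to a vector file with at least two vectors.
#' @param out output path, or `""` for standard output.
#' @param gamma,sigma kernel parameter; give exactly one.
#' @param showWork logical, append the coalition work tables.
#' @param pretty logical, round to 3 decimals instead of 12 significant
#'   digits.
#' @return the output lines, invisibly.
#' @export
explainPairFile <- function(vectorsPath, out = "", gamma = NULL,
                            sigma = NULL, showWork = FALSE,
                            pretty = FALSE) {
    vecs <- .readVectorsAuto(vectorsPath)
    if (length(vecs) < 2L)
        stop("need at least two vectors; found ", length(vecs))
    params <- kernelParams(gamma = gamma, sigma = sigma)
    x <- vecs[[1]]
    y <- vecs[[2]]
    ex <- explainKernelPair(x, y, params)
    dec <- ex@decomposition
    idx <- as.integer(names(ex@perFeature))
    lines <- c(
        .reportHeader("explain-pair",
                      sprintf("vectors=%s gamma=%.17g show_work=%s",
                              vectorsPath, kernelGamma(params), showWork)),
        paste(c("feature_index", "in_x", "in_y", "feature_class", "phi"),
              collapse = "\t"))
    if (length(idx)) {
        cls <- ifelse(idx %in% dec@intersection, "intersecting", "symdiff")
        lines <- c(lines, vapply(seq_along(idx), function(i)
            paste(c(idx[i],
                    as.integer(idx[i] %in% activeIndices(x)),
                    as.integer(idx[i] %in% activeIndices(y)),
                    cls[i], .fmt(ex@perFeature[i], pretty)),
                  collapse = "\t"), character(1)))
    }
    lines <- c(lines,
        sprintf("# kernel_value\t%s", .fmt(ex@kernelValue, pretty)),
        sprintf("# sum_phi\t%s", .fmt(sum(ex@perFeature), pretty)),
        sprintf("# sum_phi_intersecting\t%s",
                .fmt(sum(ex@perFeature[idx %in% dec@intersection]),
                     pretty)),
        sprintf("# sum_phi_symdiff\t%s",
                .fmt(sum(ex@perFeature[idx %in% dec@symDifference]),
                     pretty)))
    if (ex@degenerate)
        lines <- c(lines,
            "# degenerate\tempty union: kernel value 1 has no players")
    if (showWork) {
        I <- length(dec@intersection)
        D <- length(dec@symDifference)
        if (I >= 1)
            lines <- c(lines,
                       .workSection(I, D, params, "intersecting", pretty))
        if (D >= 1)
            lines <- c(lines,
                       .workSection(I, D, params, "symdiff", pretty))
    }
    writeLines(lines, if (nzchar(out)) out else stdout())
    invisible(lines)
}

.attributionBlock <- function(ex, label, dense, universe, pretty) {
    withLog <- length(ex@logodds) == 1L
    idx <- as.integer(names(ex@perFeatureDistance))
    if (dense) {
        nm <- as.character(0:(universe - 1L))
        phiD <- stats::setNames(numeric(universe), nm)
        phiD[names(ex@perFeatureDistance)] <- ex@perFeatureDistance
        inI <- stats::setNames(rep(FALSE, universe), nm)
        inI[names(ex@inInstance)] <- ex@inInstance
        phiL <- stats::setNames(numeric(universe), nm)
        if (withLog) phiL[names(ex@perFeatureLogodds)] <-
            ex@perFeatureLogodds
        idx <- 0:(universe - 1L)
    } else {
        phiD <- ex@perFeatureDistance
        inI <- ex@inInstance
        phiL <- if (withLog) ex@perFeatureLogodds
                else numeric(length(phiD))
    }
    rows <- vapply(seq_along(idx), function(i)
        paste(c(idx[i], as.integer(inI[i]), .fmt(phiD[i], pretty),
                if (withLog) .fmt(phiL[i], pretty) else ""),
              collapse = "\t"), character(1))
    gap <- ex@biasContribution + sum(ex@perFeatureDistance) - ex@distance
    c(sprintf("# instance\t%s", label),
      paste(c("feature_index", "in_instance", "phi_distance",
              "phi_logodds"), collapse = "\t"),
      rows,
      sprintf("# distance\t%s", .fmt(ex@distance, pretty)),
      sprintf("# bias\t%s", .fmt(ex@biasContribution, pretty)),
      if (withLog) c(
          sprintf("# expected_value\t%s", .fmt(ex@expectedValue, pretty)),
          sprintf("# logodds\t%s", .fmt(ex@logodds, pretty)),
          sprintf("# probability\t%s", .fmt(ex@probability, pretty))),
      sprintf("# efficiency_gap\t%s", .fmt(gap, pretty)),
      if (ex@degeneratePairs)
          sprintf("# degenerate_pairs\t%d", ex@degeneratePairs))
}

#' Explain SVM predictions for a batch of instances
#'
#' Reads a JSON model specification and a vector file, explains every
#' instance (log-odds attributions when the model carries Platt parameters,
#' distance attributions otherwise) and writes one attribution block per
#' instance in a deterministic order. Each block reports per-feature values
#' sorted by feature index plus `#`-prefixed summary footer lines including
#' the per-instance efficiency gap. Run metadata (N_v, universe size, mean
#' union size) is logged to standard error.
#'
#' @param modelPath path to a model JSON (see [readModelSpec()]).
#' @param vectorsPath path to a vector file.
#' @param out output path, or `""` for standard output.
#' @param dense logical, report all universe features instead of only those
#'   active in the instance or a support vector.
#' @param pretty logical, 3-decimal rounding.
#' @return the output lines, invisibly.
#' @export
explainModelFile <- function(modelPath, vectorsPath, out = "",
                             dense = FALSE, pretty = FALSE) {
    model <- readModelSpec(modelPath)
    vecs <- .readVectorsAuto(vectorsPath)
    universe <- universeSize(model)
    unions <- vapply(vecs, function(v) {
        length(Reduce(union, lapply(model@supportVectors, activeIndices),
                      activeIndices(v)))
    }, numeric(1))
    message(sprintf(
        "explain-model: N_v = %d, universe = %d, %d instance(s), mean union size = %.1f",
        length(model@supportVectors), universe, length(vecs),
        mean(unions)))
    lines <- .reportHeader("explain-model",
        sprintf("model=%s vectors=%s dense=%s", modelPath, vectorsPath,
                dense))
    for (i in seq_along(vecs)) {
        ex <- if (hasPlatt(model)) explainSvmLogodds(model, vecs[[i]])
              else explainSvmDistance(model, vecs[[i]])
        lines <- c(lines,
                   .attributionBlock(ex, sprintf("%d", i), dense, universe,
                                     pretty))
    }
    writeLines(lines, if (nzchar(out)) out else stdout())
    invisible(lines)
}

#' Validate the closed forms against exhaustive enumeration
#'
#' Regenerates the small-universe validation experiment: `nVectors` random
#' binary vectors over `universe` features, exact closed-form Shapley values
#' versus brute-force coalition enumeration for every vector pair, compared
#' value by value. Degenerate pairs (both vectors all-zero) are skipped —
#' they carry no attribution. Returns the maximum absolute deviation and the
#' Pearson correlation across all per-feature values.
#'
#' @param seed integer seed for the vector generator.
#' @param gamma RBF width (default 1).
#' @param nVectors number of vectors (default 20).
#' @param universe universe size (default 15).
#' @param density per-bit activation probability (default 0.5).
#' @param tolerance pass threshold on the maximum absolute deviation
#'   (default 1e-10).
#' @param mode enumeration route, `"counts"` (default) or `"subsets"`.
#' @return a list with `nPairs`, `nValues`, `maxDeviation`, `pearson`,
#'   `pass`, and the configuration used.
#' @examples
#' res <- validateClosedForm(seed = 1)
#' res$pearson       # 1
#' res$maxDeviation  # < 1e-10
#' @export
validateClosedForm <- function(seed = 1L, gamma = 1, nVectors = 20L,
                               universe = 15L, density = 0.5,
                               tolerance = 1e-10,
                               mode = c("counts", "subsets")) {
    mode <- match.arg(mode)
    params <- kernelParams(gamma = gamma)
    vecs <- generateRandomVectors(nVectors, universe, density = density,
                                  seed = seed)
    closed <- numeric(0)
    brute <- numeric(0)
    nPairs <- 0L
    for (i in seq_len(length(vecs) - 1L)) {
        for (j in (i + 1L):length(vecs)) {
            exC <- explainKernelPair(vecs[[i]], vecs[[j]], params)
            if (exC@degenerate) next
            exB <- exactShapleyEnumeration(vecs[[i]], vecs[[j]], params,
                                           maxUnion = universe,
                                           mode = mode)
            closed <- c(closed, exC@perFeature)
            brute <- c(brute, exB@perFeature)
            nPairs <- nPairs + 1L
        }
    }
    maxDev <- max(abs(closed - brute))
    r <- stats::cor(closed, brute)
    list(nPairs = nPairs, nValues = length(closed), maxDeviation = maxDev,
         pearson = r, pass = maxDev < tolerance, seed = seed,
         gamma = gamma, nVectors = nVectors, universe = universe,
         density = density, mode = mode, tolerance = tolerance)
}
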
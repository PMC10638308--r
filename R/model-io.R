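#' Write an SVM model specification to JSON
#'
#' Serialises the model as a JSON object with fields `universe_size`,
#' `gamma`, `bias`, `support_vectors` (a list of 0-based active-index
#' lists), `dual_weights`, and optionally `platt_A`/`platt_B`. Numbers are
#' written at full precision (17 significant digits) so the round-trip
#' through [readModelSpec()] is bit-exact.
#'
#' @param model an [SVMModelSpec-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeModelSpec <- function(model, path) {
    obj <- list(
        universe_size = universeSize(model),
        gamma = kernelGamma(model),
        bias = model@bias,
        support_vectors = lapply(model@supportVectors, activeIndices),
        dual_weights = model@dualWeights)
    if (hasPlatt(model)) {
        obj$platt_A <- model@plattA
        obj$platt_B <- model@plattB
    }
    # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' Read an SVM model specification from JSON
#'
#' @param path path to a JSON file written by [writeModelSpec()] (or
#'   assembled by hand in the same schema).
#' @return an [SVMModelSpec-class].
#' @export
readModelSpec <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("universe_size", "gamma", "bias", "support_vectors",
              "dual_weights")
    missing <- setdiff(need, names(obj))
    if (length(missing))
        stop("model JSON lacks field(s): ", paste(missing, collapse = ", "))
    universe <- as.integer(obj$universe_size)
    svRaw <- obj$support_vectors
    if (is.matrix(svRaw))  # simplifyVector collapses equal-length lists
        svRaw <- lapply(seq_len(nrow(svRaw)), function(i) svRaw[i, ])
    svs <- lapply(svRaw, function(ix)
        sparseBinaryVector(as.integer(ix), universe))
    hasA <- "platt_A" %in% names(obj)
    hasB <- "platt_B" %in% names(obj)
    if (hasA != hasB)
        stop("platt_A and platt_B must both be present or absent")
    svmModelSpec(
        supportVectors = svs,
        dualWeights = as.numeric(obj$dual_weights),
        bias = as.numeric(obj$bias),
        params = kernelParams(gamma = as.numeric(obj$gamma)),
        plattA = if (hasA) as.numeric(obj$platt_A) else numeric(0),
        plattB = if (hasB) as.numeric(obj$platt_B) else numeric(0))
}
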
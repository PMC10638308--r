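#' Read sparse binary vectors from an index-list text file
#'
#' The sparse text format holds one vector per line as whitespace- or
#' comma-separated active 0-based indices, preceded by a header line
#' `#universe_size=<int>`. A blank (or whitespace-only) line encodes the
#' all-zero vector. Lines starting with `#` after the header are comments.
#'
#' @param path file path.
#' @return list of [SparseBinaryVector-class].
#' @seealso [writeSparseVectors()], [readDenseVectors()]
#' @export
readSparseVectors <- function(path) {
    lines <- readLines(path)
    if (!length(lines))
        stop("empty vector file: ", path)
    hdr <- grep("^#universe_size=", lines, value = TRUE)
    if (length(hdr) != 1L)
        stop("expected exactly one '#universe_size=<int>' header line")
    universe <- as.integer(sub("^#universe_size=", "", hdr))
    if (is.na(universe) || universe < 1L)
        stop("invalid universe_size header")
    body <- lines[!startsWith(lines, "#")]
    lapply(body, function(line) {
        toks <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
        toks <- toks[nzchar(toks)]
        idx <- if (length(toks)) as.integer(toks) else integer(0)
        if (anyNA(idx))
            stop("non-integer token in vector line: ", line)
        sparseBinaryVector(idx, universe)
    })
}

#' Write sparse binary vectors to the index-list text format
#'
#' @param vectors list of [SparseBinaryVector-class] sharing one universe.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSparseVectors <- function(vectors, path) {
    us <- unique(vapply(vectors, universeSize, integer(1)))
    if (length(us) != 1L)
        stop("all vectors must share one universe size")
    lines <- c(sprintf("#universe_size=%d", us),
               vapply(vectors, function(v)
                   paste(activeIndices(v), collapse = " "), character(1)))
    writeLines(lines, path)
    invisible(path)
}

#' Read binary vectors from dense delimited 0/1 rows
#'
#' Each row is one vector; fields are 0 or 1, separated by `sep`. All rows
#' must have equal length, which becomes the universe size.
#'
#' @param path file path.
#' @param sep field separator (default: any whitespace).
#' @return list of [SparseBinaryVector-class].
#' @export
readDenseVectors <- function(path, sep = "") {
    mat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    if (!all(mat %in% c(0, 1)))
        stop("dense vector file must contain only 0s and 1s")
    lapply(seq_len(nrow(mat)), function(i) denseToSparse(mat[i, ]))
}
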
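## Count-matrix and gene-set I/O.
## TSV dialect: tab-separated, UTF-8, no quoting, header row of sample IDs,
## first column named "gene_id". MTX: MatrixMarket coordinate integer triplet
## with sidecar gene/sample ID files (<prefix>.mtx, <prefix>.genes.txt,
## <prefix>.samples.txt).

.checkCountMatrix <- function(x) {
    if (anyDuplicated(rownames(x))) {
        d <- rownames(x)[duplicated(rownames(x))][1]
        stop("duplicate gene ID: ", d)
    }
    if (anyDuplicated(colnames(x))) {
        d <- colnames(x)[duplicated(colnames(x))][1]
        stop("duplicate sample ID: ", d)
    }
    if (any(x < 0)) stop("negative counts are not allowed")
    if (any(x != round(x))) stop("non-integer counts are not allowed")
    x
}

#' Read and write gene-by-sample count matrices
#'
#' `readCounts()` parses a raw count matrix from either a TSV (first column
#' `gene_id`, header row of sample IDs) or a MatrixMarket triplet written
#' by `writeCounts()`. IDs are validated (unique, counts nonnegative
#' integers) and the TSV dialect round-trips byte-identically.
#'
#' @param path file path (TSV) or path prefix (MTX triplet).
#' @param format `"tsv"` or `"mtx"`.
#' @return integer matrix, genes in rows, samples in columns.
#' @export
readCounts <- function(path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    if (format == "tsv") {
        if (!file.exists(path)) stop("no such file: ", path)
        df <- read.delim(path, check.names = FALSE, quote = "")
        if (names(df)[1] != "gene_id")
            stop("malformed header: first column must be 'gene_id'")
        x <- as.matrix(df[, -1, drop = FALSE])
        rownames(x) <- df$gene_id
    } else {
        m <- Matrix::readMM(paste0(path, ".mtx"))
        x <- as.matrix(m)
        rownames(x) <- readLines(paste0(path, ".genes.txt"))
        colnames(x) <- readLines(paste0(path, ".samples.txt"))
    }
    .checkCountMatrix(x)
    storage.mode(x) <- "integer"
    x
}

#' @rdname readCounts
#' @param x integer count matrix (or a `SummarizedExperiment` with a
#'   `counts` assay).
#' @export
writeCounts <- function(x, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    if (methods::is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    .checkCountMatrix(x)
    if (format == "tsv") {
        df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE),
                        paste0(path, ".mtx"))
        writeLines(rownames(x), paste0(path, ".genes.txt"))
        writeLines(colnames(x), paste0(path, ".samples.txt"))
    }
    invisible(path)
}

#' Read and write gene-set collections in GMT format
#'
#' Thin wrappers: reading goes through `fgsea::gmtPathways()`; writing
#' emits the standard name / description / tab-separated member layout.
#'
#' @param path GMT file path.
#' @return `readGMT()`: named list of character vectors. Empty sets are
#'   dropped with a warning.
#' @export
readGMT <- function(path) {
    sets <- fgsea::gmtPathways(path)
    empty <- lengths(sets) == 0
    if (any(empty)) {
        warning("dropping ", sum(empty), " empty gene set(s)")
        sets <- sets[!empty]
    }
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
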
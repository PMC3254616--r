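#' Construct an ExpressionTimeSeries
#'
#' Wraps a gene x time expression matrix, its gene identifiers and its
#' (equally spaced) sampling times into an
#' \linkS4class{ExpressionTimeSeries}. Missing measurements are represented
#' as \code{NA}.
#'
#' @param values numeric N x M matrix, rows = genes, columns = time points.
#' @param times numeric vector of M sampling times in minutes, strictly
#'   increasing with constant spacing.
#' @param geneIds character vector of N unique gene identifiers; defaults to
#'   \code{rownames(values)}.
#' @return an \linkS4class{ExpressionTimeSeries}.
#' @examples
#' x <- ExpressionTimeSeries(matrix(rnorm(6), 2), times = c(0, 7, 14),
#'                           geneIds = c("YAL001C", "YAL002W"))
#' timePoints(x)
#' @export
ExpressionTimeSeries <- function(values, times, geneIds = rownames(values)) {
    values <- as.matrix(values)
    if (is.null(geneIds))
        stop("gene identifiers are required (geneIds or rownames)")
    if (length(times) != ncol(values))
        stop("length(times) must equal ncol(values)")
    storage.mode(values) <- "double"
    rownames(values) <- as.character(geneIds)
    colnames(values) <- paste0("t", format(times, trim = TRUE))
    se <- SummarizedExperiment(assays = SimpleList(exprs = values),
                               colData = DataFrame(time = as.numeric(times)))
    new("ExpressionTimeSeries", se)
}

#' Expression values of an ExpressionTimeSeries
#'
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @return the N x M expression matrix (with \code{NA} for missing values).
#' @export
exprs <- function(x) assay(x, "exprs")

#' Sampling times
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @return numeric vector of time points in minutes.
#' @export
setMethod("timePoints", "ExpressionTimeSeries", function(x) x$time)

#' Missing-value mask
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @return logical N x M matrix, TRUE where the measurement is missing.
#' @export
setMethod("missingMask", "ExpressionTimeSeries", function(x) is.na(exprs(x)))

#' Sampling interval tau
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @return the (constant) spacing between consecutive time points, minutes.
#' @export
setMethod("sampleInterval", "ExpressionTimeSeries", function(x) {
    tm <- timePoints(x)
    if (length(tm) < 2) stop("need at least two time points")
    diff(tm)[1]
})

#' @export
setMethod("show", "ExpressionTimeSeries", function(object) {
    tm <- timePoints(object)
    nmiss <- sum(is.na(exprs(object)))
    cat(sprintf("ExpressionTimeSeries: %d genes x %d time points (t = %g..%g min, tau = %g)\n",
                nrow(object), ncol(object), tm[1], tm[length(tm)],
                if (length(tm) > 1) diff(tm)[1] else NA))
    cat(sprintf("  missing values: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(exprs(object))))
})

#' Read a gene-expression time series from tab-separated text
#'
#' Expects a header line \code{gene<TAB>t0<TAB>t7<TAB>...} (time labels may
#' be bare numbers or carry a non-numeric prefix/suffix such as \code{t0} or
#' \code{X0min}), one row per gene with the identifier in the first column.
#' Empty cells and the sentinels \code{NA}, \code{NaN}, \code{null}
#' (case-insensitive) are read as missing.
#'
#' @param path path to the TSV file.
#' @return an \linkS4class{ExpressionTimeSeries}.
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                            na.strings = c("", "NA", "NaN", "null", "NULL",
                                           "na", "nan", "Null"))
    if (ncol(df) < 2)
        stop("expected a gene-identifier column plus at least one time point")
    ids <- df[[1]]
    if (anyDuplicated(ids))
        stop("duplicate gene identifiers: ",
             paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                   collapse = ", "))
    lab <- colnames(df)[-1]
    times <- suppressWarnings(as.numeric(sub("^[^0-9.+-]*", "",
                                             sub("[^0-9.]*$", "", lab))))
    if (any(is.na(times)))
        stop("cannot parse time points from column labels: ",
             paste(lab[is.na(times)], collapse = ", "))
    vals <- vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
                   numeric(nrow(df)))
    vals <- matrix(vals, nrow = nrow(df),
                   dimnames = list(ids, NULL))
    bad <- !is.na(as.matrix(df[-1])) & is.na(vals)
    if (any(bad))
        stop("non-numeric expression values in ", sum(bad), " cell(s)")
    ExpressionTimeSeries(vals, times = times, geneIds = ids)
}

#' Write a gene-expression time series as tab-separated text
#'
#' Inverse of \code{\link{readExpression}}: header
#' \code{gene<TAB>t0<TAB>t7...}, missing values written as \code{NA}.
#'
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path) {
    tm <- timePoints(x)
    df <- data.frame(gene = rownames(x), exprs(x), check.names = FALSE)
    colnames(df) <- c("gene", paste0("t", format(tm, trim = TRUE)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
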
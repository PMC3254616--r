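#' Write a per-gene POP table as tab-separated text
#'
#' Columns \code{gene}, \code{c1}, \code{c2}, \code{amplitude},
#' \code{phase_deg}.
#'
#' @param table a \linkS4class{GenePopTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenePopTable <- function(table, path) {
    df <- data.frame(gene = table$gene, c1 = table$c1, c2 = table$c2,
                     amplitude = table$amplitude, phase_deg = table$phase)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Eigenvalue summary of a POP analysis as a plain list
#'
#' JSON-ready summary: every oscillation pair (eigenvalue, period, Nyquist
#' reliability, explained variance) and the real decay modes.
#'
#' @param x a \linkS4class{PopAnalysis}.
#' @return a nested list suitable for \code{jsonlite::write_json}.
#' @export
eigenvalueReport <- function(x) {
    list(
        rank = eigenRank(x@eigenSystem),
        covarianceCaptured = covarianceCaptured(x@eigenSystem),
        pairs = lapply(popPairs(x), function(p) list(
            real = Re(p@eigenvalue), imag = Im(p@eigenvalue),
            period_min = p@period,
            explainedVariance = p@explainedVariance,
            nyquistReliable = p@nyquistReliable)),
        decayModes = as.list(decayModes(x)))
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the package version, the seed, the configuration and the MD5
#' checksums of every input file, so that any output can be regenerated.
#'
#' @param path manifest output path (JSON).
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (checksummed).
#' @param seed the seed used, or NULL.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(path, config = list(), inputs = character(),
                          seed = NULL) {
    sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
    manifest <- list(
        package = "popgex",
        version = as.character(utils::packageVersion("popgex")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        config = config,
        inputChecksums = sums)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' Read a flat key = value configuration file
#'
#' One \code{key = value} assignment per line; \code{#} starts a comment;
#' values are parsed as numbers or logicals when possible, otherwise kept
#' as (optionally quoted) strings. Command-line flags override file values.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
readConfigFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    out <- list()
    for (ln in lines) {
        if (!grepl("=", ln, fixed = TRUE))
            stop("malformed config line (expected key = value): ", ln)
        key <- trimws(sub("=.*$", "", ln))
        val <- trimws(sub("^[^=]*=", "", ln))
        val <- gsub('^"|"$', "", val)
        num <- suppressWarnings(as.numeric(val))
        out[[key]] <- if (!is.na(num)) num
            else if (tolower(val) %in% c("true", "false"))
                as.logical(toupper(val))
            else val
    }
    out
}
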
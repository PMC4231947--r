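#' Read an aligned multi-FASTA file of sample-annotated reads
#'
#' Reads one OTU's aligned reads from a multi-FASTA file whose headers
#' follow the \code{>[SampleName]_[ReadId]} convention. The header is
#' split at the \emph{last} underscore: sample names routinely contain
#' underscores (e.g. \code{HGB_0013}) while read identifiers do not, so
#' splitting at the first underscore would mangle real data. Sequence
#' lines may be wrapped arbitrarily; residue case is normalised to upper.
#'
#' @param path Path to a multi-FASTA file.
#' @return An \linkS4class{OTAlignment} with records in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">S1_r1", "GATTACA", ">S1_r2", "GATT-CA"), fa)
#' readAlignment(fa)
#' @export
readAlignment <- function(path) {
    if (!file.exists(path))
        stop("file not found: '", path, "'")
    seqs <- tryCatch(Biostrings::readBStringSet(path),
        error = function(e) stop("no sequences could be read from '",
            path, "': ", conditionMessage(e), call. = FALSE))
    if (length(seqs) == 0L)
        stop("no sequences in '", path, "'")
    w <- Biostrings::width(seqs)
    if (length(unique(w)) != 1L) {
        bad <- which(w != w[1L])[1L]
        stop("not an alignment: record '", names(seqs)[bad],
            "' has length ", w[bad], " but the first record has length ",
            w[1L])
    }
    headers <- names(seqs)
    cut <- regexpr("_[^_]*$", headers)
    bad <- which(cut < 1L | cut == 1L | cut == nchar(headers))
    if (length(bad))
        stop("malformed header (expected '>[SampleName]_[ReadId]'): '",
            headers[bad[1L]], "'")
    sample <- substr(headers, 1L, cut - 1L)
    read <- substring(headers, cut + 1L)
    otAlignment(as.character(seqs), sample, read)
}

#' Write an alignment as multi-FASTA
#'
#' Headers are reconstructed as \code{sample_readId}; sequences are
#' written unwrapped. \code{readAlignment(writeAlignment(aln))}
#' round-trips exactly.
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(alignment, path) {
    seqs <- alignment@sequences
    names(seqs) <- paste(alignment@sampleName, alignment@readId, sep = "_")
    Biostrings::writeXStringSet(seqs, path, width = 20000L)
    invisible(path)
}

#' Write a sample-by-oligotype table as TSV
#'
#' Tab-separated, no quoting: the header row holds an empty leading field
#' followed by the oligotype labels; each subsequent row starts with the
#' sample name followed by integer counts.
#' \code{readOTTable(writeOTTable(t))} reproduces \code{t} exactly.
#'
#' @param table An \linkS4class{OTTable}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @seealso \code{\link{readOTTable}}
#' @export
writeOTTable <- function(table, path) {
    cts <- otCounts(table)
    header <- paste(c("", colnames(cts)), collapse = "\t")
    body <- vapply(seq_len(nrow(cts)), function(i)
        paste(c(rownames(cts)[i], cts[i, ]), collapse = "\t"),
        character(1))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(header, body), con)
    invisible(path)
}

#' Read a sample-by-oligotype table from TSV
#'
#' Inverse of \code{\link{writeOTTable}}. Column order of the file is
#' preserved through the \code{\link{otTable}} abundance re-ordering only
#' when the file is already abundance-ordered (as all tables written by
#' this package are).
#'
#' @param path Path to a TSV written by \code{\link{writeOTTable}}.
#' @return An \linkS4class{OTTable}.
#' @export
readOTTable <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    if (length(lines) < 1L)
        stop("empty table file: '", path, "'")
    # pad trailing empty fields dropped by strsplit (empty OT labels)
    fields <- lapply(lines, function(line) {
        f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
        n <- nchar(line) - nchar(gsub("\t", "", line, fixed = TRUE)) + 1L
        c(f, rep("", n - length(f)))
    })
    labels <- fields[[1L]][-1L]
    rows <- fields[-1L]
    samples <- vapply(rows, `[`, character(1), 1L)
    cts <- matrix(0L, nrow = length(rows), ncol = length(labels),
        dimnames = list(samples, labels))
    for (i in seq_along(rows)) {
        vals <- rows[[i]][-1L]
        if (length(vals) != length(labels))
            stop("malformed table row for sample '", samples[i], "'")
        cts[i, ] <- as.integer(vals)
    }
    otTable(cts)
}

#' Write an oligotype assignment as TSV
#'
#' One row per read: read id, sample name, oligotype label.
#'
#' @param assignment An \linkS4class{OTAssignment}.
#' @param alignment The \linkS4class{OTAlignment} the assignment was
#'   computed from.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAssignment <- function(assignment, alignment, path) {
    stopifnot(nReads(assignment) == nReads(alignment))
    df <- data.frame(
        read_id = readIds(alignment),
        sample_name = sampleNames(alignment),
        ot_label = otAssignments(assignment),
        check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        fileEncoding = "UTF-8")
    invisible(path)
}
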
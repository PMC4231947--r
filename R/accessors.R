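#' Construct an OTAlignment from character data
#'
#' Programmatic counterpart of \code{\link{readAlignment}}: builds an
#' \linkS4class{OTAlignment} from in-memory sequences, e.g. those produced
#' by \code{\link{generateAlignment}}. Residues are upper-cased; every
#' printable character (including the gap \code{"-"}) is retained as an
#' ordinary alphabet symbol.
#'
#' @param sequences Character vector of equal-length aligned reads.
#' @param sampleNames Character vector of sample labels, one per read.
#' @param readIds Character vector of unique-ish read identifiers, one per
#'   read. Duplicates are tolerated with a warning: counts, not read
#'   identities, drive all downstream computation.
#' @return An \linkS4class{OTAlignment}.
#' @examples
#' aln <- otAlignment(c("AAC", "AAG"), c("S1", "S1"), c("r1", "r2"))
#' nReads(aln)
#' @export
otAlignment <- function(sequences, sampleNames, readIds) {
    if (anyDuplicated(readIds))
        warning("duplicate read ids; downstream results use counts only")
    new("OTAlignment",
        sequences = Biostrings::BStringSet(toupper(sequences)),
        sampleName = as.character(sampleNames),
        readId = as.character(readIds))
}

#' @rdname OTAlignment-class
#' @export
setMethod("nReads", "OTAlignment", function(x) length(x@sequences))

#' @rdname OTAlignment-class
#' @export
setMethod("alignmentLength", "OTAlignment",
    function(x) Biostrings::width(x@sequences)[1L])

#' @rdname OTAlignment-class
#' @export
setMethod("sampleNames", "OTAlignment", function(x) x@sampleName)

#' @rdname OTAlignment-class
#' @export
setMethod("readIds", "OTAlignment", function(x) x@readId)

#' @describeIn OTAlignment-class Reads x positions character matrix.
#' @export
setMethod("as.matrix", "OTAlignment", function(x, ...) {
    m <- as.matrix(x@sequences)
    rownames(m) <- paste(x@sampleName, x@readId, sep = "_")
    m
})

setMethod("show", "OTAlignment", function(object) {
    cat("OTAlignment:", nReads(object), "reads x",
        alignmentLength(object), "positions;",
        length(unique(object@sampleName)), "samples\n")
})

#' Construct an OTTable from a count matrix
#'
#' Columns are reordered by decreasing total abundance (ties broken by
#' label) so the table matches the conventional presentation of
#' decomposition results.
#'
#' @param counts Numeric matrix of non-negative integer counts with sample
#'   row names and oligotype column names.
#' @return An \linkS4class{OTTable}.
#' @examples
#' otTable(matrix(c(2, 0, 1, 1), 2, 2,
#'     dimnames = list(c("S1", "S2"), c("AC", "AG"))))
#' @export
otTable <- function(counts) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (ncol(counts) > 1L) {
        ord <- order(-colSums(counts), colnames(counts))
        counts <- counts[, ord, drop = FALSE]
    }
    new("OTTable", counts = counts)
}

#' @rdname OTTable-class
#' @export
setMethod("sampleNames", "OTTable", function(x) rownames(x@counts))

#' @rdname OTTable-class
#' @export
setMethod("otLabels", "OTTable", function(x) colnames(x@counts))

#' @rdname OTTable-class
#' @export
setMethod("otCounts", "OTTable", function(x) x@counts)

#' @describeIn OTTable-class Total reads per oligotype column.
#' @export
setMethod("otTotals", "OTTable", function(x) colSums(x@counts))

#' @describeIn OTTable-class Number of oligotypes (columns).
#' @param x,... See base.
#' @export
setMethod("dim", "OTTable", function(x) dim(x@counts))

#' @describeIn OTTable-class Underlying count matrix.
#' @export
setMethod("as.matrix", "OTTable", function(x, ...) x@counts)

setMethod("show", "OTTable", function(object) {
    cat("OTTable:", nrow(object@counts), "samples x",
        ncol(object@counts), "oligotypes;",
        sum(object@counts), "reads\n")
    if (ncol(object@counts) > 0L)
        print(utils::head(object@counts, 6L))
})

#' @rdname OTAssignment-class
#' @export
setMethod("otAssignments", "OTAssignment", function(x) x@labels)

#' @describeIn OTAssignment-class Number of reads assigned.
#' @export
setMethod("nReads", "OTAssignment", function(x) length(x@labels))

setMethod("show", "OTAssignment", function(object) {
    cat("OTAssignment (", object@method, "): ", length(object@labels),
        " reads -> ", length(unique(object@labels)), " oligotypes\n",
        sep = "")
    if (!is.null(object@positionsUsed))
        cat("  positions used:",
            paste(object@positionsUsed, collapse = ", "), "\n")
})

setMethod("show", "EntropyProfile", function(object) {
    cat("EntropyProfile:", length(object@values), "positions,",
        object@nReads, "reads; max H =",
        format(max(object@values), digits = 4), "at position",
        which.max(object@values), "\n")
})

setMethod("show", "BSMExpectation", function(object) {
    cat("BSMExpectation: p =", object@p, "pieces\n")
    print(utils::head(object@proportions, 10L))
})

setMethod("show", "Ordination", function(object) {
    cat("Ordination:", nrow(object@rowPrincipal), "samples,",
        length(object@inertia), "axes; inertias:",
        paste(format(object@inertia, digits = 4), collapse = ", "), "\n")
})

setMethod("show", "SynthSpec", function(object) {
    cat("SynthSpec:", object@nSamples, "samples,",
        sum(object@readsPerSample), "reads x", object@alignmentLength,
        "positions;", length(object@components),
        "planted components;", ncol(object@mixing),
        "subpopulations; noise", object@noiseRate, "\n")
})
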
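#' Build a sample-by-oligotype count table
#'
#' Cross-tabulates an oligotype assignment against the sample annotation
#' of its alignment. Samples appear in order of first appearance in the
#' alignment; oligotypes are ordered by decreasing total abundance (ties
#' broken by label). The grand total equals the number of reads -- no
#' read is dropped.
#'
#' @param assignment An \linkS4class{OTAssignment}.
#' @param alignment The \linkS4class{OTAlignment} the assignment was
#'   computed from.
#' @return An \linkS4class{OTTable}.
#' @examples
#' aln <- otAlignment(c("AC", "AC", "AG", "AG"),
#'     c("S1", "S1", "S1", "S2"), paste0("r", 1:4))
#' buildOTTable(oligotype(aln, 1:2), aln)
#' @export
buildOTTable <- function(assignment, alignment) {
    if (nReads(assignment) != nReads(alignment))
        stop("assignment covers ", nReads(assignment),
            " reads but the alignment has ", nReads(alignment))
    samples <- sampleNames(alignment)
    labels <- otAssignments(assignment)
    tab <- table(
        factor(samples, levels = unique(samples)),
        factor(labels, levels = sort(unique(labels))))
    cts <- matrix(as.integer(tab), nrow = nrow(tab),
        dimnames = dimnames(tab))
    otTable(cts)
}

#' Drop oligotypes below a minimum total abundance
#'
#' Retains the oligotype columns whose total count is at least \code{m}
#' (an inclusive floor); sample rows are unchanged.
#'
#' @param table An \linkS4class{OTTable}.
#' @param m Positive integer minimum abundance.
#' @return The filtered \linkS4class{OTTable}.
#' @export
filterMinAbundance <- function(table, m) {
    stopifnot(m >= 1)
    cts <- otCounts(table)
    otTable(cts[, colSums(cts) >= m, drop = FALSE])
}

#' Number of singleton oligotypes
#'
#' A singleton oligotype contains exactly one read across all samples.
#' An excess of singletons is the typical signature of sequencing noise
#' surviving decomposition.
#'
#' @param table An \linkS4class{OTTable}.
#' @return Non-negative integer count of singleton columns.
#' @export
singletonCount <- function(table) {
    sum(colSums(otCounts(table)) == 1L)
}

#' Total variance of an OT table
#'
#' Sum over oligotype columns of the across-sample variance (n - 1
#' denominator): the trace of the sample covariance matrix of oligotype
#' abundances, i.e. the total community variance retained in the table.
#'
#' @param table An \linkS4class{OTTable} with at least two samples.
#' @return Non-negative real.
#' @export
totalVariance <- function(table) {
    cts <- otCounts(table)
    if (nrow(cts) < 2L)
        stop("total variance requires at least two samples")
    if (ncol(cts) == 0L)
        return(0)
    sum(apply(cts, 2L, var))
}
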
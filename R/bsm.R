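#' Broken stick expected abundance proportions
#'
#' Closed form for the expected ranked piece sizes when a whole is broken
#' into \code{p} pieces at random: the k-th largest piece has expected
#' proportion b_k = (1/p) * sum_{i=k..p} (1/i). Applied to oligotype
#' tables this is the null abundance profile of an OTU whose reads were
#' split into p oligotypes by chance alone.
#'
#' @param p Number of pieces (oligotypes), a positive integer.
#' @return A \linkS4class{BSMExpectation}.
#' @examples
#' bsmProportions(brokenStick(2))  # 0.75 0.25
#' @export
brokenStick <- function(p) {
    p <- as.integer(p)
    if (length(p) != 1L || is.na(p) || p < 1L)
        stop("p must be a positive integer")
    b <- rev(cumsum(1 / rev(seq_len(p)))) / p
    new("BSMExpectation", p = p, proportions = b)
}

#' @describeIn brokenStick Expected proportions b_1..b_p.
#' @param x A \linkS4class{BSMExpectation}.
#' @export
bsmProportions <- function(x) x@proportions

#' @describeIn brokenStick Expected counts N * b_k for a total of N reads.
#' @param N Total read count.
#' @export
bsmExpectedCounts <- function(x, N) N * x@proportions

#' Rank-by-rank broken stick report for an OT table
#'
#' Ranks oligotypes by decreasing total abundance (ties broken by label)
#' and tabulates observed versus broken-stick expected counts, with the
#' retention decision of \code{\link{bsmFilter}}.
#'
#' @param table An \linkS4class{OTTable} with at least one oligotype.
#' @param mode \code{"prefix"} (default) retains the maximal leading run
#'   of ranks whose observed count strictly exceeds the expectation,
#'   stopping at the first failure; \code{"rank"} retains every rank that
#'   individually exceeds its expectation (for sensitivity analysis).
#' @return A data.frame: \code{rank}, \code{label}, \code{observed},
#'   \code{expected}, \code{retained}.
#' @export
bsmReport <- function(table, mode = c("prefix", "rank")) {
    mode <- match.arg(mode)
    cts <- otCounts(table)
    p <- ncol(cts)
    if (p == 0L)
        stop("no OTs in table")
    totals <- colSums(cts)
    ord <- order(-totals, colnames(cts))
    obs <- totals[ord]
    expd <- bsmExpectedCounts(brokenStick(p), sum(cts))
    # strict "larger than": exact ties (up to rounding noise) fail
    exceeds <- obs > expd + 1e-9
    retained <- if (mode == "prefix") cumprod(exceeds) > 0 else exceeds
    if (p == 1L)
        retained <- TRUE  # degenerate: a single piece is never filtered
    data.frame(rank = seq_len(p), label = names(obs),
        observed = as.numeric(obs), expected = expd,
        retained = retained, row.names = NULL)
}

#' Filter an OT table against the broken stick null
#'
#' Keeps only the oligotypes whose abundance exceeds what random
#' fragmentation of the same read pool into the same number of pieces
#' would produce -- a principled alternative to an arbitrary minimum
#' abundance cut-off. The number of pieces p is the oligotype count of
#' the unfiltered table, and comparison is strict ("larger than" the
#' null). With \code{mode = "prefix"} retention stops at the first rank
#' whose observed count fails to beat the expectation, guaranteeing a
#' contiguous abundant set (the convention also used when the broken
#' stick selects principal axes). A single-oligotype table is returned
#' unchanged.
#'
#' @inheritParams bsmReport
#' @return An \linkS4class{OTTable} restricted to the retained oligotype
#'   columns; sample rows and counts are unchanged.
#' @examples
#' t <- otTable(matrix(c(90, 5, 5), 1, 3,
#'     dimnames = list("S1", c("A", "B", "C"))))
#' otLabels(bsmFilter(t))  # only "A" beats the null
#' @export
bsmFilter <- function(table, mode = c("prefix", "rank")) {
    mode <- match.arg(mode)
    if (ncol(otCounts(table)) == 1L)
        return(table)
    rpt <- bsmReport(table, mode = mode)
    keep <- rpt$label[rpt$retained]
    cts <- otCounts(table)
    otTable(cts[, colnames(cts) %in% keep, drop = FALSE])
}

#' Monte-Carlo broken stick null
#'
#' Simulates the stick-breaking null directly: each replicate drops
#' \code{p - 1} uniform cut points on \code{[0, N]}, sorts the resulting
#' piece lengths in decreasing order, and the across-replicate mean is
#' returned. Converges to \code{N * b_k} of \code{\link{brokenStick}};
#' each is the independent check of the other.
#'
#' @param N Total read count (stick length).
#' @param p Number of pieces, \code{1 <= p <= N}.
#' @param reps Number of replicates.
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return Numeric vector of length \code{p}: mean sorted piece sizes,
#'   summing to \code{N}.
#' @export
bsmSimulate <- function(N, p, reps, seed = 1L) {
    if (N < 1 || p < 1 || p > N)
        stop("need N >= p >= 1")
    stopifnot(reps >= 1)
    if (p == 1L)
        return(N)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    cuts <- matrix(runif(reps * (p - 1L), 0, N), nrow = reps)
    acc <- numeric(p)
    for (i in seq_len(reps)) {
        pieces <- diff(c(0, sort(cuts[i, ]), N))
        acc <- acc + sort(pieces, decreasing = TRUE)
    }
    acc / reps
}
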
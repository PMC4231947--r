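# Run expr with a locally seeded RNG, restoring the caller's state.
withLocalSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    if (!is.null(seed)) set.seed(seed)
    force(expr)
}

# Align tableB's sample rows to tableA's; error on any mismatch.
matchSamples <- function(tableA, tableB) {
    a <- sampleNames(tableA)
    b <- sampleNames(tableB)
    if (!setequal(a, b) || length(a) != length(b))
        stop("tables cover different sample sets")
    otCounts(tableB)[match(a, b), , drop = FALSE]
}

#' Pairwise correlations between the oligotypes of two tables
#'
#' Pearson correlation, across samples, between every oligotype abundance
#' column of \code{tableA} and every column of \code{tableB}. An
#' oligotype with constant abundance across samples has no defined
#' correlation and is reported as \code{NA}, never coerced to 0:
#' uncorrelated-by-degeneracy and uncorrelated-in-fact must stay
#' distinguishable.
#'
#' @param tableA,tableB \linkS4class{OTTable}s over the same samples (any
#'   row order).
#' @return Numeric matrix, rows = oligotypes of \code{tableA}, columns =
#'   oligotypes of \code{tableB}.
#' @export
otCorrelations <- function(tableA, tableB) {
    Y <- matchSamples(tableA, tableB)
    X <- otCounts(tableA)
    suppressWarnings(cor(X, Y))
}

#' RV coefficient between two OT tables
#'
#' Matrix-level analogue of a squared correlation between two
#' multivariate data sets on the same samples: with X and Y the
#' column-centred count matrices,
#' RV = trace(X'Y Y'X) / sqrt(trace((X'X)^2) trace((Y'Y)^2)),
#' the cosine between the sample cross-product matrices XX' and YY'.
#' Computed on raw (centred, unscaled) counts.
#'
#' @param tableA,tableB \linkS4class{OTTable}s over the same samples,
#'   with at least two samples.
#' @return Real in [0, 1]; 1 for identical configurations.
#' @export
rvCoefficient <- function(tableA, tableB) {
    Y <- matchSamples(tableA, tableB)
    X <- otCounts(tableA)
    if (nrow(X) < 2L)
        stop("RV requires at least two samples")
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- scale(Y, center = TRUE, scale = FALSE)
    xx <- tcrossprod(X)
    yy <- tcrossprod(Y)
    den <- sqrt(sum(xx * xx) * sum(yy * yy))
    if (den == 0)
        stop("RV undefined: a table is constant across samples")
    sum(xx * yy) / den
}

#' Sample dissimilarity matrix of an OT table
#'
#' Bray-Curtis (asymmetric, ignores joint absences, in [0, 1]) or
#' Euclidean (symmetric) dissimilarities between sample rows, computed on
#' raw counts via \code{\link[vegan]{vegdist}}. A pair of all-empty
#' samples has Bray-Curtis dissimilarity 0 by convention.
#'
#' @param table An \linkS4class{OTTable}.
#' @param metric \code{"bray_curtis"} or \code{"euclidean"}.
#' @return A \code{\link[stats]{dist}} object labelled by sample.
#' @export
dissimilarity <- function(table, metric = c("bray_curtis", "euclidean")) {
    metric <- match.arg(metric)
    cts <- otCounts(table)
    # empty samples are legitimate here: a both-empty pair is defined
    # as 0 below, so vegdist's empty-row warning is redundant
    d <- withCallingHandlers(
        vegan::vegdist(cts,
            method = if (metric == "bray_curtis") "bray" else
                "euclidean"),
        warning = function(w) {
            if (grepl("empty rows|missing values", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    d[is.nan(d)] <- 0
    d
}

#' Mantel test between two dissimilarity matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance
#' from random relabelling of one matrix's samples:
#' p = (1 + #\{permuted r >= observed r\}) / (nPerm + 1).
#'
#' @param d1,d2 \code{dist} objects over the same samples (at least 3).
#' @param nPerm Number of permutations.
#' @param seed Integer seed for the permutations, or \code{NULL}.
#' @return List with elements \code{r} and \code{p}.
#' @export
mantelTest <- function(d1, d2, nPerm = 999, seed = NULL) {
    if (attr(d1, "Size") < 3L || attr(d1, "Size") != attr(d2, "Size"))
        stop("Mantel test requires two matrices over the same >= 3 samples")
    fit <- withLocalSeed(seed,
        vegan::mantel(d1, d2, permutations = nPerm))
    list(r = unname(fit$statistic), p = unname(fit$signif))
}

#' Correspondence analysis of an OT table
#'
#' Standard CA: with P the table divided by its grand total and r, c the
#' row and column mass vectors, the matrix of standardised residuals
#' S = diag(r)^(-1/2) (P - r c') diag(c)^(-1/2) is decomposed by SVD,
#' S = U Sigma V'. Row standard coordinates are diag(r)^(-1/2) U (unit
#' weighted variance per axis); principal coordinates additionally scale
#' each axis by its singular value. Axis inertias are the squared
#' singular values. All-zero rows or columns are dropped with a warning;
#' a table with no residual structure (rank 0) has no ordination.
#'
#' @param table An \linkS4class{OTTable} with at least two non-empty rows
#'   and columns.
#' @return An \linkS4class{Ordination}.
#' @export
correspondenceAnalysis <- function(table) {
    cts <- otCounts(table)
    keepR <- rowSums(cts) > 0
    keepC <- colSums(cts) > 0
    if (!all(keepR) || !all(keepC)) {
        warning("dropping ", sum(!keepR), " empty sample(s) and ",
            sum(!keepC), " empty oligotype(s)")
        cts <- cts[keepR, keepC, drop = FALSE]
    }
    if (nrow(cts) < 2L || ncol(cts) < 2L)
        stop("CA requires at least two non-empty rows and columns")
    P <- cts / sum(cts)
    r <- rowSums(P)
    cm <- colSums(P)
    S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
    sv <- svd(S)
    rank <- sum(sv$d > max(dim(S)) * .Machine$double.eps * sv$d[1L])
    rank <- min(rank, min(dim(cts)) - 1L)
    if (rank < 1L)
        stop("no inertia: the table matches the independence model")
    ax <- seq_len(rank)
    rowStd <- sv$u[, ax, drop = FALSE] / sqrt(r)
    colStd <- sv$v[, ax, drop = FALSE] / sqrt(cm)
    rowPrin <- sweep(rowStd, 2L, sv$d[ax], `*`)
    dimnames(rowStd) <- dimnames(rowPrin) <-
        list(rownames(cts), paste0("CA", ax))
    dimnames(colStd) <- list(colnames(cts), paste0("CA", ax))
    new("Ordination", rowPrincipal = rowPrin, rowStandard = rowStd,
        colStandard = colStd, inertia = sv$d[ax]^2)
}

#' Procrustes correlation between two ordinations
#'
#' Symmetric Procrustes rotation (both configurations centred and scaled
#' to unit sum of squares, then optimally rotated/reflected) of the first
#' \code{nAxes} sample scores, giving r = sqrt(1 - m^2) where m^2 is the
#' minimised residual sum of squares; significance by permutation of one
#' configuration's rows (\code{\link[vegan]{protest}}). Standard
#' coordinates (unit weighted variance per axis) are the default
#' configuration, the convention under which CA ordinations of community
#' tables are usually compared.
#'
#' @param ordA,ordB \linkS4class{Ordination}s over the same samples, each
#'   with at least \code{nAxes} axes.
#' @param nAxes Number of leading axes to compare.
#' @param nPerm Number of permutations.
#' @param seed Integer seed, or \code{NULL}.
#' @param scores Which row score scaling to rotate: \code{"standard"}
#'   (default) or \code{"principal"}.
#' @return List with elements \code{r} and \code{p}.
#' @export
procrustesCorr <- function(ordA, ordB, nAxes = 2, nPerm = 999,
    seed = NULL, scores = c("standard", "principal")) {
    scores <- match.arg(scores)
    X <- if (scores == "standard") ordA@rowStandard else ordA@rowPrincipal
    Y <- if (scores == "standard") ordB@rowStandard else ordB@rowPrincipal
    if (ncol(X) < nAxes || ncol(Y) < nAxes)
        stop("both ordinations need at least ", nAxes, " axes")
    if (!identical(rownames(X), rownames(Y)))
        Y <- Y[match(rownames(X), rownames(Y)), , drop = FALSE]
    if (anyNA(Y))
        stop("ordinations cover different sample sets")
    X <- X[, seq_len(nAxes), drop = FALSE]
    Y <- Y[, seq_len(nAxes), drop = FALSE]
    fit <- withLocalSeed(seed,
        vegan::protest(X, Y, permutations = nPerm))
    list(r = unname(sqrt(1 - fit$ss)), p = unname(fit$signif))
}

#' Full comparison report between two OT tables
#'
#' Computes the statistics conventionally used to judge whether two
#' decompositions of the same OTU carry the same community signal:
#' per-table oligotype counts, singleton counts and total variance; the
#' RV coefficient; Mantel tests on Bray-Curtis and Euclidean sample
#' dissimilarities; and the Procrustes correlation of the two
#' correspondence analysis ordinations.
#'
#' @param tableA,tableB \linkS4class{OTTable}s over the same samples.
#' @param nPerm Permutations for the Mantel and Procrustes tests.
#' @param seed Integer seed for the permutation tests.
#' @param nAxes Number of CA axes for the Procrustes comparison; if
#'   either ordination has fewer axes the Procrustes entry is \code{NA}
#'   with an explanatory \code{note}.
#' @return A list mirroring the usual comparison summary.
#' @export
compareTables <- function(tableA, tableB, nPerm = 999, seed = 1L,
    nAxes = 2) {
    matchSamples(tableA, tableB)  # fail early on sample mismatch
    mb <- mantelTest(dissimilarity(tableA, "bray_curtis"),
        dissimilarity(tableB, "bray_curtis"), nPerm = nPerm, seed = seed)
    me <- mantelTest(dissimilarity(tableA, "euclidean"),
        dissimilarity(tableB, "euclidean"), nPerm = nPerm, seed = seed)
    pro <- tryCatch({
        procrustesCorr(correspondenceAnalysis(tableA),
            correspondenceAnalysis(tableB), nAxes = nAxes,
            nPerm = nPerm, seed = seed)
    }, error = function(e) list(r = NA_real_, p = NA_real_,
        note = conditionMessage(e)))
    list(
        n_ots = list(A = ncol(otCounts(tableA)),
            B = ncol(otCounts(tableB))),
        singletons = list(A = singletonCount(tableA),
            B = singletonCount(tableB)),
        total_variance = list(A = totalVariance(tableA),
            B = totalVariance(tableB)),
        rv = rvCoefficient(tableA, tableB),
        mantel_bray = mb,
        mantel_euclidean = me,
        procrustes = pro,
        parameters = list(nPerm = nPerm, seed = seed, nAxes = nAxes))
}
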
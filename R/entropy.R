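# Column-wise Shannon entropies of a reads x positions character matrix.
# Gaps and ambiguity codes are ordinary symbols: a gap column carries
# information about indel structure and is deliberately not masked.
columnEntropies <- function(m, base = 2) {
    chars <- sort(unique(as.vector(m)))
    f <- factor(m, levels = chars)
    dim(f) <- dim(m)
    counts <- vapply(seq_len(ncol(m)),
        function(j) tabulate(f[, j], nbins = length(chars)),
        integer(length(chars)))
    counts <- matrix(counts, nrow = length(chars),
        dimnames = list(chars, NULL))
    p <- counts / nrow(m)
    lp <- ifelse(p > 0, log(p, base = base), 0)
    list(values = -colSums(p * lp), counts = counts)
}

#' Per-position Shannon entropy profile
#'
#' Computes, for every alignment column j, the Shannon entropy
#' H_j = -sum_c f_c log2(f_c) of the observed character frequencies f_c.
#' All observed characters contribute, including the alignment gap
#' \code{"-"}, which is treated as informative; zero-frequency terms
#' contribute nothing.
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param base Logarithm base; 2 (the default) yields bits.
#' @return An \linkS4class{EntropyProfile}.
#' @examples
#' aln <- otAlignment(c("AAC", "AAG", "TAC", "TAG"),
#'     rep("S1", 4), paste0("r", 1:4))
#' entropyValues(entropyProfile(aln))  # 1, 0, 1
#' @export
entropyProfile <- function(alignment, base = 2) {
    stopifnot(base > 1)
    m <- as.matrix(alignment)
    ce <- columnEntropies(m, base = base)
    new("EntropyProfile", values = ce$values, counts = ce$counts,
        nReads = nrow(m), base = base)
}

#' @describeIn entropyProfile Entropy values, one per 1-based position.
#' @param profile An \linkS4class{EntropyProfile}.
#' @export
entropyValues <- function(profile) profile@values

#' Character composition of one alignment column
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param position 1-based column index.
#' @return Named integer vector of character counts at that column,
#'   sorted by decreasing count (ties by character); counts sum to the
#'   number of reads.
#' @examples
#' aln <- otAlignment(c("A-C", "AAC", "AAG"), rep("S", 3), paste0("r", 1:3))
#' composition(aln, 2)  # A: 2, -: 1
#' @export
composition <- function(alignment, position) {
    len <- alignmentLength(alignment)
    if (length(position) != 1L || position < 1L || position > len)
        stop("position must lie in 1..", len)
    col <- as.matrix(alignment)[, position]
    tab <- table(col)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    cnt[order(-cnt, names(cnt))]
}

#' Positions exceeding an entropy threshold
#'
#' Returns the 1-based positions whose entropy is strictly greater than
#' the threshold, in ascending order. These are the "components" used to
#' bin reads into oligotypes.
#'
#' @param profile An \linkS4class{EntropyProfile}.
#' @param threshold Non-negative entropy threshold (same base as the
#'   profile).
#' @return Integer vector of positions, possibly empty.
#' @export
highEntropyPositions <- function(profile, threshold) {
    stopifnot(length(threshold) == 1L, threshold >= 0)
    which(profile@values > threshold)
}

#' Export an entropy profile as TSV
#'
#' One row per position: position, entropy, then one column per observed
#' character with its count.
#'
#' @param profile An \linkS4class{EntropyProfile}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeEntropyProfile <- function(profile, path) {
    df <- data.frame(
        position = seq_along(profile@values),
        entropy = profile@values,
        t(profile@counts),
        check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
        fileEncoding = "UTF-8")
    invisible(path)
}

#' Plot an entropy profile
#'
#' Needle plot of per-position entropy, the standard way to eyeball which
#' alignment columns carry subtype information.
#'
#' @param profile An \linkS4class{EntropyProfile}.
#' @param threshold Optional horizontal reference line.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @return Invisibly, \code{NULL}.
#' @importFrom graphics abline
#' @export
plotEntropyProfile <- function(profile, threshold = NULL, ...) {
    v <- profile@values
    graphics::plot(seq_along(v), v, type = "h",
        xlab = "Alignment position", ylab = "Shannon entropy (bits)",
        ...)
    if (!is.null(threshold))
        abline(h = threshold, lty = 2, col = "red")
    invisible(NULL)
}
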
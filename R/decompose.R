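#' Supervised oligotyping at user-chosen positions
#'
#' Bins reads by the concatenation of their characters at the given
#' high-entropy positions ("components"), in the given order. Reads with
#' identical concatenated characters form one oligotype.
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param positions Non-empty vector of 1-based column indices.
#' @return An \linkS4class{OTAssignment} with one label per read.
#' @examples
#' aln <- otAlignment(c("AAC", "AAG", "TAC", "TAG"),
#'     rep("S1", 4), paste0("r", 1:4))
#' otAssignments(oligotype(aln, c(1, 3)))  # "AC" "AG" "TC" "TG"
#' @export
oligotype <- function(alignment, positions) {
    len <- alignmentLength(alignment)
    positions <- as.integer(positions)
    if (length(positions) < 1L)
        stop("at least one position required")
    if (any(positions < 1L) || any(positions > len))
        stop("positions must lie in 1..", len)
    m <- as.matrix(alignment)[, positions, drop = FALSE]
    labels <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    new("OTAssignment", method = "oligotype", positionsUsed = positions,
        labels = labels, parameters = list(positions = positions))
}

#' One-pass (OP) decomposition
#'
#' A single round of entropy profiling: all positions with entropy
#' strictly above the threshold are selected at once and reads are binned
#' by their concatenated characters there. Fast, and suited to screening
#' many OTUs before running the recursive decomposition on promising
#' ones. If no position exceeds the threshold all reads fall into a
#' single oligotype with the empty label.
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param threshold Non-negative entropy threshold (bits by default).
#' @param base Logarithm base for the entropies.
#' @return An \linkS4class{OTAssignment} with method \code{"OP"}.
#' @export
onePass <- function(alignment, threshold = 0.2, base = 2) {
    profile <- entropyProfile(alignment, base = base)
    pos <- highEntropyPositions(profile, threshold)
    if (length(pos) == 0L) {
        labels <- rep("", nReads(alignment))
    } else {
        labels <- otAssignments(oligotype(alignment, pos))
    }
    new("OTAssignment", method = "OP", positionsUsed = as.integer(pos),
        labels = labels,
        parameters = list(threshold = threshold, base = base))
}

#' Minimum Entropy Decomposition (MED)
#'
#' Unsupervised recursive oligotyping. At each node the entropy profile
#' of the node's reads is recomputed; if the maximal entropy does not
#' exceed \code{threshold}, or the node holds fewer than
#' \code{minNodeSize} reads, the node becomes a leaf. Otherwise the reads
#' are split by their character at the maximal-entropy position (ties
#' broken towards the lowest position), one child per observed character
#' -- a character unique to one read yields a singleton child. The
#' procedure repeats until no partition retains a high-entropy position.
#' Leaf labels are the concatenation of split characters along the
#' root-to-leaf path, so labels from different depths have different
#' lengths. The recursion is fully deterministic.
#'
#' @param alignment An \linkS4class{OTAlignment}.
#' @param threshold Entropy threshold; a node splits only while its
#'   maximal column entropy is strictly greater.
#' @param minNodeSize Nodes smaller than this are never split further
#'   (the split itself may create smaller children).
#' @param base Logarithm base for the entropies.
#' @return An \linkS4class{OTAssignment} with method \code{"MED"};
#'   \code{parameters$splits} records each internal node's path label and
#'   split position.
#' @examples
#' aln <- otAlignment(c("AAC", "AAG", "TAC", "TAG"),
#'     rep("S1", 4), paste0("r", 1:4))
#' otAssignments(med(aln, threshold = 0.5, minNodeSize = 1))
#' @export
med <- function(alignment, threshold = 0.2, minNodeSize = 10, base = 2) {
    stopifnot(threshold >= 0, minNodeSize >= 1)
    m <- as.matrix(alignment)
    n <- nrow(m)
    labels <- character(n)
    splits <- list()

    recurse <- function(idx, path) {
        if (length(idx) < minNodeSize) {
            labels[idx] <<- path
            return()
        }
        sub <- m[idx, , drop = FALSE]
        H <- columnEntropies(sub, base = base)$values
        jstar <- which.max(H)   # ties resolve to the lowest position
        if (H[jstar] <= threshold) {
            labels[idx] <<- path
            return()
        }
        splits[[length(splits) + 1L]] <<-
            list(path = path, position = jstar, size = length(idx))
        ch <- sub[, jstar]
        for (c in sort(unique(ch)))
            recurse(idx[ch == c], paste0(path, c))
    }
    recurse(seq_len(n), "")

    new("OTAssignment", method = "MED", positionsUsed = NULL,
        labels = labels,
        parameters = list(threshold = threshold,
            minNodeSize = minNodeSize, base = base, splits = splits))
}

#' Screen a directory of OTU alignments by entropy
#'
#' Profiles every aligned FASTA file in a directory and reports, per
#' file, the maximal column entropy, the number of positions above the
#' threshold, and the alignment dimensions -- the usual first pass to
#' decide which OTUs are worth decomposing. Files that fail validation
#' are reported in the \code{error} column rather than aborting the
#' batch.
#'
#' @param directory Directory containing aligned multi-FASTA files
#'   (\code{.fasta}, \code{.fa} or \code{.fna}).
#' @param threshold Entropy threshold for flagging.
#' @param base Logarithm base for the entropies.
#' @return A data.frame with one row per file: \code{file},
#'   \code{n_reads}, \code{length}, \code{max_entropy},
#'   \code{n_positions_above}, \code{flagged}, \code{error}.
#' @export
batchScreen <- function(directory, threshold = 0.6, base = 2) {
    if (!dir.exists(directory))
        stop("no input: directory '", directory, "' does not exist")
    files <- list.files(directory,
        pattern = "\\.(fasta|fa|fna)$", ignore.case = TRUE,
        full.names = TRUE)
    if (length(files) == 0L)
        stop("no input: no FASTA files in '", directory, "'")
    rows <- lapply(files, function(f) {
        res <- tryCatch({
            aln <- readAlignment(f)
            prof <- entropyProfile(aln, base = base)
            v <- entropyValues(prof)
            data.frame(file = basename(f), n_reads = nReads(aln),
                length = alignmentLength(aln), max_entropy = max(v),
                n_positions_above = sum(v > threshold),
                flagged = max(v) > threshold, error = NA_character_)
        }, error = function(e)
            data.frame(file = basename(f), n_reads = NA_integer_,
                length = NA_integer_, max_entropy = NA_real_,
                n_positions_above = NA_integer_, flagged = FALSE,
                error = conditionMessage(e)))
        res
    })
    do.call(rbind, rows)
}
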
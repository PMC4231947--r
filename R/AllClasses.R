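#' @import methods
#' @importFrom stats cor runif var
#' @importFrom utils write.table
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Aligned, sample-annotated read set from one OTU
#'
#' An \code{OTAlignment} holds the reads of a single OTU as an equal-width
#' \link[Biostrings]{BStringSet} together with the sample name and read
#' identifier parsed from each FASTA header. It is the universe every
#' decomposition operation acts on: all residues, including the alignment
#' gap \code{"-"}, are ordinary symbols.
#'
#' @slot sequences A \code{BStringSet}; all elements have equal width and
#'   residues are upper case.
#' @slot sampleName Character vector, one sample label per read.
#' @slot readId Character vector, one read identifier per read.
#'
#' @seealso \code{\link{readAlignment}}, \code{\link{otAlignment}}
#' @export
setClass("OTAlignment",
    representation(
        sequences = "BStringSet",
        sampleName = "character",
        readId = "character"
    )
)

setValidity("OTAlignment", function(object) {
    n <- length(object@sequences)
    if (n < 1L)
        return("alignment must contain at least one record")
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) != 1L)
        return("all records must have equal width")
    if (w[1L] < 1L)
        return("residues must be non-empty")
    if (length(object@sampleName) != n || length(object@readId) != n)
        return("sampleName and readId must have one entry per record")
    if (any(!nzchar(object@sampleName)) || any(!nzchar(object@readId)))
        return("sample names and read ids must be non-empty")
    TRUE
})

#' Per-position Shannon entropy profile of an alignment
#'
#' Holds the column-wise Shannon entropies H_j of an \code{OTAlignment}
#' together with the per-position character tallies they were computed
#' from. Positions are 1-based everywhere user-visible.
#'
#' @slot values Numeric vector of entropies, one per alignment column.
#' @slot counts Integer matrix (characters x positions) of residue tallies;
#'   row names are the observed characters.
#' @slot nReads Number of reads tallied at every position.
#' @slot base Logarithm base used (2 = bits).
#'
#' @seealso \code{\link{entropyProfile}}
#' @export
setClass("EntropyProfile",
    representation(
        values = "numeric",
        counts = "matrix",
        nReads = "integer",
        base = "numeric"
    )
)

setValidity("EntropyProfile", function(object) {
    if (length(object@values) != ncol(object@counts))
        return("one entropy value per tallied position required")
    if (any(object@values < -1e-12))
        return("entropies must be non-negative")
    if (!all(colSums(object@counts) == object@nReads))
        return("per-position counts must sum to the read count")
    TRUE
})

#' Assignment of reads to oligotypes
#'
#' Maps every read of an alignment to exactly one oligotype label. For the
#' supervised and one-pass methods the label is the concatenation of the
#' read's characters at the selected high-entropy positions; for MED it is
#' the concatenation of split characters along the root-to-leaf path, so
#' labels may have unequal lengths.
#'
#' @slot method One of \code{"oligotype"}, \code{"OP"}, \code{"MED"}.
#' @slot positionsUsed Integer vector of 1-based positions (supervised/OP)
#'   or \code{NULL} for MED, whose per-node split positions live in
#'   \code{parameters$splits}.
#' @slot labels Character vector, one oligotype label per read.
#' @slot parameters Run parameters (threshold, minimum node size, ...).
#'
#' @export
setClass("OTAssignment",
    representation(
        method = "character",
        positionsUsed = "integerOrNULL",
        labels = "character",
        parameters = "list"
    )
)

setValidity("OTAssignment", function(object) {
    if (!object@method %in% c("oligotype", "OP", "MED"))
        return("method must be one of 'oligotype', 'OP', 'MED'")
    if (length(object@labels) < 1L)
        return("labels must cover at least one read")
    TRUE
})

#' Sample-by-oligotype count table
#'
#' A non-negative integer contingency table with samples as rows and
#' oligotypes as columns. Columns are ordered by decreasing total
#' abundance (ties broken by label); rows follow first appearance of each
#' sample in the alignment.
#'
#' @slot counts Integer matrix with unique row (sample) and column
#'   (oligotype) names.
#'
#' @seealso \code{\link{buildOTTable}}, \code{\link{bsmFilter}}
#' @export
setClass("OTTable", representation(counts = "matrix"))

setValidity("OTTable", function(object) {
    cts <- object@counts
    if (!is.numeric(cts))
        return("counts must be numeric")
    if (any(cts < 0))
        return("counts must be non-negative")
    if (any(cts != round(cts)))
        return("counts must be integers")
    if (anyDuplicated(rownames(cts)))
        return("duplicate sample names")
    if (anyDuplicated(colnames(cts)))
        return("duplicate oligotype labels")
    TRUE
})

#' Broken stick expectation for oligotype abundances
#'
#' Expected ranked abundance proportions when one OTU's reads are split
#' into p oligotypes purely at random: b_k = (1/p) * sum_{i=k..p} 1/i.
#'
#' @slot p Number of pieces (oligotypes).
#' @slot proportions Numeric vector b_1 > ... > b_p, summing to 1.
#'
#' @seealso \code{\link{brokenStick}}, \code{\link{bsmFilter}}
#' @export
setClass("BSMExpectation",
    representation(p = "integer", proportions = "numeric"))

setValidity("BSMExpectation", function(object) {
    b <- object@proportions
    if (length(b) != object@p)
        return("one proportion per piece required")
    if (abs(sum(b) - 1) > 1e-12)
        return("proportions must sum to 1")
    if (any(diff(b) >= 0) || any(b <= 0))
        return("proportions must be strictly decreasing and positive")
    TRUE
})

#' Correspondence analysis ordination of an OT table
#'
#' Row (sample) scores of a correspondence analysis in two scalings:
#' principal coordinates (standard coordinates scaled by the singular
#' values, so inter-sample chi-square distances are preserved) and
#' standard coordinates (unit weighted variance per axis). Axis inertias
#' are the squared singular values, in decreasing order.
#'
#' @slot rowPrincipal Samples x axes matrix of principal coordinates.
#' @slot rowStandard Samples x axes matrix of standard coordinates.
#' @slot colStandard Oligotypes x axes matrix of column standard
#'   coordinates.
#' @slot inertia Numeric vector of axis inertias, decreasing.
#'
#' @seealso \code{\link{correspondenceAnalysis}}, \code{\link{procrustesCorr}}
#' @export
setClass("Ordination",
    representation(
        rowPrincipal = "matrix",
        rowStandard = "matrix",
        colStandard = "matrix",
        inertia = "numeric"
    )
)

setValidity("Ordination", function(object) {
    if (ncol(object@rowPrincipal) != length(object@inertia))
        return("one inertia per axis required")
    if (is.unsorted(rev(object@inertia)))
        return("inertias must be in decreasing order")
    TRUE
})

#' Specification of a synthetic aligned read set
#'
#' Describes an alignment with homogeneous background columns and a small
#' number of planted variable positions whose characters are deterministic
#' per latent subpopulation, mimicking the within-OTU structure that
#' oligotyping resolves. Substitution noise creates the spurious singleton
#' oligotypes seen in real data.
#'
#' @slot nSamples Number of samples.
#' @slot readsPerSample Integer vector of reads per sample.
#' @slot alignmentLength Number of alignment columns.
#' @slot components List of planted components, each a list with
#'   \code{position} (1-based column) and \code{chars} (character of the
#'   k-th subpopulation at that column).
#' @slot mixing Samples x subpopulations matrix of mixing proportions;
#'   rows sum to 1.
#' @slot noiseRate Per-character substitution probability in [0, 1).
#' @slot seed Integer seed making generation reproducible.
#'
#' @seealso \code{\link{synthSpec}}, \code{\link{generateAlignment}}
#' @export
setClass("SynthSpec",
    representation(
        nSamples = "integer",
        readsPerSample = "integer",
        alignmentLength = "integer",
        components = "list",
        mixing = "matrix",
        noiseRate = "numeric",
        seed = "integer"
    )
)

setValidity("SynthSpec", function(object) {
    k <- ncol(object@mixing)
    if (object@nSamples < 1L || object@alignmentLength < 1L)
        return("need at least one sample and one column")
    if (length(object@readsPerSample) != object@nSamples)
        return("one read count per sample required")
    if (any(object@readsPerSample < 1L))
        return("every sample needs at least one read")
    if (nrow(object@mixing) != object@nSamples)
        return("one mixing row per sample required")
    if (any(object@mixing < 0) ||
        any(abs(rowSums(object@mixing) - 1) > 1e-8))
        return("mixing proportions per sample must be non-negative and sum to 1")
    pos <- vapply(object@components, function(cmp) cmp$position, numeric(1))
    if (anyDuplicated(pos))
        return("planted positions must be distinct")
    if (length(pos) && (any(pos < 1) || any(pos > object@alignmentLength)))
        return("planted positions must lie within the alignment")
    for (cmp in object@components) {
        if (length(cmp$chars) != k)
            return("each component needs one character per subpopulation")
        if (any(nchar(cmp$chars) != 1L))
            return("component characters must be single characters")
    }
    if (object@noiseRate < 0 || object@noiseRate >= 1)
        return("noiseRate must lie in [0, 1)")
    TRUE
})
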
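#' Specify a synthetic aligned read set with planted structure
#'
#' Builds a \linkS4class{SynthSpec} describing an alignment whose
#' background columns are homogeneous and whose variability is confined
#' to a few planted positions, each carrying a deterministic character
#' per latent subpopulation. This emulates the within-OTU situation that
#' entropy decomposition targets: a handful of information-rich columns
#' against a conserved backbone, with optional i.i.d. substitution noise
#' standing in for sequencing error.
#'
#' @param nSamples Number of samples.
#' @param readsPerSample Reads per sample; recycled to \code{nSamples}.
#' @param alignmentLength Number of alignment columns.
#' @param components List of planted components: each a
#'   \code{list(position =, chars =)} where \code{chars[k]} is the
#'   character subpopulation k carries at that column. Positions must be
#'   distinct.
#' @param mixing Samples x subpopulations matrix of mixing proportions
#'   (rows sum to 1); the default mixes all subpopulations equally in
#'   every sample.
#' @param nSubpop Number of subpopulations when \code{mixing} is not
#'   given.
#' @param noiseRate Per-character substitution probability in [0, 1);
#'   substitutions draw uniformly (with replacement) from
#'   \code{A, C, G, U, -}.
#' @param seed Integer seed.
#' @return A validated \linkS4class{SynthSpec}.
#' @examples
#' sp <- synthSpec(3, 50, 40,
#'     components = list(list(position = 10, chars = c("A", "C"))),
#'     nSubpop = 2, seed = 7)
#' @export
synthSpec <- function(nSamples, readsPerSample, alignmentLength,
    components = list(), mixing = NULL, nSubpop = NULL,
    noiseRate = 0, seed = 1L) {
    nSamples <- as.integer(nSamples)
    readsPerSample <- as.integer(rep_len(readsPerSample, nSamples))
    if (is.null(mixing)) {
        if (is.null(nSubpop))
            nSubpop <- if (length(components))
                length(components[[1L]]$chars) else 1L
        mixing <- matrix(1 / nSubpop, nSamples, nSubpop)
    }
    mixing <- as.matrix(mixing)
    components <- lapply(components, function(cmp)
        list(position = as.integer(cmp$position),
            chars = toupper(cmp$chars)))
    new("SynthSpec", nSamples = nSamples,
        readsPerSample = readsPerSample,
        alignmentLength = as.integer(alignmentLength),
        components = components, mixing = mixing,
        noiseRate = noiseRate, seed = as.integer(seed))
}

noiseAlphabet <- c("A", "C", "G", "U", "-")

#' Generate a synthetic alignment with known truth
#'
#' Realises a \linkS4class{SynthSpec}: per sample, reads are assigned to
#' subpopulations according to the mixing proportions; background
#' columns get one fixed character each; planted columns get each read's
#' subpopulation character; finally every character is independently
#' substituted with probability \code{noiseRate}. Fully seeded -- the
#' same spec always yields the same alignment -- and the caller's RNG
#' state is untouched. The true subpopulation of every read is returned
#' alongside the alignment (FASTA headers carry only sample and read
#' ids, matching the real input contract).
#'
#' @param spec A \linkS4class{SynthSpec}.
#' @return List with elements \code{alignment} (an
#'   \linkS4class{OTAlignment}) and \code{truth} (integer subpopulation
#'   per read).
#' @export
generateAlignment <- function(spec) {
    validObject(spec)
    withLocalSeed(spec@seed, {
        nSub <- ncol(spec@mixing)
        nTot <- sum(spec@readsPerSample)
        L <- spec@alignmentLength
        background <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
        samples <- rep(paste0("S", seq_len(spec@nSamples)),
            spec@readsPerSample)
        truth <- unlist(lapply(seq_len(spec@nSamples), function(s)
            sample.int(nSub, spec@readsPerSample[s], replace = TRUE,
                prob = spec@mixing[s, ])))
        m <- matrix(background, nrow = nTot, ncol = L, byrow = TRUE)
        for (cmp in spec@components)
            m[, cmp$position] <- cmp$chars[truth]
        if (spec@noiseRate > 0) {
            hit <- which(runif(length(m)) < spec@noiseRate)
            m[hit] <- sample(noiseAlphabet, length(hit), replace = TRUE)
        }
        aln <- otAlignment(
            apply(m, 1L, paste0, collapse = ""),
            samples,
            sprintf("r%06d", seq_len(nTot)))
        list(alignment = aln, truth = truth)
    })
}

#' Closed-form expected entropy at a planted position
#'
#' Entropy (bits) of the marginal character distribution at a planted
#' column under the spec, mixing subpopulations by their overall
#' read-weighted proportions and ignoring both sampling fluctuation and
#' substitution noise. Serves as the large-n oracle for
#' \code{\link{entropyProfile}}. An unplanted position is homogeneous by
#' construction and returns 0.
#'
#' @param spec A \linkS4class{SynthSpec}.
#' @param position 1-based column index.
#' @return Non-negative real (bits).
#' @export
expectedEntropy <- function(spec, position) {
    cmp <- Filter(function(x) x$position == position, spec@components)
    if (length(cmp) == 0L)
        return(0)
    cmp <- cmp[[1L]]
    w <- as.numeric(spec@readsPerSample %*% spec@mixing)
    w <- w / sum(w)
    p <- tapply(w, cmp$chars, sum)
    p <- p[p > 0]
    -sum(p * log2(p))
}

#' Write a synthetic data set to disk
#'
#' FASTA alignment plus a truth TSV (read id, sample, subpopulation) and
#' the spec serialised as JSON, so a generated fixture is fully
#' self-describing.
#'
#' @param spec A \linkS4class{SynthSpec}.
#' @param dir Output directory (created if needed).
#' @param name Base name for the three files.
#' @return Invisibly, the generated list from
#'   \code{\link{generateAlignment}}.
#' @export
writeSyntheticData <- function(spec, dir, name = "synthetic") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateAlignment(spec)
    writeAlignment(gen$alignment, file.path(dir, paste0(name, ".fasta")))
    write.table(
        data.frame(read_id = readIds(gen$alignment),
            sample_name = sampleNames(gen$alignment),
            subpopulation = gen$truth),
        file.path(dir, paste0(name, "_truth.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(nSamples = spec@nSamples,
            readsPerSample = spec@readsPerSample,
            alignmentLength = spec@alignmentLength,
            components = spec@components,
            mixing = spec@mixing, noiseRate = spec@noiseRate,
            seed = spec@seed),
        file.path(dir, paste0(name, "_spec.json")),
        auto_unbox = TRUE, digits = NA)
    invisible(gen)
}
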
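---
title: "Entropy decomposition of amplicon alignments: methods and design"
author: "oligotypeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy decomposition of amplicon alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotypeR)
```

## The model

An OTU clustered at 97% identity can hide ecologically distinct
lineages that differ at a handful of nucleotide positions. oligotypeR
treats the OTU's aligned reads as a reads × positions character matrix
and scores each column j by its Shannon entropy

$$H_j = -\sum_c f_c \log_2 f_c,$$

where the sum runs over **all** characters observed at the column —
including the alignment gap `-`, which is informative for indel-prone
chemistries, and any ambiguity code. No masking or small-sample
correction is applied; a column's entropy is exactly the entropy of its
observed character histogram. Logarithms are base 2 (bits) by default
and configurable, since nothing downstream depends on the base beyond a
rescaling of thresholds.

Three decompositions share this profile:

* **Supervised oligotyping** — the analyst picks positions; a read's
  oligotype label is the concatenation of its characters there, in the
  given order. All labels have equal length.
* **One-pass (OP)** — one profile is computed and every position with
  $H_j$ *strictly* above a threshold is used at once. OP is a screening
  tool: it answers "is this OTU worth decomposing?" for hundreds of
  OTUs at a cost of one profile each.
* **MED** — recursive: split the reads at the maximal-entropy position
  (one child per observed character), recompute the profile within each
  child, and stop a branch when its maximal entropy no longer exceeds
  the threshold or the node falls below a minimum size. Leaf labels
  concatenate the split characters along the root-to-leaf path, so
  labels from different depths have different lengths — which is how
  MED tables are recognisable at a glance.

Strict `>` is used for every threshold comparison, in all three
methods: a position *at* the threshold never splits. Ties at the
maximal entropy resolve to the lowest position index, making MED fully
deterministic and independent of read order; no randomness exists
anywhere in the decomposition path. Because each split leaves its
children homogeneous at the split column, recursion depth is bounded by
the alignment length. A character unique to a single read forms its own
child — this is precisely how singleton oligotypes arise — and the
minimum node size only gates *further* splitting; it does not suppress
small children at split time. No post-hoc relocation of outlier reads
is performed.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` (OP/MED) | 0.2 bits | minimum column entropy to act on |
| `minNodeSize` (MED) | 10 reads | nodes smaller than this become leaves |
| `base` | 2 | entropy logarithm base |
| screening threshold | 0.6 bits | flag in `batchScreen`/`runScreen` |
| `nPerm` | 999 | Mantel/Procrustes permutations |
| `nAxes` | 2 | CA axes compared by Procrustes |

The 0.2-bit default echoes the practice of pruning low-information
positions whose variation is indistinguishable from sequencing error at
typical read depths; published oligotype counts for any given data set
are conditional on the thresholds used, so every run summary echoes all
parameters and the workflow functions make them settable. The 0.6-bit
screening default is the level above which an OTU's most variable
position is clearly worth decomposing.

## The broken stick filter

If an OTU's N reads were split into p oligotypes by chance alone, the
expected proportion of the k-th largest piece is
$b_k = \frac{1}{p}\sum_{i=k}^{p} \frac{1}{i}$. `bsmFilter` ranks
oligotypes by decreasing abundance (ties broken by label, so ranking is
deterministic) and retains the maximal *prefix* of ranks whose observed
count strictly exceeds $N b_k$, stopping at the first failure — the
same convention the broken stick uses when selecting principal axes,
and one that guarantees a contiguous abundant set. A per-rank variant
(`mode = "rank"`) is available for sensitivity analysis. p is always
the oligotype count of the *unfiltered* table (the observed number of
pieces), and a single-oligotype table passes through unchanged: with
observed equal to the whole stick the strict test is vacuous and
discarding the only oligotype would be absurd. `bsmSimulate` implements
the same null by Monte Carlo (p − 1 uniform cuts on [0, N], pieces
sorted, averaged); simulation and closed form validate each other in
the test suite, agreeing within 1% at 2·10⁵ replicates.

## Comparing decompositions

All table comparisons run on **raw counts** — no relative-abundance
transform — which is the convention under which the package's example
statistics (e.g. a total variance of 472.1 for the shipped MED table)
are exact. Total variance is the trace of the sample covariance matrix
of oligotype abundances with the n − 1 denominator. The RV coefficient
is computed on column-centred counts. Bray–Curtis and Euclidean
dissimilarities, the Mantel permutation test (p-value with the +1
correction) and symmetric Procrustes come from vegan; correspondence
analysis is implemented in-package as the SVD of the chi-square
standardised residuals and cross-checked against `vegan::cca` in the
tests.

Two CA coordinate scalings are kept: principal coordinates
(standard coordinates scaled per-axis by the singular values) and
standard coordinates (unit weighted variance per axis). The Procrustes
comparison defaults to **standard** coordinates — the convention of
`protest` on `cca` ordinations, under which the shipped example pair
gives r = 0.879; principal coordinates (r = 0.889 on the same pair) are
available via `scores = "principal"`. A table is considered to have a
valid 2-D representation when its CA retains at least two positive
inertias after empty rows and columns are dropped. Undefined Pearson
correlations (constant oligotype columns) are reported as `NA`, never
coerced to 0: uncorrelated-by-degeneracy must stay distinguishable from
uncorrelated-in-fact.

## Synthetic data: what it does and does not emulate

`synthSpec`/`generateAlignment` produce alignments with (i) homogeneous
background columns, (ii) planted components where each latent
subpopulation carries a deterministic character, with per-sample mixing
proportions, and (iii) i.i.d. substitution noise drawn uniformly from
`{A, C, G, U, -}` with replacement. Everything is seeded; the caller's
RNG state is untouched. `expectedEntropy` gives the closed-form
marginal entropy of a planted column, the large-n oracle for the
profile code.

This emulates the *separable* regime: with zero noise and a threshold
strictly between 0 and the smallest planted entropy, OP and MED
provably recover the planted partition exactly, and the suite asserts
they do. It deliberately does not emulate homopolymer error profiles,
chimeras, correlated errors, or alignment artefacts — so passing tests
demonstrate correctness of the decomposition machinery, not robustness
to every real-world noise process. The qualitative noise mechanism is
reproduced, though: raising the substitution rate inflates singleton
oligotypes in OP, because one pass concatenates every contaminated
position while MED's recursion confines most noise to terminal
branches.

## Numerical choices and degenerate inputs

* Entropy terms with $f_c = 0$ contribute 0; profiles equal a
  brute-force histogram oracle to 1e-12.
* The broken-stick strict comparison uses a 1e-9 absolute guard so an
  observed count exactly at its (rational) expectation never passes by
  floating-point accident.
* CA drops all-zero rows/columns with a warning; a table with no
  residual structure (rank 0, e.g. an outer product) raises a "no
  inertia" error rather than returning an empty ordination. The number
  of axes is capped at min(rows, cols) − 1.
* FASTA headers with no underscore, empty files and ragged (unequal
  width) records raise errors naming the offending record; duplicate
  read ids warn but are kept, since counts rather than identities feed
  every downstream computation.
* A sample name ending in an underscore parses by the same
  last-underscore rule as any other (the trailing piece becomes the
  read id); a header *ending* in an underscore would imply an empty
  read id and is rejected.
* An OT table written with an empty oligotype label (the no-split case)
  still round-trips through TSV.

## Problem sizes

The shipped example tables are 13 samples × 3 oligotypes. Test-suite
simulations use alignments of roughly 400–1000 reads × 60 columns,
permutation tests use 99–199 permutations, and the stick-breaking
Monte-Carlo check uses 2·10⁵ replicates with N = 1000 and p = 3; the
acceptance script uses 999 permutations. These sizes make every
statistic stable to well within the tolerances asserted while keeping a
full run fast on a laptop.

## Known limitations

* Only one component (the maximal-entropy position) is selected per MED
  split step; multi-component splits are out of scope.
* No BLAST or taxonomy annotation of representative sequences.
* No rarefaction to equal depth; the broken stick is the only abundance
  null provided (log-series, log-normal or neutral nulls would be
  natural extensions).
* Alignment itself is out of scope: input reads must already be
  aligned, and the equal-width contract is enforced, not repaired.
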
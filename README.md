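# oligotypeR

Entropy decomposition of aligned amplicon reads into oligotypes.

## The problem

Clustering 16S rRNA amplicon reads into OTUs at 97% identity erases the
subtle nucleotide variation that often tracks real ecological structure:
distinct hosts, environments or spatial gradients can hide inside a
single OTU. *Oligotyping* recovers that structure. Given the aligned
reads of one OTU, the per-position Shannon entropy

H_j = −Σ_c f_c · log₂ f_c

(over all observed characters c at column j, alignment gaps included as
informative symbols) pinpoints the few information-rich positions; reads
sharing identical characters there form an *oligotype* (OT). The package
implements three decompositions of this idea, plus the statistics used
to judge them, for microbial ecologists working with within-OTU
microdiversity:

- **Supervised oligotyping** (`oligotype`): the user names the
  high-entropy positions ("components"); reads are binned by their
  concatenated characters there.
- **One-pass decomposition, OP** (`onePass`): a single entropy profile;
  every position with H_j above a threshold is used at once. Cheap, and
  suited to screening hundreds of OTUs (`batchScreen`, `runScreen`).
- **Minimum Entropy Decomposition, MED** (`med`): unsupervised
  recursion — split at the maximal-entropy position, recompute the
  profile inside each partition, repeat until no partition retains a
  high-entropy position. Leaf labels are split-path concatenations.

Sample-by-oligotype count tables (`buildOTTable`) can be filtered
against a **broken stick null model** (`bsmFilter`): an OT is kept only
if its abundance exceeds the expected size of the k-th largest of p
random pieces,

b_k = (1/p) · Σ_{i=k..p} 1/i,

a principled alternative to an arbitrary minimum-abundance cut-off.
Tables produced by different methods are compared with column-wise
Pearson correlations, the RV coefficient, Mantel tests on Bray–Curtis
and Euclidean dissimilarities, and the Procrustes correlation of
correspondence analysis ordinations (`compareTables`). A seeded
generator of synthetic alignments with planted high-entropy positions
(`synthSpec`, `generateAlignment`) makes every step testable against
known ground truth.

## Worked example

Input FASTA headers must follow `>[SampleName]_[ReadId]`; the header is
split at the *last* underscore, so sample names may themselves contain
underscores.

```r
library(oligotypeR)

## two BSM-filtered tables of the same 1175-read OTU, decomposed by
## MED and by OP (13 Arctic sediment samples; shipped with the package)
med <- readOTTable(system.file("extdata", "arctic_otu_med_bsm.tsv",
    package = "oligotypeR"))
op  <- readOTTable(system.file("extdata", "arctic_otu_op_bsm.tsv",
    package = "oligotypeR"))

otTotals(med)
#>   - UC-  UU
#> 355 313 161

totalVariance(med)   # 472.0641
totalVariance(op)    # 953.3205
rvCoefficient(med, op)   # 0.9823777

mantelTest(dissimilarity(med, "bray_curtis"),
           dissimilarity(op,  "bray_curtis"), nPerm = 999, seed = 1)$r
#> 0.9866511

procrustesCorr(correspondenceAnalysis(med),
               correspondenceAnalysis(op), nAxes = 2, seed = 1)$r
#> 0.8793338
```

Both decompositions retain three dominant oligotypes carrying the same
sample pattern (RV ≈ 0.98, Mantel r ≈ 0.99), yet OP's table holds about
twice the community variance of MED's (953 vs 472) because OP splits
the read pool less finely; the Procrustes correlation of the CA
ordinations (0.879) is the most sensitive of the three agreement
measures. Decomposing an alignment end-to-end:

```r
gen <- generateAlignment(synthSpec(4, 120, 60,
    components = list(list(position = 10, chars = c("A", "C", "G", "U"))),
    nSubpop = 4, seed = 7))
tab <- buildOTTable(med(gen$alignment, threshold = 0.2,
    minNodeSize = 10), gen$alignment)
bsmFilter(tab)
```

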
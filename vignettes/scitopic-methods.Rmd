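---
title: "Topic-model discovery of cell types from sci-ATAC-seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-model discovery of cell types from sci-ATAC-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scitopic analyzes single-cell combinatorial-indexing ATAC-seq data: sparse,
binary observations of which genomic regions were accessible in which
cells. Its central model is latent Dirichlet allocation (LDA) fitted by
collapsed Gibbs sampling, with cells in the role of documents and peaks in
the role of words. Around the model sit the steps a practitioner needs to
go from per-cell fragment records to interpreted cell-type clusters:
cut-site extraction, matrix construction and filtering, topic-number
selection by held-out perplexity, topic-based clustering, pseudobulk
peak calling with an iterative refinement loop, and enrichment statistics
for interpreting topics against tissue expression and TF binding
compendia. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions that were genuinely open.

## From fragments to cut sites

A Tn5 insertion is evidenced at both ends of every sequenced fragment.
`fragments_to_cutsites()` places the insertion point at `start + 4` for
the forward-strand end and at `(end - 1) - 5` for the reverse-strand end
(the usual Tn5 dyad correction, applied to BED half-open records), and
emits a 60-bp window centred on each insertion, clipped at chromosome
bounds. One deliberate convention: the reverse-strand shift is applied to
the last covered base `end - 1`, not the half-open end coordinate. These
windows, not the raw fragments, are what the peak callers and the binary
matrix consume.

Cell barcodes are corrected against a whitelist by `correct_barcode()`:
an observed barcode is accepted for the best-matching whitelist entry
when it is within 3 edits and no other entry is within 5; otherwise it is
rejected as `no-match` or `ambiguous`. Barcodes have fixed length, so
Hamming distance is the default metric; Levenshtein is available behind a
flag. PCR duplicates (identical barcode and coordinates) are collapsed,
and cells with fewer than 150 unique fragments are dropped — at the
depths this assay produces (hundreds of fragments per cell), shallower
cells carry almost no clustering information.

## The binary cells-by-peaks matrix and its change-point filter

`build_matrix()` records a 1 wherever at least one cut-site window of a
cell overlaps a peak by one or more base pairs; multiplicity is ignored.
The binary convention reflects the assay: a diploid locus offers at most
two chances to be cut, so counts beyond presence are mostly noise.

Before modeling, `filter_matrix()` removes pathological rows and columns:
cells detecting almost no peaks, and peaks detected in almost no cells or
in almost all cells (real but useless for discriminating types). The rule
sorts the per-item detection fractions, mean-centres them, convolves the
sorted curve with a zero-centred logistic (sigmoid) kernel — a smoothed
slope detector — and flags items beyond the point where the response
exceeds `mean + 4 * IQR` of the convolution output. Parameters the
original description leaves open, and the choices made here:

* **Kernel**: logistic curve sampled at `kernel_width` (default 101)
  evenly spaced points on [-6, 6], zero-centred by subtracting its mean.
* **Boundary handling**: the sorted curve is padded by edge replication
  so every item has a centred convolution value. A "valid"-mode
  convolution was considered and rejected: it leaves no response centred
  on the outermost `kernel_width / 2` items, so any contiguous
  threshold rule must flag about half a kernel width of inliers along
  with the outliers.
* **Localization**: within the requested extreme, the change point is
  the position of the maximal above-threshold response — the slope jump
  itself — and only items beyond it are removed. Ties go to the
  position nearer the bulk of the data.
* **Degeneracy**: when the convolution IQR is zero (constant input) every
  value ties with the threshold and nothing is removed.

On planted data (990 inliers near 0.05, 10 outliers near 0.9) this flags
at least 9 of the 10 outliers and at most one inlier, and the flagged
boundary agrees with a direct largest-slope-jump oracle to within one
position.

## LDA by collapsed Gibbs sampling

Each cell d has a topic mixture theta_d ~ Dirichlet(alpha/K, ..., alpha/K)
and each topic k a peak distribution phi_k ~ Dirichlet(beta/V, ...,
beta/V). Each present peak (token) i in cell d draws a topic z_i ~
theta_d and then its identity from phi_{z_i}. Collapsing theta and phi
gives the standard conditional used by the sampler (written in C++ via
Rcpp, as is usual for Gibbs LDA implementations):

p(z_i = k | z_-i, w)  prop.to  (n_dk + alpha/K) * (n_wk + beta/V) / (n_k + beta)

**Prior convention.** `alpha` and `beta` are *total* prior weights by
default (`prior_scaling = "total"`): the per-component Dirichlet weights
are `alpha / K` and `beta / V`. This is what makes a beta of 2000
sensible against a vocabulary of tens of thousands of peaks — the
per-peak weight is then about 0.06 — and it matches the reading of alpha
and beta as "how much mass the uniform prior carries". A flag switches to
the per-component interpretation. Consequence for small synthetic
vocabularies: a verbatim `beta = 2000` against V of order 100 puts
roughly twenty times more prior mass than data mass on every peak and
flattens all structure, so the desk-scale tests keep `alpha = 3` but set
`beta = 0.06 * V`, preserving the per-peak prior weight rather than the
raw total.

**Defaults**: `alpha = 3.0`, `beta = 2000.0`, 4000 sweeps, burn-in of
half the chain, one posterior sample every 40 post-burn-in sweeps
(`sample_stride`).

**Estimators.** theta and phi are prior-smoothed means over the sampled
count matrices (`estimator = "mean"`); `"mode"` instead takes each
token's most frequent sampled topic and rebuilds counts from that single
modal assignment. `docTopic` and `wordTopic` are always integer count
matrices (final state under "mean", modal state under "mode") so the
token-conservation invariant `sum_k docTopic[d, k] = tokens in cell d`
holds exactly; the probability matrices carry the posterior averaging.

**Correctness oracle.** On a two-cell, four-peak corpus the collapsed
posterior can be enumerated exactly (16 assignment vectors). Per-token
topic frequencies from a 50,000-sweep chain match the enumerated
marginals within total-variation 0.05. Because symmetric priors make the
topic labels exchangeable, the exact marginals are uniform; the value of
the comparison is that a poorly mixing sampler would *not* reach them.
Asymmetric structure is exercised separately: held-out scoring of a
single token matches the closed-form mixture sum to nine decimals.

**Partitioned training.** `n_workers > 1` splits documents into
contiguous blocks; within one sweep each block is sampled against a
stale snapshot of the word-topic counts and the deltas are merged
afterwards (the approximation used by distributed LDA implementations).
It executes serially here — what the option provides is the
*approximation semantics*, so that results obtained with partitioned
updates can be validated: held-out perplexity of a 4-partition run is
within 2% of the serial run on planted data. With `n_workers = 1` runs
are bit-reproducible given the seed. Because the sampler consumes
randomness in token storage order, permuting the cells permutes the
random stream too: reordering invariance is therefore a statistical
property (same partition of cells up to topic relabeling), checked as
ARI = 1 on well-separated planted data, not bitwise equality.

## Topic-number selection by held-out perplexity

In-sample likelihood keeps improving as topics are added, so the topic
count is chosen by five-fold cross-validation: cells are split evenly
and randomly into five disjoint folds; for each candidate K a model is
trained on four folds and the held-out fold is scored; the K with lowest
mean held-out perplexity is recommended; and the production model uses
`ceiling(1.5 * recommended)` topics, exploiting the observation that
LDA largely ignores surplus topics (34 recommended gives 51; 37 gives
56 — the rounding rule is a package choice, the 1.5 factor is not).
Ties are broken toward smaller K.

Held-out scoring fixes phi at the trained values and estimates
log p(w | phi, alpha) for each held-out cell with a Chib-style
estimator: a Gibbs chain over the cell's token assignments locates a
high-probability pivot z* (the best state visited after burn-in), and

log p(w) = log p(w, z*) - log p-hat(z* | w),

where p-hat(z* | w) is the mean, over states z_s drawn from the
stationary chain, of the probability that one full sequential Gibbs sweep
moves z_s to z* (log-sum-exp averaged). Stationarity of the sweep kernel
makes that mean exactly p(z* | w) in expectation. A left-to-right
sequential estimator is included as an independent cross-check
(`method = "l2r"`). Per-cell log-likelihoods are reported as perplexity
`exp(-L / N)`, with N the cell's token count, so lower is better and the
uniform-phi baseline equals V (checked within 1%); for K = 1 the
estimator collapses to the closed form exactly.

Per-(K, fold) seeds are derived deterministically from the master seed,
so enlarging the grid never changes existing scores.

## Clustering cells by topics

Topics worth clustering on are those whose strongest cells agree with
each other. For each topic, the 50 cells with the highest theta are
averaged into a centroid, and the topic's score is the mean dot product
of those rows with the centroid; topics scoring above 0.2 are candidate
cell-type topics. Cells with more than 50% probability on one selected
topic are assigned to it (at most one topic can qualify; exactly 0.5
stays unassigned).

Clusters smaller than 150 cells are grown in a 10-dimensional embedding
of the L2-row-normalized theta matrix. Per iteration: the cluster
centroid is the mean of 200 draws from a Gaussian KDE of the member
coordinates (Scott's bandwidth); the nearest `ceiling(1.25 * size)`
cells are ranked by distance; the ranked distances are convolved with a
step kernel (difference of two 10-wide means) whose positive response
marks distance jumps; and the closest unassigned cell is added if its
response does not exceed `median + 1.5 * IQR` of the response values.
The median centring is a deliberate correction: ranked distances always
have a positive baseline slope, so a cutoff of `1.5 * IQR` on the raw
response rejects every candidate and the growth step becomes a no-op
(observed on planted blobs); centring makes the rule scale-free while
keeping the intended jump detection — co-located unassigned cells are
absorbed, cells beyond a distance jump never are. Existing assignments
are immutable; small clusters are processed in ascending size order;
the embedding is computed once, not per accretion step. After growth,
clusters still under 50 cells are dissolved (too little pooled coverage
to call peaks from).

The embedding engine is injected: UMAP (uwot, seeded, single-threaded)
for display and augmentation by default, and a deterministic PCA reducer
used throughout the tests; when theta has fewer dimensions than
requested the PCA coordinates are zero-padded.

## Pseudobulk peak calling and the iterative loop

`call_peaks_external()` is a thin adapter around MACS2 with the flag set
used throughout (`--format BED -g 9e7 --nomodel --qvalue 0.05 --SPMR
--tsize 60 --bdg --keep-dup all --call-summits`), with tagmented naked
genomic DNA as the input control. Because an external caller cannot be
assumed at desk scale, `call_peaks_builtin()` provides a deliberately
simple stand-in (not a MACS2 reimplementation): cut-site counts in 150-bp
windows stepped by 75 bp are tested against a Poisson rate equal to the
maximum of the global mean, a 10-kb local background, and a depth-scaled
control rate evaluated at both window and local resolution;
Benjamini–Hochberg correction is applied across windows (q <= 0.05) and
adjacent significant windows are merged. Under the null
(treatment = control) the per-window false-positive rate stays below q.

Wide peaks whose signal has several local maxima are split into
contiguous single-summit segments by `split_multisummit()`: the per-base
signal is smoothed with a 50-bp moving average, local maxima with
prominence at least 10% of the peak maximum become summits (both
parameters exposed; the originals are unpublished), and boundaries sit at
the minimum-signal position between adjacent summits, ties resolved
toward the midpoint. Segments exactly tile the original interval — a
property checked on a thousand random signals.

`run_iteration()` wires the loop: build and filter the matrix on the
current peak set, fit LDA, cluster, pool each cluster's cut sites, call
peaks per cluster, merge. Peak calling on pooled cluster data is the
point of the design: a site accessible only in one cell type sits below
the detection limit when its signal is diluted by every other type's
background, but clears it in the cluster pseudobulk. On planted data
(below) one iteration recovers the cluster-specific peaks that
bulk calling misses, and a second iteration is a near fixed point
(base-pair Jaccard >= 0.95).

## Interpreting topics

`topic_specificity()` scores each peak for each topic cluster as the
fraction of its carrying cells that belong to the cluster;
`top_topic_peaks()` takes the top 250 peaks by specificity or all peaks
above 0.5, whichever set is larger. Peaks map to genes through the
nearest *downstream* exon in the gene's orientation within 1200 bp
(`nearest_downstream_gene()`), with overlap handling exposed as a flag
because different analyses want different conventions: topic-to-gene
mapping ignores overlapping pairs, entropy analyses allow them.

Enrichment statistics share one shape: an observed per-category quantity,
a null built from seeded random draws, a per-category log2 ratio, and a
percentile (2.5/97.5) 95% confidence interval across draws —
`tissue_enrichment()` against a genes-by-tissues expression table (100
samples of 250 genes), `chip_overlap_enrichment()` against TF ChIP peaks
with the null drawing peaks in proportion to each topic's peak count
(zero counts get a flagged pseudo-count of 0.5), and
`stage_enrichment()` against per-stage peak sets, with stage membership
defined by a per-peak z-score of at least 1.5 across stages. HOT sites —
intervals bound in more than 40 other ChIP experiments — are removed by
`filter_hot_sites()` before TF-specific analysis. `overlap_stats()`
reports element overlaps in both directions and a right-tailed Fisher
exact p on the 2x2 *base-pair* table (an element-count table is not
used; the base-pair convention matches how genome-arithmetic tools frame
the test), which equals the hypergeometric tail exactly.

Tissue specificity of regulation is summarized by Shannon entropy
(base 2 by default, configurable and recorded): gene expression entropy
across tissues versus the mean entropy of the tissue-overlap
distributions of the peaks linked to the gene, plus a peak diversity
score — the number of distinct tissue signatures among the connected
components (>= 1 bp overlap) of the gene's linked peaks. A gene with a
lone neuron peak plus overlapping intestine and pharynx peaks scores 2.
Whether identical signatures deduplicate is exposed as a flag; the
default counts distinct signatures. Marker-gene cell sets
(`marker_gene_cells()`) collect the cells with any peak touching the gene
body or the stranded window from 1200 bp upstream to 100 bp downstream.

## The synthetic data and what passing tests do (and do not) show

`simulate_matrix()` plants cell types directly in binary space: 600
cells in 5 types, 80 specific peaks per type plus 100 shared, detection
rates 0.35 (own peaks) and 0.01 (cross-type). These defaults make
recovery achievable but not trivial: roughly 28 informative tokens per
cell against 4 background tokens and a shared block that carries no type
signal.

`simulate_fragments()` plants the iterative loop's study condition at
the fragment level. The defaults — 3 types of 150 cells, 60 fragments
per cell (deliberately far below a real experiment's per-cell depth; the
generator scales), 40% of fragments landing in accessible peaks, 150-bp
planted peaks, lognormal(4.4, 0.3) fragment lengths (~80 bp,
sub-nucleosomal), and three peak strength classes (shared : strong :
weak = 3 : 2 : 0.5) — were set by Poisson detection arithmetic so that
the weak class sits about two standard deviations above the pseudobulk
caller's detection threshold and well below the bulk caller's: pooled
over one 150-cell cluster a weak peak contributes ~25 cut sites to its
best window against a background rate near 3.5 (clearly detectable),
while in the bulk pool the same ~25 cut sites face a background near 17
and a correspondingly higher Benjamini–Hochberg bar (not detectable).
Strong peaks are detectable in bulk by design — they are what gives the
first-round LDA its clustering signal.

`simulate_expression()` and `simulate_chip()` provide tissue-block
expression tables (exclusive markers, uniform housekeeping genes,
multiplicative noise) and truth-linked TF interval sets with occupancy
counts and stage labels, including HOT contamination for the non-HOT
filter.

All generators are pure functions of their parameters and seed, and
their truth objects carry everything needed to score recovery. What they
do *not* emulate: Tn5 sequence bias, barcode collisions, doublets,
copy-number variation, fragment-length nucleosome phasing, or the heavy
cell-depth skew of real experiments. Passing the planted-recovery tests
shows the estimators and the pipeline plumbing are correct at the
configured signal-to-noise, not that real tissues will separate this
cleanly.

## Numerical choices and known limitations

* Problem sizes in the test suite and the acceptance script are desk
  scale by design: 150–600 cells, 100–600 peaks, 300–4000 Gibbs sweeps,
  600-kb toy genomes. They were chosen as the smallest sizes at which
  the planted effects are comfortably resolved.
* Discrete sampling uses an inverse-CDF draw from the seeded generator;
  no argmax ties arise. Ranking ties (top-cells, top-peaks) follow the
  stable input order.
* The Chib estimator's bias shrinks with chain length; the uniform-phi
  check uses 10,000 sweeps to sit within 1% of the analytic value.
  Scoring cells with hundreds of tokens at large K is the slowest step
  of cross-validation.
* The built-in caller's local background includes the window itself and
  its test is one-sided Poisson; it is a desk-scale stand-in and is not
  intended to reproduce an external caller's peak boundaries.
* K = 0 or an empty vocabulary is a hard error; a cell with zero tokens
  is an error pointing at filtering; degenerate inputs elsewhere warn
  and no-op (constant change-point input, sub-kernel-width item counts,
  clusters of fewer than two members in augmentation).
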
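---
title: "CpG-set statistics for sparse methylomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CpG-set statistics for sparse methylomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgkit)
```

## The problem cgkit addresses

DNA methylation is measured on CpG dinucleotides, and most assays observe
only a sliver of them: Infinium arrays cover 1--3% of genomic CpGs, RRBS
around 10%, and single-cell methylomes typically 1--10% at one or a few reads
per site. At that sparsity, region-based analysis (differentially methylated
regions, gene-centric aggregation) becomes subjective or impossible, while
the biology of interest -- transcription-factor binding, chromatin state,
cell-type identity -- often acts on single CpGs dispersed across the genome.

cgkit works at the base level instead. A fixed reference ordering of CpGs
(the **CpG index**) makes every dataset a vector keyed by CpG ordinal: a
query set, a knowledgebase set (CpGs linked to a known feature), a universe
(the background actually assayed), M/U read counts, or a continuous score.
Set comparisons are then vectorised bit operations, and the statistics below
run across thousands of knowledgebases in seconds.

## Coordinate conventions

A CpG is identified by the 0-based position of its C on the forward strand,
with the palindromic G merged into the same site. This is a genuine choice --
an equally defensible convention would anchor on the midpoint of the CG --
and it shifts interval-edge membership by up to 1 bp, so it is stated
prominently: an interval `[start, end)` with extension `e` contains a CpG at
position `p` iff `start - e <= p < end + e`. Chromosome order is the order of
first appearance in the index-construction input and is persisted in the
index header; lexicographic re-sorting of chromosomes would silently re-key
every vector. Ordinals are 1-based in the R API.

## Encodings and the container

Three codecs cover the data types of the field, and all of them are exact
inverses -- there is no lossy path anywhere:

* **Bit sets** pack 8 sites per byte. For sparse sets the byte stream is
  run-length encoded ((run, value) byte pairs) and DEFLATEd; the `auto`
  scheme switches to plain bit-packing above 25% density, where RLE stops
  paying for itself. The threshold is a storage trade-off only; correctness
  is scheme-independent.
* **MU counts** store a site's methylated (M) and unmethylated (U) read
  counts in one 64-bit word, M in the upper 32 bits and U in the lower.
  Coverage 0 *is* the missing state. Counts above `2^32 - 1` are a hard
  error rather than a saturation, because silently clipped counts would bias
  beta values. R has no native 64-bit integer, so a packed code travels as a
  double carrying the raw 8-byte payload; conversions go through bytes and
  are exact over the whole range.
* **State vectors** keep the textual state dictionary separate from the
  per-site small-integer codes (1 byte up to 256 states), so repetitive
  categorical annotations compress well.

Streams carry a format tag, site count, payload length and an Adler-32
checksum; truncation and corruption are detected with a byte offset. The
`.cgx` container holds many named streams with a footer offset table, so one
entry of many is readable by touching only the footer and that entry's bytes,
and appending never rewrites existing entry bytes.

## Enrichment testing

For query `Q`, knowledgebase `K` and universe `U`, let `N = |U|`,
`n = |Q ∩ U|`, `K' = |K ∩ U|`, `x = |Q ∩ K ∩ U|`. Under the null that `Q`
falls uniformly in `U`, `x` is hypergeometric; the enrich-side p-value is
`P(X ≥ x)`, deplete-side `P(X ≤ x)`, and the two-sided p-value is Fisher's
exact (total probability of tables no more likely than the observed one).
The test assumes independence among CpGs -- dense local correlation of
methylation is exactly what the proximity test (below) is for.

Two conventions matter more than the formula:

* **Everything is intersected into the universe first**, and all reported
  counts are post-intersection. This is what makes results from a CpG
  subspace (an array manifest, a sparse cell's covered sites) comparable to
  whole-genome results, and it is the property the stability harness
  quantifies.
* **FDR is computed within testing domains.** A domain (chromatin states,
  motifs, traits, technical masks, ...) is one hypothesis space; applying
  Benjamini--Hochberg within it prevents a 100,000-term domain from drowning
  a 15-term one. The step-up itself is `stats::p.adjust(method = "BH")`
  applied per group.

The log2 odds ratio comes from the 2x2 table; when any cell is zero the raw
estimate is infinite, so a 0.5-corrected companion is always reported and
serves as the tie-break (after the p-value, then input order) in rankings --
rank-stability comparisons need a total order.

NPMI (normalized pointwise mutual information) complements the p-value with
an effect-size-like co-occurrence score in [-1, 1]:
`ln(p_ab / (p_a p_b)) / (-ln p_ab)`, with -1 assigned at `p_ab = 0` and +1
when the two sets have identical traces in the universe (the limits of the
expression). It is used to cross-validate knowledgebases against each other.

The set-vs-continuous test compares a continuous per-CpG score between a
target set and the rest of the universe with the two-sample
Kolmogorov--Smirnov statistic. Significance comes from a permutation null
(random relabelings within the universe; add-one p-value, so the floor is
`1/(n_perm+1)`); the `gaussian` option fits a normal to the permuted
statistics by moment matching and returns its upper tail -- an explicit
approximation for large inputs, not an asymptotic KS null.

## Genomic proximity test

Cell-type marker CpGs often concentrate in CpG islands; a spatial-clustering
score distinguishes that from dispersed signals. The genome is tiled into
fixed 1500-bp windows; the default statistic counts query CpGs that share a
window with at least one other query CpG (`events = "members"`), and the
null rate lambda is the mean statistic over 1000 uniform draws of equally
many CpGs from the index. The p-value is the Poisson upper tail at lambda.

The event definition is an interpretive choice: "CpGs co-occurring in a
window" can also be read as the number of multi-occupancy windows
(`events = "bins"`). Both are implemented. They are not statistically
equivalent: in the rare-pair regime the member count is twice the pair count,
so its variance is about twice its mean and the Poisson tail is only an
approximation, while the bin count matches the Poisson rare-event null. A
null simulation on the default fixture index (100,000 CpGs, one per ~100 bp)
shows where the default is trustworthy: at query sizes around 3% of the index
the member-count statistic has variance/mean ~ 0.95 and its p-values are
uniform to KS D ~ 0.02; at much smaller query sizes it is overdispersed
(variance/mean ~ 1.7) and p-values are conservative in the tail. The
calibration test in this package uses 3000-CpG queries for that reason, and
users testing very small sets should prefer `events = "bins"` when the
p-value itself (rather than the ranking) matters.

## Differential methylation between sparse profiles

`call_dmc()` compares two MU profiles. The comparison universe is the set of
sites covered in both profiles (at `cov_min` or more reads, optionally
intersected with a user mask for "comparable" sites); hyper/hypo sets are
the sites whose beta difference reaches `delta_min` in either direction. The
threshold comparison is done by cross-multiplication on raw counts with
`delta_min` written as an integer fraction over 10^6, so it is exact integer
arithmetic: calls do not flicker at rational thresholds (a beta difference of
exactly 0.4 at delta 0.4 is a call), and swapping the two profiles exchanges
hyper and hypo exactly. For binary single-cell profiles, `delta_min = 1`
selects precisely the +1/-1 differences.

Aggregation over knowledgebases (`aggregate_kb()`, `feature_matrix()`)
defaults to the pooled count-weighted beta `sum(M)/sum(M+U)`, which is the
robust choice when most covered sites carry a single read; the unweighted
mean of per-site betas is available behind `weighting = "site"` since
pseudobulk averaging is sometimes defined that way.

## Cell-type signature discovery

Signatures are found by a nonparametric discriminant screen: at each CpG the
target and background sample groups are compared with the Wilcoxon rank-sum
U (mid-ranks for ties), reported as the AUC `U/(n_t n_b)`, together with the
group beta difference. Markers must pass `AUC > 0.95` *and*
`|delta beta| > 0.5` -- both inequalities strict, as printed; the AUC alone
saturates quickly at small n, and the delta filter keeps only differences
that matter at single-read resolution. Sites with fewer than 2 non-missing
values per group are skipped and reported (the minimum is configurable; no
imputation is ever applied, since imputation would inject structure into
exactly the sparse data the screen is meant to respect). A normal-theory
p-value with tie correction is emitted for transparency but is not the
selection criterion.

## Stability under sparsity

`run_stability()` asks how far a testing universe can be thinned before
enrichment conclusions change: the reference ranking on the full universe is
compared with re-tests on universes uniformly downsampled by `2^k`
(k up to 14, fifty iterations per level, seeds derived deterministically from
the master seed), recording the Spearman correlation of the `-log10 p`
ranking and whether the top term changed. Iterations in which the query
vanishes from the thinned universe are recorded as failed rather than
dropped -- at the extreme levels that is itself the finding.

Interpreting the correlation needs care at the extremes. Once knowledgebase
p-values saturate at 1 (sub-universes of ~100 sites at desk scale), the rank
correlation no longer measures ranking fidelity: if only one term carries
signal, rho collapses to the concordance of that single anchor and plateaus
at a small positive floor with non-monotone wobble. For this reason the
package's decay test uses a graded fixture -- every knowledgebase given its
own true enrichment fold, the way chromatin-state families behave against
real queries -- where median rho decays monotonically from 1 until iterations
begin to fail, and monotonicity is asserted only across levels at which every
iteration yields a defined comparison. The top-term change rate, in
contrast, is well defined on a single planted term and is asserted on the
pure decoy fixture.

## Knowledgebase construction rules

* **Motifs**: hit locations extended by +/-10 bp before intersection, so
  edge CpGs count.
* **Consensus sets** (TF binding, histone marks across many samples): all
  CpGs with overlap frequency at least `t`, where `t` is the largest
  threshold whose result reaches the target size -- ties at `t` are all
  included, which is why consensus sets land "at least" at their nominal
  50,000--100,000 sizes. The chosen threshold is recorded in provenance.
* **Gene links**: 10 kb upstream of the TSS through the TTS, strand-aware,
  truncated at chromosome bounds. No clipping against neighbouring genes is
  applied (a documented caveat for users, since nested gene architectures
  will share CpGs).
* **Universes**: joint coverage (intersection of per-sample covered sets) for
  sequencing data; the fixed probe subspace for arrays. An empty universe is
  an error -- no test is defined on it.

## Synthetic data: what it emulates, and what it does not

All tests run on seeded generators; identical configuration reproduces
byte-identical data. The default conditions are desk-scale versions of the
regimes the toolkit targets, chosen once: a 100,000-CpG index over 5
chromosomes with geometric inter-CpG gaps of mean 100 bp (human-like density,
minimum gap 2 bp), 100 knowledgebases of 500--2000 CpGs, queries of 10,000
CpGs (10% of the index, the upper end of single-cell coverage), planted
enrichment fold 10, per-sample coverage 10% at depth `1 + Poisson(0.5)` with
a 0.002 per-read error rate, planted DMC sites fully separated (beta 1 vs 0,
as cell-type markers are), and signature matrices of 12 target vs 12
background samples with group separation 0.6, noise SD 0.05 and 5%
missingness. Problem sizes in the test suite (for example 1000-site
signature matrices and 25--50 stability iterations in the reporting script)
are the package's chosen desk scale; the statistical regimes, not the raw
dimensions, are what carries over.

The generators emulate sparsity, planted effect sizes and coverage dropout.
They do **not** emulate CpG-island clustering, PMD/solo-WCGW sequence
structure, spatially correlated methylation, batch effects, or read-level
error structure. Passing tests therefore demonstrate that the statistics are
correct and well calibrated under their stated assumptions -- not that those
assumptions hold in any particular real dataset; the technical-artifact
knowledgebase machinery exists precisely because real data violate them.

## Numerical choices

* Hypergeometric tails via `phyper`/`dhyper`; the two-sided test sums table
  probabilities `<= observed * (1 + 1e-7)`, the standard guard against
  floating-point ties.
* Beta-threshold comparisons are integer arithmetic (exact for coverages up
  to ~10^4 per site, far beyond sparse-methylome depths).
* Degenerate cases are explicit: empty knowledgebase-in-universe gives p = 1
  and a `degenerate` flag; knowledgebase = universe likewise; empty
  query-in-universe is an error; a zero-event proximity observation has
  p = 1 by `P(X >= 0)`.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; there is no hidden global state anywhere.
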
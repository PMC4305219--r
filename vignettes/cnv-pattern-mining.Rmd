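---
title: "Mining recurrent CNV regions with error-tolerant interval patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining recurrent CNV regions with error-tolerant interval patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvminer)
```

## The problem

Array-based copy-number data arrive as a probes × samples matrix of log
intensity ratios (LRR): values near 0 mean the sample has the reference
copy number at that probe, positive values suggest a gain, negative values
a loss. A recurrent CNV region is a run of consecutive probes that is
aberrant in the *same* subset of samples — a bicluster whose row set is
constrained to be a genomic interval. Positional summary statistics (the
G-score / peel-off family) aggregate evidence per probe across the whole
cohort, so a "peak" can stitch together probes that are actually aberrant
in different sample subsets. `cnvminer` instead searches explicitly over
(interval, sample-subset) pairs, tolerating a controlled fraction of
missing calls, and reports each maximal region together with the samples
that support it.

## The model

After binarization the data are an m × n 0/1 matrix D: probes are items,
samples are transactions. Three definitions drive the search:

* **Weak error-tolerant itemset (ETI).** An interval I′ is supported by a
  sample subset T′ when the mean of D over I′ × T′ is at least 1 − ε. The
  *weak support* of I′ is the maximum |T′|/n over all such subsets. This
  pooled condition deliberately permits individual rows or columns of the
  submatrix to be empty.
* **Strong ETI.** Adds the per-sample condition that every t ∈ T′
  individually carries at least 1 − ε of the interval's probes. Strong
  ETIs are implemented only as a reference check
  (`check_strong_eti()`): the per-sample requirement is usually too strict
  to discover anything beyond near-exact patterns.
* **Recursive weak ETI.** I′ is recursively weak when I′ and all of its
  (interval-constrained) subsets are weak ETIs. This restores the
  anti-monotone pruning that plain weak ETIs lack: if an interval fails,
  no super-interval need be visited.

The search is level-wise. Round 1 computes the **exact** support of every
probe — by convention no tolerance is granted to singletons, otherwise ε
would let arbitrary samples support any single probe — and prunes those
below `sup_min`. Each later round tries to merge every pair of frequent
size-k intervals that (a) differ only in their first and last probe, so
their union is a contiguous size-(k+1) interval, and (b) have support sets
with Jaccard distance (symmetric difference over union) at most δ. A
candidate that reaches `sup_min` weak support becomes frequent and
consumes both parents; otherwise the parents stand. The miner reports the
frequent intervals never consumed by a successful merge — the maximal
patterns — each with its maximizing support set.

### Why the greedy support computation is exact

`weak_eti_support()` ranks samples by their in-interval 1-count
(descending, ties by ascending index) and returns the longest feasible
prefix. For any target subset size k, the top-k prefix maximizes the total
number of 1s, so feasibility of *some* size-k subset is equivalent to
feasibility of the prefix; and the cumulative density of the ranked prefix
is non-increasing in k, so the largest feasible prefix is the global
optimum. The package still ships an exhaustive subset-enumeration oracle
(`bruteforce_weak_support()`, guarded to n ≤ 16) and a
dynamic-programming enumerator of all recursive-weak intervals
(`mine_bruteforce()`, m ≤ 40); the test suite checks the production path
against both on hundreds of random instances. The oracles are
intentionally independent implementations, not refactorings of the search
code.

## The parameters

* `sup_min` ∈ (0, 1]: minimum support as a fraction of samples; an
  interval needs `ceiling(sup_min * n)` supporting samples. Cohort studies
  of germline CNV typically use 0.1–0.2; above ~0.35 little survives in
  balanced multi-population cohorts.
* `epsilon` ∈ [0, 1): the error tolerance of the density condition, in
  units of "fraction of cells allowed to be 0" in the pattern submatrix.
  0.2 is a sensible default for noisy array calls; 0 reduces the whole
  machinery to classical exact-support interval mining.
* `delta` ∈ [0, 1]: the merge dissimilarity budget. 0 forces merged
  intervals to share identical support sets; 1 disables the check. The
  Jaccard-distance form was chosen because it satisfies both stated
  endpoints and reproduces the canonical worked example below. δ is
  applied to the parents' support sets *before* the candidate is
  evaluated: it is a merge precondition, not a post-filter.
* `tau` ≥ 0 (binarization): a cell is a candidate gain when LRR > τ, a
  candidate loss when LRR < −τ; ties stay 0 and the two directions are
  mined separately. Instead of fixing τ, `select_tau()` chooses the
  (1 − d) quantile of |LRR| pooled over the matrix so that a target
  fraction d of cells (commonly 10%) is flagged. A single global τ is
  used — the sparsity target is a genome-wide property — and it is
  symmetric for gains and losses.

## The worked toy example

`toy_cohort()` builds a 7-probe × 10-sample matrix that exercises every
branch at `sup_min = 0.5`, `epsilon = 0.2`, `delta = 0.4`. The matrix is a
reconstruction built to the documented support values, not data from any
cohort.

```{r toy}
toy <- toy_cohort()
fit <- mine_cnv(toy$matrix, sup_min = 0.5, epsilon = 0.2, delta = 0.4)
fit
as.data.frame(fit)[, 1:7]
```

Probe 1 (support 0.4) is pruned at round 1. Probes 2–5 share one support
set and merge into the size-4 pattern. Probes 6 (support 1.0) and 7
(support 0.5, nested) form a candidate whose weak support at ε = 0.2 is
0.8 — eight samples give pooled density 13/16 ≥ 0.8 — yet the merge is
rejected because the parents' support sets differ by Jaccard distance
5/10 = 0.5 > δ; both probes are reported individually. This is the δ
criterion doing its job: a 100%-support probe should not absorb a
50%-support neighbour into one blurred pattern.

```{r toy-details}
weak_eti_support(toy$matrix, 6, 7, epsilon = 0.2)$support
merge_dissimilarity(singleton_support(toy$matrix, 6, 0.5)$support_set,
                    singleton_support(toy$matrix, 7, 0.5)$support_set)
```

## Numerical and reporting choices

* **Support quota.** `ceiling(sup_min * n)` with a 1e-9 guard so that,
  e.g., `0.3 * 10` never rounds up to 4 through floating-point error. The
  same guard appears in every `≥ 1 − ε` density comparison (cell counts
  are integers; the threshold is not exactly representable).
* **Determinism.** Sample ranking ties break by ascending index;
  candidates are generated in ascending start order; output is sorted by
  (chromosome, start, end, direction) and printed with fixed formatting —
  repeated runs are byte-identical.
* **Consumed parents.** An interval that participates in *any* successful
  merge is not reported, even if its sibling merged elsewhere; unconsumed
  frequent intervals are reported even when they overlap a longer pattern
  that grew from different parents. Reported patterns may therefore
  overlap.
* **Free riders.** Because the weak condition is pooled, a maximizing
  support set can include samples contributing no 1s at all, as long as
  the pooled density stays above 1 − ε (for an interval with N total 1s,
  up to `floor(N / ((1 − ε)|I′|))` samples are feasible). This is inherent
  to the weak-ETI definition, and is the reason singletons are evaluated
  exactly and the strong checker exists. With ε = 0 the reported set is
  exactly the samples carrying the full interval.
* **Degenerate inputs.** Empty matrices mine to empty pattern frames;
  an all-constant intensity matrix makes `select_tau()` warn and return
  the common |value| (achieved density 0); non-finite intensities are
  rejected naming the first offending probe and sample rather than being
  silently imputed, since imputation would corrupt support counts.
* **Open choices.** The contingency test is 2 × K (support vs non-support
  across all K groups, df = K − 1) rather than a collapsed 2 × 2 per
  target group; no continuity correction; no multiplicity adjustment by
  default (a Bonferroni mode exists). Output coordinates are 1-based
  inclusive base pairs; on-disk probe/sample indices are 0-based while
  in-memory R indices are 1-based, and the pattern-file header states the
  convention.

## What the synthetic generator emulates — and what it does not

`generate_binary_cohort()` draws i.i.d. Bernoulli background (default
density 0.02, scattered spurious calls) and overwrites implanted
interval × sample-subset blocks with Bernoulli(`presence_prob`) cells
(default 0.9, i.e. 10% flip-out noise). `generate_intensity_cohort()`
draws N(0, `noise_sd`²) background (default 0.15, a typical LRR noise
scale) and adds ±`shift_mean` (default 0.5, roughly a single-copy change)
with per-cell jitter. Sample subsets are drawn uniformly without
replacement; overlapping implants OR in binary mode and add in continuous
mode. Both generators are pure functions of their seed.

Deliberately not modelled: genomic waves and GC-content artifacts,
probe-density variation, family/trio structure, linkage between nearby
events, and batch effects. Passing recovery tests on these cohorts shows
the search machinery is correct under the stated noise model; it does not
certify performance on real arrays, where binarization quality dominates.

The test suite runs the exhaustive-oracle comparisons at n ≤ 12 samples
and m ≤ 40 probes, recovery sweeps at 200 × 100 over 20 seeds, and the
type-I-error simulation with 1500 null patterns on a 90-sample, 3-group
cohort — sizes at which every property is checked exhaustively or with
tight Monte-Carlo error while the whole suite stays fast.

## Known limitations

* No overall significance is attached to mined patterns (no permutation
  null); the χ² specificity test conditions on the mined support set and
  is a *ranking* device, not a calibrated discovery test, since patterns
  are selected by the same data.
* The δ criterion is greedy and order-free within a round, but a pattern
  family with gradually drifting support can still fragment or
  over-merge near the δ boundary.
* Chromosomes are mined independently; events spanning assembly gaps or
  chromosome ends are necessarily split.
* At ε = 0 the maximal report of a noisy block fragments into overlapping
  exact intervals; total reported length is therefore not comparable
  between ε = 0 and ε > 0 (the frequent-interval *set* is monotone in ε,
  and the suite checks exactly that).
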
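# cnvminer

Error-tolerant subspace pattern mining of recurrent copy-number variation
(CNV) regions in probe × sample SNP-array matrices.

## What it does and for whom

Cohort CNV studies (population genetics on germline variants, tumor
cohorts on somatic aberrations) need the regions of the genome that are
deleted or amplified in the *same subset* of samples. Per-probe summary
statistics with peel-off heuristics (the GISTIC/JISTIC family) can report
"peaks" whose probes are each aberrant in different samples; `cnvminer`
searches instead over (probe-interval, sample-subset) pairs directly, with
explicit noise tolerance, and reports every maximal region together with
the exact samples supporting it. It is aimed at analysts holding
log-R-ratio (LRR) matrices, e.g. from PennCNV-processed arrays or tangent-
normalized SNP6 data.

## The method

Data are binarized per direction: cell (j,k) of the gain matrix is 1 iff
LRR<sub>j,k</sub> > τ (loss: < −τ); gains and losses are mined separately.
On the resulting m × n 0/1 matrix **D** (probes = items, samples =
transactions), an interval of consecutive probes I′ has *weak
error-tolerant support*

> sup(I′) = max { |T′|/n : T′ ⊆ samples,
>   Σ<sub>i∈I′</sub> Σ<sub>t∈T′</sub> D<sub>i,t</sub> ≥ (1 − ε)·|I′|·|T′| }

A level-wise search keeps the probes with exact support ≥ sup\_min, then
repeatedly merges adjacent frequent intervals of equal size — allowed only
when their support sets have Jaccard distance ≤ δ — and accepts the merged
candidate when its weak support reaches sup\_min (its parents being
frequent certifies the recursive-weak condition that every sub-interval is
a weak ETI). Frequent intervals never consumed by a successful merge are
the reported maximal patterns. The maximizing support set is computed
exactly by a greedy ranked-prefix argument; exhaustive brute-force oracles
(`bruteforce_weak_support()`, `mine_bruteforce()`) ship with the package
and the test suite proves the equivalence on hundreds of random instances.

Post-processing: per-pattern group-specificity by Pearson χ² on the
2 × K support/non-support × group table (`specificity_tests()`), genomic
coordinates via a probe track (`pattern_to_region()`), synthetic cohorts
with implanted ground-truth aberrations (`generate_binary_cohort()`,
`generate_intensity_cohort()`) and recovery scoring (`recovery_score()`).

## Worked example

The built-in toy cohort (7 probes × 10 samples) at sup\_min = 0.5,
ε = 0.2, δ = 0.4:

```r
library(cnvminer)
toy <- toy_cohort()
fit <- mine_cnv(toy$matrix, sup_min = 0.5, epsilon = 0.2, delta = 0.4)
fit
#> CNV pattern mining: 7 probes x 10 samples (sup_min=0.5, epsilon=0.2, delta=0.4)
#> 3 maximal pattern(s); sizes 1-4, support 0.50-1.00
as.data.frame(fit)[, 1:7]
#>   chromosome direction start end size support_count support
#> 1       chr1      gain     2   5    4             6     0.6
#> 2       chr1      gain     6   6    1            10     1.0
#> 3       chr1      gain     7   7    1             5     0.5
```

Reading the output: probe 1 (exact support 0.4 < 0.5) is pruned before
any merging. Probes 2–5 share one support set and merge into the size-4
region `[2, 5]`; its support 0.6 exceeds the five carriers because the
pooled ε = 0.2 condition legitimately tolerates one empty sample column.
Probes 6 (support 1.0) and 7 (support 0.5) are *not* merged even though
the candidate `{6,7}` has weak support 0.8: their support sets differ by
Jaccard distance 0.5 > δ, so each is reported individually — the δ
criterion prevents a universally supported probe from absorbing a
half-supported neighbour into one blurred pattern.

The same run from a shell, mirroring the classic 4-argument invocation
(patterns to stdout, log to stderr):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cnvminer.R", package="cnvminer"))')" \
    chr1.txt 0.5 0.2 0.4 > patterns.txt
```

`binarize`, `mine`, `stats` and `simulate` subcommands cover thresholding
intensity files, genome-wide runs, χ² specificity and synthetic cohorts;
see `?cli_main`.

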
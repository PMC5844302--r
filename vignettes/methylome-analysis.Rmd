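---
title: "Methods: WGBS methylome analysis with dmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGBS methylome analysis with dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dmrkit analyses two-group whole-genome bisulfite sequencing (WGBS)
experiments downstream of alignment: its inputs are strand-split
per-position pileups and per-CpG count tables, not reads. This vignette
documents the statistical model of each stage, the tunable parameters and
why their defaults are what they are, what the bundled simulator does and
does not emulate, and the numerical and design choices a maintainer would
want written down.

## Coordinates and containers

All user-facing tables use the BED convention: 0-based, half-open
`[start, end)` intervals in plain data frames. A CpG site is keyed by the
coordinate N of its plus-strand cytosine and spans `[N, N+2)`. Interval
algebra (union, subtraction, overlap counting) is delegated to
GenomicRanges; conversion to its 1-based closed ranges happens in exactly
one pair of internal helpers, so off-by-one risk is confined there.

## M-bias and the trim-range rule

Bisulfite libraries show position-within-read artifacts (M-bias), typically
at read ends. `compute_mbias()` aggregates methylation calls into one
profile per (mate, read-length class) — a *library-level* profile in the
style of Bismark's M-bias output. A per-sequenced-read statistic is not
estimable (each read contributes single Bernoulli calls), so "mid-read mean
and SD" is interpreted at the library-profile level.

`select_trim_range()` takes the mid-read window (positions 30–100 for
PE150, 20–50 for PE75; both configurable in `trim_policy()`), computes the
arithmetic mean and sample SD (n−1) of the per-position levels, and returns
the longest contiguous run of positions such that

1. every position is within 3 SD of the mid-read mean, except
2. isolated outliers — never two adjacent — within 4 SD, and
3. the run starts and ends on positions meeting the 3 SD criterion.

Numerical choices: a constant window has SD 0, which would make the
acceptance band degenerate, so the SD is floored at `sd_floor = 0.002`
(about a third of the binomial noise at 5000 calls/position and typical
levels, i.e. small enough never to mask a real artifact). Zero-depth
positions satisfy no criterion and terminate runs. When several runs tie on
length, the run containing the mid-read window midpoint wins, then the
earlier run — ties are otherwise genuinely ambiguous and this makes the
result deterministic. The implementation is a linear scan; the test suite
checks it against a literal enumerate-all-runs oracle on 400 randomized
profiles (the scan's greedy restart is safe because the
isolated-outlier state resets at every inner position, so runs starting
inside a maximal run end where it ends).

## Genomic-context validation

In a mixed genetic background, a reference CpG may be destroyed by a
polymorphism in the sample; calling methylation there would be meaningless.
A site passes validation only if, in the pileup summed over **all**
samples, four inclusive criteria hold: G fraction ≥ `min_frac` (0.95) among
mapped bases at N+1 on the plus strand and at N on the minus strand, and
G depth ≥ `min_g_depth` (5) at both coordinates. The denominator is all
mapped bases at the coordinate, so ambiguous calls count against the
fraction. Coordinates with no coverage fail on depth rather than raising an
error. The same pass/fail set then applies to every sample, which is what
"in CpG context in all samples" requires; sites absent from the reference
CpG list are never validated (no de-novo CpG discovery).

## Methylation calling and conversion QC

Strand evidence is pooled into one record per CpG before filtering, because
CpG methylation is strand-symmetric and downstream comparisons use one
value per site. Replicates are merged by summing counts — equivalent to
merging alignments — so the group-level ratio is the depth-weighted mean of
replicate ratios. The depth filter (`min_depth = 10`) is inclusive.
Distribution summaries use strict outer inequalities (methylated
mCG/CG > 0.75, unmethylated < 0.25); a ratio exactly at a boundary is
intermediate.

Conversion is estimated from controls known to be unmethylated (the phage λ
spike-in; a mitochondrial surrogate can be supplied as a second source):
every methylated call there is a conversion failure, so
`conversion_rate = 1 − meth calls / total calls`, reported per source and
pooled.

## The credible methylation difference

Established DMR callers summarize a two-group count comparison by a
difference statistic that discounts sampling noise. dmrkit's site statistic
is deliberately simple and fully specified: each group's methylation
proportion gets a Jeffreys-prior posterior `Beta(meth + ½, total − meth + ½)`;
let (L, U) be the equal-tailed 95 % credibility interval of `p₂ − p₁`. The
credible difference is L if L > 0, U if U < 0, and 0 otherwise — the
interval edge nearest zero, a conservative lower bound on the magnitude of
the true difference that is zero exactly when the interval straddles zero.
This is a documented stand-in for the credible-difference concept of
model-based bisulfite comparison tools, not a re-implementation of any of
them; agreement with such tools on real data is not claimed.

Numerics: with `u ~ U(0,1)`, `P(p₂ − p₁ ≤ d) = E[F₂(Q₁(u) + d)]` where Q₁
is the group-1 posterior quantile function; the integrand is smooth and
bounded in u, so a 64-node midpoint rule is accurate (observed error
< 0.004 against 10⁶-draw Monte-Carlo sampling, including
boundary-concentrated posteriors like 30/30 vs 0/30), and quantiles of the
difference follow by monotone bisection (22 steps). Because the statistic
is nonzero only when the interval excludes zero, sites are first screened
with a single CDF evaluation at d = 0, and only the passing minority needs
the one relevant quantile; this makes genome-scale tables cheap. A seeded
Monte-Carlo fallback (`method = "mc"`) is available for cross-checks.

Regions: consecutive significant sites of identical sign are chained while
the inter-CpG gap is ≤ `max_gap_bp` (300 bp, a typical inter-CpG chaining
distance in DMR callers); chains need ≥ `min_cpgs = 3` members; region
levels are count-pooled, and only regions with pooled |nominal difference|
≥ `min_nominal_dif = 0.2` are reported. Non-significant sites between
significant neighbours do not break chains (they carry no evidence either
way) and do not contribute to region levels. Direction is *hypo* when group
2 is lower.

## Annotation geometry

With t the 0-based TSS coordinate: plus-strand promoters are
`[t−1000, t+500)`, minus-strand promoters the mirror `[t−499, t+1001)`;
3′-end windows are `[tes−1000, tes+1001)` on either strand; gene bodies run
TSS→TES; introns are body minus exons. CpG shores are the 2 kb flanks of
islands minus island bases; shelves the next 2 kb minus shores and islands
— the three classes partition, and a property test verifies no base is ever
in two of them. Overlap flags are non-exclusive (a region spanning an
exon/intron junction sets both; promoter/3′-end windows may double-count
exonic bases), and *intergenic* means no overlap with promoter, exon,
intron or 3′ end. Each gene model contributes one TSS/TES; supply multiple
transcripts as separate models if needed.

TSS distance is edge-to-point in the `closest`-utility convention (an
adjacent feature is at distance 1), signed positive when the region lies
downstream in the TSS's strand orientation, with the nearest TSS chosen by
absolute distance (ties toward downstream, then lower coordinate). Bin
edges default to 5 kb / 50 kb / 500 kb and are configurable.

## Shuffled nulls and the enrichment test

Null regions are length-matched: each query is relocated to a start drawn
uniformly over all placements of its exact length that fit in unmasked
space, with placed regions added to the mask when `no_overlap` is set
(default). This is the same conditional distribution a rejection sampler
over the genome has, computed exactly — important because masks can leave
windows that exactly fit a region, where rejection sampling would almost
never terminate. Placement is deterministic given the seed (default 1000).
Sequential placement is greedy; in pathologically tight genomes an
arrangement might exist that greedy placement misses, in which case the
error names the failing region.

Overlap is counted region-wise (a region either overlaps a feature or not),
and each (direction, category) cell is tested with the pooled two-proportion
Z-test, z defined as 0 when the pooled proportion is degenerate. Raw
p-values are reported (starred at 0.05 and 0.001) with no multiple-testing
correction, matching the reporting convention of the analyses this
reproduces. The null set size equals the query set size and one shuffle is
performed per direction; expression uses the inclusive mean-FPKM ≥ 1 rule
over replicates.

## What the simulator emulates — and what it does not

`sim_config()` defaults are the study conditions: two 1-Mb chromosomes at
CpG density 0.02/bp (with 8× density inside promoter CpG islands), a
48.5-kb λ spike-in, a 0.82/0.07/0.11 high/low/intermediate mixture,
Poisson(30) per-strand read depth, three replicates per group, 0.16 %
conversion failure, 0.5 % base miscalls on opposite-strand G evidence, 5 %
CpG-destroying polymorphisms, and 20 hypo- + 10 hyper-methylation effects
of exact size Δ = 0.4 spanning 10 consecutive CpGs, hypomethylation placed
inside expressed gene bodies with probability 0.8. Mixture components are
supported strictly inside their class intervals with densities vanishing at
the 0.25/0.75 boundaries, so class fractions are recoverable despite
sampling noise. Read-end bias is injected only into the read-position call
table, because the pipeline consumes post-trimming pileups and the trim
report is advisory.

Two generator choices deserve emphasis. First, baseline levels inside
planted regions are redrawn uniformly from the sub-interval of [0, 1] that
accommodates the full Δ (hypo: WT ∈ [Δ, 1]; hyper: WT ∈ [0, 1−Δ]), so the
planted difference is exact at every member CpG; without this, clipping at
the unit interval would silently shrink effects below the detection
threshold wherever the baseline lacks headroom (set
`dmr_redraw_wt = FALSE` to get clipping instead). Second, polymorphisms
replace the G of the dinucleotide, so the plus-strand N+1 evidence
collapses while the minus-strand N evidence stays intact — one failed
criterion suffices for exclusion, mirroring the asymmetric signature of a
real SNP on one strand's context.

The simulator does **not** emulate: reads (no FASTQ/BAM, no fragment-level
correlation between neighbouring CpGs' depths), non-CpG methylation,
indels, copy-number or mappability structure, spatial autocorrelation of
methylation levels outside planted regions, or biological replicate
heterogeneity (replicates are i.i.d. redraws). Passing tests therefore
demonstrate correctness of the algorithms under clean sampling assumptions,
not robustness to every artifact of real libraries.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to keep properties
statistically sharp while running comfortably on a laptop: oracle
equivalence for context validation on a 2 × 1 Mb genome (≈ 45,000 CpGs,
combined depth ≈ 360×), distribution recovery on a 5-Mb genome
(≈ 100,000 CpGs), conversion recovery on ≥ 50,000 spike-in calls with a
100-seed unbiasedness check, DMR recovery at the default 30-region
configuration, 400 randomized trim profiles against the all-runs oracle,
a 1000-draw type-I-error check of the Z-test, and 50 null re-shuffles for
the no-enrichment direction.

## Known limitations

- The credible-difference stand-in shares the *concept* of model-based
  bisulfite comparison tools but none of their implementation details
  (no local smoothing, no variance moderation across sites, no
  region-level posterior); region boundaries come from greedy chaining.
- Validation consumes a combined pileup and cannot distinguish a
  polymorphism fixed in one group from low-level contamination.
- Greedy, order-dependent null placement; with `no_overlap` and very
  dense query sets relative to unmasked space, placement may fail where
  backtracking would succeed.
- One TSS per gene model; isoform-aware annotation requires exploding
  transcripts into separate models.
- The generator draws per-CpG levels independently, so it cannot be used
  to study methods that exploit spatial correlation of methylation.
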
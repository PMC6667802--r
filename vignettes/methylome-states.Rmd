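---
title: "Methylome states, region calling and promoter classification"
author: "methylStates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylome states, region calling and promoter classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylStates)
```

## The analysis in one paragraph

WGBS yields, per CpG site, counts of reads supporting methylation out of a
total. `methylStates` turns the ordered sequence of per-CpG methylation
fractions into *methylome states* at three granularities — change-point
segments with ordered classes, discrete UMR/LMR calls with permutation FDR
calibration, and optional HMM-decoded partially methylated domains — and
then classifies gene promoters against those states. The headline output
is a per-gene hypermethylation verdict and its aggregates: gene-set
percentages, heatmap matrices, and TSS-proximal CpG profiles.

## Data model and conventions

A `Methylome` wraps a sorted width-1 `GRanges` of CpG cytosines (forward
strand, strand-merged) with integer `countMeth`/`countTotal` columns. All
internal coordinates follow the Bioconductor convention (1-based, closed);
BED and bedGraph output is 0-based half-open, and Bismark inputs are
1-based, with conversions confined to the I/O layer. Symmetric CpG counts
from the two strands are summed onto the forward C at ingest — standard
WGBS practice, since CpG methylation is symmetric. Only CpG-context rows
are used; CHH/CHG rows are parsed and discarded. Sites under `minCov`
(default 5 reads) are excluded: at the ~17–22x coverages this pipeline is
designed around, that removes the long lower tail of unreliable fraction
estimates while keeping most sites.

## Change-point segmentation

Each chromosome's fraction sequence is split by greedy binary
segmentation: the candidate split maximizes the decrease in within-segment
sum of squared errors (computable in O(1) per candidate from prefix sums),
and is accepted when the decrease exceeds `cpPenalty * log(n)` with `n`
the chromosome's CpG count — a BIC-style rule. Both children must keep at
least `minCpgPerSegment` (10) CpGs; argmax ties break to the smallest
index, so results are deterministic.

`cpPenalty` defaults to 0.1. The noise floor motivating it: with Beta
concentration ~20 around a mean of 0.85 plus binomial sampling at ~20x,
the per-CpG fraction variance is ~0.013, so spurious SSE gains from noise
scale like `0.013 * 2 log n` (≈ 0.3 for n = 10^5), while a genuine
10-CpG region differing by 0.5 in mean yields a gain near 1.7 and typical
island-versus-background contrasts yield far more. The threshold
`0.1 log n` (≈ 1.15 at n = 10^5) sits between the two. Because greedy
splits are nested, lowering the penalty can only refine the segmentation —
a property the tests assert.

Segment means are then clustered into `kClasses = 4` groups by exact
dynamic-programming one-dimensional k-means — the global optimum of the
within-group sum of squares, verified in tests against exhaustive
enumeration of all ordered cut placements. Classes are labeled 1..4 in
ascending order of group center, so "class 3 or 4" always denotes the
high-methylation states regardless of how the methylome's density is
shaped. Four classes are the package default because the promoter rule
consumes exactly the 3-vs-4 distinction; `kClasses` is configurable, and
when fewer segments than classes exist, k is reduced with a warning.

## UMR/LMR calling and FDR calibration

Candidate regions are maximal runs of consecutive CpGs whose smoothed
fraction (centered 3-CpG running mean, shrinking at the edges) is below a
cutoff `m`, retained when the run has at least `n` CpGs. Rather than fix
`(m, n)`, the caller calibrates them: for each pair on a grid
(`m` in {0.3, …, 0.7}, `n` in {2, …, 20}) the observed region count is
compared with the mean count over `nPerm = 10` methylomes in which
fractions are shuffled across positions within each chromosome. Shuffling
preserves the marginal fraction distribution and the CpG spacing while
destroying spatial structure, so randomized calls estimate the false
discovery count; the FDR estimate is randomized/observed (0/0 taken as 0,
capped at 1). Among pairs with FDR at most `fdrTarget` (0.05), the pair
maximizing the observed count wins; ties resolve to smaller `m`, then
smaller `n`. When no pair qualifies — e.g. on noise, or when low-methylated
CpGs are so abundant that shuffled methylomes produce long low runs — the
caller stops with an instructive error rather than emit uncalibrated
calls.

Called regions with at least `umrLmrCpgThreshold = 30` CpGs are UMRs
(CpG-island-like), smaller ones LMRs (CpG-poor, enhancer-like). The region
span is first-to-last member CpG with no midpoint extension — the simplest
defensible convention; since the >500 bp size rule later keys off this
span, both the convention and the threshold are configurable. No size
filter is applied at calling time: the 500 bp rule belongs to promoter
classification, and is applied there to UMRs and LMRs alike (reading the
"larger than 500 bp" qualifier as attaching to both region types).

## The PMD HMM

Partially methylated domains — long stretches of disordered intermediate
methylation — are modeled with a two-state HMM over per-CpG fractions:
state 1 is the concentrated high-methylation background (Beta mean 0.85,
concentration 20), state 2 the diffuse PMD emission (mean 0.5,
concentration 4). Per-CpG Beta emissions keep the module exactly
decodable and testable; fractions are clipped to [1e-3, 1 − 1e-3] before
density evaluation. Viterbi decoding runs in log space with ties broken
toward the background state; tests verify it against exhaustive 2^n path
enumeration. Runs of the PMD state shorter than `pmdMinLenBp` (10 kb) are
discarded, which also keeps kilobase-scale UMRs — whose near-zero
fractions the diffuse PMD emission likes better than the background
does — from surfacing as spurious domains.

Baum–Welch fits the parameters by EM with log-space forward–backward.
Initial and transition probabilities use their closed-form M-step. For the
Beta emissions, the method-of-moments solution from the
posterior-weighted data seeds a numerical maximization of the weighted
Beta likelihood (a function of three sufficient statistics), bounded so
the concentration cannot exceed 1e4 (degenerate all-identical input hits
the cap with a warning); a candidate is accepted only when it does not
lower the EM objective. This keeps every iteration's log-likelihood
non-decreasing — asserted numerically to 1e-8 in the tests — which a raw
method-of-moments update cannot guarantee.

PMD calling is off by default in the pipeline: the mouse-retina-like
simulations the defaults target contain no planted PMDs, and the stage is
enabled per config when domains are expected.

## Promoter classification

Promoter windows default to 1000 bp upstream and 200 bp downstream of each
distinct TSS (strand-aware, clamped to chromosome bounds) — a standard
promoter definition with a small downstream margin to capture TSS-proximal
CpGs. Genes with several transcripts contribute one promoter per distinct
TSS.

The hypermethylation rule has two clauses:

* the promoter is *located in* a class-3 or class-4 segment, and
* no UMR or LMR larger than `regionSizeFilterBp = 500` bp is *present in*
  the promoter area.

"Located in" is operationalized as majority overlap: the segment covering
more than 50% of the promoter's length (an exact tie assigns nothing);
`overlapRule` can switch to any-overlap or full containment since other
readings are defensible. "Present in", by contrast, is an existence claim,
so any positive overlap by a large-enough region blocks the call. The rule
is enumerable — 4 classes by 5 region configurations — and the test suite
checks all 20 combinations, plus the monotonicity that adding a blocking
region can never turn a promoter hypermethylated.

Per gene, among promoters whose assigned segment or overlapping UMR/LMR
spans more than 500 bp (and that cover at least one CpG), the one with the
lowest mean percent methylation — an unweighted mean over covered CpGs,
times 100 — is the representative, with ties going to the 5'-most TSS. A
gene is hypermethylated only when *all* its promoters are. This all-
promoters reading is the conservative companion to picking the
lowest-methylation representative: a single open promoter suffices for
expression, so a gene with any non-hypermethylated promoter should not
count as silenced by methylation. (Any-promoter and
representative-promoter readings are possible alternatives; the promoter
table retains everything needed to recompute them.)

Gene-set percentages divide by the set genes present in the annotation,
warning about absentees. Heatmap matrices hold representative percent
methylation per gene and sample with NA where no promoter qualifies, and
`cpgProfile()` reports signed strand-oriented offsets from the TSS over
the union of promoter and first exon, counting CpGs in the overlap once.

## The synthetic methylome generator

`simDesign()` describes what the generator emulates: clustered CpG
positions (geometric spacings, mean 100 bp in background, 10 bp inside
island slots), a high-methylation FMR background (Beta mean 0.85,
concentration 20), planted UMR (mean 0.05) and LMR (mean 0.30) regions,
optional diffuse PMDs (mean 0.5, concentration 4), Poisson coverage with
mean 20 (inside the 17–22x band the pipeline targets), and mild
beta-binomial overdispersion rho = 0.05 (set 0 for exact binomial).
Region-length defaults mirror published mammalian methylome scales —
UMRs 1–5 kb, LMRs 0.3–1 kb, PMDs 50–200 kb; gene slots are 2–5 kb so that
every promoter window of a 1–3-transcript gene fits inside its plantable
slot. The default two-condition experiment places 12 photoreceptor-set and
40 non-photoreceptor genes on a 2 Mb chromosome: photoreceptor promoter
slots are fully methylated in the progenitor-like condition and
unmethylated in the photoreceptor-like condition; all other promoters are
unmethylated in both.

What the simulation does *not* emulate: sequence-driven CpG density (no
real genome), bisulfite conversion failure, SNP artifacts, read-level
errors, replicate-to-replicate biological variance beyond the
beta-binomial, and chromosome-scale covariates (replication timing,
compartments) that shape real PMDs. Passing the end-to-end tests therefore
demonstrates that the algorithms recover the states they define under
realistic coverage and noise — not that any particular biological dataset
would yield a particular percentage.

All randomness flows from one integer seed; per-stage sub-seeds are
derived by a stable hash of (seed, stage name) so stages are reproducible
independently.

## Numerical choices and degenerate inputs

* Change-point argmax ties take the smallest index; k-means clustering is
  the exact DP optimum; Viterbi ties prefer the background state — every
  decision path is deterministic.
* Empty CpG sequences, empty gene-set files, zero permutations, genes
  without promoters, and promoters on chromosomes without segments raise
  errors; zero-coverage sites and sub-`minCov` sites are dropped at
  ingest; promoters without covered CpGs get NA means and never qualify
  as representatives.
* The FDR grid's 0/0 cells count as FDR 0 but are excluded from selection
  (observed must be positive).
* Fractions are clipped only inside the HMM (Beta densities); everywhere
  else exact 0 and 1 are legal values.

## Problem sizes used in the checks

The packaged validation runs at sizes chosen to make every oracle
exhaustive yet quick: rule enumeration over all 20 class-by-region
configurations; breakpoint recovery over every admissible split of a
40-CpG two-level sequence; clustering against brute-force enumeration for
up to 50 segments; Viterbi against 2^n enumeration for n ≤ 10; UMR
recovery on one simulated 10 Mb chromosome with 50 planted UMRs
(~115,000 CpGs); the two-condition experiment on 2 Mb with 52 genes; EM
diagnostics on 5,000 simulated CpGs with 20 random restarts.

## Known limitations

* Calibration can legitimately fail on methylomes where low-methylated
  CpGs dominate (the shuffled null then contains long low runs); the
  remedy is a larger `nGrid`, stricter `mGrid`, or accepting that the
  UMR/LMR model does not fit such a sample.
* The 2-state HMM will absorb kilobase UMRs into the PMD state when the
  length filter is disabled; a 3-state emission model is out of scope.
* Joint multi-sample segmentation and differential methylation testing
  are out of scope; samples are processed independently and compared at
  the aggregate level.
* The segment interval convention (first-to-last CpG) leaves genomic gaps
  between adjacent segments in sparse territory; majority overlap against
  promoters is robust to this, but full-containment assignment in very
  sparse regions may assign nothing.
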
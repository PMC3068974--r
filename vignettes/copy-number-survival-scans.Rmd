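---
title: "Genome-wide survival scans on copy-number profiles: models and methods"
author: "survscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide survival scans on copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscan)
```

# The problem

Tumor genomes carry recurrent copy-number alterations — deletions and
gains of chromosomal segments — and in several cancers specific
alterations predict patient survival (in multiple myeloma, for example,
del(13) confers poor prognosis while hyperdiploidy confers good
prognosis). Given a SNP-array copy-number matrix (markers ordered by
chromosome and position, one column per patient) and censored survival
outcomes, `survscan` answers: *which genomic regions' copy number is
associated with survival, after accounting for the thousands of markers
tested?*

The workflow is the classic one from the interactive microarray-analysis
era, made scriptable:

1. **Smooth** each sample's profile with a local median over 10
   consecutive markers.
2. Optionally **rescale** each sample so its modal copy level is 2
   (ploidy correction).
3. **Score** one of every 10 markers, either by the k-group log-rank
   test on Deletion / No-change / Gain groups, or by the Wald z of a Cox
   proportional-hazards fit on the continuous copy number.
4. **Permute** — clinical (time, event) pairs across samples, or
   contiguous genome blocks within each sample — and take the MaxT
   distribution of the per-permutation maximal score as the genome-wide
   reference.
5. **Report** maximal runs of supra-threshold markers as candidate
   regions, and draw Kaplan-Meier comparisons at individual markers or
   between expression-derived sample clusters.

# Statistical components

## Kaplan-Meier and the log-rank test

The product-limit estimator multiplies survival by $(1 - d_t/n_t)$ at
each distinct event time $t$ with $d_t$ events among $n_t$ at risk.
Censored-only times reduce the risk set without changing survival. For
$g$ groups the log-rank test accumulates, over pooled event times, the
observed events $O_k$ per group against their hypergeometric
expectations $E_k$ and covariance $V$; the statistic is
$(O-E)^\top V^{-}(O-E)$ on any $g-1$ groups, with a generalized inverse
when $V$ is singular, on $g-1$ degrees of freedom (nonempty groups
only). Per-group expected events are reported next to observed events in
every K-M legend, and over groups $\sum_k O_k = \sum_k E_k$ exactly —
both equal the total event count — which the tests assert on arbitrary
datasets.

A p-value is *quoted* only when at least two groups have at least
`minExpected = 5` expected events. The chi-square reference distribution
is an asymptotic approximation; with a near-singleton group the
upper-tail p-value can be anti-conservative by many orders of magnitude.
The statistic is still computed and stored for ineligible markers, but
genome-wide inference (MaxT maxima, the observed maximum, region
calling) is restricted to eligible markers, with eligibility recomputed
inside every permutation from that permutation's expected events. Because
the same rule is applied to the observed and every permuted dataset, the
scores remain exchangeable under the null and the family-wise error
calibration is preserved (verified by simulation in the test suite).

## Cox regression

At each tested marker the smoothed copy number enters a Cox
proportional-hazards model $\lambda(t \mid x) = \lambda_0(t) e^{\beta
x}$, optionally with clinical adjustment covariates. The partial
likelihood is maximized by Newton-Raphson from $\beta = 0$ with step
halving, convergence declared when the log-likelihood changes by less
than $10^{-8}$, and a cap of 50 iterations. Ties are handled by the
Breslow approximation by default (Efron available); both variants are
verified against an independent reference implementation to relative
error below $10^{-6}$ on random small datasets. The marker score is the
signed Wald $z = \hat\beta/\mathrm{SE}$: negative z means less hazard —
longer survival — as copy number increases. Monotone likelihoods
(perfect separation) are detected by coefficient drift and flagged
`converged = FALSE`; such markers carry a missing score rather than a
spurious one.

## MaxT permutation

The null hypothesis is that *no region's copy number is associated with
survival*. Two permutation schemes simulate it:

* **clinical** — one random permutation applied jointly to the
  (time, event) pairs across samples; the copy-number matrix is
  untouched.
* **blocks** — for each sample independently, the genome-ordered profile
  is cut at $K-1$ breakpoints drawn uniformly without replacement from
  the $L-1$ internal boundaries and the $K$ blocks are rearranged by a
  uniform random permutation. This relocates alterations while
  preserving the local correlation of neighboring markers. Blocks may
  span chromosome boundaries: the partition is of the whole genome in
  chromosome-then-position order.

Each permutation reruns the identical scan; the maximal score per
permutation (over eligible markers) forms the null distribution, and the
$\lceil \alpha \cdot B \rceil$-th largest of the $B$ maxima is the
genome-wide threshold at level $\alpha$ (the 5th largest of 100 at
$\alpha = 0.05$). The empirical genome-wide p-value for the observed
maximum uses the add-one convention $(1 + \#\{m_b \ge m_{obs}\})/(B+1)$,
so it can never be exactly zero.

Two block-permutation details worth recording. First, the profiles
permuted are the *smoothed* ones: smoothing commutes with the analysis
order here because block permutation is applied to whatever matrix the
scan consumes, and permuting the smoothed matrix preserves the tested
statistic's input distribution at a fraction of the cost of re-smoothing
per permutation. Second, a cut adjacency can be *rejoined* by chance
when the random block order places block $i$ directly before block
$i+1$ (probability $1/K$ per junction), so the expected number of
preserved adjacent pairs is $L - K + (K-1)/K$, slightly above the naive
$L - K$; the tests assert the exact per-draw bound (at most $K-1$
adjacencies broken) and the mean within $[L-K,\, L-K+1]$.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window` | 10 markers | local median smoothing span; windows are centered (4 left, 5 right at 10), truncated at chromosome ends, never spanning chromosomes |
| `delThresh` / `gainThresh` | 1.5 / 2.5 copies | inclusive group boundaries: ≤ 1.5 Deletion, ≥ 2.5 Gain, strictly between No-change |
| `stride` | 10 | test one of every 10 markers, restarting at each chromosome's first marker; smoothing makes neighboring statistics redundant |
| `minExpected` | 5 events | per-group expected-events gate for quoting / genome-wide use of log-rank p-values |
| `nPerm` | 100 | permutations; must be ≥ 1/α for a defined threshold |
| `K` | 10 | genome blocks in the blocks scheme |
| `alpha` | 0.05 | family-wise level |

Ploidy rescaling (`scaleModeToTwo()`) estimates each sample's modal copy
level as the center of the highest-count bin of a histogram with bin
width 0.1 copy and bin *centers* at 0.0, 0.1, ..., 8.0, then multiplies
the profile by 2/mode. Centers (rather than edges) at multiples of 0.1
make integer-valued profiles map exactly (a constant-3 profile becomes
exactly 2); ties break toward the lower level, and a modal level ≤ 0.2
is rejected as degenerate. When rescaling is used it is applied to the
raw profiles *before* smoothing — the mode is a property of the raw
measurement scale, and smoothing first would only narrow the histogram
without moving its mode.

# The synthetic-data generator

All tests and the acceptance analysis run on generated data, so the
generator is first-class, tested code. Its model: true copy 2
everywhere; each planted region assigns a random carrier subset copy 1
(deletion) or 3 (gain); observed copies add Gaussian noise with sd 0.35
on the copy scale, truncated at 0. Survival is exponential with rate
$\lambda_0 \exp(\sum_r \beta_r \cdot \text{carrier}_r)$ and independent
uniform$(0, C)$ censoring. The exponential baseline is chosen for
closed-form checkability: with $\lambda_0 = \log 2 / 36$ the baseline
median survival is 36 time units (months), a carrier of a HR-3 deletion
has median $36/3 = 12$, and the censoring fraction
$(1 - e^{-\lambda C})/(\lambda C)$ is analytic — all asserted in tests.

The **demo conditions** are 200 samples, 2,000 markers over 4
chromosomes, one 50-marker deletion on chromosome 1 (markers 201–250)
carried by 40% of samples with hazard ratio 3. The **null conditions**
(100 samples, 500 markers) plant four alteration regions — two
deletions, two gains, 40% carriers — whose log hazard ratio is exactly
0. The null of interest is *no association*, not *no alterations*: a
genome without alterations would put every sample in the No-change group
at every marker and leave the grouping-based scan undefined, which is a
property of an unrealistically clean genome, not of the method.

What the generator does *not* emulate: linkage-disequilibrium structure
among markers, allele-specific intensities, wavy baselines and batch
effects, subclonal (fractional) copy states, and non-exponential
hazards. Passing tests therefore demonstrate correctness of the
statistics and calibration of the permutation procedure under idealized
noise, not robustness to array artifacts.

Expression data for the clustering workflow are log-normal (log2 scale,
mean 7, sd 0.5) with a configurable number of informative genes shifted
between groups and an optional per-group hazard effect.

# Numerical choices and degenerate inputs

* Log-rank variance solves use an exact solve with a pseudo-inverse
  fallback for singular covariance; a negative statistic from rounding
  is clamped to 0.
* Markers where all samples fall in one group, or where the Cox
  covariate has zero variance, carry missing scores — never zero, which
  would understate evidence elsewhere on the track.
* Samples with missing survival (or a missing value of the tested
  marker / an adjustment covariate) are excluded per test,
  complete-case, with the omitted count carried on every result object.
* A sample with time but no event indicator (or vice versa) is treated
  as missing both.
* Clustering uses 1 − Pearson correlation over row-standardized genes
  with average linkage (complete and centroid available); `hclust`'s
  deterministic agglomeration order resolves ties, so gene order never
  affects the tree. The exact linkage and distance of the original
  interactive tool are not documented; this choice is fixed here and
  configurable.
* The variation filter keeps rows with sd/mean in [0.5, 1000]; all-zero
  rows have an undefined ratio and are always dropped.

# Problem sizes in the test suite

The calibration test uses 200 replicate null datasets (100 samples, 500
markers, stride 10) with 200 clinical permutations each; the
power/localization test uses 50 replicates of the demo conditions with
100 permutations per scan, for both scoring methods. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands
(e.g. ±0.015 on a 0.05 rejection rate) while keeping the default test
run in the minutes range.

# Known limitations

* Scores are per-marker; no multi-marker region statistic is computed —
  regions come from thresholded runs of marker scores.
* The Cox scan assumes proportional hazards and uses the continuous
  smoothed copy number linearly.
* Block permutation relocates blocks independently per sample, which
  breaks sample-to-sample co-location of alterations under the null —
  intended, but it means recurrent-alteration structure is not preserved.
* No segmentation (CBS/HMM), LOH inference, or allele-specific copy
  number; inputs are assumed to be already-normalized copy estimates.

# A worked run

```{r demo, eval = FALSE}
sim <- simulateDataset(demoSpec(), seed = 1)
sm  <- smoothCopyNumber(sim$cn, 10)
lr  <- scanLogrank(sm, sim$surv, stride = 10)
nul <- maxtThreshold(lr, sm, sim$surv, scheme = "clinical",
                     nPerm = 100, alpha = 0.05, seed = 2)
significantRegions(lr, nul)
```

The demo run recovers a single region on chromosome 1 overlapping
markers 201–250 with an empirical genome-wide p of 1/101 — the add-one
floor, since the observed maximum exceeds every permutation maximum.
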
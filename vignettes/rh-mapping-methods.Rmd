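---
title: "Radiation hybrid mapping with rhmap: models, parameters and design choices"
author: "rhmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiation hybrid mapping with rhmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhmap)
```

## Background

Radiation hybrid (RH) mapping orders markers by physical proximity without
meiotic recombination. Irradiated donor chromosomes shatter into fragments;
a recipient cell line rescues a random subset of those fragments; each
resulting hybrid line either carries or lacks every donor marker. Two
markers that are physically close usually sit on the same fragment and are
therefore retained or lost together, while distant markers segregate nearly
independently. In plants with very large genomes, panels of this kind are
built in vitro by asymmetric somatic hybridization: donor protoplasts are
irradiated (UV or gamma) and fused with recipient protoplasts, and the
regenerated hybrid cell clones are genotyped with SSR or EST markers. Such
panels show donor marker retention around 15–34%, one to a few retained
fragments per hybrid, a small percentage of undetermined genotype calls,
and a dose-dependent decline in donor retention — the regime the defaults
of this package emulate.

`rhmap` covers the full analysis chain: panel containers and I/O
(`RHPanel`, `readPanel`, `exportCarthagene`), a generative simulator
(`simConfig`, `simulatePanel`), two-point estimation and grouping
(`estimateTwoPoint`, `allPairs`, `buildLinkageGroups`), ordering and
multipoint mapping (`orderExact`, `orderHeuristic`, `fitMap`,
`buildComprehensiveMap`) and panel statistics (`retentionReport`,
`friedmanHomogeneity`, `resolutionReport`, `frequencyTable`,
`orderConcordance`).

## The generative model

For each chromosome of length $L$ bp, break positions are a homogeneous
Poisson process with rate $\lambda$ per Mb (a dose surrogate), partitioning
$[0, L)$ into fragments. Each fragment is retained independently with
probability $\rho$; a marker is retained iff its fragment is, so markers on
one fragment are perfectly correlated. Each call is finally replaced by a
missing (undetermined) score independently with probability $m$. Under this
model the marginal retention of every marker is $\rho$ regardless of
$\lambda$, and the discordance probability of two markers at genomic
distance $d$ Mb is

$$\Pr(\text{discordant}) = 2\rho(1-\rho)\left(1 - e^{-\lambda d}\right),$$

which the test suite verifies by Monte-Carlo against the simulator.

**Defaults.** The default `simConfig()` is calibrated once to the published
scale of in vitro wheat RH panels: one 781 Mb chromosome ("5A") carrying 68
uniformly spaced markers, 184 hybrids, $\rho = 0.34$, $m = 0.01$ (about 116
undetermined calls in a 68×184 panel), and $\lambda = 0.027$ breaks/Mb.
The break rate follows from the reported comprehensive map scale: a
~2100 cR map over 67 intervals is ~31 cR per interval, i.e.
$\theta \approx 0.27$ across the ~11.5 Mb marker spacing, and
$\lambda = -\ln(1-\theta)/d \approx 0.027$. With these defaults a simulated
panel reproduces ~34% retention, ~1500–2000 obligate breaks at 184 hybrids
and a ~2100 cR fitted map without further tuning.

**What the simulator does not model.** Breakage hotspots (the process is
homogeneous), fragment-size-dependent retention (retention is per fragment,
independent of its length), clone viability or differentiation selection,
translocation of donor fragments into recipient chromosomes, and
structured missingness (missing calls are independent per call, not per
hybrid or per gel). Passing tests therefore show that the estimators invert
this idealized generative process at realistic sizes; they do not show
robustness to hotspot breakage or assay artefacts in real panels.

## Two-point estimation

For a marker pair, hybrids with both calls determined contribute to the
2×2 table $(n_{11}, n_{10}, n_{01}, n_{00})$ (pairwise-complete handling of
missing data — standard RH practice). The haploid equal-retention model with
breakage fraction $\theta$ and retention probability $r$ has cell
probabilities

$$P_{11} = r(1-\theta(1-r)),\quad P_{10}=P_{01}=r\theta(1-r),\quad
P_{00}=(1-r)(1-\theta r),$$

with closed-form MLEs $\hat r = (2n_{11}+n_{10}+n_{01})/(2n)$ and
$\hat\theta = (n_{10}+n_{01})/(2n\hat r(1-\hat r))$, clipped to $[0,1]$.
The test suite checks the closed forms against a brute-force grid
maximization of the joint likelihood on a $10^{-3}$ grid. The LOD score is
the base-10 likelihood ratio against independence ($\theta = 1$) at the
same $\hat r$, floored at 0; the centiRay distance is
$-100\ln(1-\hat\theta)$.

Design choices made here, where practice varies:

* $r$ is estimated **per pair**, not globally: marker retention in real
  panels varies several-fold (reported ranges 5.8–27.7% within one panel),
  so a global $r$ is untenable, while the pairwise model keeps the closed
  forms.
* A pair with $\hat r \in \{0, 1\}$ (monomorphic) is flagged
  non-informative: $\hat\theta$ is undefined and LOD is 0.
* $\hat\theta = 1$ yields an infinite cR distance in R; writers of tabular
  output should treat it as an "unlinked" sentinel.
* Linkage thresholds are **inclusive**: LOD exactly at the threshold and
  distance exactly at 100 cR both count as linked. Grouping is
  single-linkage (connected components), so it is invariant to marker input
  order.

## Ordering and the obligate-break criterion

The obligate chromosome break (OCB) count of an order is, per hybrid, the
number of retained/absent transitions along the order after dropping
missing calls, summed over hybrids — the minimum number of breaks the data
force. With no missing data, OCB equals the sum of adjacent pairwise
discordances; with missing data OCB is **at least** that sum, because every
discordant adjacent pair is also a transition of the non-missing
subsequence while transitions spanning missing-call gaps are counted only
by the subsequence.

True OCB is not decomposable over adjacent pairs once calls are missing, so
the ordering criterion is the decomposable pairwise-discordance surrogate:
exact open-path minimization by Held–Karp dynamic programming up to 12
markers (the state space doubles per marker), and greedy nearest-neighbour
construction plus 2-opt reversal beyond. Exact OCB is recomputed on the
final order for reporting. Orientation of a path is arbitrary, so of an
order and its reversal the one whose first marker id sorts lexicographically
smaller is returned, making results deterministic; the heuristic's
remaining tie-breaks are driven by an explicit seed.

## Multipoint maps

Given an order, the map likelihood treats the retention state along the
chromosome as a two-state Markov chain: initial retention probability $r$;
across interval $i$ with breakage fraction $\theta_i$, the state is copied
with probability $1-\theta_i$ and redrawn (retained with probability $r$)
with probability $\theta_i$. Determined calls observe the state exactly;
missing calls are marginalized by a scaled forward recursion, verified in
the tests against exhaustive summation over all $2^k$ hidden state vectors
for $k \le 5$.

`fitMap()` initializes $\theta_i$ from two-point estimates of adjacent
pairs (0.5 where a pair is non-informative) and refines
$(\theta_1..\theta_{k-1}, r)$ by coordinate-wise 1-D maximization
(`stats::optimize`) to a relative log-likelihood tolerance of $10^{-6}$
with at most 200 sweeps — smooth one-dimensional problems, reproducible
without stochastic search. Fitted $\theta_i < 10^{-7}$ are snapped to 0 so
duplicate markers yield exactly zero-length intervals. Positions are
cumulative $-100\ln(1-\theta_i)$ from the first marker.

`buildComprehensiveMap()` follows the two-stage practice of a stringent
framework map plus relaxed-confidence insertion: remaining markers are
taken in decreasing order of their best two-point LOD to a framework
marker, inserted at the position (including ends) maximizing the multipoint
log-likelihood with intervals re-initialized from two-point estimates, and
markers whose best LOD falls below the insertion threshold (default 2) are
reported unplaced. The final order is refit with `fitMap()`.

## Panel statistics

* `retentionReport()` computes per-marker retention both as a percentage of
  determined calls and of all calls. The panel-wide average uses all
  assayed calls as denominator, the convention under which a 68×184 panel
  with 4252 retained calls gives 33.98%; the determined-call variant is
  reported alongside because published figures are not always consistent
  about the denominator.
* `resolutionReport()` reproduces the printed conventions exactly:
  kb/break is truncated (not rounded) to one decimal — 781 Mb over 2034
  breaks is 383.9, not 384.0 — and kb/cR is truncated to an integer
  (781 Mb over 2103 cR gives 371). Exact quotients are returned alongside.
* `friedmanHomogeneity()` implements the uncorrected mid-rank Friedman
  statistic $\chi^2 = \frac{12}{bk(k+1)}\sum_j R_j^2 - 3b(k+1)$ with the
  $\chi^2_{k-1}$ reference distribution. `stats::friedman.test` applies a
  tie correction; the uncorrected form is kept as the package's definition
  and the two agree exactly on tie-free data (tested).
* `orderConcordance()` operationalizes "consistent order" as the longest
  common subsequence of the shared markers, taking the better of the
  reference as given and reversed. Published concordance fractions rarely
  state their definition (per-marker displacement and LCS differ), so no
  claim is made that LCS reproduces any particular printed fraction.

## Test problem sizes

The suite validates each estimator against an independent brute-force
oracle at sizes where enumeration is exact: 200 random 2×2 tables against a
$10^{-3}$ likelihood grid; 8-marker × 20-hybrid panels against exhaustive
missing-call completion for OCB; $k \le 5$ markers against $2^k$
hidden-state enumeration; $n \le 8$ markers against full permutation
enumeration for ordering. Statistical recoveries use the study conditions:
retention $\rho \in \{0.15, 0.34\}$ at 92 and 184 hybrids; adjacent-interval
$\hat\theta$ at 500 hybrids; order recovery on 20-marker × 184-hybrid
panels at ~1.5 obligate breaks per interval per 100 hybrids over 20 seeded
replicates; and the panel-size/resolution relation (92 vs 184 hybrids) over
20 replicates. Because calls within a hybrid are correlated through shared
fragments, recovery checks calibrate their tolerance with the empirical
standard error of per-hybrid retention means (hybrids are iid) rather than
a naive all-calls binomial standard error, which would understate the
sampling variance.

## Known limitations

* The two-point model is haploid with equal retention within a pair; no
  diploid, dose-annotated ($cR_{3000}$-style) or copy-number models.
* The ordering machinery is deliberately modest (Held–Karp + 2-opt); no
  simulated annealing or LKH-grade solvers, and no simultaneous
  multi-chromosome ordering.
* Whether a published map's criterion was OCB or maximum multipoint
  likelihood is often unstated; `rhmap` reports both for a fitted map and
  does not assert their equivalence.
* The dose → $(\lambda, \rho)$ calibration is user-supplied
  (`dose_model`): published dose series constrain the direction of the
  retention trend, not its functional form.
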
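---
title: "Intensity bounds for spatial cluster delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity bounds for spatial cluster delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intensitybounds)
```

## The problem

A spatial scan statistic divides a disease map into two parts: the most
likely cluster (MLC) and everything else. That clear-cut boundary hides
considerable uncertainty, especially when case counts are small: areas just
outside the detected cluster may be nearly as suspicious as areas inside
it, and not every area inside the cluster carries the same weight. This
package quantifies that uncertainty. It treats the observed case vector as
one realisation of a random vector whose expectation is estimated from the
data itself, regenerates the map many times, and records where the scan's
most likely cluster lands on each regeneration. The result is a per-area
score `q` — an "intensity bound" — measuring the plausibility of each area
belonging to the real cluster.

## The circular Poisson scan

The map has `K` areas with populations `n_i` (total `N`) and case counts
`c_i` (total `C`). Under the null, cases are uniformly distributed in the
population, so a zone `z` with population `n_z` expects
`mu_z = C n_z / N` cases. With relative risks inside and outside,
`I(z) = c_z / mu_z` and `O(z) = (C - c_z) / (C - mu_z)`, the Poisson
log-likelihood ratio is

```
LLR(z) = c_z log I(z) + (C - c_z) log O(z)   if I(z) > 1,   0 otherwise.
```

Candidate zones are circular windows: for each area as centre, the nested
sets of areas obtained by adding neighbours in increasing centroid-distance
order, capped at a fraction of the total population
(`max_pop_fraction`, default 0.5, the conventional cap — a "cluster"
containing most of the population is the complement of one that does not).
The zone maximising the LLR is the MLC; its significance comes from Monte
Carlo replication of the null (`null_pvalue()`), using the positive-biased
estimator `p = (1 + #{null max-LLR >= observed}) / (1 + B)`.

Numerical conventions, chosen once:

* `0 * log(0) = 0` when a zone holds every case (continuity).
* LLR ties between zones break by smaller zone population, then fewer
  members, then lower centre index — determinism for testing; with
  continuous jittered coordinates genuine ties essentially never occur.
* Centroid distance ties are assumed absent (the generator jitters
  coordinates for exactly this reason); if user data contain ties they
  break by area index after a warning.
* An area whose lone population already exceeds the cap is skipped as a
  centre with a warning rather than erroring the whole scan.

The window enumeration and LLR maximisation run in C++ (`Rcpp`); a scan of
the 203-cell benchmark takes under a millisecond, so the Monte Carlo layers
above it stay interactive.

## The intensity function and q

`intensity_bounds()` draws `m` replicates of the case vector from a
multinomial with probabilities given by the *mean model*:

* **raw** — `p_i = c_i / C`: the observed counts are the expected counts.
* **smoothed** — local empirical-Bayes smoothed expected counts,
  normalised (below).

For each replicate the scan records the primary MLC only. Sorting the `m`
MLC log-likelihood ratios increasingly gives the intensity function
`f(j) = LLR_(j)`. Each area receives

```
q(a_i) = (1/m) * argmax { f(j) : a_i in MLC_(j) },    q(a_i) = 0 if a_i is in no MLC_(j)
```

— the rank, as a fraction of `m`, of the strongest replicate cluster
containing the area. Members of the top-ranked MLC get `q = 1`; areas never
swept into any replicate cluster stay blank at `q = 0`. A choropleth of
`quantile_shading(q)` (default breakpoints 0.90 / 0.95 / 0.99 / 1, freely
overridable — published maps choose per-map levels) shows the cluster core
in the darkest class and its uncertainty halo in lighter ones.

Two definitional edge cases are fixed by design:

* Ties in `f` rank by replicate order (stable sort), and `q` takes the
  *highest* qualifying rank, which makes it well-defined under ties.
* A replicate whose scan finds no excess (max LLR 0) keeps its rank with
  `f(j) = 0` but contributes no membership, keeping `f` defined on all of
  `{1..m}` without letting an empty "cluster" mark areas.

`m` defaults to 999. The procedure is embarrassingly incremental — the map
sharpens as replicates accumulate — so long runs checkpoint every 50
replicates (`checkpoint_file=`) and resume to a bit-identical result: all
`m` multinomial draws are generated up front from the seed, so resumption
replays the identical stream.

## Marshall empirical-Bayes smoothing

With very few cases, zero-count areas get replication probability 0 under
the raw model and can never seed a replicate cluster. The smoothed mean
model replaces raw rates by Marshall's estimator
`theta_hat_i = w_i t_i + (1 - w_i) m_i`, `w_i = A / (A + m / n_i)`, with
method-of-moments prior moments `m = sum(y) / sum(n)`,
`s2 = sum(n_i (t_i - m)^2) / sum(n_i)`, `nbar = sum(n_i)/K`,
`A = max(0, s2 - m/nbar)`. The *local* variant (the default used by the
smoothed mean model) evaluates these on each area's first-order
neighbourhood. Replication probabilities are then the normalised smoothed
expected counts `n_i theta_hat_i / sum(n_j theta_hat_j)`.

Open design points, resolved as follows:

* The neighbourhood includes the area itself. This is the common
  convention, prevents undefined estimates when all neighbours are empty,
  and makes an isolated area degrade gracefully to its raw rate
  (`|N(i)| = 1` forces zero prior variance, hence `w = 0` and
  `theta_hat = t_i`, with a warning).
* A negative moment estimate of the prior variance is clamped to 0,
  giving complete shrinkage to the neighbourhood mean.
* Smoothing operates on rates and converts back to expected counts via the
  population, rather than smoothing counts directly; this keeps the
  estimator's weights on the scale they were derived for.

Smoothing diffuses the intensity maps (the acceptance suite verifies the
smoothed non-blank set is at least as large as the raw one in the median);
with ample cases the raw model is preferable, since the circular window
already averages over zero-count areas.

## The synthetic benchmark

`hex_grid()` builds the study geometry: a 7 × 29 rectangular array of 203
hexagonal cells (unit spacing, offset rows), population 1000 per cell, and
centroids jittered by a uniform displacement of ±5% of the spacing on each
axis so all pairwise distances are distinct; adjacency comes from the
unjittered lattice (≤ 6 neighbours). 203 = 7 × 29 factors exactly, so no
cells need deleting from the rectangle. `inject_cases()` distributes 406
cases (2 per cell on average) multinomially with weight `n_i * rr` inside
the true cluster and `n_i` outside — the generated maps are noisy, with
heterogeneous counts inside and outside the cluster, as intended.

`scenario_map()` packages five benchmarks plus a null: a 7-cell circular
(hex-flower) cluster at very high (`rr = 8`, scenario A) or moderately
high (`rr = 3`, B) risk; an L-shaped cluster of two 5-cell braces
(`rr = 8`, C); and a double circular cluster with unequal component risks
(8 and 5, D; 3 and 2, E). The relative risks and case total are not
dictated by any published table — they were fixed once so that A is
sharply detectable while B sits near the detection margin, reproducing the
intended qualitative contrast, and are all arguments for sensitivity
analysis.

What the generator does *not* emulate about real maps: unequal area
populations, irregular geography and adjacency, spatially structured
covariates, and overdispersion beyond multinomial noise. Passing the
benchmark therefore demonstrates correctness of the machinery and the
qualitative behaviour of the method, not performance guarantees on any
particular real map.

## Problem sizes and verification

The test suite verifies the scan against an independent brute-force
maximiser on 200 random small maps (exact agreement, including the
tie-break), the LLR against direct evaluation across its boundary cases,
`q` against its defining equation on stored replicate clusters, the
smoothers against exact-rational hand calculations on 3-area and 7-cell
fixtures, and type-I error calibration over 500 null benchmark maps at
`B = 199` (99% binomial band around 0.05). Stochastic delineation
properties run at 50 independent benchmark draws with `m = 199` replicates
(`m = 999` for the double cluster, where rare visits to the weaker
component matter), sizes at which the full suite completes in a few
minutes on one core.

## Limitations

* Only the primary MLC per replicate feeds `q`; secondary clusters within
  a replicate are ignored by design, so a much weaker secondary anomaly
  may stay blank unless `m` is large.
* `q` is a plausibility ranking, not a posterior probability; its scale is
  relative to the replicate ensemble.
* Only circular windows are scanned. Irregular true clusters are
  delineated through the union of circular replicate MLCs, which works
  well for compact irregular shapes (the L benchmark) but inherits the
  circular scan's limits for very elongated ones.
* Planar coordinates are assumed throughout; project before use.
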
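---
title: "Analysing regional livestock trade networks with herdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing regional livestock trade networks with herdnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Live animals in West Africa move from Sahelian production areas through
chains of markets towards urban and coastal consumption basins. Each
record in a market survey describes one shipment — a number of animals
of one species moving in one month from a loading point through a data
collection market to an unloading point. `herdnet` turns such records
into directed, weighted market networks and characterises them with the
statistics used in veterinary epidemiology and trade analysis: who
trades with whom, how concentrated trade is on hub markets, whether
trading pairs are geographically close (propinquity), whether observed
structure exceeds what a degree-preserving null model explains, whether
degree distributions are heavy-tailed, and how markets group into trade
communities.

```{r, eval = FALSE}
library(herdnet)
cfg <- synthetic_config(seed = 1)
markets <- generate_markets(cfg)
entries <- generate_movements(cfg, markets)
table <- preprocess_entries(entries, markets)
networks <- build_yearly_networks(table)
metric_report(networks[["2017"]], markets)
```

## Preprocessing model

A raw survey entry is an origin → survey point → destination triplet.
It is split into at most two directed movements (origin → survey and
survey → destination); a leg is emitted only when its outer endpoint is
present and differs from the survey market, so splitting can never
create a self-loop. Filtering then removes records with a missing or
non-geolocatable endpoint and any residual self-loops. Every drop is
counted by reason, and the identity
*records retained = rows read (or legs split) − Σ drops*
holds on every input; the tests assert it on random tables.

The international flag is always recomputed from the origin and
destination countries; a conflicting input flag is overridden with a
warning, since endpoint countries are the authoritative source.

## Network model

Movements aggregate by calendar year (and overall) into directed simple
graphs. A link between an ordered market pair carries two weights: the
movement count and the summed (scaled) animal volume. All topological
statistics — diameters, density, transitivity, path length,
assortativity, centralizations, components — are computed on the
unweighted topology; weights enter only node volumes and shipment
degrees. Two degree notions coexist: *neighbors* (distinct trading
partners; reciprocal partners count once in the total) and *movements*
(shipment counts).

Conventions that needed a choice:

* **Link density** is `l / (n(n−1))`, the fraction of realised ordered
  pairs. A `2n(n−1)` divisor is available for comparison with reports
  that print that formula, but published per-year values for networks
  of this kind are consistent with `n(n−1)`.
* **Diameter and average path length** use finite geodesics only:
  unreachable ordered pairs are excluded from both numerator and
  denominator. Yearly trade networks are far from strongly connected,
  so the alternative (infinite or `n`-imputed distances) would make the
  statistics degenerate.
* **Transitivity** defaults to the average of local clustering
  coefficients with degree-<2 markets excluded (configurable to count
  them as zero); the global triangle-to-triple ratio is also available.
* **Degree assortativity** defaults to the directed convention
  (source out-degree vs target in-degree over links), the default of
  the graph libraries used in this field; an undirected-total variant
  is provided.
* **Freeman centralizations** are normalised by the star-graph maximum
  for the measure and directedness at hand; closeness is not
  well-defined on disconnected graphs, so it is computed on the giant
  weakly connected component and flagged with a warning.
* **Undefined metrics** (edgeless graph diameter, zero-variance
  assortativity, …) return `NA` with a classed warning rather than a
  number, so reports can carry the gap explicitly.

## Propinquity

The propinquity statistic asks whether trading markets are closer in
space than non-trading ones. All unordered market pairs are split into
linked (traded in either direction) and unlinked; the one-sided
Mann-Whitney test compares Haversine distances (IUGG mean Earth radius
6371.0088 km) with the alternative that unlinked distances are
stochastically larger. With both groups of size ≤ 10 the p-value is an
exact enumeration over label assignments (conditional on observed
ties); beyond that it uses the normal approximation with continuity and
tie correction, matching `stats::wilcox.test` — the convention under
which the tiny published p-values of this statistic are obtainable.

## Configuration-model null ensembles

Each yearly network is compared with an ensemble of degree-preserving
randomisations: attempted double-edge swaps (default ten per link) that
reject any swap creating a self-loop or parallel link, so every
replicate keeps each market's in- and out-degree exactly and the graph
simple. Metrics not fixed by construction (directed and undirected
diameter, transitivity, average path length, degree assortativity,
betweenness centralization) get z-scores
`(observed − ensemble mean) / ensemble sd` with the sample standard
deviation. The propinquity test is applied to every replicate with the
observed coordinates and the minimum p over the ensemble reported: a
minimum near 1 means no randomisation reproduces the observed spatial
structure. Replicate seeds derive deterministically from one master
seed, so ensembles reproduce independently of execution order.

## Heavy-tailed degree distributions

For the overall network the package fits a discrete power law
`p(k) ∝ k^(−α)` above a cutoff `x_min`, with `α` by zeta-normalised
maximum likelihood (Hurwitz zeta via Euler-Maclaurin summation,
accuracy below 1e-10) and `x_min` chosen to minimise the KS distance
between the tail and the fitted model; candidate cutoffs are all
distinct observed values keeping at least 8 tail points, which guards
against the known small-tail instability of the KS scan. Goodness of
fit is a semi-parametric bootstrap (body resampled empirically, tail
drawn from the fitted model via the standard inverse-transform
generator, full refit per replicate); a fit is conventionally plausible
when p > 0.1. A discretised log-normal truncated at the same cutoff is
fitted by maximum likelihood for comparison, and a Vuong
likelihood-ratio test decides between the two non-nested models —
declared indeterminate when its two-sided p exceeds 0.1.

## Communities

Trade communities come from fast-greedy agglomerative modularity
maximisation on the undirected simplification (reciprocal links merged,
movement counts summed; unweighted by default since the weighting used
in published analyses of this kind is not always stated). The returned
Q always equals an independent recomputation of Newman modularity on
the returned membership; merge tie-breaking is delegated to the
deterministic library implementation.

## What the synthetic generator emulates

The generator produces raw survey entries with the structure the
analysis assumes, so the whole pipeline is testable without access to
original survey records:

* ~200 markets uniform in a West-Africa-like box, countries as
  longitude bands, border flags within 50 km of a band boundary;
* 12 hub markets placed by farthest-point dispersal (hubs serve
  separate catchments) — dispersal is what makes rewired null networks
  connect distant hubs and thus *lose* the observed propinquity;
* persistent partner pools per survey point (means of 8 partners per
  direction for hubs, 1.5 for other survey markets) with partner
  weight `hub_bias^is_hub · exp(−d/200 km)` and a 4% exploration rate,
  planting corridor structure (few, heavily repeated links),
  propinquity and disassortativity;
* a north→south flow gradient (e-folding 1.5° latitude) that makes
  trade largely one-directional, keeping strongly connected components
  small;
* about 375 entries per month over January 2013 – August 2017, species
  mix ≈ 74% cattle / 20% sheep / 6% goat / <1% donkey, transport ≈ 94%
  vehicle, log-normal scaled head counts, a tripled sheep rate in the
  two months before each Tabaski festival, and a 5% missing-endpoint
  rate to exercise the filters.

These defaults were fixed once to match the magnitudes reported for
regional livestock trade surveys (yearly networks of 100–200 markets
with 150–500 links and thousands of shipments, strong planted
propinquity, assortativity z-scores far below −5 against ensembles of
200, modularity near 0.5 with 6–8 communities). What passing tests on
this stand-in do **not** show: anything about a particular real
dataset — real survey coverage changes year to year, real borders are
not meridians, and real movement weights are anonymised by scaling.

## Problem sizes used in the tests

The bundled checks run the full pipeline at the default generator
scale (~40,000 movements), with configuration ensembles of 100–200
replicates, 120–500 bootstrap replicates for goodness of fit, and
brute-force oracle comparisons on random graphs of up to 12 nodes;
exact Mann-Whitney enumeration is exercised up to group size 10.

## Known limitations

* The propinquity exact-enumeration path is O(C(n_x+n_y, n_x)) and is
  only used for tiny groups; real networks always take the normal
  approximation.
* Closeness centralization on disconnected networks describes only the
  giant component.
* The movements-degree sequence of a hub-dominated network is bimodal
  rather than smoothly heavy-tailed; the KS cutoff scan then selects a
  deep tail, and the fitted exponent describes hubs only.
* Alternative null models (Erdős–Rényi, gravity/distance-penalised)
  and alternative community algorithms are out of scope.
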
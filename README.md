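# herdnet

Network analysis of regional livestock trade.

Livestock in West Africa moves from Sahelian production areas through
chains of markets towards urban and coastal consumption basins, and
most of this trade is informal and sparsely recorded. Market surveys
capture it as entries of the form *origin market → data-collection
market → destination market*, with the month, species, transport mode
and a (scaled) head count. `herdnet` is for epidemiologists and trade
analysts who need to turn such records into quantitative statements
about market structure: where the hubs are, whether trade follows
spatial corridors, and which structural features exceed chance.

The package provides, end to end:

* **Preprocessing** — split each survey entry into up to two directed
  movements (a leg is emitted only when its endpoint exists and
  differs from the survey market, so no self-loops), drop incomplete
  and unmappable records, and keep full provenance counters.
* **Network construction** — yearly and overall directed simple graphs
  with per-link movement counts and animal volumes (*n* markets,
  *m* shipments, *l* links).
* **Metrics** — diameters (directed/undirected, finite geodesics),
  link density *l*/(*n*(*n*−1)), average link degree *l*/*n*, average
  shipments *m*/*n*, transitivity, average path length, degree
  assortativity, Freeman degree/betweenness/closeness centralizations,
  GSCC/GWCC sizes, node volumes and degrees, key-market rankings.
* **Propinquity** — a one-sided Mann–Whitney test on Haversine
  distances comparing linked vs unlinked market pairs (H₁: non-trading
  pairs are farther apart), exact by enumeration for tiny groups and
  normal-approximated with tie correction otherwise.
* **Null models** — configuration-model ensembles by degree-preserving
  double-edge swaps (no self-loops or multi-edges), z-scores
  *(observed − mean)/sd* for the non-fixed metrics, and the minimum
  ensemble propinquity p-value.
* **Heavy tails** — discrete power-law fits (α by zeta-normalised MLE,
  x_min by KS minimisation), semi-parametric bootstrap goodness of
  fit, truncated discretised log-normal fits, and a Vuong comparison.
* **Communities** — fast-greedy modularity maximisation with
  self-consistent Q.
* **Synthetic data** — a seeded generator of raw survey entries with
  the structure the analysis assumes (hub catchments, distance decay,
  north→south flow, pre-Tabaski sheep peaks), so the whole pipeline is
  testable without access to any survey database.

## Worked example

```r
library(herdnet)

cfg     <- synthetic_config(seed = 1)       # the bundled study conditions
markets <- generate_markets(cfg)
entries <- generate_movements(cfg, markets)
table   <- preprocess_entries(entries, markets)
table
#> <movement_table> 39683 movements, 2013-01 to 2017-08
#>   counters: entries_read=20834 records_split=39683 dropped_incomplete=0 ...

networks <- build_yearly_networks(table)
networks[["2017"]]
#> <trade_network 2017> n = 182 markets, m = 5705 shipments, l = 441 links

summarize_movements(table, "livestock")
#>   category     n        pct
#> 1   cattle 27916 70.3475040
#> 2    sheep  9213 23.2164907
#> 3     goat  2373  5.9798906
#> 4   donkey   181  0.4561147

propinquity_test(networks[["2017"]], markets)
#> <propinquity> p = 5.9e-69 (normal), linked pairs 431 (median 478 km),
#>               unlinked 16040 (median 848 km)

fast_greedy_communities(networks[["2017"]])
#> <community_partition> 6 communities, Q = 0.478 over 182 markets

lnk <- degree_sequences(build_overall_network(table), "neighbors", "all")
fit_discrete_power_law(lnk)
#> <power_law_fit> x_min = 32, alpha = 4.480, KS = 0.0705, n_tail = 29
```

Reading the output: 20,834 raw entries became 39,683 directed
movements (some legs were missing an endpoint or started at the survey
market — the counters account for every one). The 2017 network has 182
markets trading over 441 directed links; trading pairs are much closer
(median 478 km) than non-trading pairs (median 848 km), and the
one-sided Mann–Whitney p-value ≈ 6e-69 says that propinquity is far
beyond chance. Fast-greedy modularity finds 6 trade communities
(Q = 0.478), and the partner-count distribution has a heavy tail
(29 hub-like markets above the fitted cutoff).

`ensemble_report(network, markets, size = 1000, seed = 1)` compares any
of these networks against its degree-preserving null ensemble, and
`run_pipeline(run_config(...))` (or the thin CLI in
`inst/scripts/herdnet-pipeline.R`) writes the full artifact set —
summary, metric, z-score, component and key-market tables, degree-fit
JSON, community memberships and a provenance record.

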
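test_that("diameter and path length match hand-checked cases", {
  cyc <- make_network(from = c("A", "B", "C"), to = c("B", "C", "A"))
  expect_equal(net_diameter(cyc, TRUE), 2L)
  expect_equal(net_diameter(cyc, FALSE), 1L)
  single <- make_network("A", "B")
  expect_equal(net_diameter(single, TRUE), 1L)
  # directed path A->B->C: ordered reachable pairs {1, 1, 2}
  path <- make_network(from = c("A", "B"), to = c("B", "C"))
  expect_equal(average_path_length(path, TRUE), 4 / 3)
  # complete graph: every geodesic is one link
  nodes <- c("A", "B", "C", "D")
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  complete <- make_network(pairs$from, pairs$to)
  expect_equal(average_path_length(complete, TRUE), 1)
  expect_equal(link_density(complete), 1)
})

test_that("density and averages follow their defining ratios", {
  star <- make_network(from = rep("H", 9), to = sprintf("S%d", 1:9))
  expect_equal(link_density(star), 0.1)
  avg <- average_quantities(star)
  expect_equal(avg$avg_link_degree, 0.9)
  expect_equal(avg$avg_shipments, 0.9)
  two <- make_network("A", "B")
  expect_equal(average_quantities(two)$avg_link_degree, 0.5)
  expect_equal(link_density(two, "2n(n-1)"), 0.25)
})

test_that("transitivity matches triple enumeration on known graphs", {
  tri <- make_network(from = c("A", "B", "C"), to = c("B", "C", "A"))
  expect_equal(transitivity_coefficient(tri, "average-local"), 1)
  expect_equal(transitivity_coefficient(tri, "global"), 1)
  star <- make_network(from = rep("H", 5), to = sprintf("S%d", 1:5))
  expect_equal(transitivity_coefficient(star, "average-local"), 0)
  expect_equal(transitivity_coefficient(star, "global"), 0)
  # triangle plus a pendant: values frozen from the enumeration oracle
  tp <- make_network(from = c("A", "B", "C", "C"), to = c("B", "C", "A", "D"))
  expect_equal(transitivity_coefficient(tp, "global"), 0.6)
  expect_equal(transitivity_coefficient(tp, "average-local", "drop"), 7 / 9)
  expect_equal(transitivity_coefficient(tp, "average-local", "zero"), 7 / 12)
  expect_equal(oracle_transitivity(tp, "average-local", "drop"), 7 / 9)
  expect_equal(oracle_transitivity(tp, "average-local", "zero"), 7 / 12)
  # no node with two partners: undefined
  expect_warning(v <- transitivity_coefficient(make_network("A", "B")),
                 class = "herdnet_undefined_metric")
  expect_true(is.na(v))
})

test_that("assortativity is -1 on a star and undefined without variance", {
  star <- make_network(from = rep("H", 6), to = sprintf("S%d", 1:6))
  expect_equal(degree_assortativity(star, "undirected-total"), -1)
  two <- make_network(from = c("A", "C"), to = c("B", "D"))
  expect_warning(v <- degree_assortativity(two),
                 class = "herdnet_undefined_metric")
  expect_true(is.na(v))
})

test_that("centralization is 1 on stars, 0 on cycles", {
  star <- make_network(from = rep("H", 7), to = sprintf("S%d", 1:7))
  expect_equal(centralization(star, "out-degree"), 1)
  in_star <- make_network(from = sprintf("S%d", 1:7), to = rep("H", 7))
  expect_equal(centralization(in_star, "in-degree"), 1)
  nodes <- sprintf("N%d", 1:6)
  cyc <- make_network(nodes, c(nodes[-1], nodes[1]))
  expect_equal(centralization(cyc, "degree"), 0)
  expect_equal(centralization(cyc, "betweenness"), 0)
  expect_equal(centralization(cyc, "closeness"), 0)
})

test_that("closeness centralization on a disconnected network warns and uses the giant component", {
  net <- make_network(from = c("A", "B", "C", "X"), to = c("B", "C", "D", "Y"))
  expect_warning(v <- centralization(net, "closeness"),
                 "giant weakly connected component")
  expect_true(is.finite(v))
})

test_that("component sizes respect and neglect direction", {
  # 4-cycle is strongly connected; adding a pendant leaves it the GSCC
  net <- make_network(from = c("A", "B", "C", "D", "D"),
                      to = c("B", "C", "D", "A", "E"))
  expect_equal(connected_components(net, "strong"), c(4L, 1L))
  expect_equal(connected_components(net, "weak"), 5L)
})

test_that("metrics agree with the brute-force oracle on random graphs", {
  for (seed in 1:12) {
    set.seed(seed)
    net <- random_network(n = sample(4:12, 1), p = runif(1, 0.1, 0.45),
                          seed = seed * 131)
    expect_equal(net_diameter(net, TRUE), oracle_diameter(net, TRUE),
                 info = paste("diameter dir, seed", seed))
    expect_equal(net_diameter(net, FALSE), oracle_diameter(net, FALSE),
                 info = paste("diameter und, seed", seed))
    expect_equal(average_path_length(net, TRUE), oracle_apl(net, TRUE),
                 tolerance = 1e-12, info = paste("apl, seed", seed))
    tr <- suppressWarnings(transitivity_coefficient(net, "average-local"))
    tro <- oracle_transitivity(net, "average-local", "drop")
    if (!is.na(tr)) expect_equal(tr, tro, tolerance = 1e-12,
                                 info = paste("transitivity, seed", seed))
    expect_equal(transitivity_coefficient(net, "global"),
                 oracle_transitivity(net, "global"), tolerance = 1e-12,
                 info = paste("global transitivity, seed", seed))
    as_impl <- suppressWarnings(degree_assortativity(net))
    as_orac <- oracle_assortativity(net)
    if (!is.na(as_impl) && !is.na(as_orac)) {
      expect_equal(as_impl, as_orac, tolerance = 1e-10,
                   info = paste("assortativity, seed", seed))
    }
    expect_equal(centralization(net, "betweenness"),
                 oracle_betweenness_centralization(net), tolerance = 1e-10,
                 info = paste("betweenness centralization, seed", seed))
  }
})

test_that("metrics are invariant under node relabeling", {
  net <- random_network(10, 0.3, seed = 99)
  el <- igraph::as_data_frame(net$graph)
  set.seed(7)
  labels <- sort(unique(c(el$from, el$to)))
  perm <- setNames(sprintf("Q%02d", sample(length(labels))), labels)
  moved <- make_network(unname(perm[el$from]), unname(perm[el$to]),
                        movements = el$movement_count)
  expect_equal(net_diameter(moved, TRUE), net_diameter(net, TRUE))
  expect_equal(average_path_length(moved, TRUE), average_path_length(net, TRUE))
  expect_equal(suppressWarnings(degree_assortativity(moved)),
               suppressWarnings(degree_assortativity(net)))
  expect_equal(centralization(moved, "betweenness"),
               centralization(net, "betweenness"))
  expect_equal(connected_components(moved, "strong"),
               connected_components(net, "strong"))
})

test_that("undirected diameter is no larger when the graph is strongly connected", {
  for (seed in 1:8) {
    net <- random_network(n = 8, p = 0.5, seed = 100 + seed)
    comp <- connected_components(net, "strong")
    if (comp[1] == net$n) {
      expect_lte(net_diameter(net, FALSE), net_diameter(net, TRUE))
    }
  }
})

test_that("node metrics add volumes and count partners per direction", {
  tab <- make_table(from = c("A", "B"), to = c("B", "C"), heads = c(10, 5))
  net <- build_network(tab)
  nm <- node_metrics(net)
  expect_equal(nm$volume[nm$code == "B"], 15)
  # hub with three in-partners of two movements each
  hub <- make_network(from = c("X", "Y", "Z"), to = rep("H", 3),
                      movements = 2)
  nm <- node_metrics(hub)
  h <- nm[nm$code == "H", ]
  expect_equal(h$links_in, 3L)
  expect_equal(h$shipments_in, 6L)
  expect_equal(h$links_out, 0L)
  # reciprocal partners count once in links_all
  rec <- make_network(from = c("A", "B"), to = c("B", "A"))
  nm <- node_metrics(rec)
  expect_equal(nm$links_all, c(1L, 1L))
  expect_true(all(nm$links_in + nm$links_out >= nm$links_all))
})

test_that("key market table ranks deterministically with annotations", {
  nets <- list("2015" = make_network(from = c("A", "A", "B"),
                                     to = c("B", "C", "C"),
                                     movements = c(5, 1, 1), heads = 2))
  ann <- make_nodes(c("A", "B", "C"), lat = c(10, 11, 12), lon = 0:2)
  ann$border_within_50km <- c(TRUE, FALSE, FALSE)
  key <- key_market_table(nets, ann)
  expect_equal(key$market[key$metric == "links_out"], "A")
  expect_equal(key$market[key$metric == "shipments_in"], "B")
  expect_true(key$border_within_50km[key$metric == "links_out"])
  # single-market ties break lexicographically
  tie <- list("2016" = make_network(from = c("A", "B"), to = c("B", "A")))
  key2 <- key_market_table(tie, make_nodes(c("A", "B"), c(1, 2), c(1, 2)))
  expect_true(all(key2$market == "A"))
})

test_that("the metric report is internally consistent", {
  cfg <- small_synthetic_config(seed = 31)
  m <- generate_markets(cfg)
  tab <- preprocess_entries(generate_movements(cfg, m), m)
  net <- build_overall_network(tab)
  rep <- suppressWarnings(metric_report(net, m))
  expect_equal(rep$avg_link_degree, rep$l / rep$n)
  expect_equal(rep$avg_shipments, rep$m / rep$n)
  expect_lte(rep$gscc_size, rep$gwcc_size)
  expect_lte(rep$gwcc_size, rep$n)
  expect_true(rep$link_density >= 0 && rep$link_density <= 1)
  expect_true(abs(rep$degree_assortativity) <= 1)
  for (f in c("centralization_degree", "centralization_in",
              "centralization_out", "centralization_betweenness")) {
    expect_true(rep[[f]] >= 0 && rep[[f]] <= 1, info = f)
  }
  tab5 <- metric_report_table(list(rep))
  expect_equal(ncol(tab5), 2L)
  expect_true("degree_assortativity" %in% tab5$metric)
})
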
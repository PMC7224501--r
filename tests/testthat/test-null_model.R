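test_that("rewiring preserves degree sequences, simplicity and sizes", {
  cfg <- small_synthetic_config(seed = 17)
  m <- generate_markets(cfg)
  net <- build_overall_network(preprocess_entries(generate_movements(cfg, m),
                                                  m))
  for (seed in 1:5) {
    rw <- rewire_configuration(net, seed = seed)
    expect_equal(rw$n, net$n)
    expect_equal(rw$l, net$l)
    expect_true(igraph::is_simple(rw$graph))
    expect_equal(igraph::degree(rw$graph, mode = "in"),
                 igraph::degree(net$graph, mode = "in"))
    expect_equal(igraph::degree(rw$graph, mode = "out"),
                 igraph::degree(net$graph, mode = "out"))
  }
})

test_that("a directed 3-cycle can only rewire to itself", {
  cyc <- make_network(from = c("A", "B", "C"), to = c("B", "C", "A"))
  # the only simple digraph with this in/out degree sequence is the cycle
  ens <- generate_ensemble(cyc, size = 10, seed = 4)
  # every defined metric has zero ensemble variance (assortativity is
  # undefined on the cycle's constant degrees)
  expect_true(all(apply(ens$metrics, 2, function(col) {
    all(is.na(col)) || sd(col) == 0
  })))
  rw <- rewire_configuration(cyc, seed = 1)
  expect_equal(sort(apply(igraph::as_edgelist(rw$graph), 1, paste,
                          collapse = ">")),
               sort(apply(igraph::as_edgelist(cyc$graph), 1, paste,
                          collapse = ">")))
})

test_that("ensembles are reproducible under a seed and density is fixed", {
  net <- random_network(12, 0.3, seed = 3)
  e1 <- generate_ensemble(net, size = 4, seed = 42, keep_networks = TRUE)
  e2 <- generate_ensemble(net, size = 4, seed = 42)
  expect_identical(e1$metrics, e2$metrics)
  for (rep_net in e1$networks) {
    expect_equal(link_density(rep_net), link_density(net))
  }
})

test_that("z-scores follow their definition and flag zero variance", {
  obs <- list(transitivity = 0.5, avg_path_length = 3,
              diameter_directed = 4, diameter_undirected = 3,
              degree_assortativity = -0.2, centralization_betweenness = 0.1)
  mat <- matrix(
    c(0.5, 0.5, 0.5, 2, 3, 4, 4, 4, 4, 3, 3, 3, -0.1, -0.2, -0.3, 0.1,
      0.1, 0.1),
    nrow = 3,
    dimnames = list(NULL, c("transitivity", "avg_path_length",
                            "diameter_directed", "diameter_undirected",
                            "degree_assortativity",
                            "centralization_betweenness")))
  expect_warning(z <- z_scores(obs, list(metrics = mat)), "zero ensemble")
  # observed equal to the mean: z = 0
  expect_equal(z$z[z$metric == "avg_path_length"], 0)
  expect_equal(z$z[z$metric == "degree_assortativity"], 0)
  # observed = mean + 2 sd (sample sd of {-0.1,-0.2,-0.3} is 0.1)
  obs$degree_assortativity <- -0.2 + 2 * 0.1
  z <- suppressWarnings(z_scores(obs, list(metrics = mat)))
  expect_equal(z$z[z$metric == "degree_assortativity"], 2)
  # fixed-by-construction metrics get no z
  expect_true(is.na(z$z[z$metric == "transitivity"]))
})

test_that("z-scores are invariant to node relabeling", {
  net <- random_network(10, 0.35, seed = 12)
  el <- igraph::as_data_frame(net$graph)
  labels <- sort(unique(c(el$from, el$to)))
  perm <- setNames(sprintf("R%02d", rev(seq_along(labels))), labels)
  moved <- make_network(unname(perm[el$from]), unname(perm[el$to]))
  obs1 <- suppressWarnings(metric_report(net))
  obs2 <- suppressWarnings(metric_report(moved))
  ens1 <- suppressWarnings(generate_ensemble(net, size = 30, seed = 6))
  ens2 <- suppressWarnings(generate_ensemble(moved, size = 30, seed = 6))
  z1 <- suppressWarnings(z_scores(obs1, ens1))
  z2 <- suppressWarnings(z_scores(obs2, ens2))
  expect_equal(z1$observed, z2$observed)
  # ensemble draws differ only through edge identities, not statistics
  expect_equal(colMeans(ens1$metrics), colMeans(ens2$metrics),
               tolerance = 0.5)
})

test_that("ensemble means converge with ensemble size", {
  net <- random_network(12, 0.3, seed = 21)
  small <- suppressWarnings(generate_ensemble(net, size = 100, seed = 7))
  large <- suppressWarnings(generate_ensemble(net, size = 400, seed = 8))
  for (mc in colnames(small$metrics)) {
    s <- sd(large$metrics[, mc])
    if (s > 0) {
      expect_lt(abs(mean(small$metrics[, mc]) - mean(large$metrics[, mc])),
                4 * s / sqrt(100), label = mc)
    }
  }
})

test_that("an ensemble of size one returns that replicate's propinquity p", {
  cfg <- small_synthetic_config(seed = 19)
  m <- generate_markets(cfg)
  net <- build_overall_network(preprocess_entries(generate_movements(cfg, m),
                                                  m))
  ep <- ensemble_propinquity(net, m, size = 1, seed = 5)
  expect_equal(ep$min_p, ep$p_values[1])
  expect_length(ep$p_values, 1)
})
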
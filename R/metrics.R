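# Network-, subset- and node-level statistics of trade networks. All
# metrics are computed on the unweighted topology; weights enter only
# through node volumes and shipment degrees.

#' Network diameter
#'
#' Longest finite geodesic distance (in links) between any pair of
#' markets; unreachable pairs are ignored, so the value is defined for
#' networks that are not (strongly) connected.
#'
#' @param network A `trade_network` with at least one link.
#' @param respect_direction If `TRUE`, paths follow link direction;
#'   otherwise directions are neglected.
#' @return Nonnegative integer, or `NA` with a warning for an edgeless
#'   network.
#' @export
net_diameter <- function(network, respect_direction = TRUE) {
  stopifnot(inherits(network, "trade_network"))
  if (network$l == 0L) {
    return(undefined_metric("diameter", "network has no links"))
  }
  g <- if (respect_direction) network$graph else
    undirected_simplification(network)
  as.integer(igraph::diameter(g, directed = respect_direction,
                              unconnected = TRUE, weights = NA))
}

#' Link density
#'
#' Ratio of realised directed links to possible ordered market pairs,
#' `l / (n (n - 1))`. A variant divisor `2 n (n - 1)` is provided for
#' comparison with reports that use it.
#'
#' @param network A `trade_network` with `n >= 2`.
#' @param divisor `"n(n-1)"` (default) or `"2n(n-1)"`.
#' @return Fraction in `[0, 1]`.
#' @export
link_density <- function(network, divisor = c("n(n-1)", "2n(n-1)")) {
  stopifnot(inherits(network, "trade_network"))
  divisor <- match.arg(divisor)
  n <- network$n
  if (n < 2L) {
    return(undefined_metric("link_density", "fewer than 2 markets"))
  }
  denom <- n * (n - 1)
  if (divisor == "2n(n-1)") denom <- 2 * denom
  network$l / denom
}

#' Average link degree and average shipments
#'
#' `l / n` (average number of trading partners per market, counting
#' directed links) and `m / n` (average shipments per market), unrounded.
#'
#' @param network A `trade_network` with `n >= 1`.
#' @return List with `avg_link_degree` and `avg_shipments`.
#' @export
average_quantities <- function(network) {
  stopifnot(inherits(network, "trade_network"), network$n >= 1L)
  list(avg_link_degree = network$l / network$n,
       avg_shipments = network$m / network$n)
}

#' Transitivity (clustering coefficient)
#'
#' Computed on the undirected simplification. `"average-local"` is the
#' mean of local clustering coefficients; nodes with degree below 2 are
#' excluded from the mean by default (`isolates = "drop"`) or counted as
#' zero (`isolates = "zero"`). `"global"` is three times the number of
#' triangles over the number of connected triples.
#'
#' @param network A `trade_network`.
#' @param variant `"average-local"` or `"global"`.
#' @param isolates Treatment of degree-&lt;2 nodes in the average-local
#'   variant.
#' @return Fraction in `[0, 1]`, or `NA` with a warning when no node has
#'   degree 2 or more.
#' @export
transitivity_coefficient <- function(network,
                                     variant = c("average-local", "global"),
                                     isolates = c("drop", "zero")) {
  stopifnot(inherits(network, "trade_network"))
  variant <- match.arg(variant)
  isolates <- match.arg(isolates)
  gu <- undirected_simplification(network)
  if (igraph::vcount(gu) == 0L || max(c(0, igraph::degree(gu))) < 2) {
    return(undefined_metric("transitivity", "no market with 2 or more partners"))
  }
  if (variant == "global") {
    return(igraph::transitivity(gu, type = "global"))
  }
  igraph::transitivity(gu, type = "average",
                       isolates = if (isolates == "zero") "zero" else "NaN")
}

#' Average path length
#'
#' Mean geodesic distance over ordered pairs of markets; unreachable
#' pairs are excluded from both numerator and denominator.
#'
#' @param network A `trade_network` with at least one link.
#' @param respect_direction If `TRUE`, paths follow link direction.
#' @return Positive real, or `NA` with a warning when no pair is
#'   reachable.
#' @export
average_path_length <- function(network, respect_direction = TRUE) {
  stopifnot(inherits(network, "trade_network"))
  if (network$l == 0L) {
    return(undefined_metric("average_path_length", "network has no links"))
  }
  g <- if (respect_direction) network$graph else
    undirected_simplification(network)
  igraph::mean_distance(g, directed = respect_direction, unconnected = TRUE,
                        weights = NA)
}

#' Degree assortativity
#'
#' Pearson correlation between the degrees at the two ends of each link.
#' The default directed convention correlates the out-degree of the
#' source with the in-degree of the target; `"undirected-total"`
#' correlates total degrees on the undirected simplification.
#'
#' @param network A `trade_network` with `l >= 2`.
#' @param convention `"directed-out-in"` or `"undirected-total"`.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning when an
#'   endpoint degree vector has zero variance.
#' @export
degree_assortativity <- function(network,
                                 convention = c("directed-out-in",
                                                "undirected-total")) {
  stopifnot(inherits(network, "trade_network"))
  convention <- match.arg(convention)
  if (network$l < 2L) {
    return(undefined_metric("degree_assortativity", "fewer than 2 links"))
  }
  g <- if (convention == "directed-out-in") network$graph else
    undirected_simplification(network)
  r <- suppressWarnings(
    igraph::assortativity_degree(g, directed = igraph::is_directed(g)))
  if (!is.finite(r)) {
    return(undefined_metric("degree_assortativity",
                            "zero variance in endpoint degrees"))
  }
  r
}

#' Freeman centralization
#'
#' Network-level concentration of a centrality measure: the summed
#' differences between the most central market and every other market,
#' divided by the theoretical maximum for a network of the same size
#' (attained by a star). Closeness is not well-defined for disconnected
#' graphs and is computed on the largest weakly connected component, with
#' a warning when that component is not the whole network.
#'
#' @param network A `trade_network` with `n >= 3`.
#' @param measure One of `"degree"`, `"in-degree"`, `"out-degree"`,
#'   `"betweenness"`, `"closeness"`.
#' @return Fraction in `[0, 1]`.
#' @export
centralization <- function(network,
                           measure = c("degree", "in-degree", "out-degree",
                                       "betweenness", "closeness")) {
  stopifnot(inherits(network, "trade_network"))
  measure <- match.arg(measure)
  g <- network$graph
  if (network$n < 3L) {
    return(undefined_metric(paste0(measure, " centralization"),
                            "fewer than 3 markets"))
  }
  switch(measure,
    "degree" = igraph::centr_degree(g, mode = "all",
                                    loops = FALSE)$centralization,
    "in-degree" = igraph::centr_degree(g, mode = "in",
                                       loops = FALSE)$centralization,
    "out-degree" = igraph::centr_degree(g, mode = "out",
                                        loops = FALSE)$centralization,
    "betweenness" = igraph::centr_betw(g, directed = TRUE)$centralization,
    "closeness" = {
      gu <- undirected_simplification(network)
      comp <- igraph::components(gu)
      if (comp$no > 1L) {
        warning("closeness centralization computed on the giant weakly connected component (graph is disconnected)")
        giant <- which.max(comp$csize)
        gu <- igraph::induced_subgraph(gu, which(comp$membership == giant))
      }
      if (igraph::vcount(gu) < 3L) {
        return(undefined_metric("closeness centralization",
                                "giant component has fewer than 3 markets"))
      }
      igraph::centr_clo(gu)$centralization
    }
  )
}

#' Connected component sizes
#'
#' @param network A `trade_network`.
#' @param mode `"strong"` (mutual directed reachability) or `"weak"`
#'   (direction neglected). The giant component size is the first element.
#' @return Integer vector of component sizes, descending.
#' @export
connected_components <- function(network, mode = c("strong", "weak")) {
  stopifnot(inherits(network, "trade_network"))
  mode <- match.arg(mode)
  if (network$n == 0L) return(integer())
  comp <- igraph::components(network$graph, mode = mode)
  sort(as.integer(comp$csize), decreasing = TRUE)
}

#' Node-level metrics
#'
#' Per-market trade volume and degrees: `volume` is the summed animal
#' volume on incident links (in plus out); `links_*` count distinct
#' trading partners (for `links_all`, reciprocal partners count once);
#' `shipments_*` count movements.
#'
#' @param network A `trade_network`.
#' @return Data frame with one row per market: `code`, `volume`,
#'   `links_all`, `links_in`, `links_out`, `shipments_all`,
#'   `shipments_in`, `shipments_out`.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "trade_network"))
  g <- network$graph
  if (network$n == 0L) {
    return(data.frame(code = character(), volume = numeric(),
                      links_all = integer(), links_in = integer(),
                      links_out = integer(), shipments_all = integer(),
                      shipments_in = integer(), shipments_out = integer()))
  }
  vol <- igraph::strength(g, mode = "all",
                          weights = igraph::E(g)$animal_volume)
  data.frame(
    code = igraph::V(g)$name,
    volume = as.numeric(vol),
    links_all = unname(degree_sequences(network, "neighbors", "all")),
    links_in = unname(degree_sequences(network, "neighbors", "in")),
    links_out = unname(degree_sequences(network, "neighbors", "out")),
    shipments_all = unname(degree_sequences(network, "movements", "all")),
    shipments_in = unname(degree_sequences(network, "movements", "in")),
    shipments_out = unname(degree_sequences(network, "movements", "out")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Key markets by year and metric
#'
#' For each yearly network, identifies the top market by total volume and
#' by total, in and out degree in links and in shipments. Ties are broken
#' lexicographically by market code, so results are deterministic. Each
#' leader is tagged with its border and urban annotations.
#'
#' @param networks Named list of `trade_network` objects (as from
#'   [build_yearly_networks()]).
#' @param annotations A `market_nodes` data frame; markets without
#'   annotations are reported untagged with a warning.
#' @return Data frame with columns `year`, `metric`, `market`, `value`,
#'   `border_within_50km`, `is_urban`.
#' @export
key_market_table <- function(networks, annotations) {
  metrics <- c("volume", "links_all", "links_in", "links_out",
               "shipments_all", "shipments_in", "shipments_out")
  rows <- lapply(names(networks), function(year) {
    nm <- node_metrics(networks[[year]])
    nm <- nm[order(nm$code), , drop = FALSE]
    do.call(rbind, lapply(metrics, function(mc) {
      lead <- nm$code[which.max(nm[[mc]])]
      data.frame(year = year, metric = mc, market = lead,
                 value = max(nm[[mc]]), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  idx <- match(out$market, annotations$code)
  if (anyNA(idx)) {
    warning(sprintf("no annotations for market(s): %s",
                    paste(unique(out$market[is.na(idx)]), collapse = ", ")))
  }
  out$border_within_50km <- annotations$border_within_50km[idx]
  out$is_urban <- annotations$is_urban[idx]
  rownames(out) <- NULL
  out
}

#' Network-level metric report
#'
#' Assembles the standard vector of network statistics for one network:
#' sizes, diameters, density, averages, transitivity, path length,
#' assortativity, centralizations and giant component sizes, plus the
#' propinquity p-value when coordinates are supplied.
#'
#' @param network A `trade_network`.
#' @param nodes Optional `market_nodes` for survey-market counts and the
#'   propinquity test.
#' @param density_divisor,transitivity_variant,assortativity_convention
#'   Metric variants, passed through to the individual functions.
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(network, nodes = NULL,
                          density_divisor = "n(n-1)",
                          transitivity_variant = "average-local",
                          assortativity_convention = "directed-out-in") {
  stopifnot(inherits(network, "trade_network"))
  avg <- average_quantities(network)
  survey <- NA_integer_
  prop_p <- NA_real_
  if (!is.null(nodes)) {
    codes <- igraph::V(network$graph)$name
    survey <- sum(nodes$is_survey_point[match(codes, nodes$code)],
                  na.rm = TRUE)
    prop <- propinquity_test(network, nodes)
    prop_p <- prop$p_value
  }
  rep <- list(
    year = network$year,
    survey_markets = survey,
    n = network$n, m = network$m, l = network$l,
    diameter_directed = net_diameter(network, TRUE),
    diameter_undirected = net_diameter(network, FALSE),
    link_density = link_density(network, density_divisor),
    avg_link_degree = avg$avg_link_degree,
    avg_shipments = avg$avg_shipments,
    transitivity = transitivity_coefficient(network, transitivity_variant),
    avg_path_length = average_path_length(network, TRUE),
    propinquity_p = prop_p,
    degree_assortativity = degree_assortativity(network,
                                                assortativity_convention),
    centralization_degree = centralization(network, "degree"),
    centralization_in = centralization(network, "in-degree"),
    centralization_out = centralization(network, "out-degree"),
    centralization_betweenness = centralization(network, "betweenness"),
    centralization_closeness = suppressWarnings(
      centralization(network, "closeness")),
    gscc_size = connected_components(network, "strong")[1] %||% NA_integer_,
    gwcc_size = connected_components(network, "weak")[1] %||% NA_integer_
  )
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report %s>\n", x$year))
  vals <- x[setdiff(names(x), "year")]
  for (nm in names(vals)) {
    v <- vals[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.na(v)) "NA" else format(v, digits = 4)))
  }
  invisible(x)
}

#' Serialise metric reports in a years-as-columns table
#'
#' @param reports List of `metric_report` objects.
#' @param path Optional CSV output path (metrics as rows, networks as
#'   columns).
#' @return The assembled data frame, invisibly if written.
#' @export
metric_report_table <- function(reports, path = NULL) {
  cols <- lapply(reports, function(r) {
    unlist(r[setdiff(names(r), "year")])
  })
  out <- data.frame(metric = names(cols[[1]]),
                    do.call(cbind, cols), check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1] <- vapply(reports, function(r) as.character(r$year), "")
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
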
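# Configuration-model null ensembles: degree-preserving rewiring of the
# observed networks, per-metric z-scores, and ensemble propinquity
# p-values. Metrics fixed by construction (n, m, l, density, degree
# centralization) are not compared.

ENSEMBLE_METRICS <- c("diameter_directed", "diameter_undirected",
                      "transitivity", "avg_path_length",
                      "degree_assortativity", "centralization_betweenness")

#' Degree-preserving rewiring of a trade network
#'
#' Randomises the links by attempted double-edge swaps that preserve
#' every market's in- and out-degree while keeping the graph simple:
#' swaps that would create a self-loop or a parallel link are rejected
#' and re-drawn. The default swap budget is ten attempted swaps per link.
#'
#' @param network A `trade_network` with `l >= 2`.
#' @param n_swaps Number of attempted swaps; default `10 * l`.
#' @param seed Optional seed for this rewire.
#' @return A rewired `trade_network` with the same `n`, `m`, `l` and
#'   degree sequences.
#' @export
rewire_configuration <- function(network, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(network, "trade_network"), network$l >= 2L)
  if (!is.null(seed)) set.seed(seed)
  n_swaps <- n_swaps %||% (10L * network$l)
  g <- igraph::rewire(network$graph,
                      igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swaps))
  out <- new_trade_network(g, network$year, m = network$m)
  out
}

ensemble_metric_vector <- function(network) {
  suppressWarnings(c(
    diameter_directed = net_diameter(network, TRUE),
    diameter_undirected = net_diameter(network, FALSE),
    transitivity = transitivity_coefficient(network, "average-local"),
    avg_path_length = average_path_length(network, TRUE),
    degree_assortativity = degree_assortativity(network, "directed-out-in"),
    centralization_betweenness = centralization(network, "betweenness")
  ))
}

#' Generate a configuration-model ensemble
#'
#' Produces `size` independently rewired replicates of the network (each
#' from a deterministic seed derived from the master seed, so results do
#' not depend on execution order) and computes the non-fixed network
#' metrics on each.
#'
#' @param network A `trade_network`.
#' @param size Ensemble size (default 1000).
#' @param seed Master seed.
#' @param swaps_per_link Attempted swaps per link per replicate.
#' @param keep_networks If `TRUE`, also return the rewired networks.
#' @return A list with `metrics` (size-by-metric matrix), `seed`, `size`
#'   and optionally `networks`.
#' @export
generate_ensemble <- function(network, size = 1000L, seed = 1L,
                              swaps_per_link = 10L, keep_networks = FALSE) {
  stopifnot(size >= 2L)
  seeds <- replicate_seeds(seed, size)
  nets <- vector("list", if (keep_networks) size else 0L)
  mat <- matrix(NA_real_, nrow = size, ncol = length(ENSEMBLE_METRICS),
                dimnames = list(NULL, ENSEMBLE_METRICS))
  for (i in seq_len(size)) {
    rep_net <- rewire_configuration(network,
                                    n_swaps = swaps_per_link * network$l,
                                    seed = seeds[i])
    mat[i, ] <- ensemble_metric_vector(rep_net)
    if (keep_networks) nets[[i]] <- rep_net
  }
  out <- list(metrics = mat, seed = seed, size = size)
  if (keep_networks) out$networks <- nets
  out
}

#' z-scores of observed metrics against an ensemble
#'
#' `z = (observed - ensemble mean) / ensemble sd`, with the sample
#' (n - 1) standard deviation. Metrics whose ensemble variance is zero
#' are flagged and get no z-score.
#'
#' @param observed A `metric_report` of the observed network.
#' @param ensemble Result of [generate_ensemble()].
#' @return Data frame with columns `metric`, `observed`, `ensemble_mean`,
#'   `ensemble_sd`, `z`.
#' @export
z_scores <- function(observed, ensemble) {
  mat <- ensemble$metrics
  metrics <- colnames(mat)
  obs <- vapply(metrics, function(mc) {
    v <- observed[[mc]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  mu <- colMeans(mat, na.rm = TRUE)
  sds <- apply(mat, 2, sd, na.rm = TRUE)
  z <- ifelse(sds > 0, (obs - mu) / sds, NA_real_)
  if (any(sds == 0, na.rm = TRUE)) {
    warning(sprintf("zero ensemble variance for: %s (z undefined)",
                    paste(metrics[which(sds == 0)], collapse = ", ")))
  }
  data.frame(metric = metrics, observed = obs, ensemble_mean = mu,
             ensemble_sd = sds, z = z, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Minimum ensemble propinquity p-value
#'
#' Applies the propinquity test to each rewired replicate, using the
#' observed market coordinates, and returns the minimum p-value over the
#' ensemble. A minimum close to 1 means no replicate shows the spatial
#' propinquity of the observed network.
#'
#' @inheritParams generate_ensemble
#' @param nodes A `market_nodes` data frame with coordinates.
#' @return List with `min_p` and the vector `p_values`.
#' @export
ensemble_propinquity <- function(network, nodes, size = 1000L, seed = 1L,
                                 swaps_per_link = 10L) {
  stopifnot(size >= 1L)
  codes <- igraph::V(network$graph)$name
  idx <- match(codes, nodes$code)
  if (anyNA(idx)) {
    stop(sprintf("no coordinates for market(s): %s",
                 paste(codes[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  dist_full <- haversine_matrix(nodes$lat, nodes$lon)
  dimnames(dist_full) <- list(nodes$code, nodes$code)
  seeds <- replicate_seeds(seed + 1L, size)
  p_values <- vapply(seq_len(size), function(i) {
    rep_net <- rewire_configuration(network,
                                    n_swaps = swaps_per_link * network$l,
                                    seed = seeds[i])
    propinquity_test(rep_net, nodes, dist_matrix = dist_full)$p_value
  }, numeric(1))
  list(min_p = min(p_values), p_values = p_values)
}

#' Full ensemble report for one network
#'
#' Convenience wrapper: generates the ensemble, computes z-scores for the
#' non-fixed metrics and the minimum ensemble propinquity p-value.
#'
#' @inheritParams ensemble_propinquity
#' @param observed Optional precomputed `metric_report`; computed if
#'   missing.
#' @return A list of class `ensemble_report`: `z` (data frame),
#'   `min_ensemble_propinquity_p`, `ensemble_size`, `seed`.
#' @export
ensemble_report <- function(network, nodes, size = 1000L, seed = 1L,
                            swaps_per_link = 10L, observed = NULL) {
  observed <- observed %||% metric_report(network, nodes)
  ens <- generate_ensemble(network, size = size, seed = seed,
                           swaps_per_link = swaps_per_link)
  prop <- ensemble_propinquity(network, nodes, size = size, seed = seed,
                               swaps_per_link = swaps_per_link)
  structure(list(
    z = z_scores(observed, ens),
    min_ensemble_propinquity_p = prop$min_p,
    observed_propinquity_p = observed$propinquity_p,
    ensemble_size = size, seed = seed
  ), class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> size %d, seed %d\n", x$ensemble_size,
              x$seed))
  print(x$z, digits = 3)
  cat(sprintf("  min ensemble propinquity p = %.3g (observed %.3g)\n",
              x$min_ensemble_propinquity_p, x$observed_propinquity_p))
  invisible(x)
}
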
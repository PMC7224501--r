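# Trade-community detection: fast-greedy agglomerative modularity
# maximisation on the undirected simplification of a trade network.

#' Modularity of a community partition
#'
#' Newman modularity `Q = sum_i (e_ii - a_i^2)` on the undirected
#' simplification of the network (reciprocal links merged); the weighted
#' variant uses summed movement counts as link weights.
#'
#' @param network A `trade_network`.
#' @param membership Named vector (by market code) or vector in vertex
#'   order assigning each market a community id; must cover all nodes.
#' @param weighted Use movement counts as weights.
#' @return Modularity `Q`.
#' @export
modularity_q <- function(network, membership, weighted = FALSE) {
  stopifnot(inherits(network, "trade_network"))
  gu <- undirected_simplification(network)
  codes <- igraph::V(gu)$name
  if (!is.null(names(membership))) {
    if (!all(codes %in% names(membership))) {
      stop(sprintf("membership missing market(s): %s",
                   paste(setdiff(codes, names(membership)), collapse = ", ")),
           call. = FALSE)
    }
    membership <- membership[codes]
  } else if (length(membership) != length(codes)) {
    stop("membership must cover every market", call. = FALSE)
  }
  w <- if (weighted) igraph::E(gu)$movement_count else NULL
  igraph::modularity(gu, as.integer(factor(membership)), weights = w)
}

#' Fast-greedy community detection
#'
#' Agglomerative modularity optimisation: starting from singleton
#' communities, repeatedly merges the pair of communities giving the
#' greatest modularity increase, and returns the partition at the maximum
#' modularity along the merge path. Runs on the undirected simplification
#' (reciprocal links merged; isolated markets allowed, each ending as its
#' own community on an edgeless graph).
#'
#' @param network A `trade_network`.
#' @param weighted Use summed movement counts as link weights.
#' @return A list of class `community_partition`: `membership` (named by
#'   market code), `q`, `n_communities`.
#' @export
fast_greedy_communities <- function(network, weighted = FALSE) {
  stopifnot(inherits(network, "trade_network"))
  gu <- undirected_simplification(network)
  if (igraph::ecount(gu) == 0L) {
    memb <- setNames(seq_len(igraph::vcount(gu)), igraph::V(gu)$name)
    return(structure(list(membership = memb, q = 0,
                          n_communities = length(memb)),
                     class = "community_partition"))
  }
  w <- if (weighted) igraph::E(gu)$movement_count else NULL
  cl <- igraph::cluster_fast_greedy(gu, weights = w)
  memb <- setNames(as.integer(igraph::membership(cl)), igraph::V(gu)$name)
  structure(list(
    membership = memb,
    q = igraph::modularity(gu, igraph::membership(cl), weights = w),
    n_communities = length(unique(memb))
  ), class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.3f over %d markets\n",
              x$n_communities, x$q, length(x$membership)))
  invisible(x)
}

#' Write community memberships as CSV
#'
#' @param partition A `community_partition`.
#' @param nodes Optional `market_nodes` to add the country column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(partition, nodes = NULL, path) {
  out <- data.frame(market = names(partition$membership),
                    community = unname(partition$membership),
                    stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    out$country <- nodes$country[match(out$market, nodes$code)]
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
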
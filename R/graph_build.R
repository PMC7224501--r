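# Aggregating movement records into directed, weighted trade networks.
#
# A trade network is a directed simple graph of markets; each link carries
# the number of movements and the (scaled) animal volume between an
# ordered pair. The symbols follow the usual convention: n markets,
# m shipments, l directed links (pairs of trading markets).

#' Build a trade network from a movement table
#'
#' Parallel movements between the same ordered market pair are merged into
#' one link accumulating `movement_count` and `animal_volume`. Nodes are
#' exactly the markets appearing as endpoints.
#'
#' @param table A `movement_table` (already filtered: no self-loops).
#' @param year_label Year of the network, or `"overall"`.
#' @return A list of class `trade_network` with elements `graph` (a
#'   directed [igraph][igraph::graph_from_data_frame] graph with edge
#'   attributes `movement_count` and `animal_volume`), `year`, `n`, `m`,
#'   `l`.
#' @export
build_network <- function(table, year_label = "overall") {
  stopifnot(inherits(table, "movement_table"))
  rec <- as.data.frame(table)
  if (nrow(rec) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    return(new_trade_network(g, year_label, m = 0L))
  }
  if (any(rec$from == rec$to)) {
    stop("movement table contains self-loops; run filter_movements() first",
         call. = FALSE)
  }
  key <- paste(rec$from, rec$to, sep = "\r")
  agg <- data.frame(
    from = rec$from[!duplicated(key)],
    to = rec$to[!duplicated(key)],
    movement_count = as.integer(tapply(rep(1L, nrow(rec)), key, sum)[unique(key)]),
    animal_volume = as.numeric(tapply(rec$heads, key, sum)[unique(key)]),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(agg, directed = TRUE)
  new_trade_network(g, year_label, m = sum(agg$movement_count))
}

new_trade_network <- function(graph, year_label, m = NULL) {
  if (is.null(m)) m <- sum(igraph::E(graph)$movement_count)
  structure(list(
    graph = graph, year = year_label,
    n = igraph::vcount(graph), m = as.integer(m),
    l = igraph::ecount(graph)
  ), class = "trade_network")
}

#' @export
print.trade_network <- function(x, ...) {
  cat(sprintf("<trade_network %s> n = %d markets, m = %d shipments, l = %d links\n",
              x$year, x$n, x$m, x$l))
  invisible(x)
}

#' Build one network per year
#'
#' Movements are aggregated over each calendar year into a directed
#' static network with weighted links.
#'
#' @param table A filtered `movement_table`.
#' @param years Years to build; defaults to the sorted years present.
#'   A record outside `years` is an error naming the record.
#' @return Named list (by year) of `trade_network` objects.
#' @export
build_yearly_networks <- function(table, years = NULL) {
  stopifnot(inherits(table, "movement_table"))
  rec_years <- table$year
  if (is.null(years)) years <- sort(unique(rec_years))
  outside <- which(!(rec_years %in% years))
  if (length(outside)) {
    stop(sprintf("record %d (%s -> %s, %s) outside the requested years",
                 outside[1], table$from[outside[1]], table$to[outside[1]],
                 format_month(table$month[outside[1]])), call. = FALSE)
  }
  nets <- lapply(years, function(y) {
    build_network(subset_table(table, rec_years == y), year_label = y)
  })
  names(nets) <- as.character(years)
  nets
}

# Subset a movement_table preserving class and counters.
subset_table <- function(table, keep) {
  new_movement_table(as.data.frame(table)[keep, , drop = FALSE],
                     provenance(table))
}

#' Build the overall network for the whole study period
#'
#' @param table A filtered `movement_table`.
#' @return A `trade_network` labelled `"overall"`; its node set is the
#'   union of all yearly node sets and parallel links across years are
#'   merged.
#' @export
build_overall_network <- function(table) {
  build_network(table, year_label = "overall")
}

#' Degree sequences of a trade network
#'
#' Two notions of degree are used: `"neighbors"` counts distinct trading
#' partners (for `direction = "all"`, reciprocal partners count once), and
#' `"movements"` counts shipments (for `direction = "all"`, the sum of
#' incoming and outgoing movement counts).
#'
#' @param network A `trade_network`.
#' @param mode `"neighbors"` or `"movements"`.
#' @param direction `"all"`, `"in"` or `"out"`.
#' @return Named integer vector, one entry per market.
#' @export
degree_sequences <- function(network, mode = c("neighbors", "movements"),
                             direction = c("all", "in", "out")) {
  stopifnot(inherits(network, "trade_network"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  g <- network$graph
  if (mode == "neighbors") {
    if (direction == "all") {
      gu <- undirected_simplification(network)
      d <- igraph::degree(gu)
    } else {
      d <- igraph::degree(g, mode = direction)
    }
  } else {
    w <- igraph::E(g)$movement_count
    d <- igraph::strength(g, mode = direction, weights = w)
  }
  stats::setNames(as.integer(round(d)), names(d))
}

# Undirected simple graph underlying a trade network: reciprocal links are
# merged, movement counts and volumes summed.
undirected_simplification <- function(network) {
  igraph::as_undirected(network$graph, mode = "collapse",
                        edge.attr.comb = list(movement_count = "sum",
                                              animal_volume = "sum"))
}

# ---- import / export ------------------------------------------------------

#' Export a trade network
#'
#' @param network A `trade_network`.
#' @param path Output path.
#' @param format `"csv"` (edge list `from,to,movement_count,animal_volume`)
#'   or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network$graph, what = "edges")
    write.csv(el, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Import a trade network written by [export_network()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"graphml"`.
#' @param year_label Year label for the imported network.
#' @return A `trade_network`.
#' @export
import_network <- function(path, format = c("csv", "graphml"),
                           year_label = "overall") {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::V(g)$name <- igraph::V(g)$name %||% as.character(igraph::V(g))
    return(new_trade_network(g, year_label))
  }
  el <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "movement_count", "animal_volume") %in%
                  names(el)))
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  new_trade_network(g, year_label)
}
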
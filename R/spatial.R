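# Spatial propinquity: are trading market pairs geographically closer
# than non-trading pairs? Great-circle distances plus a one-sided
# Mann-Whitney rank test.

IUGG_EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between two points
#'
#' Haversine distance in kilometres. Coordinates are `(lat, lon)` in
#' decimal degrees; the Earth radius defaults to the IUGG mean radius.
#'
#' @param a,b Numeric vectors `c(lat, lon)`.
#' @param radius_km Sphere radius in km.
#' @return Distance in km.
#' @export
haversine_km <- function(a, b, radius_km = IUGG_EARTH_RADIUS_KM) {
  check_coord <- function(p) {
    if (length(p) != 2L || any(!is.finite(p)) || abs(p[1]) > 90 ||
        abs(p[2]) > 180) {
      stop("coordinates must be finite c(lat, lon) with lat in [-90, 90], lon in [-180, 180]",
           call. = FALSE)
    }
  }
  check_coord(a)
  check_coord(b)
  # geosphere expects (lon, lat) and metres
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                           r = radius_km * 1000) / 1000
}

# All-pairs haversine distance matrix (km) for coordinate vectors.
haversine_matrix <- function(lat, lon, radius_km = IUGG_EARTH_RADIUS_KM) {
  pts <- cbind(lon, lat)
  d_m <- geosphere::distm(pts, fun = geosphere::distHaversine)
  # distm uses geosphere's default radius (6378137 m); rescale and convert to km
  d_m * radius_km / 6378137
}

#' One-sided Mann-Whitney test
#'
#' Tests whether `group_y` is stochastically larger than `group_x`
#' (alternative: positive location shift of `y` relative to `x`). The U
#' statistic uses midranks for ties. The p-value is computed by exact
#' enumeration of all label assignments (conditional on the observed
#' ties) when both groups have at most `exact_threshold` observations,
#' and otherwise by the normal approximation with continuity and tie
#' correction, matching the convention of [stats::wilcox.test()].
#'
#' @param group_x,group_y Numeric vectors, both nonempty.
#' @param exact_threshold Use exact enumeration when both group sizes are
#'   at most this value.
#' @return List with elements `u` (U statistic of `group_x`), `p`
#'   (one-sided p-value) and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_one_sided <- function(group_x, group_y, exact_threshold = 10L) {
  x <- as.numeric(group_x)
  y <- as.numeric(group_y)
  if (!length(x) || !length(y)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (nx <= exact_threshold && ny <= exact_threshold) {
    # enumerate every way of labelling nx of the pooled values as group x;
    # small values of U favour the alternative (y shifted upward)
    sets <- combn(nx + ny, nx)
    u_all <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(u_all <= u + 1e-9)
    return(list(u = u, p = p, method = "exact"))
  }
  n <- nx + ny
  ties <- table(pooled)
  sigma2 <- (nx * ny / 12) *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - nx * ny / 2 + 0.5) / sqrt(sigma2)
  list(u = u, p = pnorm(z), method = "normal")
}

#' Propinquity test of a trade network
#'
#' Partitions all unordered pairs of the network's markets into linked
#' (the pair traded in at least one direction) and unlinked pairs, and
#' applies the one-sided Mann-Whitney test of whether the distances
#' separating unlinked pairs are stochastically larger than those
#' separating linked pairs. A small p-value means trading markets are
#' significantly closer to each other than non-trading markets.
#'
#' @param network A `trade_network`.
#' @param nodes A `market_nodes` data frame covering every network node.
#' @param dist_matrix Optional precomputed distance matrix over
#'   `nodes$code` (used by the ensemble machinery to avoid recomputation).
#' @param exact_threshold Passed to [mann_whitney_one_sided()].
#' @return A list of class `propinquity_result`: `u_statistic`, `p_value`,
#'   `n_linked_pairs`, `n_unlinked_pairs`, `median_linked_km`,
#'   `median_unlinked_km`.
#' @export
propinquity_test <- function(network, nodes, dist_matrix = NULL,
                             exact_threshold = 10L) {
  stopifnot(inherits(network, "trade_network"))
  g <- network$graph
  codes <- igraph::V(g)$name
  missing <- setdiff(codes, nodes$code)
  if (length(missing)) {
    stop(sprintf("no coordinates for market(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  idx <- match(codes, nodes$code)
  if (is.null(dist_matrix)) {
    d <- haversine_matrix(nodes$lat[idx], nodes$lon[idx])
  } else {
    d <- dist_matrix[idx, idx]
  }
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  linked_mask <- (adj | t(adj))[upper.tri(adj)]
  dvec <- d[upper.tri(d)]
  linked <- dvec[linked_mask]
  unlinked <- dvec[!linked_mask]
  if (!length(unlinked)) {
    stop("every pair of markets trades: no unlinked pairs to compare",
         call. = FALSE)
  }
  if (!length(linked)) {
    stop("network has no linked pairs", call. = FALSE)
  }
  mw <- mann_whitney_one_sided(linked, unlinked,
                               exact_threshold = exact_threshold)
  structure(list(
    u_statistic = mw$u, p_value = mw$p,
    n_linked_pairs = length(linked), n_unlinked_pairs = length(unlinked),
    median_linked_km = stats::median(linked),
    median_unlinked_km = stats::median(unlinked),
    method = mw$method
  ), class = "propinquity_result")
}

#' @export
print.propinquity_result <- function(x, ...) {
  cat(sprintf(
    "<propinquity> p = %.3g (%s), linked pairs %d (median %.0f km), unlinked %d (median %.0f km)\n",
    x$p_value, x$method, x$n_linked_pairs, x$median_linked_km,
    x$n_unlinked_pairs, x$median_unlinked_km))
  invisible(x)
}
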
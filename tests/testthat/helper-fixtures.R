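# Builders for small in-code fixtures used across the tests.

# Movement table straight from an edge data frame (one row per movement).
make_table <- function(from, to, fromc = "C01", toc = "C01",
                       month = "2015-03", heads = 10, type = "cattle",
                       transp = "vehicle") {
  n <- length(from)
  df <- data.frame(
    from = from, to = to,
    fromc = rep_len(fromc, n), toc = rep_len(toc, n),
    dmonth = rep_len(month, n), type = rep_len(type, n),
    weight = rep_len(heads, n), transp = rep_len(transp, n),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  on.exit(unlink(path))
  read_edge_list(path)
}

# Trade network from explicit directed edges.
make_network <- function(from, to, movements = 1, heads = 10,
                         year = "overall") {
  moves <- rep(seq_along(from), times = rep_len(movements, length(from)))
  build_network(make_table(from[moves], to[moves], heads = heads),
                year_label = year)
}

# Node table with coordinates for the named markets.
make_nodes <- function(codes, lat, lon, country = "C01") {
  structure(data.frame(
    code = codes, name = codes, country = rep_len(country, length(codes)),
    lat = lat, lon = lon,
    is_survey_point = FALSE, border_within_50km = FALSE, is_urban = FALSE,
    stringsAsFactors = FALSE
  ), class = c("market_nodes", "data.frame"))
}

# Random simple directed graph as a trade_network, for oracle comparisons.
random_network <- function(n, p, seed) {
  set.seed(seed)
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(pairs) == 0L) pairs <- data.frame(from = 1L, to = 2L)
  make_network(sprintf("N%02d", pairs$from), sprintf("N%02d", pairs$to))
}

small_synthetic_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_markets = 60L, n_hubs = 5L,
                   monthly_volume = 120, period = c("2015-01", "2016-12"),
                   tabaski_months = c("2015-09", "2016-09"), ...)
}
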
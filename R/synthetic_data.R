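# Seeded generator of synthetic survey data with the statistical structure
# the analysis assumes: hub-dominated, spatially decaying trade between
# markets scattered over a West-Africa-like bounding box, four livestock
# types with realistic proportions, a pre-Tabaski sheep peak and three
# transport modes. Used throughout the tests and the bundled pipeline runs
# in place of the original (non-redistributable) survey records.

#' Configuration for the synthetic survey-data generator
#'
#' Defaults emulate the regional livestock-trade setting the package
#' targets: roughly two hundred markets in a West-African bounding box,
#' five countries as longitude bands, a small number of hub markets that
#' dominate trade, distance-decaying partner choice (planting propinquity
#' and disassortativity), movement volumes and category proportions at the
#' scale of the 2013-2017 survey period (about 375 raw entries per month;
#' cattle roughly three quarters of movements, vehicle transport
#' dominant), and a sheep peak in the two months before each Tabaski
#' festival.
#'
#' @param seed Master seed; all generator randomness derives from it.
#' @param n_markets Number of markets.
#' @param n_countries Number of countries (longitude bands).
#' @param bbox Named vector `c(lon_min, lat_min, lon_max, lat_max)` in
#'   decimal degrees.
#' @param n_hubs Number of hub markets (must be < `n_markets`).
#' @param hub_attachment_bias Multiplicative sampling weight of a hub as
#'   trade partner or survey point; `>= 0`, `0` removes hub structure.
#' @param distance_decay_km e-folding distance of partner choice in km;
#'   larger values weaken the planted propinquity.
#' @param monthly_volume Mean raw entries per month (Poisson).
#' @param livestock_mix Named probabilities over
#'   `cattle, goat, sheep, donkey`; must sum to 1.
#' @param transport_mix Named probabilities over `vehicle, foot, train`;
#'   must sum to 1.
#' @param tabaski_months Character vector of `"YYYY-MM"` festival months.
#' @param sheep_peak_multiplier Factor (`>= 1`) applied to the sheep
#'   probability in the two months preceding each Tabaski month.
#' @param partner_pool_hub,partner_pool Mean number of persistent trade
#'   partners (per direction) of hub and non-hub survey markets. Trade
#'   runs along persistent corridors: most entries pick their origin and
#'   destination from these fixed pools, which keeps the networks sparse
#'   with heavily repeated links, as observed in regional trade data.
#' @param flow_gradient_deg Latitude scale (degrees) of the north-to-south
#'   flow bias: origins are preferentially drawn from markets north of
#'   the survey point and destinations from markets south of it, making
#'   trade largely one-directional (small strongly connected components).
#'   `Inf` disables the bias.
#' @param exploration_rate Fraction of legs sampled from the full
#'   hub-and-distance-weighted distribution instead of the pool,
#'   producing occasional one-off links.
#' @param missing_endpoint_rate Fraction of entries with a missing origin
#'   or destination, to exercise the preprocessing filters.
#' @param origin_at_survey_rate Fraction of entries whose origin (or
#'   destination) coincides with the survey point, exercising the
#'   split rule that suppresses the degenerate leg.
#' @param period Character vector `c(first, last)` month, `"YYYY-MM"`.
#' @param heads_meanlog,heads_sdlog Log-normal parameters of the scaled
#'   animal count per entry.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_markets = 200L,
                             n_countries = 5L,
                             bbox = c(lon_min = -12, lat_min = 5,
                                      lon_max = 8, lat_max = 16),
                             n_hubs = 12L,
                             hub_attachment_bias = 2,
                             distance_decay_km = 200,
                             monthly_volume = 375,
                             livestock_mix = c(cattle = 0.74, goat = 0.06,
                                               sheep = 0.195, donkey = 0.005),
                             transport_mix = c(vehicle = 0.94, foot = 0.045,
                                               train = 0.015),
                             tabaski_months = c("2013-10", "2014-10",
                                                "2015-09", "2016-09",
                                                "2017-09"),
                             sheep_peak_multiplier = 3,
                             partner_pool_hub = 8,
                             partner_pool = 1.5,
                             flow_gradient_deg = 1.5,
                             exploration_rate = 0.04,
                             missing_endpoint_rate = 0.05,
                             origin_at_survey_rate = 0.05,
                             period = c("2013-01", "2017-08"),
                             heads_meanlog = 3, heads_sdlog = 1) {
  stopifnot(n_hubs < n_markets, n_countries >= 1,
            hub_attachment_bias >= 0, distance_decay_km > 0,
            sheep_peak_multiplier >= 1,
            missing_endpoint_rate >= 0, missing_endpoint_rate < 1,
            bbox["lon_max"] > bbox["lon_min"],
            bbox["lat_max"] > bbox["lat_min"])
  if (abs(sum(livestock_mix) - 1) > 1e-8 || abs(sum(transport_mix) - 1) > 1e-8) {
    stop("livestock_mix and transport_mix must each sum to 1", call. = FALSE)
  }
  stopifnot(identical(sort(names(livestock_mix)), sort(CANONICAL_LIVESTOCK)),
            identical(sort(names(transport_mix)), sort(CANONICAL_TRANSPORT)))
  structure(as.list(environment()), class = "synthetic_config")
}

month_sequence <- function(period) {
  first <- parse_month(period[1])
  last <- parse_month(period[2])
  stopifnot(!is.na(first), !is.na(last), first <= last)
  format_month(seq(first, last, by = "month"))
}

#' Generate a synthetic market node list
#'
#' Markets are placed uniformly in the bounding box; countries are
#' longitude bands; `n_hubs` markets are flagged as hubs and (together
#' with a deterministic subset of the rest) as survey points; the border
#' flag marks markets within 50 km of a country-band boundary, computed on
#' the synthetic geometry; hubs and a random tenth of markets are flagged
#' urban. Hubs are chosen by farthest-point dispersal (each hub maximises
#' the minimum distance to the hubs already chosen), reflecting that
#' regional trade hubs serve geographically separate catchments. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `market_nodes` data frame with an extra logical `is_hub`
#'   column.
#' @export
generate_markets <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_markets
  b <- config$bbox
  code <- sprintf("M%03d", seq_len(n))
  lon <- round(runif(n, b["lon_min"], b["lon_max"]), 5)
  lat <- round(runif(n, b["lat_min"], b["lat_max"]), 5)
  breaks <- seq(b["lon_min"], b["lon_max"], length.out = config$n_countries + 1)
  band <- findInterval(lon, breaks, rightmost.closed = TRUE)
  country <- sprintf("C%02d", band)
  # farthest-point dispersal: hubs spread out over the study area
  dmat <- haversine_matrix(lat, lon)
  hubs <- sample.int(n, 1L)
  while (length(hubs) < config$n_hubs) {
    min_d <- apply(dmat[, hubs, drop = FALSE], 1, min)
    min_d[hubs] <- -1
    hubs <- c(hubs, which.max(min_d))
  }
  is_hub <- seq_len(n) %in% hubs
  # survey points: all hubs plus every eighth non-hub market
  is_survey <- is_hub
  non_hub <- which(!is_hub)
  is_survey[non_hub[seq_along(non_hub) %% 8L == 0L]] <- TRUE
  # border flag: within 50 km of an interior band meridian at own latitude
  interior <- breaks[-c(1, length(breaks))]
  border <- vapply(seq_len(n), function(i) {
    if (!length(interior)) return(FALSE)
    d <- vapply(interior, function(m) {
      haversine_km(c(lat[i], lon[i]), c(lat[i], m))
    }, numeric(1))
    any(d <= 50)
  }, logical(1))
  is_urban <- is_hub | (runif(n) < 0.1)
  structure(data.frame(
    code = code, name = code, country = country, lat = lat, lon = lon,
    is_survey_point = is_survey, border_within_50km = border,
    is_urban = is_urban, is_hub = is_hub, stringsAsFactors = FALSE
  ), class = c("market_nodes", "data.frame"))
}

#' Generate synthetic raw survey entries
#'
#' Each entry picks a survey point (hub-biased). Its origin and
#' destination come from the survey point's persistent partner pools --
#' fixed sets of markets drawn once per survey point with probability
#' proportional to
#' `hub_attachment_bias^is_hub * exp(-distance / distance_decay_km)` --
#' or, with probability `exploration_rate`, directly from that weighted
#' distribution. This plants disassortativity (hub survey points with
#' large pools trade with many peripheral markets), propinquity (partner
#' weight decays with distance) and the corridor structure of regional
#' trade (few, heavily repeated links). Livestock type follows `livestock_mix` with the sheep probability
#' multiplied by `sheep_peak_multiplier` in the two months before each
#' Tabaski month; transport follows `transport_mix`; heads are
#' log-normal. A configurable fraction of entries has a missing origin or
#' destination.
#'
#' @param config A [synthetic_config()].
#' @param markets Node list from [generate_markets()].
#' @return A data frame of raw entries (`origin`, `survey`, `destination`,
#'   `dmonth`, `type`, `heads`, `transp`) of class `raw_survey_entries`.
#' @export
generate_movements <- function(config, markets) {
  stopifnot(inherits(config, "synthetic_config"),
            is.data.frame(markets), "is_hub" %in% names(markets))
  set.seed(config$seed + 1L)
  months <- month_sequence(config$period)
  n_mkt <- nrow(markets)
  survey_idx <- which(markets$is_survey_point)
  hub_w <- ifelse(markets$is_hub, config$hub_attachment_bias, 1)
  hub_w_survey <- hub_w[survey_idx]
  dist_mat <- haversine_matrix(markets$lat, markets$lon)
  decay <- exp(-dist_mat / config$distance_decay_km)
  # partner weight of market j seen from survey point s; the flow
  # gradient biases origins northward and destinations southward
  partner_w <- sweep(decay, 2, hub_w, `*`)
  diag(partner_w) <- 0
  lat_diff <- outer(markets$lat, markets$lat, function(a, b) b - a)  # j - s
  north_bias <- exp(pmin(lat_diff / config$flow_gradient_deg, 20))
  partner_w_in <- partner_w * north_bias      # origins lie north of s
  partner_w_out <- partner_w / north_bias     # destinations lie south of s

  # persistent corridor pools, drawn once per survey point and direction
  draw_pool <- function(si, mean_size, w) {
    size <- max(1L, min(rpois(1L, mean_size), n_mkt - 1L))
    sample.int(n_mkt, size, prob = w[si, ])
  }
  pool_mean <- ifelse(markets$is_hub[survey_idx], config$partner_pool_hub,
                      config$partner_pool)
  pool_in <- lapply(seq_along(survey_idx),
                    function(i) draw_pool(survey_idx[i], pool_mean[i],
                                          partner_w_in))
  pool_out <- lapply(seq_along(survey_idx),
                     function(i) draw_pool(survey_idx[i], pool_mean[i],
                                           partner_w_out))
  names(pool_in) <- names(pool_out) <- as.character(survey_idx)

  # sheep probability is boosted in the two months before each festival
  peak_months <- unlist(lapply(parse_month(config$tabaski_months), function(m) {
    format_month(seq(m, by = "-1 month", length.out = 3L)[2:3])
  }))
  base_mix <- config$livestock_mix[CANONICAL_LIVESTOCK]
  peak_mix <- base_mix
  peak_mix["sheep"] <- peak_mix["sheep"] * config$sheep_peak_multiplier
  peak_mix <- peak_mix / sum(peak_mix)

  out <- vector("list", length(months))
  for (mi in seq_along(months)) {
    n_entries <- rpois(1L, config$monthly_volume)
    if (n_entries == 0L) next
    s <- survey_idx[sample.int(length(survey_idx), n_entries, replace = TRUE,
                               prob = hub_w_survey)]
    pick_partner <- function(si, pools, w) {
      if (runif(1L) < config$exploration_rate) {
        sample.int(n_mkt, 1L, prob = w[si, ])
      } else {
        pool <- pools[[as.character(si)]]
        pool[sample.int(length(pool), 1L)]
      }
    }
    o <- vapply(s, pick_partner, integer(1), pools = pool_in,
                w = partner_w_in)
    d <- vapply(s, pick_partner, integer(1), pools = pool_out,
                w = partner_w_out)
    # degenerate legs: occasionally the entry starts or ends at the survey point
    at_survey <- runif(n_entries) < config$origin_at_survey_rate
    side <- runif(n_entries) < 0.5
    o[at_survey & side] <- s[at_survey & side]
    d[at_survey & !side] <- s[at_survey & !side]
    mix <- if (months[mi] %in% peak_months) peak_mix else base_mix
    type <- sample(names(mix), n_entries, replace = TRUE, prob = mix)
    transp <- sample(names(config$transport_mix), n_entries, replace = TRUE,
                     prob = config$transport_mix)
    origin <- markets$code[o]
    destination <- markets$code[d]
    miss <- runif(n_entries) < config$missing_endpoint_rate
    miss_side <- runif(n_entries) < 0.5
    origin[miss & miss_side] <- NA_character_
    destination[miss & !miss_side] <- NA_character_
    out[[mi]] <- data.frame(
      origin = origin, survey = markets$code[s], destination = destination,
      dmonth = months[mi], type = type,
      heads = round(rlnorm(n_entries, config$heads_meanlog,
                           config$heads_sdlog), 2),
      transp = transp, stringsAsFactors = FALSE
    )
  }
  entries <- do.call(rbind, out)
  rownames(entries) <- NULL
  structure(entries, class = c("raw_survey_entries", "data.frame"))
}

#' Run the preprocessing pipeline on raw entries
#'
#' Convenience wrapper: split entries at the survey point, then filter to
#' complete, mapped, non-self-loop movements.
#'
#' @param entries Raw entries from [generate_movements()].
#' @param markets Node list from [generate_markets()].
#' @return A filtered `movement_table`.
#' @export
preprocess_entries <- function(entries, markets) {
  filter_movements(split_survey_entries(entries, markets), markets$code)
}

#' Write a synthetic fixture to disk
#'
#' Emits the raw-entry CSV plus the post-split, post-filter edge list and
#' the node list in the canonical dialect, so both input paths of the
#' reader are exercised.
#'
#' @param entries Raw entries.
#' @param markets Node list.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(entries, markets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  raw_path <- file.path(dir, "raw_entries.csv")
  edge_path <- file.path(dir, "edge_list.csv")
  node_path <- file.path(dir, "node_list.csv")
  write.csv(entries, raw_path, row.names = FALSE, quote = FALSE, na = "")
  table <- preprocess_entries(entries, markets)
  write_movement_table(table, edge_path)
  nodes_out <- data.frame(
    id = markets$code, name = markets$name, country = markets$country,
    lat = markets$lat, lon = markets$lon,
    survey = markets$is_survey_point, border = markets$border_within_50km,
    urban = markets$is_urban, stringsAsFactors = FALSE
  )
  write.csv(nodes_out, node_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(raw = raw_path, edges = edge_path, nodes = node_path))
}
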
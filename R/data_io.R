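# Reading, preprocessing and summarising livestock movement records.
#
# A movement record is one directed shipment between two markets in one
# calendar month. Raw survey entries instead describe an
# origin -> survey point -> destination triplet and must be split into up
# to two movements before network construction.

CANONICAL_LIVESTOCK <- c("cattle", "goat", "sheep", "donkey")
CANONICAL_TRANSPORT <- c("vehicle", "foot", "train")

#' Column dialect for movement edge lists
#'
#' Maps the canonical record fields onto the column names used in a CSV
#' edge list, and normalises category labels. The defaults follow the
#' variable names conventional in regional livestock-trade databases
#' (`from`, `to`, `fromc`, `toc`, `dmonth`, `type`, `weight`, `transp`,
#' `intl`).
#'
#' @param from,to Columns holding origin and destination market codes.
#' @param fromc,toc Columns holding origin and destination country codes.
#' @param dmonth Column holding the movement month (`"YYYY-MM"` or a date).
#' @param type Column holding the livestock type.
#' @param weight Column holding the (possibly scaled) number of animals.
#' @param transp Column holding the transport mode.
#' @param intl Column holding an international-movement flag, or `NULL` if
#'   absent. The flag is always recomputed from the country columns; a
#'   conflicting input value triggers a warning.
#' @param na_tokens Strings treated as missing values.
#' @param livestock_map,transport_map Named character vectors mapping
#'   (lower-cased) input labels to the canonical categories
#'   `r paste(CANONICAL_LIVESTOCK, collapse = ", ")` and
#'   `r paste(CANONICAL_TRANSPORT, collapse = ", ")`.
#' @return A list of class `herdnet_dialect`.
#' @export
edge_dialect <- function(from = "from", to = "to", fromc = "fromc",
                         toc = "toc", dmonth = "dmonth", type = "type",
                         weight = "weight", transp = "transp",
                         intl = "intl",
                         na_tokens = c("", "NA", "na", "."),
                         livestock_map = NULL, transport_map = NULL) {
  default_livestock <- c(
    cattle = "cattle", bovine = "cattle", cow = "cattle",
    goat = "goat", goats = "goat",
    sheep = "sheep", ovine = "sheep",
    donkey = "donkey", donkeys = "donkey"
  )
  default_transport <- c(
    vehicle = "vehicle", truck = "vehicle", car = "vehicle",
    foot = "foot", "on foot" = "foot", "on the hoof" = "foot", hoof = "foot",
    train = "train", rail = "train"
  )
  structure(list(
    from = from, to = to, fromc = fromc, toc = toc, dmonth = dmonth,
    type = type, weight = weight, transp = transp, intl = intl,
    na_tokens = na_tokens,
    livestock_map = c(livestock_map, default_livestock),
    transport_map = c(transport_map, default_transport)
  ), class = "herdnet_dialect")
}

#' Column dialect for market node lists
#'
#' @param code,name,country,lat,lon Column names for the market code,
#'   display name, country code and coordinates in decimal degrees.
#' @param is_survey_point,border_within_50km,is_urban Optional columns with
#'   logical annotations; `NULL` if absent (annotations default to `NA`).
#' @param na_tokens Strings treated as missing values.
#' @return A list of class `herdnet_dialect`.
#' @export
node_dialect <- function(code = "id", name = "name", country = "country",
                         lat = "lat", lon = "lon",
                         is_survey_point = "survey",
                         border_within_50km = "border",
                         is_urban = "urban",
                         na_tokens = c("", "NA", "na", ".")) {
  structure(list(
    code = code, name = name, country = country, lat = lat, lon = lon,
    is_survey_point = is_survey_point,
    border_within_50km = border_within_50km, is_urban = is_urban,
    na_tokens = na_tokens
  ), class = "herdnet_dialect")
}

# ---- movement_table -------------------------------------------------------

new_movement_table <- function(records, counters) {
  required <- c("from", "to", "fromc", "toc", "month", "type", "heads",
                "transp", "intl")
  stopifnot(all(required %in% names(records)))
  records$year <- as.integer(format(records$month, "%Y"))
  rownames(records) <- NULL
  structure(records,
            counters = counters,
            class = c("movement_table", "data.frame"))
}

default_counters <- function() {
  c(entries_read = 0L, records_split = 0L, dropped_incomplete = 0L,
    dropped_unparseable = 0L, dropped_bad_category = 0L,
    dropped_unmapped = 0L, dropped_self_loop = 0L)
}

#' Provenance counters of a movement table
#'
#' Every reader and filter updates a named integer vector recording how
#' many rows were read, split and dropped (and why), so that
#' `rows read = records retained + dropped` always holds.
#'
#' @param x A `movement_table`.
#' @return Named integer vector of counters.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "movement_table"))
  attr(x, "counters")
}

#' @export
print.movement_table <- function(x, ...) {
  cat(sprintf("<movement_table> %d movements, %s\n", nrow(x),
              if (nrow(x)) paste(format_month(range(x$month)), collapse = " to ")
              else "empty"))
  cnt <- provenance(x)
  cat("  counters:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
      "\n")
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}

normalize_category <- function(x, map) {
  unname(map[tolower(trimws(as.character(x)))])
}

resolve_cols <- function(df, dialect, fields) {
  cols <- unlist(dialect[fields])
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("column mapping unresolvable: %s not found in input (have: %s)",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  cols
}

blank_to_na <- function(x, na_tokens) {
  x <- trimws(as.character(x))
  x[x %in% na_tokens] <- NA_character_
  x
}

#' Read a movement edge list
#'
#' Parses a CSV edge list of directed livestock movements into a
#' [`movement_table`][provenance]. Every input row either becomes a
#' movement record or is counted as dropped with a reason (missing
#' endpoint, unparseable month, unknown category). Category labels are
#' normalised to the canonical sets and the international flag is
#' recomputed from the country columns (a conflicting input flag is
#' overridden with a warning).
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect An [edge_dialect()] mapping canonical fields to columns.
#' @return A `movement_table` (data frame of records plus provenance
#'   counters).
#' @export
read_edge_list <- function(path, dialect = edge_dialect()) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  counters <- default_counters()
  counters["entries_read"] <- nrow(df)
  fields <- c("from", "to", "fromc", "toc", "dmonth", "type", "weight",
              "transp")
  resolve_cols(df, dialect, fields)
  if (nrow(df) == 0L) {
    return(new_movement_table(empty_records(), counters))
  }
  rec <- data.frame(
    from = blank_to_na(df[[dialect$from]], dialect$na_tokens),
    to = blank_to_na(df[[dialect$to]], dialect$na_tokens),
    fromc = blank_to_na(df[[dialect$fromc]], dialect$na_tokens),
    toc = blank_to_na(df[[dialect$toc]], dialect$na_tokens),
    month = parse_month(df[[dialect$dmonth]]),
    type = normalize_category(df[[dialect$type]], dialect$livestock_map),
    heads = suppressWarnings(as.numeric(df[[dialect$weight]])),
    transp = normalize_category(df[[dialect$transp]], dialect$transport_map),
    stringsAsFactors = FALSE
  )

  incomplete <- is.na(rec$from) | is.na(rec$to)
  bad_month <- !incomplete & is.na(rec$month)
  bad_cat <- !incomplete & !bad_month &
    (is.na(rec$type) | is.na(rec$transp) | is.na(rec$heads) | rec$heads <= 0)
  keep <- !(incomplete | bad_month | bad_cat)
  counters["dropped_incomplete"] <- sum(incomplete)
  counters["dropped_unparseable"] <- sum(bad_month)
  counters["dropped_bad_category"] <- sum(bad_cat)
  rec <- rec[keep, , drop = FALSE]

  rec$intl <- rec$fromc != rec$toc
  if (!is.null(dialect$intl) && dialect$intl %in% names(df)) {
    given <- tolower(blank_to_na(df[[dialect$intl]], dialect$na_tokens))[keep]
    given_lgl <- given %in% c("true", "1", "yes", "international", "intl")
    conflict <- !is.na(given) & given_lgl != rec$intl
    if (any(conflict)) {
      warning(sprintf(
        "international flag recomputed from countries; %d input value(s) overridden",
        sum(conflict)))
    }
  }
  new_movement_table(rec, counters)
}

empty_records <- function() {
  data.frame(from = character(), to = character(), fromc = character(),
             toc = character(), month = as.Date(character()),
             type = character(), heads = numeric(), transp = character(),
             intl = logical(), stringsAsFactors = FALSE)
}

#' Read a market node list
#'
#' Parses a CSV node list into a data frame of geolocated markets.
#' Duplicate market codes are an error; rows with out-of-range or missing
#' coordinates are rejected (with a `rejected` attribute naming the
#' reasons).
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect A [node_dialect()].
#' @return A data frame of class `market_nodes` with columns `code`,
#'   `name`, `country`, `lat`, `lon`, `is_survey_point`,
#'   `border_within_50km`, `is_urban`.
#' @export
read_node_list <- function(path, dialect = node_dialect()) {
  stopifnot(file.exists(path))
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  resolve_cols(df, dialect, c("code", "country", "lat", "lon"))
  opt_lgl <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(df)) {
      as.logical(df[[col]])
    } else {
      rep(NA, nrow(df))
    }
  }
  nodes <- data.frame(
    code = blank_to_na(df[[dialect$code]], dialect$na_tokens),
    name = if (!is.null(dialect$name) && dialect$name %in% names(df)) {
      as.character(df[[dialect$name]])
    } else {
      blank_to_na(df[[dialect$code]], dialect$na_tokens)
    },
    country = blank_to_na(df[[dialect$country]], dialect$na_tokens),
    lat = suppressWarnings(as.numeric(df[[dialect$lat]])),
    lon = suppressWarnings(as.numeric(df[[dialect$lon]])),
    is_survey_point = opt_lgl("is_survey_point"),
    border_within_50km = opt_lgl("border_within_50km"),
    is_urban = opt_lgl("is_urban"),
    stringsAsFactors = FALSE
  )
  bad_coord <- is.na(nodes$lat) | is.na(nodes$lon) |
    abs(nodes$lat) > 90 | abs(nodes$lon) > 180
  bad_code <- is.na(nodes$code)
  rejected <- nodes$code[bad_coord & !bad_code]
  nodes <- nodes[!(bad_coord | bad_code), , drop = FALSE]
  dup <- duplicated(nodes$code)
  if (any(dup)) {
    stop(sprintf("duplicate market code(s) in node list: %s",
                 paste(unique(nodes$code[dup]), collapse = ", ")),
         call. = FALSE)
  }
  rownames(nodes) <- NULL
  structure(nodes, rejected = rejected,
            class = c("market_nodes", "data.frame"))
}

# ---- splitting raw survey entries ----------------------------------------

#' Split raw survey entries into movement records
#'
#' Each raw entry describes a shipment from an origin market through a
#' survey (data collection) market to a destination market. It is split
#' into up to two directed movements: origin to survey point and survey
#' point to destination. A leg is emitted only when its outer endpoint is
#' present and differs from the survey market, so splitting never creates
#' a self-loop. All attribute fields are copied to both emitted records.
#'
#' @param entries Data frame of raw entries with columns `origin`,
#'   `survey`, `destination`, `dmonth`, `type`, `heads`, `transp`
#'   (as produced by [generate_movements()] or read from a raw CSV).
#' @param nodes A `market_nodes` data frame used to resolve the country of
#'   each endpoint.
#' @return A `movement_table`; counters record entries read, records
#'   emitted and legs skipped because an endpoint was missing or equal to
#'   the survey market.
#' @export
split_survey_entries <- function(entries, nodes) {
  stopifnot(is.data.frame(entries),
            all(c("origin", "survey", "destination", "dmonth", "type",
                  "heads", "transp") %in% names(entries)))
  if (any(is.na(entries$survey))) {
    stop("survey market must be present in every raw entry", call. = FALSE)
  }
  country_of <- setNames(nodes$country, nodes$code)
  one_leg <- function(from, to, src) {
    ok <- !is.na(from) & !is.na(to) & from != to
    data.frame(
      from = from[ok], to = to[ok],
      fromc = unname(country_of[from[ok]]),
      toc = unname(country_of[to[ok]]),
      month = parse_month(src$dmonth)[ok],
      type = as.character(src$type)[ok],
      heads = as.numeric(src$heads)[ok],
      transp = as.character(src$transp)[ok],
      stringsAsFactors = FALSE
    )
  }
  origin <- as.character(entries$origin)
  survey <- as.character(entries$survey)
  destination <- as.character(entries$destination)
  inbound <- one_leg(origin, survey, entries)
  outbound <- one_leg(survey, destination, entries)
  rec <- rbind(inbound, outbound)
  rec$intl <- rec$fromc != rec$toc
  counters <- c(default_counters(), legs_missing_endpoint = 0L,
                legs_at_survey_point = 0L)
  counters["entries_read"] <- nrow(entries)
  counters["records_split"] <- nrow(rec)
  counters["legs_missing_endpoint"] <- sum(is.na(origin)) +
    sum(is.na(destination))
  counters["legs_at_survey_point"] <-
    sum(!is.na(origin) & origin == survey) +
    sum(!is.na(destination) & destination == survey)
  if (nrow(rec) == 0L) rec <- empty_records()
  new_movement_table(rec, counters)
}

#' Filter movements to complete, mapped, non-self-loop records
#'
#' Applies the preprocessing exclusions: records missing an endpoint,
#' records whose endpoint is not in the set of geolocatable markets, and
#' self-loops are dropped, each with its own provenance counter.
#'
#' @param table A `movement_table`.
#' @param geolocatable Character vector of market codes with known
#'   coordinates (typically `nodes$code`).
#' @return The filtered `movement_table` with updated counters.
#' @export
filter_movements <- function(table, geolocatable) {
  stopifnot(inherits(table, "movement_table"))
  counters <- provenance(table)
  rec <- as.data.frame(table)
  incomplete <- is.na(rec$from) | is.na(rec$to)
  unmapped <- !incomplete &
    (!(rec$from %in% geolocatable) | !(rec$to %in% geolocatable))
  self_loop <- !incomplete & !unmapped & rec$from == rec$to
  counters["dropped_incomplete"] <- counters["dropped_incomplete"] +
    sum(incomplete)
  counters["dropped_unmapped"] <- counters["dropped_unmapped"] + sum(unmapped)
  counters["dropped_self_loop"] <- counters["dropped_self_loop"] +
    sum(self_loop)
  keep <- !(incomplete | unmapped | self_loop)
  new_movement_table(rec[keep, , drop = FALSE], counters)
}

# ---- summaries ------------------------------------------------------------

#' Summarise movements along one dimension
#'
#' Produces the descriptive breakdowns used to characterise a movement
#' dataset: counts and percentages by movement type
#' (international/national), livestock type, transport mode, origin or
#' destination country, or a month-by-livestock time series suitable for
#' seasonality plots.
#'
#' @param table A `movement_table`.
#' @param dimension One of `"movement-type"`, `"livestock"`,
#'   `"transport"`, `"origin-country"`, `"destination-country"`,
#'   `"month-livestock"`.
#' @return A data frame with columns `category` (or `month` + `type`),
#'   `n` and (except for the time series) `pct`. Percentages over a
#'   partition sum to 100. An empty table yields an empty summary rather
#'   than a division by zero.
#' @export
summarize_movements <- function(table,
                                dimension = c("movement-type", "livestock",
                                              "transport", "origin-country",
                                              "destination-country",
                                              "month-livestock")) {
  stopifnot(inherits(table, "movement_table"))
  dimension <- match.arg(dimension)
  rec <- as.data.frame(table)
  if (dimension == "month-livestock") {
    if (nrow(rec) == 0L) {
      return(data.frame(month = character(), type = character(),
                        n = integer(), stringsAsFactors = FALSE))
    }
    tab <- as.data.frame(table(month = format_month(rec$month),
                               type = rec$type), stringsAsFactors = FALSE)
    names(tab)[3] <- "n"
    tab <- tab[order(tab$month, tab$type), ]
    rownames(tab) <- NULL
    return(tab)
  }
  key <- switch(dimension,
    "movement-type" = ifelse(rec$intl, "international", "national"),
    "livestock" = rec$type,
    "transport" = rec$transp,
    "origin-country" = rec$fromc,
    "destination-country" = rec$toc
  )
  if (nrow(rec) == 0L) {
    return(data.frame(category = character(), n = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  counts <- sort(table(key), decreasing = TRUE)
  data.frame(category = names(counts), n = as.integer(counts),
             pct = 100 * as.integer(counts) / nrow(rec),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- canonical CSV round trip --------------------------------------------

#' Write a movement table to the canonical CSV dialect
#'
#' Columns `from,to,fromc,toc,dmonth,type,weight,transp,intl`, months as
#' `"YYYY-MM"`. Reading the file back with [read_edge_list()] restores the
#' records exactly.
#'
#' @param table A `movement_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movement_table <- function(table, path) {
  stopifnot(inherits(table, "movement_table"))
  rec <- as.data.frame(table)
  out <- data.frame(
    from = rec$from, to = rec$to, fromc = rec$fromc, toc = rec$toc,
    dmonth = format_month(rec$month), type = rec$type, weight = rec$heads,
    transp = rec$transp, intl = tolower(as.character(rec$intl)),
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write provenance counters as JSON
#'
#' @param table A `movement_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(table, path) {
  jsonlite::write_json(as.list(provenance(table)), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
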
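# Internal helpers shared across modules.

# Signal that a metric is not defined for this input (e.g. diameter of an
# edgeless graph, closeness centralization of a disconnected graph).
# Returns NA_real_ so reports can carry the gap, with a classed warning so
# callers can distinguish "undefined" from a genuine zero.
undefined_metric <- function(metric, reason) {
  warning(warningCondition(
    sprintf("metric '%s' is undefined: %s", metric, reason),
    class = "herdnet_undefined_metric"
  ))
  NA_real_
}

# Month strings are stored as "YYYY-MM" throughout; parse to a Date on the
# first of the month. Accepts "YYYY-MM" and "YYYY-MM-DD"; anything else is NA.
parse_month <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  if (!length(x)) return(out)
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  out[ym] <- as.Date(paste0(x[ym], "-01"))
  ymd <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ymd] <- as.Date(x[ymd])
  if (any(ymd)) out[ymd] <- as.Date(format(out[ymd], "%Y-%m-01"))
  out
}

format_month <- function(d) format(d, "%Y-%m")

# Derive independent replicate seeds from one master seed. Keeps every seed
# a valid 32-bit integer so runs reproduce across platforms.
replicate_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
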
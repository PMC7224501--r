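# End-to-end orchestration: from an edge/node list pair or a synthetic
# configuration to the full set of report artifacts.

#' Pipeline run configuration
#'
#' Exactly one input source must be active: either paths to an edge list
#' and node list CSV, or a [synthetic_config()].
#'
#' @param edges,nodes Paths to CSV inputs (processed movement data).
#' @param synthetic A `synthetic_config` for generated data.
#' @param years Years to analyse; default all years present.
#' @param community_year Year whose network is used for community
#'   detection and node-level metrics; default the most recent year.
#' @param ensemble_size Configuration-model ensemble size.
#' @param n_boot Bootstrap replicates for the degree-distribution
#'   goodness of fit.
#' @param seed Master seed for ensembles and bootstrap.
#' @param out_dir Output directory for artifacts.
#' @param density_divisor,transitivity_variant,assortativity_convention,
#'   community_weighted Metric variants.
#' @param edge_dialect,node_dialect Input dialects.
#' @return A list of class `run_config`.
#' @export
run_config <- function(edges = NULL, nodes = NULL, synthetic = NULL,
                       years = NULL, community_year = NULL,
                       ensemble_size = 1000L, n_boot = 1000L, seed = 1L,
                       out_dir = "herdnet-run",
                       density_divisor = "n(n-1)",
                       transitivity_variant = "average-local",
                       assortativity_convention = "directed-out-in",
                       community_weighted = FALSE,
                       edge_dialect = herdnet::edge_dialect(),
                       node_dialect = herdnet::node_dialect()) {
  real <- !is.null(edges) || !is.null(nodes)
  synth <- !is.null(synthetic)
  if (real == synth) {
    stop("exactly one of (edges + nodes, synthetic) must be given",
         call. = FALSE)
  }
  if (real && (is.null(edges) || is.null(nodes))) {
    stop("both edges and nodes paths are required for file input",
         call. = FALSE)
  }
  structure(as.list(environment())[!(names(as.list(environment())) %in%
                                       c("real", "synth"))],
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `synthetic`
#' mapping is passed to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Preprocesses the input (or generates synthetic data), builds yearly
#' and overall networks, and writes: movement summary
#' (`table_summary.csv`), per-year metric report (`table_metrics.csv`),
#' ensemble z-scores (`table_zscores.csv`), component sizes
#' (`table_components.csv`), key markets (`table_key_markets.csv`),
#' degree-distribution fits (`degree_fit.json`), community memberships
#' (`communities.csv`) and a provenance record (`provenance.json`).
#'
#' @param config A `run_config` (or path to a YAML file).
#' @return Invisibly, a list with the in-memory results (`table`,
#'   `nodes`, `networks`, `overall`, `reports`, `ensembles`, `fits`,
#'   `communities`, `artifacts`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)

  if (!is.null(config$synthetic)) {
    markets <- generate_markets(config$synthetic)
    entries <- generate_movements(config$synthetic, markets)
    table <- preprocess_entries(entries, markets)
    nodes <- markets
  } else {
    table <- read_edge_list(config$edges, config$edge_dialect)
    nodes <- read_node_list(config$nodes, config$node_dialect)
    table <- filter_movements(table, nodes$code)
  }

  summary_dims <- c("movement-type", "livestock", "transport",
                    "origin-country", "destination-country")
  summaries <- do.call(rbind, lapply(summary_dims, function(d) {
    s <- summarize_movements(table, d)
    if (nrow(s)) cbind(dimension = d, s) else NULL
  }))
  write.csv(summaries, art("table_summary.csv"), row.names = FALSE)

  networks <- build_yearly_networks(table, years = config$years)
  overall <- build_overall_network(table)
  reports <- lapply(networks, metric_report, nodes = nodes,
                    density_divisor = config$density_divisor,
                    transitivity_variant = config$transitivity_variant,
                    assortativity_convention = config$assortativity_convention)
  metric_report_table(reports, art("table_metrics.csv"))

  ensembles <- lapply(seq_along(networks), function(i) {
    ensemble_report(networks[[i]], nodes, size = config$ensemble_size,
                    seed = config$seed + i, observed = reports[[i]])
  })
  names(ensembles) <- names(networks)
  ztab <- do.call(rbind, lapply(names(ensembles), function(y) {
    cbind(year = y, ensembles[[y]]$z,
          min_ensemble_propinquity_p =
            ensembles[[y]]$min_ensemble_propinquity_p)
  }))
  write.csv(ztab, art("table_zscores.csv"), row.names = FALSE)

  comp <- do.call(rbind, lapply(names(networks), function(y) {
    data.frame(year = y,
               gscc = connected_components(networks[[y]], "strong")[1],
               gwcc = connected_components(networks[[y]], "weak")[1],
               n = networks[[y]]$n, stringsAsFactors = FALSE)
  }))
  write.csv(comp, art("table_components.csv"), row.names = FALSE)

  key <- key_market_table(networks, nodes)
  write.csv(key, art("table_key_markets.csv"), row.names = FALSE)

  fits <- lapply(c(movements = "movements", links = "neighbors"),
                 function(mode) {
    seq_all <- degree_sequences(overall, mode, "all")
    fit_pl <- fit_discrete_power_law(seq_all)
    gof <- gof_pvalue(fit_pl, n_boot = config$n_boot, seed = config$seed)
    fit_ln <- fit_lognormal(seq_all, fit_pl$xmin)
    vuong <- vuong_compare(seq_all, fit_pl, fit_ln)
    list(xmin = fit_pl$xmin, alpha = fit_pl$alpha,
         ks = fit_pl$ks_statistic, gof_p = gof$p,
         lognormal_mu = fit_ln$mu, lognormal_sigma2 = fit_ln$sigma2,
         vuong_R = vuong$loglik_ratio_R, vuong_p = vuong$p_two_sided,
         favored = vuong$favored, n_tail = fit_pl$n_tail)
  })
  jsonlite::write_json(fits, art("degree_fit.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  cy <- config$community_year %||% names(networks)[length(networks)]
  comm <- fast_greedy_communities(networks[[cy]],
                                  weighted = config$community_weighted)
  write_communities(comm, nodes, art("communities.csv"))

  prov <- list(
    package_version = as.character(utils::packageVersion("herdnet")),
    seed = config$seed, ensemble_size = config$ensemble_size,
    n_boot = config$n_boot, community_year = cy,
    counters = as.list(provenance(table)),
    config = config[c("years", "density_divisor", "transitivity_variant",
                      "assortativity_convention", "community_weighted")],
    synthetic = if (!is.null(config$synthetic)) {
      config$synthetic[!vapply(config$synthetic, is.function, TRUE)]
    }
  )
  jsonlite::write_json(prov, art("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)

  invisible(list(table = table, nodes = nodes, networks = networks,
                 overall = overall, reports = reports,
                 ensembles = ensembles, fits = fits, communities = comm,
                 artifacts = list.files(config$out_dir, full.names = TRUE)))
}
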
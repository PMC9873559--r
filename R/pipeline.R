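#' Default pipeline configuration
#'
#' Desk-scale defaults: a 1-degree synthetic globe (180 x 360) with a
#' 500-draw Monte Carlo, so the full pipeline (synthetic data, sinking
#' optimisation, Monte Carlo, aggregation, sensitivity) completes in a few
#' minutes on one core; resolution and ensemble size are plain config knobs
#' (paper-scale runs would use 1/12 degree and n = 5,000). All values are
#' serialisable to YAML.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    grid = list(n_lat = 180, n_lon = 360, land_fraction = 0.3, seed = 1),
    env = list(n_ports = 20, seed = 2),
    yields = list(seed = 3),
    monte_carlo = list(n_sims = 500, scenario = "ambient", root_seed = 42),
    quantiles = c(5, 50, 95),
    supply = list(max_fraction = 0.01, benefit = "sinking"),
    sensitivity = list(outcome = "c_prod_cheap2", method = "gain"),
    out_dir = "seafarm_run"
  )
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  unname(tools::md5sum(tf))
}

validate_config <- function(config) {
  g <- config$grid
  if (is.null(g$n_lat) || is.null(g$n_lon) || g$n_lat < 8 || g$n_lon < 8) {
    stop2("config: grid must be at least 8 x 8")
  }
  mc <- config$monte_carlo
  if (is.null(mc$n_sims) || mc$n_sims < 1) {
    stop2("config: monte_carlo$n_sims must be >= 1")
  }
  if (!mc$scenario %in% c("ambient", "limited")) {
    stop2("config: scenario must be 'ambient' or 'limited'")
  }
  invisible(config)
}

#' Run the full technoeconomic pipeline
#'
#' Generates the synthetic domain, optimises sinking destinations with mean
#' parameters, runs the Monte Carlo ensemble, aggregates cheapest-area
#' statistics and supply curves, ranks parameter importance, and writes all
#' artifacts (text rasters, CSV tables, a JSON run report carrying the seed
#' and a config hash) under \code{config$out_dir}.
#'
#' @param config nested list as in \code{\link{default_config}}, or a path
#'   to a YAML file with the same structure.
#' @param quiet suppress stage messages.
#' @return list with the in-memory objects (\code{grid}, \code{env},
#'   \code{yields}, \code{assignment}, \code{ensemble}, \code{curves},
#'   \code{importance}) and \code{paths} of the written artifacts.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  validate_config(cfg)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)

  say("stage 1/5: synthetic domain")
  grid <- generate_ocean_grid(cfg$grid$n_lat, cfg$grid$n_lon,
                              cfg$grid$land_fraction, cfg$grid$seed)
  env <- generate_env_layers(grid, cfg$env$n_ports, cfg$env$seed)
  yields <- generate_yield_ensemble(grid, env, cfg$yields$seed)
  write_layers(grid,
               list(depth = env$depth, swh = env$swh, d_port = env$d_port,
                    f_seq = env$f_seq,
                    yield_med_ambient = yield_map(yields)$s_dw),
               p("layers.csv"),
               units = c(depth = "m", swh = "m", d_port = "km",
                         f_seq = "fraction",
                         yield_med_ambient = "tDW km-2 yr-1"),
               meta = list(config_hash = hash))

  say("stage 2/5: optimal sinking destinations (mean parameters)")
  ranges <- default_ranges()
  mean_sample <- mean_parameter_set(ranges)
  assignment <- optimal_sink_assignment(grid, env, yields, mean_sample)
  write_layers(grid, list(d_sink = assignment$d_sink,
                          q_assigned = assignment$q_assigned),
               p("sink_assignment.csv"),
               units = c(d_sink = "km", q_assigned = "fraction"),
               meta = list(config_hash = hash))

  say("stage 3/5: Monte Carlo ensemble (n = ", cfg$monte_carlo$n_sims, ")")
  ens <- run_ensemble(grid, env, yields, assignment,
                      n_sims = cfg$monte_carlo$n_sims,
                      scenario = cfg$monte_carlo$scenario,
                      root_seed = cfg$monte_carlo$root_seed,
                      ranges = ranges, quantiles = cfg$quantiles)
  write_parameter_csv(ens$params, p("parameters.csv"))
  write_parameter_csv(ens$summaries, p("sim_summaries.csv"))
  qlayers <- list()
  for (f in names(ens$quantile_maps)) {
    for (q in names(ens$quantile_maps[[f]])) {
      qlayers[[paste0(f, "_p", q)]] <- ens$quantile_maps[[f]][[q]]
    }
  }
  write_layers(grid, qlayers, p("cost_quantiles.csv"),
               meta = list(config_hash = hash))

  say("stage 4/5: aggregation")
  area <- grid$cell_area
  ocean_area <- sum(area[!grid$land_mask])
  med_sink <- ens$quantile_maps$c_pertonsink[["50"]]
  s_dw_med <- yield_map(yields, cfg$monte_carlo$scenario, 50)$s_dw
  mean_sim <- run_simulation(mean_sample, grid, env, yields, assignment,
                             cfg$monte_carlo$scenario)
  curves <- list(
    sinking = supply_curve(med_sink,
                           mean_sim$fields$e_sinknet * s_dw_med, area,
                           max_fraction = cfg$supply$max_fraction,
                           ocean_area = ocean_area),
    food = supply_curve(ens$quantile_maps$c_pertonprod_food[["50"]],
                        mean_sim$fields$e_prodnet_food * s_dw_med, area,
                        max_fraction = cfg$supply$max_fraction,
                        ocean_area = ocean_area)
  )
  write_supply_curve(curves$sinking, p("supply_curve_sinking.csv"))
  write_supply_curve(curves$food, p("supply_curve_food.csv"))

  say("stage 5/5: sensitivity")
  outcome <- ens$summaries[[cfg$sensitivity$outcome]]
  importance <- if (sum(is.finite(outcome)) >= 100) {
    rep <- parameter_importance(ens$params, outcome,
                                method = cfg$sensitivity$method)
    write.csv(rep$importance, p("importance.csv"), row.names = FALSE)
    rep
  } else {
    say("  too few usable simulations for importance ranking; skipped")
    NULL
  }

  report <- list(
    config = cfg, config_hash = hash,
    n_sims = ens$n_sims, scenario = ens$scenario,
    root_seed = cfg$monte_carlo$root_seed,
    ocean_area_km2 = ocean_area,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(grid = grid, env = env, yields = yields,
                 assignment = assignment, ensemble = ens, curves = curves,
                 importance = importance,
                 paths = list.files(cfg$out_dir, full.names = TRUE)))
}
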
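#' Evaluate every pathway for one economic sample
#'
#' Chains the full equation set on the grid: the drawn yield percentile of
#' the preferred type per cell, farm-gate production cost and emissions, the
#' sinking pathway at the precomputed optimal sinking assignment, and all
#' three product pathways.
#'
#' @param sample an \code{economic_sample}.
#' @param grid an \code{ocean_grid}.
#' @param env an \code{env_layers}.
#' @param yields a \code{yield_ensemble}.
#' @param sink_assignment a \code{sink_assignment} (computed once with mean
#'   parameters and shared across simulations).
#' @param scenario "ambient" or "limited".
#' @param constants output of \code{\link{sf_constants}}.
#' @return list of class \code{sim_result}: \code{production},
#'   \code{sinking}, \code{products} (per category), \code{s_dw},
#'   \code{fields} (named list of the headline per-cell maps).
#' @export
run_simulation <- function(sample, grid, env, yields, sink_assignment,
                           scenario = "ambient",
                           constants = sf_constants()) {
  ym <- yield_map(yields, scenario, sample$yield_percentile)
  layout <- farm_layout(ym$s_dw, ym$n_harv, ym$p_sline)
  prod <- production_fields(sample, layout, env$depth, env$swh, env$d_port)
  sink <- sinking_pathway(sample, prod, ym$s_dw, sink_assignment,
                          env$d_port, constants)
  prods <- lapply(product_categories(), function(cat) {
    product_pathway(sample, prod, ym$s_dw, env$d_port, cat, constants)
  })
  names(prods) <- product_categories()
  fields <- c(
    list(c_prod = prod$c_prod, c_pertonsink = sink$c_pertonsink,
         e_sinknet = sink$e_sinknet),
    stats::setNames(
      lapply(prods, `[[`, "c_pertonprod"),
      paste0("c_pertonprod_", product_categories())
    ),
    stats::setNames(
      lapply(prods, `[[`, "e_prodnet"),
      paste0("e_prodnet_", product_categories())
    )
  )
  structure(list(production = prod, sinking = sink, products = prods,
                 s_dw = ym$s_dw, scenario = scenario, fields = fields),
            class = "sim_result")
}

.default_ensemble_fields <- c("c_prod", "c_pertonsink", "c_pertonprod_food",
                              "c_pertonprod_feed", "c_pertonprod_fuel")

#' Run a Monte Carlo ensemble
#'
#' Draws \code{n_sims} independent economic samples (child seed per
#' simulation index, so results are order-independent), evaluates every
#' pathway per draw, and accumulates per-cell cost distributions and per-sim
#' scalar summaries (area-weighted mean production cost and benefit-weighted
#' mean $-per-ton costs within each simulation's cheapest 1% and 2% areas).
#'
#' @param grid,env,yields,sink_assignment shared inputs; the sinking
#'   assignment is computed once with mean parameters and reused.
#' @param n_sims number of simulations (>= 1).
#' @param scenario "ambient" or "limited".
#' @param root_seed integer; child seed per sim is \code{root_seed * 1000 +
#'   sim index} (keep \code{root_seed} modest).
#' @param ranges a \code{parameter_ranges} table.
#' @param fields per-cell maps whose across-sim distributions are stored.
#' @param quantiles percentile levels of the stored cost maps.
#' @param keep_values keep the full sims x cells matrices (needed by
#'   \code{\link{summarize_percentiles}} afterwards).
#' @param constants output of \code{\link{sf_constants}}.
#' @return object of class \code{ensemble_result}: \code{quantile_maps}
#'   (field -> level -> matrix), \code{params} (one row per sim),
#'   \code{summaries} (one row per sim), \code{values} (optional), plus the
#'   run metadata.
#' @export
run_ensemble <- function(grid, env, yields, sink_assignment, n_sims = 500,
                         scenario = "ambient", root_seed = 42,
                         ranges = default_ranges(),
                         fields = .default_ensemble_fields,
                         quantiles = c(5, 50, 95), keep_values = FALSE,
                         constants = sf_constants()) {
  if (n_sims < 1) stop2("n_sims must be >= 1")
  scenario <- match.arg(scenario, c("ambient", "limited"))
  oc <- which(!grid$land_mask)
  vals <- lapply(fields, function(f) {
    matrix(NA_real_, n_sims, length(oc))
  })
  names(vals) <- fields
  params <- vector("list", n_sims)
  summaries <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    child_seed <- (root_seed * 1000 + i) %% 2147483647L
    sample_i <- sample_parameters(ranges, seed = child_seed)
    sim <- run_simulation(sample_i, grid, env, yields, sink_assignment,
                          scenario, constants)
    for (f in fields) vals[[f]][i, ] <- sim$fields[[f]][oc]
    params[[i]] <- unlist(sample_i)
    summaries[[i]] <- sim_summary(sim, grid)
  }
  params <- as.data.frame(do.call(rbind, params))
  summaries <- as.data.frame(do.call(rbind, summaries))
  qmaps <- lapply(vals, function(v) {
    out <- lapply(quantiles, function(q) {
      m <- matrix(NA_real_, grid$n_lat, grid$n_lon)
      m[oc] <- col_nearest_rank(v, q)
      m
    })
    names(out) <- as.character(quantiles)
    out
  })
  structure(list(
    n_sims = n_sims, scenario = scenario, root_seed = root_seed,
    quantile_levels = quantiles, quantile_maps = qmaps, params = params,
    summaries = summaries, values = if (keep_values) vals,
    ocean_index = oc, grid = grid
  ), class = "ensemble_result")
}

# Nearest-rank empirical quantile down each column, NA-dropping.
col_nearest_rank <- function(v, q) {
  apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    m <- length(x)
    if (m == 0) return(NA_real_)
    sort(x, partial = NULL)[max(1, ceiling(q / 100 * m))]
  })
}

# Scalar per-sim summaries used by the sensitivity analysis: average cost
# within the simulation's own cheapest 1% / 2% areas.
sim_summary <- function(sim, grid) {
  area <- grid$cell_area
  out <- c()
  for (fr in c(0.01, 0.02)) {
    tag <- if (fr == 0.01) "cheap1" else "cheap2"
    cp <- sim$fields$c_prod
    m <- try_mask(cp, area, fr)
    out[paste0("c_prod_", tag)] <-
      if (is.null(m)) NA_real_ else average_cost(m, cp, NULL, area)
    cs <- sim$fields$c_pertonsink
    bs <- sim$fields$e_sinknet * sim$s_dw
    m <- try_mask(cs, area, fr)
    out[paste0("c_pertonsink_", tag)] <-
      if (is.null(m)) NA_real_ else average_cost(m, cs, bs, area)
    for (cat in product_categories()) {
      cf <- sim$fields[[paste0("c_pertonprod_", cat)]]
      bf <- sim$fields[[paste0("e_prodnet_", cat)]] * sim$s_dw
      m <- try_mask(cf, area, fr)
      out[paste0("c_pertonprod_", cat, "_", tag)] <-
        if (is.null(m)) NA_real_ else average_cost(m, cf, bf, area)
    }
  }
  out
}

try_mask <- function(cost, area, fraction) {
  if (all(is.na(cost))) return(NULL)
  cheapest_fraction(cost, area, fraction)
}

#' Per-cell cost percentile maps from a stored ensemble
#'
#' Nearest-rank empirical quantile across simulations, computed
#' independently per cell; simulations in which a cell's pathway is invalid
#' contribute nothing to that cell.
#'
#' @param ensemble an \code{ensemble_result} run with
#'   \code{keep_values = TRUE}.
#' @param q percentile level in (0, 100).
#' @param field which stored field.
#' @return matrix on the full grid.
#' @export
summarize_percentiles <- function(ensemble, q, field = "c_prod") {
  if (q <= 0 || q >= 100) stop2("q must be in (0, 100)")
  if (is.null(ensemble$values)) {
    stop2("ensemble was run with keep_values = FALSE")
  }
  v <- ensemble$values[[field]]
  if (is.null(v)) stop2("field not stored: ", field)
  m <- matrix(NA_real_, ensemble$grid$n_lat, ensemble$grid$n_lon)
  m[ensemble$ocean_index] <- col_nearest_rank(v, q)
  m
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d sims, %s scenario, seed %d\n",
              x$n_sims, x$scenario, x$root_seed))
  cat("fields:", paste(names(x$quantile_maps), collapse = ", "), "\n")
  invisible(x)
}
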
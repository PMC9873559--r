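#' Over-water weighted distance transform
#'
#' Multi-source shortest over-water distance from every ocean cell to the
#' nearest source cell, on the 8-connected grid graph with land impassable.
#' Edge weights are great-circle centre-to-centre distances, so east-west
#' steps shrink with the cosine of latitude and diagonal steps follow the
#' spherical geometry. Global grids wrap in longitude.
#'
#' @param grid an \code{ocean_grid}.
#' @param source_mask logical matrix, TRUE at target cells (ocean).
#' @param lon_wrap override the grid's longitude wrap flag.
#' @return list of class \code{distance_field}: \code{distance} matrix (km;
#'   0 at sources, Inf where disconnected, NA on land) and \code{n_sources}.
#' @export
weighted_distance_transform <- function(grid, source_mask, lon_wrap = NULL) {
  stopifnot(inherits(grid, "ocean_grid"))
  stopifnot(is.logical(source_mask),
            all(dim(source_mask) == c(grid$n_lat, grid$n_lon)))
  src <- source_mask & !grid$land_mask
  if (!any(src)) stop2("empty source set")
  w <- edge_weights(grid)
  d <- .wdt_dijkstra(grid$land_mask, src, w$ew, w$ns, w$dg,
                     isTRUE(lon_wrap %||% grid$lon_wrap))
  structure(list(distance = d, n_sources = sum(src)),
            class = "distance_field")
}

# Per-row great-circle pitches for the grid graph:
#   ew: east-west within row i; ns: between rows i and i+1; dg: diagonal.
edge_weights <- function(grid) {
  lat <- grid$lat
  dlon <- diff(grid$lon_edges)[1]
  dlat <- diff(grid$lat_edges)[1]
  n <- grid$n_lat
  list(
    ew = haversine_km(lat, 0, lat, dlon),
    ns = haversine_km(lat[-n], 0, lat[-n] + dlat, 0),
    dg = haversine_km(lat[-n], 0, lat[-n] + dlat, dlon)
  )
}

#' Assign each farm cell its cost-optimal sinking destination
#'
#' Harvested seaweed can be sunk where it grew or towed to water where a
#' larger fraction of the deposited carbon stays sequestered for 100 years.
#' For each candidate sequestration fraction q in 0.01, 0.02, ..., 1.00 the
#' over-water distance to the nearest cell with \code{f_seq >= q} is
#' computed, the sinking-pathway net cost per ton of CO2 removed is
#' evaluated with mean (unrounded-midpoint) parameters at that distance and
#' \code{k_fseq = q}, and each cell keeps the q minimising the cost. Ties
#' break to the smaller distance, then the larger q. Cells whose optimum is
#' their own cell keep their unmodified local \code{f_seq}.
#'
#' @param grid an \code{ocean_grid}.
#' @param env an \code{env_layers}.
#' @param yields a \code{yield_ensemble}; the median ambient map of the
#'   preferred type sets the biomass moved.
#' @param mean_sample an economic sample, normally
#'   \code{mean_parameter_set(...)}.
#' @param q_step increment of the sequestration-fraction sweep.
#' @return object of class \code{sink_assignment}: matrices \code{d_sink}
#'   (km), \code{q_assigned} (sequestration fraction at the destination),
#'   logical \code{in_place}, and the mean-parameter \code{c_perton} field.
#' @export
optimal_sink_assignment <- function(grid, env, yields, mean_sample,
                                    q_step = 0.01) {
  stopifnot(inherits(grid, "ocean_grid"), inherits(env, "env_layers"))
  ym <- yield_map(yields, "ambient", 50)
  s_dw <- ym$s_dw
  layout <- farm_layout(s_dw, ym$n_harv, ym$p_sline)
  prod <- production_fields(mean_sample, layout, env$depth, env$swh,
                            env$d_port)
  ocean <- !grid$land_mask
  f_seq <- env$f_seq
  qs <- seq(q_step, 1, by = q_step)
  qmax <- max(f_seq[ocean], na.rm = TRUE)
  best_cost <- matrix(Inf, grid$n_lat, grid$n_lon)
  best_d <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  best_q <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  for (q in qs) {
    if (q > qmax) break # no source cells beyond the field maximum
    src <- !is.na(f_seq) & f_seq >= q
    dq <- weighted_distance_transform(grid, src)$distance
    cost <- sinking_cost_per_ton(mean_sample, prod, s_dw, dq, env$d_port, q)
    cand <- is.finite(cost) & ocean
    # strict improvement, then tie-break: smaller d_sink, then larger q
    upd <- cand & (cost < best_cost - 1e-12 |
                     (abs(cost - best_cost) <= 1e-12 &
                        (dq < best_d | (dq == best_d & q > best_q))))
    upd[is.na(upd)] <- FALSE
    best_cost[upd] <- cost[upd]
    best_d[upd] <- dq[upd]
    best_q[upd] <- q
  }
  # cells the mean-parameter sweep never validates (e.g. zero yield, or net
  # emissions at every q) default to sinking in place with their local f_seq
  fallback <- is.na(best_d) & ocean & !is.na(f_seq)
  best_d[fallback] <- 0
  in_place <- !is.na(best_d) & best_d == 0
  # sinking in place keeps the cell's own (un-snapped) sequestration fraction
  best_q[in_place] <- f_seq[in_place]
  structure(list(d_sink = best_d, q_assigned = best_q, in_place = in_place,
                 c_perton = best_cost, q_step = q_step),
            class = "sink_assignment")
}

# Mean-parameter net cost per ton CO2 removed for a given d_sink field and
# sequestration fraction q; Inf where the pathway is invalid. Used both by
# the q sweep above and as the objective in tests' brute-force enumeration.
sinking_cost_per_ton <- function(sample, prod, s_dw, d_sink, d_port, q) {
  s_ww <- wet_weight(s_dw)
  val <- sinking_value(sample, s_dw, s_ww, d_sink, d_port)
  rem <- sinking_removal(sample, q, s_dw, s_ww, d_sink, d_port)
  net <- sinking_net(prod$c_prod, prod$e_prod, val$v_sink, rem$e_remsink)
  cost <- net$c_pertonsink
  cost[!net$valid_mask | is.na(cost)] <- Inf
  cost
}
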
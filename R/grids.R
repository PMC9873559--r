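#' Construct an ocean grid
#'
#' An equal-angle latitude/longitude raster with per-cell spherical areas and
#' a land mask. All spatial layers in the package hang off one of these.
#' Latitude rows are ordered south to north; coordinates are cell centres.
#'
#' @param n_lat,n_lon grid dimensions (>= 8 each).
#' @param land_mask logical n_lat x n_lon matrix, TRUE on land. Default: all
#'   ocean.
#' @param lat_range,lon_range extent in degrees.
#' @return An object of class \code{ocean_grid}: list with \code{n_lat},
#'   \code{n_lon}, \code{lat_edges}, \code{lon_edges}, \code{lat}, \code{lon}
#'   (cell centres), \code{cell_area} (km^2 matrix), \code{land_mask}.
#' @export
ocean_grid <- function(n_lat, n_lon, land_mask = NULL,
                       lat_range = c(-90, 90), lon_range = c(-180, 180)) {
  if (n_lat < 8 || n_lon < 8) stop2("grid must be at least 8 x 8")
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, n_lat, n_lon)
  }
  stopifnot(is.logical(land_mask), dim(land_mask) == c(n_lat, n_lon))
  if (all(land_mask)) stop2("degenerate grid: all cells are land")
  lat_edges <- seq(lat_range[1], lat_range[2], length.out = n_lat + 1)
  lon_edges <- seq(lon_range[1], lon_range[2], length.out = n_lon + 1)
  lat <- (lat_edges[-1] + lat_edges[-(n_lat + 1)]) / 2
  lon <- (lon_edges[-1] + lon_edges[-(n_lon + 1)]) / 2
  # spherical zone area: R^2 * dlambda * (sin(phi2) - sin(phi1)) per cell
  dlon_rad <- diff(lon_edges)[1] * pi / 180
  band <- .R_EARTH^2 * dlon_rad *
    (sin(lat_edges[-1] * pi / 180) - sin(lat_edges[-(n_lat + 1)] * pi / 180))
  cell_area <- matrix(band, n_lat, n_lon)
  structure(list(
    n_lat = n_lat, n_lon = n_lon,
    lat_edges = lat_edges, lon_edges = lon_edges,
    lat = lat, lon = lon,
    cell_area = cell_area, land_mask = land_mask,
    lon_wrap = isTRUE(all.equal(diff(lon_range), 360))
  ), class = "ocean_grid")
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf(
    "<ocean_grid> %d x %d cells, %.0f%% land, ocean area %.3g km^2\n",
    x$n_lat, x$n_lon, 100 * mean(x$land_mask),
    sum(x$cell_area[!x$land_mask])
  ))
  invisible(x)
}

# Evaluate expr under a temporary RNG seed, restoring caller state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Smooth random field: white noise blurred with a 3x3 kernel `iters` times,
# wrapping in longitude. Rescaled to [0, 1]. Draws from the current RNG.
smooth_field01 <- function(n_lat, n_lon, iters = 8, wrap = TRUE) {
  f <- matrix(rnorm(n_lat * n_lon), n_lat, n_lon)
  for (k in seq_len(iters)) {
    east <- if (wrap) f[, c(n_lon, 1:(n_lon - 1))] else f[, c(1, 1:(n_lon - 1))]
    west <- if (wrap) f[, c(2:n_lon, 1)] else f[, c(2:n_lon, n_lon)]
    north <- f[c(1, 1:(n_lat - 1)), ]
    south <- f[c(2:n_lat, n_lat), ]
    f <- (f + east + west + north + south) / 5
  }
  rng <- range(f)
  if (rng[2] > rng[1]) (f - rng[1]) / (rng[2] - rng[1]) else f * 0 + 0.5
}

#' Generate a synthetic ocean grid
#'
#' Land is laid down by thresholding a smoothed noise field, so continents
#' form contiguous blobs rather than salt-and-pepper speckle.
#'
#' @param n_lat,n_lon grid dimensions.
#' @param land_fraction fraction of cells that are land, in [0, 1).
#' @param seed integer seed; identical seeds give identical grids.
#' @param lat_range,lon_range extent in degrees.
#' @return An \code{ocean_grid}.
#' @export
generate_ocean_grid <- function(n_lat, n_lon, land_fraction = 0.3, seed = 1,
                                lat_range = c(-90, 90),
                                lon_range = c(-180, 180)) {
  if (land_fraction < 0 || land_fraction >= 1) {
    stop2("land_fraction must be in [0, 1)")
  }
  land <- with_seed(seed, {
    if (land_fraction == 0) {
      matrix(FALSE, n_lat, n_lon)
    } else {
      f <- smooth_field01(n_lat, n_lon)
      f > quantile(f, 1 - land_fraction)
    }
  })
  ocean_grid(n_lat, n_lon, land, lat_range, lon_range)
}

#' Generate synthetic environmental layers
#'
#' Emulates the rasters a real analysis would ingest: bathymetry, annual-mean
#' significant wave height, over-water distance to the nearest port, the
#' fraction of sunk carbon still sequestered after 100 years, and boolean
#' shipping-lane / marine-protected-area masks. Ports are seeded on randomly
#' chosen coastal cells and \code{d_port} is the over-water shortest-path
#' distance from them (land-blocked, great-circle edge weights). All layers
#' are NA on land.
#'
#' @param grid an \code{ocean_grid}.
#' @param n_ports number of port cells to place.
#' @param seed integer seed.
#' @return An object of class \code{env_layers}: list of matrices
#'   \code{depth} (m), \code{swh} (m), \code{d_port} (km), \code{f_seq}
#'   (0-1), \code{shipping_mask}, \code{mpa_mask}, \code{port_mask}, plus the
#'   grid.
#' @export
generate_env_layers <- function(grid, n_ports = 10, seed = 1) {
  stopifnot(inherits(grid, "ocean_grid"))
  ocean <- !grid$land_mask
  out <- with_seed(seed, {
    depth <- 6000 * smooth_field01(grid$n_lat, grid$n_lon)^1.2
    lat_abs <- matrix(abs(grid$lat), grid$n_lat, grid$n_lon)
    swh <- pmin(6, 0.5 + 2.5 * (lat_abs / 90) +
                  3 * smooth_field01(grid$n_lat, grid$n_lon))
    f_seq <- 0.01 + 0.98 * smooth_field01(grid$n_lat, grid$n_lon)
    shipping <- smooth_field01(grid$n_lat, grid$n_lon)
    shipping_mask <- shipping > quantile(shipping[ocean], 0.95)
    mpa <- smooth_field01(grid$n_lat, grid$n_lon)
    mpa_mask <- mpa > quantile(mpa[ocean], 0.95)
    coastal <- coastal_cells(grid)
    if (!any(coastal)) coastal <- ocean # open-water grid: any cell may host
    idx <- which(coastal)
    if (length(idx) < 1) stop2("no coastal cell available for a port")
    ports <- sample(idx, min(n_ports, length(idx)))
    port_mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
    port_mask[ports] <- TRUE
    list(depth = depth, swh = swh, f_seq = f_seq,
         shipping_mask = shipping_mask & ocean,
         mpa_mask = mpa_mask & ocean, port_mask = port_mask)
  })
  out$d_port <- weighted_distance_transform(grid, out$port_mask)$distance
  for (nm in c("depth", "swh", "f_seq")) out[[nm]][grid$land_mask] <- NA_real_
  out$grid <- grid
  structure(out, class = "env_layers")
}

# Ocean cells 8-adjacent to land (candidate port sites).
coastal_cells <- function(grid) {
  land <- grid$land_mask
  n_lat <- grid$n_lat
  n_lon <- grid$n_lon
  near <- matrix(FALSE, n_lat, n_lon)
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  for (k in seq_len(nrow(shifts))) {
    di <- shifts$di[k]; dj <- shifts$dj[k]
    if (di == 0 && dj == 0) next
    ii <- pmin(pmax(1:n_lat + di, 1), n_lat)
    jj <- if (grid$lon_wrap) ((1:n_lon + dj - 1) %% n_lon) + 1 else {
      pmin(pmax(1:n_lon + dj, 1), n_lon)
    }
    near <- near | land[ii, jj]
  }
  near & !land
}

#' Seaweed types modelled by the synthetic yield generator
#' @export
seaweed_types <- function() {
  c("tropical_red", "tropical_brown", "temperate_red", "temperate_brown")
}

#' Per-type farm-design defaults for the synthetic world
#'
#' Peak median yields anchor tropical reds near several thousand and
#' temperate browns near two thousand tDW km^-2 yr^-1. Line spacing follows
#' field practice: dense off-bottom/raft culture for tropical reds, net-like
#' spacing for temperate reds, sparse longlines for temperate browns; the
#' seeded-line length per km^2 is 10^6 m divided by the spacing. Harvests
#' are consolidated annual campaigns: two for the fast-turnover tropical
#' types, one for temperate types.
#'
#' @return data.frame: type, peak_yield (tDW km^-2 yr^-1), n_harv (yr^-1),
#'   line_spacing_m.
#' @export
seaweed_type_params <- function() {
  data.frame(
    type = seaweed_types(),
    peak_yield = c(6500, 4500, 2600, 2200),
    n_harv = c(2, 2, 1, 1),
    line_spacing_m = c(0.75, 1, 1, 1.5)
  )
}

#' Generate a synthetic yield ensemble
#'
#' Stands in for a gridded macroalgal growth model. Four seaweed types have
#' distinct latitude affinities (tropical types peak near the equator,
#' temperate near 45 degrees); annual harvest magnitudes are anchored so
#' tropical reds reach several thousand tDW km^-2 yr^-1 and temperate browns
#' roughly a third of that. Yield-uncertainty percentile maps (5/25/50/75/95)
#' are the median map scaled by ordered, smoothly perturbed multipliers; the
#' nutrient-limited scenario is the ambient scenario damped by a smooth
#' factor in (0, 1].
#'
#' @param grid an \code{ocean_grid}.
#' @param env an \code{env_layers} (reserved for future covariates).
#' @param seed integer seed.
#' @param percentile_mult base multipliers for the 5/25/50/75/95 percentile
#'   maps relative to the median.
#' @param perturb relative amplitude of the smooth spatial perturbation of
#'   the multipliers (cell-wise ordering is enforced afterwards).
#' @return An object of class \code{yield_ensemble}: \code{s_dw} array with
#'   dims (lat, lon, type, scenario, percentile) in tDW km^-2 yr^-1;
#'   \code{n_harv} harvests per year per type; \code{preferred_type} matrix
#'   of type indices (argmax of median ambient yield); \code{types};
#'   \code{grid}.
#' @export
generate_yield_ensemble <- function(grid, env, seed = 1,
                                    percentile_mult = c(0.5, 0.8, 1, 1.2, 1.5),
                                    perturb = 0.08) {
  stopifnot(inherits(grid, "ocean_grid"))
  types <- seaweed_types()
  pcts <- c(5, 25, 50, 75, 95)
  stopifnot(length(percentile_mult) == 5, !is.unsorted(percentile_mult),
            all(percentile_mult > 0))
  tp <- seaweed_type_params()
  peak <- stats::setNames(tp$peak_yield, tp$type)
  n_harv <- stats::setNames(tp$n_harv, tp$type)
  line_spacing <- stats::setNames(tp$line_spacing_m, tp$type)
  n_lat <- grid$n_lat; n_lon <- grid$n_lon
  lat_abs <- matrix(abs(grid$lat), n_lat, n_lon)
  s_dw <- array(0, dim = c(n_lat, n_lon, 4, 2, 5),
                dimnames = list(NULL, NULL, types,
                                c("ambient", "limited"), pcts))
  with_seed(seed, {
    limited_factor <- 0.4 + 0.6 * smooth_field01(n_lat, n_lon)
    for (t in seq_along(types)) {
      affinity <- if (grepl("tropical", types[t])) {
        exp(-(lat_abs / 18)^2)
      } else {
        exp(-((lat_abs - 45) / 12)^2)
      }
      texture <- 0.2 + 0.8 * smooth_field01(n_lat, n_lon)
      med <- peak[t] * affinity * texture
      med[med < 0.02 * peak[t]] <- 0 # unproductive water for this type
      for (p in 1:5) {
        u <- 2 * smooth_field01(n_lat, n_lon) - 1
        s_dw[, , t, "ambient", p] <- med * percentile_mult[p] *
          (1 + perturb * u)
      }
      # enforce cell-wise percentile ordering (perturbation is small, the
      # cummax almost never binds)
      for (p in 2:5) {
        s_dw[, , t, "ambient", p] <- pmax(s_dw[, , t, "ambient", p],
                                           s_dw[, , t, "ambient", p - 1])
      }
      for (p in 1:5) {
        s_dw[, , t, "limited", p] <- s_dw[, , t, "ambient", p] *
          limited_factor
      }
    }
  })
  s_dw[is.na(s_dw)] <- 0
  land_idx <- which(grid$land_mask)
  if (length(land_idx)) {
    flat <- matrix(s_dw, nrow = n_lat * n_lon)
    flat[land_idx, ] <- 0
    s_dw <- array(flat, dim = dim(s_dw), dimnames = dimnames(s_dw))
  }
  med_amb <- s_dw[, , , "ambient", "50", drop = FALSE]
  preferred <- apply(array(med_amb, c(n_lat, n_lon, 4)), c(1, 2), which.max)
  structure(list(s_dw = s_dw, n_harv = n_harv,
                 line_spacing = line_spacing, preferred_type = preferred,
                 types = types, percentiles = pcts, grid = grid),
            class = "yield_ensemble")
}

#' Per-cell yield map for one scenario and percentile, preferred type
#'
#' @param yields a \code{yield_ensemble}.
#' @param scenario "ambient" or "limited".
#' @param percentile one of 5, 25, 50, 75, 95.
#' @return list with \code{s_dw} matrix (tDW km^-2 yr^-1, the preferred
#'   type's map), \code{n_harv} matrix (harvests per year) and
#'   \code{p_sline} matrix (m of seeded line per km^2 for the preferred
#'   type's line spacing).
#' @export
yield_map <- function(yields, scenario = "ambient", percentile = 50) {
  stopifnot(inherits(yields, "yield_ensemble"))
  p <- match(as.character(percentile), dimnames(yields$s_dw)[[5]])
  if (is.na(p)) stop2("percentile must be one of 5, 25, 50, 75, 95")
  scenario <- match.arg(scenario, c("ambient", "limited"))
  n_lat <- yields$grid$n_lat; n_lon <- yields$grid$n_lon
  pref <- yields$preferred_type
  flat <- matrix(yields$s_dw[, , , scenario, p], nrow = n_lat * n_lon)
  idx <- cbind(seq_len(n_lat * n_lon), as.vector(pref))
  s_dw <- matrix(flat[idx], n_lat, n_lon)
  n_harv <- matrix(yields$n_harv[as.vector(pref)], n_lat, n_lon)
  n_harv[s_dw <= 0] <- 0
  p_sline <- matrix(1e6 / yields$line_spacing[as.vector(pref)],
                    n_lat, n_lon)
  list(s_dw = s_dw, n_harv = n_harv, p_sline = p_sline)
}
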
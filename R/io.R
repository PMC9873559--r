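#' Write spatial layers to a portable text raster
#'
#' One CSV row per cell (lat, lon, land flag, one column per layer; land
#' cells carry NA, never fill values) plus a JSON sidecar
#' (\code{<path>.json}) holding the grid geometry, per-layer units and any
#' provenance metadata (seed, config hash). The format round-trips through
#' \code{\link{read_layers}} and is trivially ingested by raster tooling,
#' so externally derived layers can be dropped into the pipeline.
#'
#' @param grid an \code{ocean_grid}.
#' @param layers named list of matrices on the grid.
#' @param path CSV file path.
#' @param units optional named character vector of layer units.
#' @param meta optional list of provenance metadata for the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_layers <- function(grid, layers, path, units = NULL, meta = list()) {
  stopifnot(inherits(grid, "ocean_grid"), length(layers) > 0,
            !is.null(names(layers)))
  df <- data.frame(
    lat = rep(grid$lat, times = grid$n_lon),
    lon = rep(grid$lon, each = grid$n_lat),
    land = as.integer(as.vector(grid$land_mask))
  )
  for (nm in names(layers)) {
    m <- layers[[nm]]
    stopifnot(all(dim(m) == c(grid$n_lat, grid$n_lon)))
    df[[nm]] <- as.vector(m)
  }
  write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(
    n_lat = grid$n_lat, n_lon = grid$n_lon,
    lat_range = range(grid$lat_edges), lon_range = range(grid$lon_edges),
    layers = names(layers),
    units = as.list(units %||% character())
  ), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read spatial layers written by \code{\link{write_layers}}
#'
#' @param path CSV file path (with its \code{.json} sidecar alongside).
#' @return list: \code{grid} (an \code{ocean_grid}), \code{layers} (named
#'   list of matrices), \code{meta} (sidecar contents).
#' @export
read_layers <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  n_lat <- meta$n_lat
  n_lon <- meta$n_lon
  if (nrow(df) != n_lat * n_lon) stop2("raster size mismatch with sidecar")
  land <- matrix(df$land == 1, n_lat, n_lon)
  grid <- ocean_grid(n_lat, n_lon, land,
                     lat_range = meta$lat_range, lon_range = meta$lon_range)
  layers <- lapply(meta$layers, function(nm) matrix(df[[nm]], n_lat, n_lon))
  names(layers) <- meta$layers
  list(grid = grid, layers = layers, meta = meta)
}

#' Write a supply curve as CSV
#' @param curve a \code{supply_curve}.
#' @param path file path.
#' @export
write_supply_curve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
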
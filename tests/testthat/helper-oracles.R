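# Shared fixtures (built once when the helpers are sourced) and independent
# oracles: an igraph Dijkstra for distance fields and a straight-line
# transliteration of the printed cost equations for the full chain.

fix_grid <- generate_ocean_grid(16, 32, 0.25, seed = 11)
fix_env <- generate_env_layers(fix_grid, n_ports = 4, seed = 12)
fix_yields <- generate_yield_ensemble(fix_grid, fix_env, seed = 13)
fix_ranges <- default_ranges()
fix_mean <- mean_parameter_set(fix_ranges)
fix_assign <- optimal_sink_assignment(fix_grid, fix_env, fix_yields,
                                      fix_mean)

# A hand-buildable sample covering every scalar the cost chain needs.
toy_sample <- function(...) {
  s <- list(
    c_capbase = 1e5, k_d = 0.1, k_w = 0.2, c_slbase = 0.1,
    c_ins = 0, c_lic = 0, c_lab = 0, c_opbase = 0,
    c_harvbase = 2e5, c_transbase = 0.2, e_transbase = 0,
    e_mntbase = 0, n_mnt = 1, a_mnt = 1, d_mnt = 10, m_eq = 100,
    k_atm = 1, v_cprice = 0,
    v_mkt_food = 600, c_conv_food = 100, e_conv_food = 0.3,
    e_subprod_food = 3,
    v_mkt_feed = 450, c_conv_feed = 50, e_conv_feed = 0.02,
    e_subprod_feed = 2,
    v_mkt_fuel = 450, c_conv_fuel = 150, e_conv_fuel = 0.1,
    e_subprod_fuel = 0.85,
    yield_percentile = 50L
  )
  mods <- list(...)
  s[names(mods)] <- mods
  structure(s, class = "economic_sample")
}

# Multi-source shortest over-water distance via igraph, same topology and
# great-circle weights as the package transform but a wholly separate
# path-finding engine.
oracle_distance <- function(grid, source_mask, lon_wrap = grid$lon_wrap) {
  skip_if_not_installed("igraph")
  n_lat <- grid$n_lat
  n_lon <- grid$n_lon
  id <- function(i, j) (j - 1L) * n_lat + i
  from <- integer()
  to <- integer()
  w <- numeric()
  for (j in seq_len(n_lon)) {
    for (i in seq_len(n_lat)) {
      if (grid$land_mask[i, j]) next
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di
        if (ni < 1 || ni > n_lat) next
        nj <- j + dj
        if (nj < 1 || nj > n_lon) {
          if (!lon_wrap) next
          nj <- ((nj - 1) %% n_lon) + 1
        }
        if (grid$land_mask[ni, nj]) next
        from <- c(from, id(i, j))
        to <- c(to, id(ni, nj))
        w <- c(w, seafarm:::haversine_km(grid$lat[i], grid$lon[j],
                                         grid$lat[ni], grid$lon[nj]))
      }
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  # pad isolated trailing vertices
  miss <- n_lat * n_lon - igraph::vcount(g)
  if (miss > 0) g <- igraph::add_vertices(g, miss)
  src <- which(source_mask & !grid$land_mask)
  dmat <- igraph::distances(g, v = src, weights = w, mode = "out")
  d <- apply(dmat, 2, min)
  out <- matrix(d, n_lat, n_lon)
  out[grid$land_mask] <- NA_real_
  out
}

# One-shot hand-coded evaluation of the complete equation chain on a single
# cell, written independently of the package's field functions.
oracle_chain <- function(p, s_dw, n_harv, depth, swh, d_port, d_sink, q,
                         p_sline = 1e6 / 1.5) {
  c_sl <- p$c_slbase * p_sline
  c_cap <- p$c_capbase +
    p$c_capbase * (p$k_d * (depth > 500) + p$k_w * (swh > 3)) + c_sl
  c_op <- p$c_ins + p$c_lic + p$c_lab + p$c_opbase
  c_harv <- p$c_harvbase * n_harv
  c_eqtrans <- p$c_transbase * p$m_eq * d_port
  c_prod <- (c_cap + c_op + c_harv + c_eqtrans) / s_dw
  e_eqtrans <- p$e_transbase * p$m_eq * d_port
  e_mnt <- (2 * d_port) * p$e_mntbase * (p$n_mnt / p$a_mnt) +
    p$e_mntbase * p$d_mnt
  e_prod <- (e_eqtrans + e_mnt) / s_dw
  s_ww <- s_dw / 0.1
  c_swtsink <- p$c_transbase * d_sink * s_ww
  c_eqtsink <- p$c_transbase * (2 * d_sink) * p$m_eq +
    p$c_transbase * d_port * p$m_eq
  v_sink <- (p$v_cprice - (c_swtsink + c_eqtsink)) / s_dw
  e_seqsink <- p$k_atm * q * 0.30 * (44 / 12) * s_dw
  e_swtsink <- p$e_transbase * d_sink * s_ww
  e_eqtsink <- p$e_transbase * (2 * d_sink) * p$m_eq +
    p$e_transbase * d_port * p$m_eq
  e_remsink <- (e_seqsink - (e_swtsink + e_eqtsink)) / s_dw
  c_sinknet <- c_prod - v_sink
  e_sinknet <- e_remsink - e_prod
  c_pertonsink <- if (e_sinknet > 0) c_sinknet / e_sinknet else NA_real_
  out <- list(c_prod = c_prod, e_prod = e_prod,
              c_pertonsink = c_pertonsink, e_sinknet = e_sinknet)
  for (cat in c("food", "feed", "fuel")) {
    c_transprod <- p$c_transbase * d_port * (s_ww + p$m_eq) / s_dw
    v_product <- p[[paste0("v_mkt_", cat)]] -
      (c_transprod + p[[paste0("c_conv_", cat)]])
    e_transprod <- p$e_transbase * d_port * (s_ww + p$m_eq) / s_dw
    e_avprod <- p[[paste0("e_subprod_", cat)]] -
      (e_transprod + p[[paste0("e_conv_", cat)]])
    c_prodnet <- c_prod - v_product
    e_prodnet <- e_avprod - e_prod
    out[[paste0("c_pertonprod_", cat)]] <-
      if (e_prodnet > 0) c_prodnet / e_prodnet else NA_real_
  }
  out
}

# Package-side single-cell chain using the exported field functions on
# scalars/1x1 values, for comparison against oracle_chain().
package_chain <- function(p, s_dw, n_harv, depth, swh, d_port, d_sink, q) {
  layout <- farm_layout(s_dw, n_harv)
  prod <- production_fields(p, layout, depth, swh, d_port)
  sink <- sinking_pathway(p, prod, s_dw,
                          list(d_sink = d_sink, q_assigned = q), d_port)
  out <- list(c_prod = prod$c_prod, e_prod = prod$e_prod,
              c_pertonsink = sink$c_pertonsink,
              e_sinknet = sink$e_sinknet)
  for (cat in c("food", "feed", "fuel")) {
    pw <- product_pathway(p, prod, s_dw, d_port, cat)
    out[[paste0("c_pertonprod_", cat)]] <- pw$c_pertonprod
  }
  out
}

expect_rel_equal <- function(a, b, tol = 1e-10) {
  if (is.na(a) && is.na(b)) return(invisible(TRUE))
  expect_false(is.na(a) != is.na(b))
  denom <- max(abs(a), abs(b), 1e-300)
  expect_lt(abs(a - b) / denom, tol)
}

# A grid with no longitude wrap (regional extent), handy for oracle tests.
regional_grid <- function(n_lat, n_lon, land_fraction, seed) {
  generate_ocean_grid(n_lat, n_lon, land_fraction, seed,
                      lat_range = c(10, 10 + 2 * n_lat),
                      lon_range = c(0, 2 * n_lon))
}
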
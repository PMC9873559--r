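test_that("distance transform basics: sources, rows, errors", {
  g <- regional_grid(8, 12, 0, seed = 1)
  src <- matrix(FALSE, 8, 12)
  src[4, 2] <- TRUE
  d <- weighted_distance_transform(g, src)$distance
  expect_equal(d[4, 2], 0)
  # straight open-water row: cumulative sum of east-west pitches
  pitch <- seafarm:::haversine_km(g$lat[4], g$lon[1], g$lat[4], g$lon[2])
  expect_equal(d[4, 2 + 1:4], pitch * 1:4, tolerance = 1e-9)
  expect_error(weighted_distance_transform(g, matrix(FALSE, 8, 12)),
               "empty source")
})

test_that("distance transform equals the Dijkstra oracle on random grids", {
  skip_if_not_installed("igraph")
  n_bad <- 0
  for (k in 1:50) {
    set.seed(1000 + k)
    n_lat <- sample(8:16, 1)
    n_lon <- sample(8:20, 1)
    g <- regional_grid(n_lat, n_lon, runif(1, 0, 0.4), seed = 2000 + k)
    ocean <- which(!g$land_mask)
    src <- matrix(FALSE, n_lat, n_lon)
    src[sample(ocean, sample(1:3, 1))] <- TRUE
    d <- weighted_distance_transform(g, src)$distance
    o <- oracle_distance(g, src)
    same <- isTRUE(all.equal(d, o, tolerance = 1e-9))
    n_bad <- n_bad + !same
  }
  expect_equal(n_bad, 0)
})

test_that("distance transform handles an L-shaped barrier like Dijkstra", {
  skip_if_not_installed("igraph")
  land <- matrix(FALSE, 12, 12)
  land[3:9, 6] <- TRUE
  land[9, 6:10] <- TRUE
  g <- ocean_grid(12, 12, land, lat_range = c(20, 44), lon_range = c(0, 24))
  src <- matrix(FALSE, 12, 12)
  src[6, 2] <- TRUE
  d <- weighted_distance_transform(g, src)$distance
  o <- oracle_distance(g, src)
  expect_equal(d, o, tolerance = 1e-9)
  # the barrier forces a detour: cells straight across are farther than
  # the unblocked great-circle distance
  straight <- seafarm:::haversine_km(g$lat[6], g$lon[2], g$lat[6], g$lon[9])
  expect_gt(d[6, 9], straight)
})

test_that("sinking in place is chosen when transport cannot help", {
  g <- regional_grid(8, 10, 0, seed = 3)
  env <- generate_env_layers(g, n_ports = 2, seed = 4)
  env$f_seq[] <- 0.6 # uniform: no destination beats home
  y <- generate_yield_ensemble(g, env, seed = 5)
  a <- optimal_sink_assignment(g, env, y, fix_mean)
  expect_true(all(a$d_sink == 0, na.rm = TRUE))
  expect_true(all(a$q_assigned == 0.6, na.rm = TRUE))
})

test_that("free transport sends everything to the best sequestration water", {
  g <- regional_grid(8, 10, 0, seed = 6)
  env <- generate_env_layers(g, n_ports = 2, seed = 7)
  y <- generate_yield_ensemble(g, env, seed = 8)
  free <- fix_mean
  free$c_transbase <- 0
  free$e_transbase <- 0
  a <- optimal_sink_assignment(g, env, y, free)
  q_top <- floor(max(env$f_seq) * 100) / 100
  moved <- !is.na(a$d_sink) & a$d_sink > 0
  expect_true(all(abs(a$q_assigned[moved] - q_top) < 1e-9))
  # cells already sitting on top-grade water stay put (among cells the
  # sweep could price at all; zero-yield cells fall back to in-place)
  stay <- is.finite(a$c_perton) & a$d_sink == 0
  expect_true(all(env$f_seq[stay] >= q_top))
})

test_that("assignment equals exhaustive (cell, q) enumeration on a toy", {
  skip_if_not_installed("igraph")
  # two sequestration plateaus and positive transport costs
  g <- regional_grid(8, 8, 0, seed = 9)
  env <- generate_env_layers(g, n_ports = 1, seed = 10)
  env$f_seq[] <- 0.3
  env$f_seq[, 5:8] <- 0.9
  y <- generate_yield_ensemble(g, env, seed = 11)
  a <- optimal_sink_assignment(g, env, y, fix_mean)
  # independent enumeration: for every q on the grid, oracle distances;
  # track the best (cost, distance, q) per cell with the same tie-breaks
  ym <- yield_map(y, "ambient", 50)
  layout <- farm_layout(ym$s_dw, ym$n_harv, ym$p_sline)
  prod <- production_fields(fix_mean, layout, env$depth, env$swh,
                            env$d_port)
  best <- list(cost = matrix(Inf, 8, 8), d = matrix(NA_real_, 8, 8),
               q = matrix(NA_real_, 8, 8))
  for (q in seq(0.01, 1, by = 0.01)) {
    src <- env$f_seq >= q
    if (!any(src)) next
    dq <- oracle_distance(g, src)
    cost <- seafarm:::sinking_cost_per_ton(fix_mean, prod, ym$s_dw, dq,
                                           env$d_port, q)
    for (cell in which(is.finite(cost))) {
      better <- cost[cell] < best$cost[cell] - 1e-12 ||
        (abs(cost[cell] - best$cost[cell]) <= 1e-12 &&
           (dq[cell] < best$d[cell] ||
              (dq[cell] == best$d[cell] && q > best$q[cell])))
      if (isTRUE(better)) {
        best$cost[cell] <- cost[cell]
        best$d[cell] <- dq[cell]
        best$q[cell] <- q
      }
    }
  }
  ok <- !is.na(best$d)
  expect_gt(sum(ok), 0)
  expect_equal(a$d_sink[ok], best$d[ok], tolerance = 1e-9)
  home <- ok & best$d == 0
  expect_equal(a$q_assigned[ok & !home], best$q[ok & !home],
               tolerance = 1e-9)
  expect_equal(a$q_assigned[home], env$f_seq[home])
})

test_that("optimised sinking never costs more than sinking in place", {
  ym <- yield_map(fix_yields, "ambient", 50)
  layout <- farm_layout(ym$s_dw, ym$n_harv, ym$p_sline)
  prod <- production_fields(fix_mean, layout, fix_env$depth, fix_env$swh,
                            fix_env$d_port)
  q_local <- floor(fix_env$f_seq * 100) / 100
  local_cost <- matrix(Inf, fix_grid$n_lat, fix_grid$n_lon)
  for (q in sort(unique(q_local[!is.na(q_local)]))) {
    if (q <= 0) next
    cells <- which(!is.na(q_local) & q_local == q)
    cost <- seafarm:::sinking_cost_per_ton(fix_mean, prod, ym$s_dw,
                                           0 * ym$s_dw, fix_env$d_port, q)
    local_cost[cells] <- cost[cells]
  }
  both <- is.finite(fix_assign$c_perton) & is.finite(local_cost)
  expect_true(all(fix_assign$c_perton[both] <= local_cost[both] + 1e-9))
  # determinism of the whole assignment
  a2 <- optimal_sink_assignment(fix_grid, fix_env, fix_yields, fix_mean)
  expect_identical(fix_assign$d_sink, a2$d_sink)
  expect_identical(fix_assign$q_assigned, a2$q_assigned)
})
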
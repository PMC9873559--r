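test_that("a simulation is deterministic and masks propagate", {
  s <- sample_parameters(fix_ranges, seed = 3)
  sim1 <- run_simulation(s, fix_grid, fix_env, fix_yields, fix_assign)
  sim2 <- run_simulation(s, fix_grid, fix_env, fix_yields, fix_assign)
  expect_identical(sim1$fields, sim2$fields)
  # zero-yield and land cells never carry a production cost
  bad <- fix_grid$land_mask | sim1$s_dw <= 0
  expect_true(all(is.na(sim1$fields$c_prod[bad])))
  # with zero emissions factors net removal equals gross removal
  s0 <- s
  s0$e_transbase <- 0
  s0$e_mntbase <- 0
  sim0 <- run_simulation(s0, fix_grid, fix_env, fix_yields, fix_assign)
  on <- !is.na(sim0$fields$e_sinknet)
  expect_equal(sim0$fields$e_sinknet[on],
               sim0$sinking$e_remsink[on])
})

test_that("simulation fields agree with the single-cell oracle chain", {
  s <- sample_parameters(fix_ranges, seed = 23)
  sim <- run_simulation(s, fix_grid, fix_env, fix_yields, fix_assign)
  cells <- which(!is.na(sim$fields$c_prod))
  ym <- yield_map(fix_yields, "ambient", s$yield_percentile)
  set.seed(77)
  for (cell in sample(cells, 12)) {
    o <- oracle_chain(
      s, s_dw = sim$s_dw[cell],
      n_harv = ym$n_harv[cell], p_sline = ym$p_sline[cell],
      depth = fix_env$depth[cell], swh = fix_env$swh[cell],
      d_port = fix_env$d_port[cell], d_sink = fix_assign$d_sink[cell],
      q = fix_assign$q_assigned[cell]
    )
    expect_rel_equal(sim$fields$c_prod[cell], o$c_prod)
    expect_rel_equal(sim$fields$c_pertonsink[cell], o$c_pertonsink)
    expect_rel_equal(sim$fields$c_pertonprod_food[cell],
                     o$c_pertonprod_food)
  }
})

test_that("ensembles are reproducible and quantiles behave", {
  e1 <- run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                     n_sims = 40, root_seed = 9, ranges = fix_ranges,
                     keep_values = TRUE)
  e2 <- run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                     n_sims = 40, root_seed = 9, ranges = fix_ranges)
  expect_identical(e1$summaries, e2$summaries)
  expect_identical(e1$quantile_maps, e2$quantile_maps)
  expect_equal(nrow(e1$params), 40)
  # n = 1: every quantile map equals the single simulation
  e0 <- run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                     n_sims = 1, root_seed = 9, ranges = fix_ranges)
  s1 <- sample_parameters(fix_ranges, seed = 9 * 1000 + 1)
  sim <- run_simulation(s1, fix_grid, fix_env, fix_yields, fix_assign)
  expect_equal(e0$quantile_maps$c_prod[["50"]], sim$fields$c_prod)
  expect_equal(e0$quantile_maps$c_prod[["5"]], sim$fields$c_prod)
  # quantile ordering cell-wise
  q5 <- e1$quantile_maps$c_prod[["5"]]
  q50 <- e1$quantile_maps$c_prod[["50"]]
  q95 <- e1$quantile_maps$c_prod[["95"]]
  on <- !is.na(q5)
  expect_true(all(q5[on] <= q50[on] & q50[on] <= q95[on]))
  expect_error(run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                            n_sims = 0), "n_sims")
})

test_that("per-cell quantiles equal a brute-force sort of stored sims", {
  e <- run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                    n_sims = 30, root_seed = 4, ranges = fix_ranges,
                    keep_values = TRUE)
  v <- e$values$c_prod
  q50 <- summarize_percentiles(e, 50, "c_prod")
  q5 <- summarize_percentiles(e, 5, "c_prod")
  set.seed(8)
  for (k in sample(ncol(v), 25)) {
    x <- sort(v[!is.na(v[, k]), k])
    cell <- e$ocean_index[k]
    if (length(x) == 0) {
      expect_true(is.na(q50[cell]))
    } else {
      expect_equal(q50[cell], x[max(1, ceiling(0.5 * length(x)))])
      expect_equal(q5[cell], x[max(1, ceiling(0.05 * length(x)))])
    }
  }
  expect_error(summarize_percentiles(e, 101), "q must be")
})

test_that("a single perturbed parameter explains the output variance", {
  # freeze every range to its midpoint except the seeded-line cost
  r <- fix_ranges
  mid <- (r$low + r$high) / 2
  r$low <- mid
  r$high <- mid
  i <- which(r$name == "c_slbase")
  r$low[i] <- fix_ranges$low[i]
  r$high[i] <- fix_ranges$high[i]
  e <- run_ensemble(fix_grid, fix_env, fix_yields, fix_assign,
                    n_sims = 50, root_seed = 6, ranges = r,
                    fields = "c_prod", keep_values = TRUE)
  # pick an always-valid cell: its cost must be an affine function of the
  # seeded-line draw (up to the yield-percentile draw, also frozen? no --
  # the percentile draw still varies, so condition on it)
  sl <- e$params$c_slbase
  pc <- e$params$yield_percentile
  v <- e$values$c_prod
  k <- which(colSums(is.na(v)) == 0)[1]
  for (p in unique(pc)) {
    sel <- pc == p
    if (sum(sel) < 3) next
    fit <- lm(v[sel, k] ~ sl[sel])
    # a perfect affine fit is exactly what we expect here
    expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-9)
  }
})
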
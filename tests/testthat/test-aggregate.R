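test_that("cheapest_fraction selects by cost with deterministic tie-breaks", {
  area <- matrix(1, 2, 5)
  cost <- matrix(c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10), 2, 5)
  m <- cheapest_fraction(cost, area, 0.3)
  expect_equal(sort(cost[m]), c(1, 2, 3)) # brute-force: three cheapest
  expect_equal(sum(m), 3)
  # fraction 1 takes every valid cell
  expect_true(all(cheapest_fraction(cost, area, 1)))
  # uniform costs: lowest cell indices win
  u <- matrix(1, 2, 5)
  mu <- cheapest_fraction(u, area, 0.4)
  expect_equal(which(mu), 1:4)
  # nesting: smaller fractions are subsets of larger ones
  for (f in c(0.2, 0.5, 0.8)) {
    expect_true(all(cheapest_fraction(cost, area, f) |
                      !cheapest_fraction(cost, area, f - 0.1)))
  }
  expect_error(cheapest_fraction(matrix(NA_real_, 2, 2),
                                 matrix(1, 2, 2), 0.5), "no valid")
})

test_that("average_cost weights by area or by benefit", {
  area <- matrix(1, 1, 2)
  cost <- matrix(c(100, 300), 1, 2)
  ben <- matrix(c(3, 1), 1, 2)
  mask <- matrix(TRUE, 1, 2)
  expect_equal(average_cost(mask, cost, NULL, area), 200)
  expect_equal(average_cost(mask, cost, ben, area), 150)
  # uniform cost is invariant to the weighting
  ucost <- matrix(42, 1, 2)
  expect_equal(average_cost(mask, ucost, ben, area), 42)
  # zero-benefit cells don't move the benefit-weighted average
  cost3 <- matrix(c(100, 300, 9999), 1, 3)
  ben3 <- matrix(c(3, 1, 0), 1, 3)
  expect_equal(average_cost(matrix(TRUE, 1, 3), cost3, ben3,
                            matrix(1, 1, 3)), 150)
  expect_error(average_cost(matrix(FALSE, 1, 2), cost, NULL, area),
               "empty mask")
})

test_that("supply curves accumulate benefit in cost order", {
  set.seed(12)
  cost <- matrix(runif(20, 10, 500), 4, 5)
  ben <- matrix(runif(20, 1, 5), 4, 5)
  area <- matrix(2, 4, 5)
  sc <- supply_curve(cost, ben, area)
  # marginal cost non-decreasing; cumulative fields non-decreasing
  expect_true(all(diff(sc$marginal_cost) >= 0))
  expect_true(all(diff(sc$benefit_gt) >= 0))
  expect_true(all(diff(sc$area_km2) > 0))
  # at fraction 1 the whole grid's benefit is on the curve
  expect_equal(sc$benefit_gt[nrow(sc)], sum(ben * area) / 1e9)
  # brute-force prefix check
  ord <- order(cost, seq_along(cost))
  for (k in c(1, 7, 20)) {
    expect_equal(sc$benefit_gt[k],
                 sum((ben * area)[ord[1:k]]) / 1e9)
    expect_equal(sc$average_cost[k],
                 sum((cost * ben * area)[ord[1:k]]) /
                   sum((ben * area)[ord[1:k]]))
  }
  # uniform benefit density: cumulative benefit linear in area
  sc_u <- supply_curve(cost, matrix(1, 4, 5), area)
  expect_equal(sc_u$benefit_gt / sc_u$benefit_gt[nrow(sc_u)],
               sc_u$area_km2 / sc_u$area_km2[nrow(sc_u)])
  # lookup of the first prefix reaching a benefit level
  hit <- supply_curve_at(sc, sc$benefit_gt[7])
  expect_equal(hit$area_km2, sc$area_km2[7])
})

test_that("compound growth reproduces the headline expansion rates", {
  # 1 Gt avoided by 2050: ~90,000 km^2 from 2,700 km^2 over 30 yr -> 12%
  expect_equal(round(100 * farm_growth_rate(90000, 2700, 30)$annual_rate),
               12)
  # 1 Gt sequestered by 2050: ~400,000 km^2 -> 18%
  expect_equal(round(100 * farm_growth_rate(400000, 2700, 30)$annual_rate),
               18)
  # same by 2030 (10 yr): 42% for avoided emissions
  expect_equal(round(100 * farm_growth_rate(90000, 2700, 10)$annual_rate),
               42)
  # limited nutrients, 1 Gt avoided by 2050: ~130,000 km^2 -> 14%
  expect_equal(round(100 * farm_growth_rate(130000, 2700, 30)$annual_rate),
               14)
  g <- farm_growth_rate(2700, 2700, 30)
  expect_equal(g$annual_rate, 0)
  expect_equal(g$fold_increase, 1)
  expect_error(farm_growth_rate(-1, 2700, 30), "positive")
})

test_that("constraint overlap counts areas exactly", {
  area <- matrix(1, 5, 10)
  mask <- matrix(FALSE, 5, 10)
  mask[1:25] <- TRUE
  ship <- matrix(FALSE, 5, 10)
  mpa <- matrix(FALSE, 5, 10)
  # disjoint masks
  ship[26:30] <- TRUE
  expect_equal(constraint_overlap(mask, ship, mpa, area)$either, 0)
  # fully inside the MPA
  mpa[1:50] <- TRUE
  expect_equal(constraint_overlap(mask, ship, mpa, area)$mpa, 1)
  # random toy vs direct counting
  set.seed(99)
  mask[] <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  ship[] <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  mpa[] <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  ov <- constraint_overlap(mask, ship, mpa, area)
  expect_equal(ov$shipping, sum(mask & ship) / sum(mask))
  expect_equal(ov$either, sum(mask & (ship | mpa)) / sum(mask))
})

test_that("headline ocean-area arithmetic holds", {
  k <- sf_constants()
  expect_equal(0.00025 * k$ocean_area_total, 90000)
  expect_equal(0.001 * k$ocean_area_total, 360000)
  expect_gt(90000 / k$current_farm_area, 30)
})
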
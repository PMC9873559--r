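#' Mask of the cheapest fraction of ocean area
#'
#' Valid (non-NA, finite) cells are sorted by cost ascending (ties broken by
#' cell index) and taken until their cumulative cell area reaches
#' \code{fraction} of the grid's total ocean area.
#'
#' @param cost per-cell cost matrix; NA cells are ignored.
#' @param cell_area per-cell area matrix, km^2.
#' @param fraction target fraction of total ocean area, in (0, 1].
#' @param ocean_area total ocean area against which the fraction is taken;
#'   defaults to the summed area of all non-NA-cost-eligible cells, i.e.
#'   the full \code{cell_area} sum. Pass the grid's ocean area to match
#'   map-wide fractions.
#' @return logical matrix.
#' @export
cheapest_fraction <- function(cost, cell_area, fraction,
                              ocean_area = sum(cell_area)) {
  if (fraction <= 0 || fraction > 1) stop2("fraction must be in (0, 1]")
  valid <- which(is.finite(cost))
  if (length(valid) == 0) stop2("no valid cells")
  ord <- valid[order(cost[valid], valid)]
  cum <- cumsum(cell_area[ord])
  take <- ord[cum <= fraction * ocean_area + 1e-9]
  if (length(take) == 0) take <- ord[1] # always keep the single cheapest
  mask <- array(FALSE, dim = dim(cost))
  mask[take] <- TRUE
  mask
}

#' Average cost over a cell mask
#'
#' With a per-area benefit map the average is benefit-weighted, i.e. total
#' dollars over total tons of climate benefit (the natural reading of an
#' average $ per tCO2); without one it is the area-weighted mean (used for
#' $ per tDW production cost).
#'
#' @param mask logical matrix selecting cells.
#' @param cost per-cell cost matrix.
#' @param benefit optional per-area benefit density, t km^-2 yr^-1.
#' @param cell_area per-cell area matrix, km^2.
#' @return scalar.
#' @export
average_cost <- function(mask, cost, benefit = NULL, cell_area) {
  sel <- mask & !is.na(cost)
  if (!any(sel)) stop2("empty mask")
  w <- if (is.null(benefit)) cell_area[sel] else {
    (benefit * cell_area)[sel]
  }
  if (sum(w, na.rm = TRUE) == 0) stop2("zero total weight")
  sum(cost[sel] * w, na.rm = TRUE) / sum(w, na.rm = TRUE)
}

#' Cumulative supply curve of climate benefit versus lowest-cost area
#'
#' Valid cells sorted by per-ton cost; walking down the ranking accumulates
#' farmed area and annual climate benefit (converted to Gt), tracking the
#' marginal cost and the benefit-weighted average cost up to each prefix.
#'
#' @param cost per-cell cost, $ per t of benefit.
#' @param benefit per-area benefit density, t km^-2 yr^-1.
#' @param cell_area per-cell area matrix, km^2.
#' @param max_fraction truncate the curve at this fraction of
#'   \code{ocean_area}.
#' @param ocean_area denominator for area fractions (default the summed
#'   cell area).
#' @return data.frame of class \code{supply_curve}: \code{area_km2},
#'   \code{area_fraction}, \code{benefit_gt} (Gt yr^-1),
#'   \code{marginal_cost}, \code{average_cost}.
#' @export
supply_curve <- function(cost, benefit, cell_area, max_fraction = 1,
                         ocean_area = sum(cell_area)) {
  valid <- which(is.finite(cost) & !is.na(benefit))
  if (length(valid) == 0) stop2("no valid cells")
  ord <- valid[order(cost[valid], valid)]
  area <- cumsum(cell_area[ord])
  keep <- area <= max_fraction * ocean_area + 1e-9
  ord <- ord[keep]
  area <- area[keep]
  ben <- cumsum((benefit * cell_area)[ord]) # t yr^-1
  dollars <- cumsum((cost * benefit * cell_area)[ord])
  out <- data.frame(
    area_km2 = area,
    area_fraction = area / ocean_area,
    benefit_gt = ben / 1e9,
    marginal_cost = cost[ord],
    average_cost = dollars / ben
  )
  class(out) <- c("supply_curve", "data.frame")
  out
}

#' Area needed on a supply curve to reach a benefit level
#'
#' @param curve a \code{supply_curve}.
#' @param benefit_gt target annual benefit, Gt.
#' @return one-row data.frame with the first prefix reaching the target
#'   (area, fraction, average cost), or NA row if the curve never does.
#' @export
supply_curve_at <- function(curve, benefit_gt) {
  i <- which(curve$benefit_gt >= benefit_gt)[1]
  if (is.na(i)) {
    return(data.frame(area_km2 = NA_real_, area_fraction = NA_real_,
                      benefit_gt = benefit_gt, average_cost = NA_real_))
  }
  data.frame(area_km2 = curve$area_km2[i],
             area_fraction = curve$area_fraction[i],
             benefit_gt = curve$benefit_gt[i],
             average_cost = curve$average_cost[i])
}

#' Compound annual growth needed to reach a farmed area
#'
#' @param target_area,current_area km^2 (> 0).
#' @param horizon_years years (> 0).
#' @return list of class \code{growth_rate_result}: \code{fold_increase}
#'   and \code{annual_rate} (fractional, e.g. 0.12 for 12% yr^-1).
#' @export
farm_growth_rate <- function(target_area, current_area = 2700,
                             horizon_years = 30) {
  if (target_area <= 0 || current_area <= 0 || horizon_years <= 0) {
    stop2("areas and horizon must be positive")
  }
  fold <- target_area / current_area
  structure(list(target_area = target_area, current_area = current_area,
                 horizon_years = horizon_years, fold_increase = fold,
                 annual_rate = fold^(1 / horizon_years) - 1),
            class = "growth_rate_result")
}

#' @export
print.growth_rate_result <- function(x, ...) {
  cat(sprintf(
    "%.0f km^2 from %.0f km^2 in %g yr: %.1f-fold, %.1f%% yr^-1\n",
    x$target_area, x$current_area, x$horizon_years, x$fold_increase,
    100 * x$annual_rate))
  invisible(x)
}

#' Overlap of a selected area with shipping lanes and protected areas
#'
#' @param mask logical matrix of selected cells.
#' @param shipping_mask,mpa_mask logical constraint masks.
#' @param cell_area per-cell area matrix, km^2.
#' @return list: area fractions \code{shipping}, \code{mpa}, \code{either}.
#' @export
constraint_overlap <- function(mask, shipping_mask, mpa_mask, cell_area) {
  tot <- sum(cell_area[mask])
  if (tot == 0) return(list(shipping = 0, mpa = 0, either = 0))
  list(
    shipping = sum(cell_area[mask & shipping_mask]) / tot,
    mpa = sum(cell_area[mask & mpa_mask]) / tot,
    either = sum(cell_area[mask & (shipping_mask | mpa_mask)]) / tot
  )
}
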
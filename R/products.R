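#' Product categories and their substituted-emissions ranges
#'
#' The CO2-equivalent emissions (GWP100) embodied in the conventional
#' product a ton of seaweed dry weight displaces: food spans the caloric
#' equivalence against pulses/vegetables/fruits/oil crops/cereals, feed
#' against oil crops and cereals, and fuel follows fossil-fuel carbon
#' intensity (3.2-3.5 tCO2 per t fuel) times the 0.25 t-biofuel-per-tDW
#' yield with energy-density equivalence.
#'
#' @param category one of "food", "feed", "fuel".
#' @return numeric length-2 range, tCO2-eq tDW^-1.
#' @export
substituted_emissions <- function(category) {
  ranges <- list(food = c(1, 6), feed = c(1, 3.1), fuel = c(0.7, 1))
  if (!category %in% names(ranges)) {
    stop2("unknown product category: ", category)
  }
  # cross-check of the fuel range against its fossil-intensity derivation
  fuel_implied <- c(3.2, 3.5) * 0.25
  stopifnot(all(abs(range(c(ranges$fuel, fuel_implied)) -
                      c(0.7, 1)) < 0.2))
  ranges[[category]]
}

#' @rdname substituted_emissions
#' @export
product_categories <- function() c("food", "feed", "fuel")

# Pull a category-specific scalar (e.g. v_mkt_food) off a sample.
cat_par <- function(sample, name, category) {
  v <- sample[[paste(name, category, sep = "_")]]
  if (is.null(v)) stop2("sample lacks parameter ", name, "_", category)
  v
}

#' Market value net of transport and conversion, per ton dry weight
#'
#' Harvest and replacement equipment are barged straight back to port; the
#' per-tDW transport cost scales wet mass plus equipment mass over the port
#' distance. Market value is globally uniform per category.
#'
#' @param sample an \code{economic_sample}.
#' @param s_dw,s_ww dry and wet harvest, t km^-2 yr^-1.
#' @param d_port distance to the nearest port, km.
#' @param category product category.
#' @return list of matrices \code{c_transprod} and \code{v_product},
#'   $ tDW^-1 (NA where \code{s_dw} = 0).
#' @export
product_value <- function(sample, s_dw, s_ww, d_port, category = "food") {
  if (any(d_port < 0, na.rm = TRUE)) stop2("d_port must be >= 0")
  c_transprod <- sample$c_transbase * d_port * (s_ww + sample$m_eq) / s_dw
  c_transprod[!is.finite(c_transprod) | s_dw <= 0] <- NA_real_
  v_product <- cat_par(sample, "v_mkt", category) -
    (c_transprod + cat_par(sample, "c_conv", category))
  list(c_transprod = c_transprod, v_product = v_product)
}

#' Avoided emissions per ton dry weight for a product category
#'
#' The category's substituted emissions minus the seaweed chain's own
#' transport and conversion emissions (all CO2-eq, GWP100).
#'
#' @inheritParams product_value
#' @return list of matrices \code{e_transprod} and \code{e_avprod},
#'   tCO2-eq tDW^-1.
#' @export
product_emissions <- function(sample, s_dw, s_ww, d_port,
                              category = "food") {
  e_transprod <- sample$e_transbase * d_port * (s_ww + sample$m_eq) / s_dw
  e_transprod[!is.finite(e_transprod) | s_dw <= 0] <- NA_real_
  e_avprod <- cat_par(sample, "e_subprod", category) -
    (e_transprod + cat_par(sample, "e_conv", category))
  list(e_transprod = e_transprod, e_avprod = e_avprod)
}

#' Net cost per ton of CO2-equivalent emissions avoided
#'
#' Net cost per ton dry weight is production cost minus product value (so a
#' valuable product can make it negative, i.e. a profit); net benefit is
#' avoided emissions minus production emissions. Cells with no net avoided
#' emissions are invalid and excluded downstream.
#'
#' @param c_prod production cost, $ tDW^-1.
#' @param e_prod production emissions, tCO2 tDW^-1.
#' @param v_product product value, $ tDW^-1.
#' @param e_avprod avoided emissions, tCO2-eq tDW^-1.
#' @return list of matrices \code{c_prodnet} ($ tDW^-1), \code{e_prodnet}
#'   (tCO2-eq tDW^-1), \code{c_pertonprod} ($ per tCO2-eq, NA off the mask)
#'   and logical \code{valid_mask}.
#' @export
product_net <- function(c_prod, e_prod, v_product, e_avprod) {
  c_prodnet <- c_prod - v_product
  e_prodnet <- e_avprod - e_prod
  valid <- !is.na(e_prodnet) & e_prodnet > .EPS_NET & !is.na(c_prodnet)
  c_pertonprod <- c_prodnet / e_prodnet
  c_pertonprod[!valid] <- NA_real_
  list(c_prodnet = c_prodnet, e_prodnet = e_prodnet,
       c_pertonprod = c_pertonprod, valid_mask = valid)
}

#' Full product pathway for one economic sample and category
#'
#' @param sample an \code{economic_sample}.
#' @param prod a \code{production_result}.
#' @param s_dw harvest matrix, tDW km^-2 yr^-1.
#' @param d_port distance-to-port matrix, km.
#' @param category product category.
#' @param constants output of \code{\link{sf_constants}}.
#' @return list of class \code{pathway_result} with all product fields.
#' @export
product_pathway <- function(sample, prod, s_dw, d_port, category = "food",
                            constants = sf_constants()) {
  s_ww <- wet_weight(s_dw, constants)
  val <- product_value(sample, s_dw, s_ww, d_port, category)
  em <- product_emissions(sample, s_dw, s_ww, d_port, category)
  net <- product_net(prod$c_prod, prod$e_prod, val$v_product, em$e_avprod)
  structure(c(val, em, net, list(pathway = category)),
            class = "pathway_result")
}
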
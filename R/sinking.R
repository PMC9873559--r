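#' Wet weight of the harvest
#'
#' Freshly harvested seaweed is mostly water; downstream transport moves wet
#' tons. Dry weight is divided by 0.1 (10 t wet per t dry).
#'
#' @param s_dw harvest, tDW km^-2 yr^-1 (matrix or scalar).
#' @param constants output of \code{\link{sf_constants}}.
#' @return wet weight, t WW km^-2 yr^-1.
#' @export
wet_weight <- function(s_dw, constants = sf_constants()) {
  if (any(s_dw < 0, na.rm = TRUE)) stop2("s_dw must be >= 0")
  s_dw / (1 / constants$wet_dry_ratio)
}

#' Value (net of transport) of seaweed sunk for carbon removal
#'
#' The barge tows harvest plus used equipment to the sinking site, returns
#' to the farm, then returns to port: seaweed transport is charged over
#' \code{d_sink} on the wet mass, equipment transport over \code{2 d_sink}
#' plus the port leg on the annualized equipment mass. With no carbon price
#' the value is a pure (negative) cost.
#'
#' @param sample an \code{economic_sample}.
#' @param s_dw,s_ww dry and wet harvest, t km^-2 yr^-1.
#' @param d_sink distance to the assigned sinking site, km.
#' @param d_port distance to the nearest port, km.
#' @return list of matrices \code{c_swtsink}, \code{c_eqtsink} ($ km^-2
#'   yr^-1) and \code{v_sink} ($ tDW^-1, NA where \code{s_dw} = 0).
#' @export
sinking_value <- function(sample, s_dw, s_ww, d_sink, d_port) {
  if (any(d_sink < 0, na.rm = TRUE) || any(d_port < 0, na.rm = TRUE)) {
    stop2("distances must be >= 0")
  }
  c_swtsink <- sample$c_transbase * d_sink * s_ww
  c_eqtsink <- sample$c_transbase * (2 * d_sink) * sample$m_eq +
    sample$c_transbase * d_port * sample$m_eq
  v_sink <- (sample$v_cprice - (c_swtsink + c_eqtsink)) / s_dw
  v_sink[!is.finite(v_sink) | s_dw <= 0] <- NA_real_
  list(c_swtsink = c_swtsink, c_eqtsink = c_eqtsink, v_sink = v_sink)
}

#' Atmospheric CO2 removed per ton of sunk seaweed
#'
#' Gross sequestration is the harvest's carbon content (30% of dry weight,
#' converted by 44/12 to CO2) scaled by the atmospheric removal fraction
#' \code{k_atm} and the destination's 100-year sequestration fraction
#' \code{k_fseq}; transport emissions for the seaweed leg and the equipment
#' legs are then netted off and the result normalised per ton dry weight.
#'
#' @inheritParams sinking_value
#' @param k_fseq sequestration fraction at the sinking site (scalar or
#'   matrix, 0-1).
#' @param constants output of \code{\link{sf_constants}}.
#' @return list of matrices \code{e_seqsink}, \code{e_swtsink},
#'   \code{e_eqtsink} (tCO2 km^-2 yr^-1) and \code{e_remsink} (tCO2 tDW^-1).
#' @export
sinking_removal <- function(sample, k_fseq, s_dw, s_ww, d_sink, d_port,
                            constants = sf_constants()) {
  stopifnot(all(k_fseq >= 0 & k_fseq <= 1, na.rm = TRUE))
  e_seqsink <- sample$k_atm * k_fseq * constants$carbon_fraction *
    constants$co2_per_c * s_dw
  e_swtsink <- sample$e_transbase * d_sink * s_ww
  e_eqtsink <- sample$e_transbase * (2 * d_sink) * sample$m_eq +
    sample$e_transbase * d_port * sample$m_eq
  e_remsink <- (e_seqsink - (e_swtsink + e_eqtsink)) / s_dw
  e_remsink[!is.finite(e_remsink) | s_dw <= 0] <- NA_real_
  list(e_seqsink = e_seqsink, e_swtsink = e_swtsink,
       e_eqtsink = e_eqtsink, e_remsink = e_remsink)
}

# Cells must remove strictly more than this much CO2 per tDW to count as
# contributing to removal; guards the division in the $-per-ton step.
.EPS_NET <- 1e-9

#' Net cost per ton of CO2 removed by sinking
#'
#' Net cost per ton dry weight is production cost minus the (negative)
#' sinking value; net removal is removal minus production emissions. Cells
#' with no net removal are marked invalid and excluded from every downstream
#' aggregate; the cost per ton of CO2 is the ratio on valid cells only.
#'
#' @param c_prod production cost, $ tDW^-1.
#' @param e_prod production emissions, tCO2 tDW^-1.
#' @param v_sink value of the sunk harvest, $ tDW^-1.
#' @param e_remsink net removal, tCO2 tDW^-1.
#' @return list of matrices \code{c_sinknet} ($ tDW^-1), \code{e_sinknet}
#'   (tCO2 tDW^-1), \code{c_pertonsink} ($ per tCO2, NA off the mask) and
#'   logical \code{valid_mask}.
#' @export
sinking_net <- function(c_prod, e_prod, v_sink, e_remsink) {
  c_sinknet <- c_prod - v_sink
  e_sinknet <- e_remsink - e_prod
  valid <- !is.na(e_sinknet) & e_sinknet > .EPS_NET & !is.na(c_sinknet)
  c_pertonsink <- c_sinknet / e_sinknet
  c_pertonsink[!valid] <- NA_real_
  list(c_sinknet = c_sinknet, e_sinknet = e_sinknet,
       c_pertonsink = c_pertonsink, valid_mask = valid)
}

#' Full sinking pathway for one economic sample
#'
#' @param sample an \code{economic_sample}.
#' @param prod a \code{production_result}.
#' @param s_dw harvest matrix, tDW km^-2 yr^-1.
#' @param assignment a \code{sink_assignment} (or a list with \code{d_sink}
#'   and \code{q_assigned}).
#' @param d_port distance-to-port matrix, km.
#' @param constants output of \code{\link{sf_constants}}.
#' @return list of class \code{pathway_result} with all sinking fields.
#' @export
sinking_pathway <- function(sample, prod, s_dw, assignment, d_port,
                            constants = sf_constants()) {
  s_ww <- wet_weight(s_dw, constants)
  d_sink <- assignment$d_sink
  k_fseq <- assignment$q_assigned
  val <- sinking_value(sample, s_dw, s_ww, d_sink, d_port)
  rem <- sinking_removal(sample, k_fseq, s_dw, s_ww, d_sink, d_port,
                         constants)
  net <- sinking_net(prod$c_prod, prod$e_prod, val$v_sink, rem$e_remsink)
  structure(c(list(s_ww = s_ww, d_sink = d_sink, k_fseq = k_fseq), val, rem,
              net, list(pathway = "sinking")),
            class = "pathway_result")
}
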
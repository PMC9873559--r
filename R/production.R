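#' Farm layout for a given yield map
#'
#' Bundles the per-cell annual harvest, harvest counts and seeded-line
#' density that the cost equations consume. Line density is the length of
#' seeded line per km^2 implied by the line spacing (default 1.5 m, i.e.
#' 666,667 m km^-2).
#'
#' @param s_dw matrix, annual harvest of the active percentile/type, tDW
#'   km^-2 yr^-1.
#' @param n_harv matrix or scalar, harvests per year.
#' @param p_sline matrix or scalar, m of seeded line per km^2 (the
#'   \code{\link{yield_map}} supplies the preferred type's value; the
#'   default is the 1.5 m-spacing baseline).
#' @return list of class \code{farm_layout}.
#' @export
farm_layout <- function(s_dw, n_harv, p_sline = sf_constants()$p_sline) {
  stopifnot(all(s_dw >= 0, na.rm = TRUE), all(p_sline > 0))
  structure(list(s_dw = s_dw, n_harv = n_harv, p_sline = p_sline),
            class = "farm_layout")
}

#' Annualized capital cost per km^2
#'
#' Base capital cost, marked up by the depth multiplier where the water is
#' deeper than 500 m and by the waviness multiplier where significant wave
#' height exceeds 3 m (strictly; boundary cells get no markup), plus the
#' annual seeded-line cost \code{c_slbase * p_sline}.
#'
#' @param sample an \code{economic_sample}.
#' @param layout a \code{farm_layout}.
#' @param depth depth matrix, m (positive down).
#' @param swh significant wave height matrix, m.
#' @return matrix \code{c_cap}, $ km^-2 yr^-1.
#' @export
capital_cost <- function(sample, layout, depth, swh) {
  if (any(depth < 0, na.rm = TRUE) || any(swh < 0, na.rm = TRUE)) {
    stop2("depth and swh must be non-negative")
  }
  mult <- 1 + sample$k_d * (depth > 500) + sample$k_w * (swh > 3)
  c_sl <- sample$c_slbase * layout$p_sline
  sample$c_capbase * mult + c_sl
}

#' Annual operating, harvest and equipment-transport costs per km^2
#'
#' Operating cost is the sum of insurance, licence, labour and other
#' operating costs; harvest cost is the per-harvest cost times the number of
#' harvests; equipment transport is the one-way barge cost of moving the
#' annualized equipment mass over the port distance.
#'
#' @inheritParams capital_cost
#' @param d_port distance-to-port matrix, km.
#' @return list of matrices \code{c_op}, \code{c_harv}, \code{c_eqtrans},
#'   $ km^-2 yr^-1.
#' @export
annual_costs <- function(sample, layout, d_port) {
  if (any(layout$n_harv < 0, na.rm = TRUE)) stop2("n_harv must be >= 0")
  if (any(d_port < 0, na.rm = TRUE)) stop2("d_port must be >= 0")
  c_op <- sample$c_ins + sample$c_lic + sample$c_lab + sample$c_opbase
  if (!is.matrix(c_op) && is.matrix(layout$s_dw)) {
    c_op <- matrix(c_op, nrow(layout$s_dw), ncol(layout$s_dw))
  }
  list(
    c_op = c_op,
    c_harv = sample$c_harvbase * layout$n_harv,
    c_eqtrans = sample$c_transbase * sample$m_eq * d_port
  )
}

#' Production cost per ton dry weight
#'
#' Total annual per-km^2 cost (capital + operating + harvest + equipment
#' transport) divided by the annual harvest. Cells with zero harvest are
#' masked (NA).
#'
#' @param c_cap,c_op,c_harv,c_eqtrans cost matrices, $ km^-2 yr^-1.
#' @param s_dw harvest matrix, tDW km^-2 yr^-1.
#' @return matrix \code{c_prod}, $ tDW^-1.
#' @export
production_cost <- function(c_cap, c_op, c_harv, c_eqtrans, s_dw) {
  total <- c_cap + c_op + c_harv + c_eqtrans
  out <- total / s_dw
  out[!is.finite(out) | s_dw <= 0] <- NA_real_
  out
}

#' Production emissions per ton dry weight
#'
#' Equipment-transport emissions mirror the one-way equipment-cost leg;
#' maintenance emissions combine round trips from port (trip count per km^2
#' over area tended per trip) with the distance travelled around each km^2.
#' The sum is normalised by the annual harvest; zero-harvest cells are
#' masked.
#'
#' @inheritParams annual_costs
#' @return list of matrices \code{e_eqtrans}, \code{e_mnt} (tCO2 km^-2
#'   yr^-1) and \code{e_prod} (tCO2 tDW^-1).
#' @export
production_emissions <- function(sample, layout, d_port) {
  e_eqtrans <- sample$e_transbase * sample$m_eq * d_port
  e_mnt <- (2 * d_port) * sample$e_mntbase * (sample$n_mnt / sample$a_mnt) +
    sample$e_mntbase * sample$d_mnt
  if (!is.matrix(e_mnt) && is.matrix(d_port)) {
    e_mnt <- matrix(e_mnt, nrow(d_port), ncol(d_port))
  }
  e_prod <- (e_eqtrans + e_mnt) / layout$s_dw
  e_prod[!is.finite(e_prod) | layout$s_dw <= 0] <- NA_real_
  list(e_eqtrans = e_eqtrans, e_mnt = e_mnt, e_prod = e_prod)
}

#' All farm-gate production fields for one economic sample
#'
#' Convenience wrapper chaining \code{\link{capital_cost}},
#' \code{\link{annual_costs}}, \code{\link{production_cost}} and
#' \code{\link{production_emissions}}, and reporting each component's share
#' of the total production cost (seeded line, capital excluding line,
#' harvest, other).
#'
#' @inheritParams capital_cost
#' @param d_port distance-to-port matrix, km.
#' @return list of class \code{production_result} with all cost and
#'   emissions fields plus \code{shares}.
#' @export
production_fields <- function(sample, layout, depth, swh, d_port) {
  c_cap <- capital_cost(sample, layout, depth, swh)
  ann <- annual_costs(sample, layout, d_port)
  c_prod <- production_cost(c_cap, ann$c_op, ann$c_harv, ann$c_eqtrans,
                            layout$s_dw)
  em <- production_emissions(sample, layout, d_port)
  c_sl <- sample$c_slbase * layout$p_sline
  total <- c_cap + ann$c_op + ann$c_harv + ann$c_eqtrans
  total[!is.finite(total)] <- NA_real_ # e.g. water unreachable from ports
  shares <- list(
    seeded_line = c_sl / total,
    capital_ex_line = (c_cap - c_sl) / total,
    harvest = ann$c_harv / total,
    other = (ann$c_op + ann$c_eqtrans) / total
  )
  structure(c(list(c_cap = c_cap, c_prod = c_prod, shares = shares), ann, em),
            class = "production_result")
}
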
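#' Fixed physical and accounting constants
#'
#' @return list: \code{wet_dry_ratio} (t wet weight per t dry weight, so the
#'   Eq. dry-to-wet divisor is 1/wet_dry_ratio), \code{carbon_fraction} (tC
#'   per tDW, average carbon content of macroalgal dry weight),
#'   \code{co2_per_c} (44/12), \code{ocean_area_total} (km^2),
#'   \code{current_farm_area} (km^2 farmed today), \code{line_spacing_m}
#'   (default spacing between seeded lines) and the implied \code{p_sline}
#'   (m of line per km^2).
#' @export
sf_constants <- function(line_spacing_m = 1.5) {
  stopifnot(line_spacing_m > 0)
  list(
    wet_dry_ratio = 10,
    carbon_fraction = 0.30,
    co2_per_c = 44 / 12,
    ocean_area_total = 3.6e8,
    current_farm_area = 2700,
    line_spacing_m = line_spacing_m,
    p_sline = 1e6 / line_spacing_m
  )
}

# Rounding increments by rule id; conversion cost rounds down at the low end
# and up at the high end, everything else half-up to the nearest increment.
.round_rules <- c(
  capital = 10000, operating = 10000, harvest = 10000,
  labour = 1000, insurance = 1000,
  line = 0.05, transport_cost = 0.05,
  transport_emissions = 0.000005, maintenance_emissions = 0.0005,
  avoided_emissions = 0.1, conversion_cost = 10, conversion_emissions = 0.01,
  none = NA_real_
)

round_half_up <- function(x, inc) floor(x / inc + 0.5 + 1e-9) * inc

#' Default raw parameter table
#'
#' One row per technoeconomic parameter: the literature values it rests on,
#' the rounding rule for its Monte Carlo range, any floor extension, and an
#' explicit model-range override where the shipped range is taken as given
#' rather than derived (multipliers defined on [0, 1], ranges whose
#' supporting literature is only partially listed here, and placeholder rows
#' -- flagged in \code{note} -- whose sources are not reproduced in this
#' package).
#'
#' @return data.frame consumed by \code{\link{build_ranges}}.
#' @export
default_parameter_table <- function() {
  row <- function(name, units, values, rule, category = NA_character_,
                  extend_low = NA_real_, override_low = NA_real_,
                  override_high = NA_real_, mean_extend_zero = FALSE,
                  note = "") {
    data.frame(name = name, units = units, values = I(list(values)),
               rule = rule, category = category, extend_low = extend_low,
               override_low = override_low, override_high = override_high,
               mean_extend_zero = mean_extend_zero, note = note,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    row("c_capbase", "$ km-2 yr-1", c(929676, 550000, 950000, 375910, 210580),
        "capital", extend_low = 10000, override_high = 1e6,
        note = "annualized capital ex seeded line; floor = autonomous farm"),
    row("k_d", "fraction", NULL, "none", override_low = 0, override_high = 1,
        note = "capital multiplier applied where depth > 500 m"),
    row("k_w", "fraction", NULL, "none", override_low = 0, override_high = 1,
        note = "capital multiplier applied where swh > 3 m"),
    row("c_slbase", "$ m-1", c(1.38, 0.13), "line",
        override_low = 0.05, override_high = 1.45,
        note = "seeded line incl. hatchery"),
    row("c_ins", "$ km-2 yr-1", 30000, "insurance",
        note = "placeholder single value"),
    row("c_lic", "$ km-2 yr-1", 1500, "insurance",
        note = "placeholder single value"),
    row("c_lab", "$ km-2 yr-1", 150000, "labour",
        note = "placeholder single value; excludes harvest labour"),
    row("c_opbase", "$ km-2 yr-1", 60000, "operating",
        note = "placeholder single value"),
    row("c_harvbase", "$ km-2 per harvest", c(381265, 138000), "harvest",
        override_low = 120000, override_high = 400000),
    row("c_transbase", "$ t-1 km-1", 0.225, "transport_cost"),
    row("e_transbase", "tCO2 t-1 km-1", 0.00003, "transport_emissions",
        extend_low = 0, mean_extend_zero = TRUE,
        note = "floor 0 = net-zero-emissions vessels"),
    row("e_mntbase", "tCO2 km-1", 0.0023653, "maintenance_emissions",
        extend_low = 0, mean_extend_zero = TRUE,
        note = "maintenance vessel; floor 0 = net-zero-emissions vessels"),
    row("n_mnt", "trips yr-1 km-2", 30, "none",
        note = "placeholder single value"),
    row("a_mnt", "km2 per trip", 4, "none",
        note = "placeholder single value"),
    row("d_mnt", "km per km2", 10, "none",
        note = "placeholder single value"),
    row("m_eq", "t km-2 yr-1", 100, "none",
        note = "placeholder: annualized equipment mass"),
    row("k_atm", "fraction", c(0.4, 0.75), "none", override_high = 1,
        note = "atmospheric removal fraction; high end taken to 1"),
    row("v_cprice", "$ per tCO2", 0, "none", override_low = 0,
        override_high = 0, note = "no carbon price assumed"),
    row("v_mkt", "$ tDW-1", NULL, "none", category = "food",
        override_low = 500, override_high = 800),
    row("v_mkt", "$ tDW-1", NULL, "none", category = "feed",
        override_low = 400, override_high = 500),
    row("v_mkt", "$ tDW-1", NULL, "none", category = "fuel",
        override_low = 400, override_high = 500),
    row("e_subprod", "tCO2-eq tDW-1", c(1, 6), "avoided_emissions",
        category = "food"),
    row("e_subprod", "tCO2-eq tDW-1", c(1, 3.1), "avoided_emissions",
        category = "feed"),
    row("e_subprod", "tCO2-eq tDW-1", c(0.7, 1), "avoided_emissions",
        category = "fuel"),
    row("c_conv", "$ tDW-1", 50, "conversion_cost", category = "food",
        note = "placeholder single value"),
    row("c_conv", "$ tDW-1", 50, "conversion_cost", category = "feed",
        note = "placeholder single value"),
    row("c_conv", "$ tDW-1", 150, "conversion_cost", category = "fuel",
        note = "placeholder single value"),
    row("e_conv", "tCO2 tDW-1", 0.02, "conversion_emissions",
        category = "food", note = "placeholder single value"),
    row("e_conv", "tCO2 tDW-1", 0.02, "conversion_emissions",
        category = "feed", note = "placeholder single value"),
    row("e_conv", "tCO2 tDW-1", 0.1, "conversion_emissions",
        category = "fuel", note = "placeholder single value")
  ))
}

#' Build Monte Carlo parameter ranges from a raw literature table
#'
#' Applies the range-construction conventions: with two or more literature
#' values, the minimum and maximum stand for the 5th and 95th percentiles;
#' with a single value the range is value +/- 50%. Bounds are then rounded
#' per each parameter's rule (conversion cost down at the low end and up at
#' the high end, all others half-up to the nearest increment), floors are
#' extended where flagged (capital cost to its autonomous-farm floor,
#' transport/maintenance emissions to zero) and explicit overrides applied.
#' Unrounded bounds are kept alongside for \code{\link{mean_parameter_set}}.
#'
#' @param table a data.frame shaped like
#'   \code{\link{default_parameter_table}}.
#' @return data.frame of class \code{parameter_ranges}: name, category,
#'   units, low, high, raw_low, raw_high, mean_extend_zero.
#' @export
build_ranges <- function(table) {
  n <- nrow(table)
  low <- high <- raw_low <- raw_high <- numeric(n)
  for (i in seq_len(n)) {
    vals <- table$values[[i]]
    if (is.null(vals) || length(vals) == 0) {
      if (is.na(table$override_low[i]) || is.na(table$override_high[i])) {
        stop2("row '", table$name[i], "': no literature value and no override")
      }
      raw_low[i] <- table$override_low[i]
      raw_high[i] <- table$override_high[i]
    } else if (length(vals) == 1) {
      raw_low[i] <- vals * 0.5
      raw_high[i] <- vals * 1.5
    } else {
      raw_low[i] <- min(vals)
      raw_high[i] <- max(vals)
    }
    lo <- raw_low[i]
    hi <- raw_high[i]
    if (!is.na(table$extend_low[i])) lo <- min(lo, table$extend_low[i])
    rule <- table$rule[i]
    inc <- .round_rules[[rule]]
    if (!is.na(inc)) {
      if (rule == "conversion_cost") {
        lo <- floor(lo / inc + 1e-9) * inc
        hi <- ceiling(hi / inc - 1e-9) * inc
      } else {
        lo <- round_half_up(lo, inc)
        hi <- round_half_up(hi, inc)
      }
    }
    if (!is.na(table$override_low[i])) lo <- table$override_low[i]
    if (!is.na(table$override_high[i])) hi <- table$override_high[i]
    if (lo > hi) stop2("row '", table$name[i], "': low > high after rounding")
    low[i] <- lo
    high[i] <- hi
  }
  out <- data.frame(name = table$name, category = table$category,
                    units = table$units, low = low, high = high,
                    raw_low = raw_low, raw_high = raw_high,
                    mean_extend_zero = table$mean_extend_zero,
                    note = table$note, stringsAsFactors = FALSE)
  class(out) <- c("parameter_ranges", "data.frame")
  out
}

#' Default Monte Carlo parameter ranges
#' @param table raw table, by default \code{\link{default_parameter_table}}.
#' @return a \code{parameter_ranges} data.frame.
#' @export
default_ranges <- function(table = default_parameter_table()) {
  build_ranges(table)
}

range_key <- function(ranges) {
  ifelse(is.na(ranges$category), ranges$name,
         paste(ranges$name, ranges$category, sep = "_"))
}

#' Draw the yield-uncertainty percentile for one simulation
#'
#' A standard-normal draw is binned into the five stored percentile maps
#' (5/25/50/75/95) with cut points at the normal quantiles of the midpoints
#' between the percentile levels (0.15, 0.375, 0.625, 0.85), so central maps
#' are picked more often than the tails.
#'
#' @param n number of draws (uses the current RNG stream).
#' @return integer vector of percentile labels in \{5, 25, 50, 75, 95\}.
#' @export
draw_yield_percentile <- function(n = 1) {
  cuts <- qnorm(c(0.15, 0.375, 0.625, 0.85))
  u <- rnorm(n)
  c(5, 25, 50, 75, 95)[findInterval(u, cuts) + 1]
}

#' Draw one Monte Carlo economic sample
#'
#' Independent uniform draws within every (rounded) parameter range, plus a
#' yield-percentile pick. With a \code{seed} the draw is reproducible and the
#' caller's RNG state is untouched; with \code{seed = NULL} the current RNG
#' stream is used.
#'
#' @param ranges a \code{parameter_ranges} data.frame.
#' @param seed optional integer seed.
#' @return object of class \code{economic_sample}: named list of scalars
#'   (category-specific parameters suffixed \code{_food}, \code{_feed},
#'   \code{_fuel}) plus \code{yield_percentile}.
#' @export
sample_parameters <- function(ranges, seed = NULL) {
  draw <- function() {
    vals <- runif(nrow(ranges), ranges$low, ranges$high)
    s <- as.list(vals)
    names(s) <- range_key(ranges)
    s$yield_percentile <- draw_yield_percentile(1)
    structure(s, class = "economic_sample")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Mean parameter set for the sinking-destination optimisation
#'
#' Every parameter is the midpoint of its unrounded literature range, except
#' transport and maintenance emissions whose minima are first extended to
#' zero. The yield percentile is pinned at the median.
#'
#' @param ranges a \code{parameter_ranges} data.frame.
#' @return an \code{economic_sample}.
#' @export
mean_parameter_set <- function(ranges) {
  lo <- ifelse(ranges$mean_extend_zero, 0, ranges$raw_low)
  vals <- (lo + ranges$raw_high) / 2
  s <- as.list(vals)
  names(s) <- range_key(ranges)
  s$yield_percentile <- 50L
  structure(s, class = "economic_sample")
}

#' @export
print.economic_sample <- function(x, ...) {
  v <- unlist(x)
  cat("<economic_sample>\n")
  print(signif(v, 5))
  invisible(x)
}

#' Export a sampled ensemble's parameter table as CSV
#' @param params data.frame, one row per simulation (as stored on an
#'   ensemble result).
#' @param path file path.
#' @export
write_parameter_csv <- function(params, path) {
  write.csv(params, path, row.names = FALSE)
  invisible(path)
}
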
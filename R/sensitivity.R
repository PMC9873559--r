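#' Rank parameter importance for a Monte Carlo outcome
#'
#' Fits a gradient-boosted regression-tree ensemble of the per-simulation
#' outcome on the sampled parameters (the yield-percentile draw included)
#' and reports each parameter's share of total tree gain, normalised to sum
#' to 1. Permutation importance (mean-squared-error inflation on a held-out
#' third when one column is shuffled) is available as a robustness check.
#' A constant outcome has no definable importance: flagged, uniform shares
#' returned.
#'
#' @param params data.frame, one row per simulation, one column per
#'   parameter (constant columns are kept, with importance 0).
#' @param outcome numeric per-sim outcome; non-finite entries are dropped
#'   with their rows.
#' @param method "gain" or "permutation".
#' @param nrounds,max_depth,eta boosting hyperparameters (modest defaults).
#' @param seed integer seed for the boosting and the permutation shuffle.
#' @return object of class \code{sensitivity_report}: data.frame
#'   \code{importance} (parameter, importance) sorted descending,
#'   \code{method}, \code{n_sims}, \code{constant_outcome}.
#' @export
parameter_importance <- function(params, outcome,
                                 method = c("gain", "permutation"),
                                 nrounds = 300, max_depth = 4, eta = 0.1,
                                 seed = 1) {
  method <- match.arg(method)
  keep <- is.finite(outcome)
  params <- params[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (nrow(params) < 100) stop2("need at least 100 usable simulations")
  x <- as.matrix(params)
  report <- function(imp, flag = FALSE) {
    imp <- imp[order(-imp$importance), ]
    rownames(imp) <- NULL
    structure(list(importance = imp, method = method,
                   n_sims = length(outcome), constant_outcome = flag),
              class = "sensitivity_report")
  }
  if (stats::var(outcome) == 0) {
    imp <- data.frame(parameter = colnames(x),
                      importance = 1 / ncol(x))
    warning("constant outcome: importance undefined, returning uniform")
    return(report(imp, flag = TRUE))
  }
  fit <- function(xmat, y) {
    dtrain <- xgboost::xgb.DMatrix(xmat, label = y, nthread = 1)
    with_seed(seed, xgboost::xgb.train(
      params = list(max_depth = max_depth, eta = eta,
                    objective = "reg:squarederror", nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0
    ))
  }
  if (method == "gain") {
    booster <- fit(x, outcome)
    tab <- xgboost::xgb.importance(model = booster)
    gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
    gain[tab$Feature] <- tab$Gain
    imp <- data.frame(parameter = names(gain),
                      importance = as.numeric(gain) / sum(gain))
  } else {
    n <- nrow(x)
    idx <- with_seed(seed, sample.int(n))
    hold <- idx[seq_len(floor(n / 3))]
    train <- setdiff(idx, hold)
    booster <- fit(x[train, , drop = FALSE], outcome[train])
    base_mse <- mean((outcome[hold] -
                        predict(booster, x[hold, , drop = FALSE]))^2)
    delta <- with_seed(seed + 1, vapply(seq_len(ncol(x)), function(j) {
      xp <- x[hold, , drop = FALSE]
      xp[, j] <- xp[sample.int(length(hold)), j]
      mean((outcome[hold] - predict(booster, xp))^2) - base_mse
    }, numeric(1)))
    delta <- pmax(delta, 0)
    if (sum(delta) == 0) delta <- rep(1, ncol(x))
    imp <- data.frame(parameter = colnames(x),
                      importance = delta / sum(delta))
  }
  report(imp)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> method=%s, n=%d sims\n",
              x$method, x$n_sims))
  print(head(transform(x$importance,
                       importance = signif(importance, 3)), 10))
  invisible(x)
}

#' Parameter distributions among low-cost simulations
#'
#' Kernel density of each parameter among simulations whose outcome is at
#' or below a threshold, alongside its unconditional density; the contrast
#' shows which parameter settings the cheapest simulations rely on.
#' Constant (zero-variance) parameters are skipped.
#'
#' @param params data.frame, one row per simulation.
#' @param outcome numeric per-sim outcome.
#' @param threshold keep simulations with \code{outcome <= threshold}.
#' @return object of class \code{conditional_distribution}: per-parameter
#'   list with \code{conditional} and \code{unconditional} \code{density}
#'   objects and the two means; plus \code{n_conditional}.
#' @export
conditional_distribution <- function(params, outcome, threshold) {
  keep <- is.finite(outcome)
  params <- params[keep, , drop = FALSE]
  outcome <- outcome[keep]
  sel <- outcome <= threshold
  if (!any(sel)) stop2("no simulations at or below the threshold")
  dens <- list()
  for (nm in colnames(params)) {
    v <- params[[nm]]
    if (stats::var(v) == 0) next
    dens[[nm]] <- list(
      conditional = density(v[sel]),
      unconditional = density(v),
      mean_conditional = mean(v[sel]),
      mean_unconditional = mean(v)
    )
  }
  structure(list(parameters = dens, n_conditional = sum(sel),
                 threshold = threshold),
            class = "conditional_distribution")
}
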
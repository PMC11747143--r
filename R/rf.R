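#' Random-forest settings
#'
#' Conventional regression-forest defaults: 500 trees, p/3 variables per
#' split, minimum node size 5. `r2_retention` is the out-of-bag r-squared a
#' model must exceed to be kept for interpretation; `cluster_tolerance` is the
#' relative importance margin within which the top three variables count as
#' "tightly grouped".
#'
#' @param n_trees,mtry,nodesize Forest hyperparameters (`mtry = NULL` uses
#'   p/3).
#' @param seed Integer seed.
#' @param r2_retention Retention threshold on OOB r-squared.
#' @param cluster_tolerance Relative margin (default 0.2 = within 20% of the
#'   leader).
#' @param changepoint_floor Minimum absolute smoothed jump for
#'   [detect_changepoint()] to report a changepoint.
#' @return An object of class `rf_settings`.
#' @export
rf_settings <- function(n_trees = 500, mtry = NULL, nodesize = 5, seed = 1L,
                        r2_retention = 0.75, cluster_tolerance = 0.2,
                        changepoint_floor = 0) {
  stopifnot(n_trees >= 1, r2_retention > 0, r2_retention < 1,
            cluster_tolerance >= 0)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 nodesize = nodesize, seed = as.integer(seed),
                 r2_retention = r2_retention,
                 cluster_tolerance = cluster_tolerance,
                 changepoint_floor = changepoint_floor),
            class = "rf_settings")
}

#' Fit a regression forest of abundance on exposure covariates
#'
#' Fits with the given seed, computes the out-of-bag r-squared
#' (1 - OOB-MSE / variance of the response), and flags whether the model
#' clears the retention threshold.
#'
#' @param covariates Data frame or matrix of exposure covariate columns.
#' @param response Numeric abundance vector.
#' @param settings An [rf_settings()].
#' @return An object of class `oyster_rf`: `model`, `oob_r2`, `retained`,
#'   `settings`, `covariates`, `response`.
#' @export
fit_rf <- function(covariates, response, settings = rf_settings()) {
  stopifnot(inherits(settings, "rf_settings"))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) < 10) stop("need at least 10 observations")
  if (anyNA(covariates) || anyNA(response)) stop("covariates/response must be complete")
  if (stats::var(response) == 0) stop("constant response: r-squared undefined")
  mtry <- if (is.null(settings$mtry)) max(floor(ncol(covariates) / 3), 1) else settings$mtry
  set.seed(settings$seed)
  model <- randomForest::randomForest(
    x = covariates, y = response, ntree = settings$n_trees,
    mtry = mtry, nodesize = settings$nodesize)
  oob_r2 <- 1 - utils::tail(model$mse, 1) / mean((response - mean(response))^2)
  structure(list(model = model, oob_r2 = oob_r2,
                 retained = oob_r2 > settings$r2_retention,
                 settings = settings, covariates = covariates,
                 response = response),
            class = "oyster_rf")
}

#' Variable importance ranking by node purity
#'
#' Covariates ranked by total decrease in node impurity (sum of squared-error
#' reductions over splits, summed over trees).
#'
#' @param fit An `oyster_rf`.
#' @return Data frame `variable`, `importance`, sorted descending.
#' @export
variable_importance <- function(fit) {
  imp <- randomForest::importance(fit$model, type = 2)
  out <- data.frame(variable = rownames(imp), importance = imp[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Choose the variable to interpret from an importance ranking
#'
#' If the second and third most important variables are within
#' `cluster_tolerance` (relative) of the leader, the top three are "tightly
#' grouped" and the one whose salinity bin has the lowest lower bound is
#' selected; otherwise the most important variable wins.
#'
#' @param ranking Data frame from [variable_importance()].
#' @param cluster_tolerance Relative margin; 0 always selects the leader.
#' @return Selected variable name.
#' @export
select_interpretation_variable <- function(ranking, cluster_tolerance = 0.2) {
  stopifnot(nrow(ranking) >= 3)
  top3 <- ranking[1:3, ]
  grouped <- all(top3$importance >= (1 - cluster_tolerance) * top3$importance[1])
  if (!grouped) return(top3$variable[1])
  lower <- vapply(top3$variable,
                  function(v) parse_exposure_column(v)$lower, numeric(1))
  top3$variable[which.min(lower)]
}

#' Partial dependence of the forest on one covariate
#'
#' For each grid value, the covariate is substituted into every training row
#' and the forest predictions are averaged: the marginal effect holding the
#' empirical distribution of the other covariates fixed. The default grid is
#' the integers spanning the observed range of the covariate.
#'
#' @param fit An `oyster_rf`.
#' @param variable Covariate name.
#' @param grid Optional numeric grid (sorted ascending).
#' @return An object of class `pdp_curve`: data.frame `day`, `yhat`.
#' @export
partial_dependence <- function(fit, variable, grid = NULL) {
  if (!variable %in% names(fit$covariates)) stop("unknown variable: ", variable)
  if (is.null(grid)) {
    grid <- seq(floor(min(fit$covariates[[variable]])),
                ceiling(max(fit$covariates[[variable]])))
  }
  stopifnot(!is.unsorted(grid))
  yhat <- vapply(grid, function(g) {
    d <- fit$covariates
    d[[variable]] <- g
    mean(stats::predict(fit$model, d))
  }, numeric(1))
  structure(data.frame(day = grid, yhat = yhat),
            class = c("pdp_curve", "data.frame"),
            variable = variable)
}

#' Detect the changepoint of a partial-dependence curve
#'
#' The grid day maximizing the absolute slope of a lightly smoothed curve
#' (centered moving average of width 3, then a centered first difference
#' assigned to the middle day). Ties break toward the smaller day. If the
#' largest jump is below `floor` the curve is considered flat and no
#' changepoint is reported. A manual `override` channel lets visually read
#' changepoints be injected to reproduce published arithmetic.
#'
#' @param curve A `pdp_curve` (or data.frame with `day`, `yhat`).
#' @param floor Minimum absolute smoothed jump (same units as the response).
#' @param override If non-NULL, returned as-is.
#' @return Day value of the changepoint, or `NA` if the curve is flat.
#' @export
detect_changepoint <- function(curve, floor = 0, override = NULL) {
  if (!is.null(override)) return(override)
  stopifnot(nrow(curve) >= 3)
  y <- curve$yhat
  n <- length(y)
  # centered moving average, width 3, partial at the ends
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 1):min(n, i + 1)
    mean(y[w])
  }, numeric(1))
  mid <- 2:(n - 1)
  jumps <- abs(sm[mid + 1] - sm[mid - 1]) / 2
  if (max(jumps) < floor || max(jumps) == 0) return(NA_real_)
  # ties break toward the smaller day; tolerate floating-point jitter
  eps <- max(jumps) * 1e-9
  curve$day[mid[which(jumps >= max(jumps) - eps)[1]]]
}
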
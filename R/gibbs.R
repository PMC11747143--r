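#' Prior specification for the hierarchical model
#'
#' Conjugate priors: normal for every location parameter (basin and grand
#' intercepts, year effects, slopes) and inverse-gamma for every variance
#' (reef, station, basin, year scales). Defaults are deliberately flat:
#' Normal(0, 1e6) and InverseGamma(0.001, 0.001).
#'
#' @param location_mean,location_var Normal prior mean and variance for
#'   location parameters.
#' @param ig_shape,ig_rate Inverse-gamma shape and rate for variances.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(location_mean = 0, location_var = 1e6,
                       ig_shape = 0.001, ig_rate = 0.001) {
  stopifnot(location_var > 0, ig_shape > 0, ig_rate > 0)
  structure(list(location_mean = location_mean, location_var = location_var,
                 ig_shape = ig_shape, ig_rate = ig_rate), class = "prior_spec")
}

#' MCMC settings
#'
#' Defaults: 3 chains of 20,000 iterations, 5,000 burn-in, thinning 5,
#' Gelman-Rubin limit 1.1. Simulation studies in the tests use shorter chains.
#'
#' @param n_chains,n_iter,burn_in,thin Chain geometry.
#' @param psrf_limit Potential-scale-reduction threshold above which a fit is
#'   flagged as non-converged (with a warning, never silently).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 20000, burn_in = 5000, thin = 5,
                          psrf_limit = 1.1) {
  stopifnot(n_chains >= 1, n_iter > burn_in, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 psrf_limit = psrf_limit), class = "mcmc_settings")
}

.level_choices <- c("station-basin-year", "station-basin", "basin-year",
                    "basin", "year")

#' Model specification
#'
#' @param levels Intercept structure: `"station-basin-year"` (station nested
#'   within basin, plus year), `"station-basin"`, `"basin-year"`, `"basin"`,
#'   or `"year"`.
#' @param covariates Character vector of exposure column names entering the
#'   mean linearly (the full five-bin design, or a single column for the
#'   final models).
#' @param quadratic If `TRUE`, `covariates` must name one column and its
#'   square is added as a second term.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(levels = "station-basin-year", covariates = character(0),
                       quadratic = FALSE) {
  levels <- match.arg(levels, .level_choices)
  if (quadratic && length(covariates) != 1) {
    stop("quadratic variant requires exactly one covariate")
  }
  structure(list(levels = levels, covariates = covariates, quadratic = quadratic),
            class = "model_spec")
}

.level_flags <- function(levels) {
  list(station = levels %in% c("station-basin-year", "station-basin"),
       basin = levels %in% c("station-basin-year", "station-basin",
                             "basin-year", "basin"),
       year = levels %in% c("station-basin-year", "basin-year", "year"))
}

# --- conjugate full-conditional primitives ---------------------------------
# Normal location given normal data summary and normal prior:
#   theta | . ~ N(m, 1/prec), prec = data_n/data_var + 1/prior_var,
#   m = (data_sum/data_var + prior_mean/prior_var)/prec.
# Vectorized over groups. For a slope with design x, pass data_sum = sum(x*r),
# data_n = sum(x^2), data_var = sigma^2.
.cond_location <- function(prior_mean, prior_var, data_sum, data_n, data_var) {
  prec <- data_n / data_var + 1 / prior_var
  m <- (data_sum / data_var + prior_mean / prior_var) / prec
  stats::rnorm(length(m), m, sqrt(1 / prec))
}

.rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# Variance given sum of squares around the current means:
#   sig2 | . ~ IG(shape0 + n/2, rate0 + ss/2)
.cond_variance <- function(shape0, rate0, n_data, ss) {
  .rinvgamma(1, shape0 + n_data / 2, rate0 + ss / 2)
}

# Joint multivariate normal update for the slope vector.
.cond_slopes <- function(prior_mean, prior_var, XtX, Xtr, sig2) {
  p <- nrow(XtX)
  P <- XtX / sig2 + diag(1 / prior_var, p)
  U <- tryCatch(chol(P), error = function(e) {
    stop("degenerate covariate design (non-positive-definite); check for ",
         "constant or collinear exposure columns")
  })
  m <- backsolve(U, forwardsolve(t(U), Xtr / sig2 + rep(prior_mean / prior_var, p)))
  as.numeric(m + backsolve(U, stats::rnorm(p)))
}

.group_sizes <- function(idx, nlev) tabulate(idx, nbins = nlev)
.group_sums <- function(x, idx, nlev) {
  out <- numeric(nlev)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# One chain of the Gibbs sampler. Returns a matrix of retained draws.
.gibbs_chain <- function(y, X, st, ba, yr, ba_of_st, flags, priors, mcmc, seed) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  J <- if (flags$station) max(st) else 0L
  I <- if (flags$basin) max(ba) else 0L
  K <- if (flags$year) max(yr) else 0L
  m0 <- priors$location_mean; v0 <- priors$location_var
  a0 <- priors$ig_shape; b0 <- priors$ig_rate

  gamma <- rep(0, p)
  beta <- rep(mean(y), J)
  alpha <- rep(mean(y), I)
  alpha0 <- mean(y)
  lambda <- rep(0, K)
  sig2 <- max(stats::var(y), 1e-8)
  sig2_st <- sig2_ba <- sig2_yr <- max(stats::var(y), 1e-8)

  if (p > 0) XtX <- crossprod(X)
  n_st <- if (flags$station) .group_sizes(st, J)
  n_ba <- if (flags$basin && !flags$station) .group_sizes(ba, I)
  n_yr <- if (flags$year) .group_sizes(yr, K)
  J_ba <- if (flags$station) .group_sizes(ba_of_st, I)

  keep <- seq(mcmc$burn_in + mcmc$thin, mcmc$n_iter, by = mcmc$thin)
  nm <- c(if (p > 0) paste0("gamma.", colnames(X)),
          if (flags$station) paste0("beta.", levels(attr(st, "fac"))),
          if (flags$basin) paste0("alpha.", levels(attr(ba, "fac"))),
          "alpha0",
          if (flags$year) paste0("lambda.", levels(attr(yr, "fac"))),
          "sigma2",
          if (flags$station) "sigma2_station",
          if (flags$basin) "sigma2_basin",
          if (flags$year) "sigma2_year")
  out <- matrix(NA_real_, length(keep), length(nm), dimnames = list(NULL, nm))
  ki <- 0L

  for (it in seq_len(mcmc$n_iter)) {
    int_obs <- if (flags$station) beta[st] else if (flags$basin) alpha[ba] else rep(alpha0, n)
    lam_obs <- if (flags$year) lambda[yr] else 0

    if (p > 0) {
      r <- y - int_obs - lam_obs
      gamma <- .cond_slopes(m0, v0, XtX, crossprod(X, r), sig2)
    }
    xg <- if (p > 0) as.numeric(X %*% gamma) else 0

    if (flags$station) {
      r <- y - lam_obs - xg
      beta <- .cond_location(alpha[ba_of_st], sig2_st,
                             .group_sums(r, st, J), n_st, sig2)
      int_obs <- beta[st]
    }
    if (flags$basin) {
      if (flags$station) {
        alpha <- .cond_location(alpha0, sig2_ba,
                                .group_sums(beta, ba_of_st, I), J_ba, sig2_st)
      } else {
        r <- y - lam_obs - xg
        alpha <- .cond_location(alpha0, sig2_ba,
                                .group_sums(r, ba, I), n_ba, sig2)
        int_obs <- alpha[ba]
      }
    }
    if (flags$basin) {
      alpha0 <- .cond_location(m0, v0, sum(alpha), I, sig2_ba)
    } else {
      r <- y - lam_obs - xg
      alpha0 <- .cond_location(m0, v0, sum(r), n, sig2)
      int_obs <- rep(alpha0, n)
    }
    if (flags$year) {
      r <- y - int_obs - xg
      lambda <- .cond_location(0, sig2_yr, .group_sums(r, yr, K), n_yr, sig2)
      lam_obs <- lambda[yr]
    }

    resid <- y - int_obs - lam_obs - xg
    sig2 <- .cond_variance(a0, b0, n, sum(resid^2))
    if (flags$station) {
      sig2_st <- .cond_variance(a0, b0, J, sum((beta - alpha[ba_of_st])^2))
    }
    if (flags$basin) {
      sig2_ba <- .cond_variance(a0, b0, I, sum((alpha - alpha0)^2))
    }
    if (flags$year) {
      sig2_yr <- .cond_variance(a0, b0, K, sum(lambda^2))
    }

    if (ki < length(keep) && it == keep[ki + 1L]) {
      ki <- ki + 1L
      out[ki, ] <- c(if (p > 0) gamma,
                     if (flags$station) beta,
                     if (flags$basin) alpha,
                     alpha0,
                     if (flags$year) lambda,
                     sig2,
                     if (flags$station) sig2_st,
                     if (flags$basin) sig2_ba,
                     if (flags$year) sig2_yr)
    }
  }
  out
}

# Merge abundance and exposure and build the design for a spec.
.build_design <- function(abundance, exposure, spec) {
  need <- spec$covariates
  miss <- setdiff(need, names(exposure))
  if (length(miss)) stop("exposure table lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  dat <- merge(abundance, exposure, by = c("station_id", "basin_id", "year"))
  if (nrow(dat) < nrow(abundance)) {
    stop("exposure table lacks rows for ", nrow(abundance) - nrow(dat),
         " abundance station-year(s)")
  }
  X <- as.matrix(dat[, need, drop = FALSE])
  if (spec$quadratic) {
    X <- cbind(X, X[, 1]^2)
    colnames(X) <- c(need, paste0(need, ".sq"))
  }
  fac <- function(x) {
    f <- factor(x)
    i <- as.integer(f)
    attr(i, "fac") <- f
    i
  }
  st <- fac(dat$station_id)
  ba <- fac(dat$basin_id)
  yr <- fac(dat$year)
  # basin of each station, aligned with station factor levels
  ba_of_st <- as.integer(factor(
    dat$basin_id[match(levels(attr(st, "fac")), dat$station_id)],
    levels = levels(attr(ba, "fac"))))
  list(y = dat$abundance, X = X, st = st, ba = ba, yr = yr,
       ba_of_st = ba_of_st, data = dat)
}

#' Fit the hierarchical abundance model by Gibbs sampling
#'
#' Abundance is normal around a linear predictor built from an intercept
#' hierarchy (station nested within basin, basin, year, per `spec$levels`) and
#' exposure covariates. All full conditionals are conjugate (normal for
#' locations, inverse-gamma for variances) and are sampled exactly; multiple
#' chains with a per-chain seed offset; Gelman-Rubin diagnostics per
#' parameter.
#'
#' @param abundance Abundance table (`station_id`, `basin_id`, `year`,
#'   `abundance`), e.g. from [collate_season()].
#' @param exposure Exposure table from [build_exposure_table()].
#' @param spec A [model_spec()].
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_settings()].
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return An object of class `oyster_fit`: `draws` (matrix, one column per
#'   parameter), `chains` (list of per-chain matrices), `spec`, `psrf`,
#'   `converged`, `dic`, `ppl`, and the model frame.
#' @export
gibbs_fit <- function(abundance, exposure, spec, priors = prior_spec(),
                      mcmc = mcmc_settings(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_settings"))
  d <- .build_design(abundance, exposure, spec)
  flags <- .level_flags(spec$levels)
  if (flags$station && max(d$st) < 2) {
    stop("station-level variance requested but the data hold a single station")
  }
  chains <- lapply(seq_len(mcmc$n_chains), function(c) {
    .gibbs_chain(d$y, d$X, d$st, d$ba, d$yr, d$ba_of_st, flags, priors, mcmc,
                 seed = seed + c)
  })
  draws <- do.call(rbind, chains)
  psrf <- rep(NA_real_, ncol(draws))
  names(psrf) <- colnames(draws)
  if (mcmc$n_chains >= 2) {
    ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
    psrf <- tryCatch(
      coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
      error = function(e) psrf)
  }
  converged <- all(is.na(psrf) | psrf <= mcmc$psrf_limit)
  if (!converged) {
    warning("potential scale reduction above ", mcmc$psrf_limit, " for: ",
            paste(names(psrf)[!is.na(psrf) & psrf > mcmc$psrf_limit], collapse = ", "))
  }
  fit <- structure(list(spec = spec, priors = priors, mcmc = mcmc, seed = seed,
                        draws = draws, chains = chains, psrf = psrf,
                        converged = converged, y = d$y, X = d$X,
                        st = d$st, ba = d$ba, yr = d$yr,
                        model_frame = d$data),
                   class = "oyster_fit")
  fit$dic <- dic(fit)
  fit$ppl <- ppl(fit)
  fit
}

#' @export
print.oyster_fit <- function(x, ...) {
  cat("Hierarchical abundance fit (", x$spec$levels, ")\n", sep = "")
  cat("  covariates:", if (length(x$spec$covariates)) paste(x$spec$covariates, collapse = ", ") else "none",
      if (x$spec$quadratic) "(+ quadratic)", "\n")
  cat("  n =", length(x$y), " draws =", nrow(x$draws),
      " DIC =", round(x$dic, 1), " PPL =", round(x$ppl, 1),
      if (!x$converged) " [NOT CONVERGED]", "\n")
  invisible(x)
}

# Linear predictor for each retained draw: S x n matrix.
.linpred_draws <- function(fit, draws = fit$draws) {
  flags <- .level_flags(fit$spec$levels)
  n <- length(fit$y)
  S <- nrow(draws)
  if (flags$station) {
    cols <- paste0("beta.", levels(attr(fit$st, "fac")))
    mu <- draws[, cols, drop = FALSE][, fit$st, drop = FALSE]
  } else if (flags$basin) {
    cols <- paste0("alpha.", levels(attr(fit$ba, "fac")))
    mu <- draws[, cols, drop = FALSE][, fit$ba, drop = FALSE]
  } else {
    mu <- matrix(draws[, "alpha0"], S, n)
  }
  if (flags$year) {
    cols <- paste0("lambda.", levels(attr(fit$yr, "fac")))
    mu <- mu + draws[, cols, drop = FALSE][, fit$yr, drop = FALSE]
  }
  if (ncol(fit$X) > 0) {
    g <- draws[, paste0("gamma.", colnames(fit$X)), drop = FALSE]
    mu <- mu + g %*% t(fit$X)
  }
  mu
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with D(theta) = -2 log-likelihood under the normal
#' observation model and pD = Dbar - D(posterior means). Deterministic given
#' the saved draws.
#'
#' @param fit An `oyster_fit`.
#' @return DIC value.
#' @export
dic <- function(fit) {
  if (nrow(fit$draws) == 0) stop("no posterior draws")
  mu <- .linpred_draws(fit)
  sig2 <- fit$draws[, "sigma2"]
  n <- length(fit$y)
  # per-draw deviance, vectorized over observations
  dev <- -2 * (rowSums(stats::dnorm(matrix(fit$y, nrow(mu), n, byrow = TRUE),
                                    mu, sqrt(sig2), log = TRUE)))
  dbar <- mean(dev)
  mu_hat <- colMeans(mu)
  sig2_hat <- mean(sig2)
  dhat <- -2 * sum(stats::dnorm(fit$y, mu_hat, sqrt(sig2_hat), log = TRUE))
  dbar + (dbar - dhat)
}

#' Posterior predictive loss
#'
#' Squared-error form: goodness-of-fit term (squared differences between the
#' observations and posterior-predictive means) plus a penalty term (sum of
#' posterior-predictive variances). For the normal model the predictive
#' variance decomposes as var over draws of the mean plus the mean residual
#' variance. Deterministic given the saved draws.
#'
#' @param fit An `oyster_fit`.
#' @return PPL value.
#' @export
ppl <- function(fit) {
  if (nrow(fit$draws) == 0) stop("no posterior draws")
  mu <- .linpred_draws(fit)
  e_rep <- colMeans(mu)
  v_rep <- apply(mu, 2, stats::var) + mean(fit$draws[, "sigma2"])
  sum((fit$y - e_rep)^2) + sum(v_rep)
}

#' Rank fitted models by DIC or PPL
#'
#' Models sharing the same hierarchy are ranked by DIC, with every model
#' within 2 DIC of the best flagged co-best; models with differing hierarchy
#' levels are ranked by PPL (DIC is not comparable across hierarchies), where
#' co-best is the single lowest-PPL model.
#'
#' @param fits List of `oyster_fit` objects on the same response data.
#' @param labels Optional model labels.
#' @return Data frame ordered by the ranking metric, with columns `model`,
#'   `levels`, `covariates`, `dic`, `ppl`, `metric`, `co_best`.
#' @export
compare_models <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1)
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (length(f$y) != length(y0) || any(sort(f$y) != sort(y0))) {
      stop("models were fitted to different response data")
    }
  }
  if (is.null(labels)) {
    labels <- vapply(fits, function(f) {
      paste0(f$spec$levels, if (length(f$spec$covariates))
        paste0(" | ", paste(f$spec$covariates, collapse = "+")))
    }, character(1))
  }
  tab <- data.frame(
    model = labels,
    levels = vapply(fits, function(f) f$spec$levels, character(1)),
    covariates = vapply(fits, function(f)
      paste(f$spec$covariates, collapse = "+"), character(1)),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    ppl = vapply(fits, function(f) f$ppl, numeric(1)),
    stringsAsFactors = FALSE)
  same_levels <- length(unique(tab$levels)) == 1
  tab$metric <- if (same_levels) "dic" else "ppl"
  ord <- order(if (same_levels) tab$dic else tab$ppl)
  tab <- tab[ord, ]
  tab$co_best <- if (same_levels) tab$dic - min(tab$dic) <= 2 else
    seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' Classify a coefficient's sign from its posterior
#'
#' Equal-tailed credible intervals: `negative-95` when the 95% CI lies below
#' zero, `negative-50` when only the 50% CI does, symmetrically for positive,
#' and `indeterminate` when both intervals straddle zero.
#'
#' @param fit An `oyster_fit`.
#' @param coefficient Parameter name (a covariate name resolves to its
#'   `gamma.` column).
#' @return One of `"negative-95"`, `"negative-50"`, `"positive-95"`,
#'   `"positive-50"`, `"indeterminate"`.
#' @export
classify_effect <- function(fit, coefficient) {
  col <- if (coefficient %in% colnames(fit$draws)) coefficient else
    paste0("gamma.", coefficient)
  if (!col %in% colnames(fit$draws)) stop("no such coefficient: ", coefficient)
  q <- stats::quantile(fit$draws[, col], c(0.025, 0.25, 0.75, 0.975), names = FALSE)
  if (q[4] < 0) "negative-95"
  else if (q[1] > 0) "positive-95"
  else if (q[3] < 0) "negative-50"
  else if (q[2] > 0) "positive-50"
  else "indeterminate"
}

#' Fit the quadratic variant of a single-covariate model
#'
#' Adds the squared covariate to the linear predictor, with the same sampler
#' machinery, to probe curvature in positive relations.
#'
#' @inheritParams gibbs_fit
#' @return An `oyster_fit` with coefficients for the linear and squared terms.
#' @export
fit_quadratic_variant <- function(abundance, exposure, spec, priors = prior_spec(),
                                  mcmc = mcmc_settings(), seed = 1L) {
  if (length(spec$covariates) != 1) stop("quadratic variant requires one covariate")
  spec2 <- model_spec(spec$levels, spec$covariates, quadratic = TRUE)
  gibbs_fit(abundance, exposure, spec2, priors, mcmc, seed)
}
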
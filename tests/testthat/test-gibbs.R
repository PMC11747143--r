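# A tiny dataset shared by several blocks: 2 basins x 2 stations x 3 years.
small_data <- function(sigma = 1, gamma = 0, seed = 42, value = NULL) {
  set.seed(seed)
  grid <- expand.grid(station = 1:2, basin = c("Barataria", "Terrebonne"),
                      year = 2016:2018, stringsAsFactors = FALSE)
  grid$station_id <- paste0(grid$basin, "-S", grid$station)
  x <- sample(0:60, nrow(grid), replace = TRUE)
  mu <- 30 + gamma * x
  y <- if (is.null(value)) rnorm(nrow(grid), mu, sigma) else rep(value, nrow(grid))
  abundance <- data.frame(station_id = grid$station_id, basin_id = grid$basin,
                          year = grid$year, abundance = y, stringsAsFactors = FALSE)
  exposure <- data.frame(station_id = grid$station_id, basin_id = grid$basin,
                         year = grid$year, c.d_su0.1 = x, stringsAsFactors = FALSE)
  list(abundance = abundance, exposure = exposure)
}

test_that("draw bookkeeping matches the chain geometry and variances are positive", {
  d <- small_data()
  mc <- mcmc_settings(n_chains = 2, n_iter = 600, burn_in = 200, thin = 4)
  fit <- gibbs_fit(d$abundance, d$exposure, model_spec("station-basin-year", "c.d_su0.1"),
                   mcmc = mc, seed = 1)
  expect_equal(nrow(fit$draws), (600 - 200) / 4 * 2)
  expect_true(all(fit$draws[, "sigma2"] > 0))
  expect_true(all(fit$draws[, "sigma2_station"] > 0))
  expect_true(all(c("gamma.c.d_su0.1", "alpha.Barataria", "lambda.2016") %in%
                    colnames(fit$draws)))
})

test_that("the intercept-only posterior collapses to constant data", {
  d <- small_data(value = 17)
  fit <- gibbs_fit(d$abundance, d$exposure, model_spec("year"),
                   mcmc = test_mcmc(), seed = 2)
  expect_lt(abs(mean(fit$draws[, "alpha0"]) - 17), 0.2)
})

test_that("a planted negative slope is recovered inside its credible interval", {
  fx <- make_fixture("negative-slope-east", seed = 3)
  fit <- gibbs_fit(fx$abundance, fx$exposure,
                   model_spec("station-basin-year", "c.d_su0.1"),
                   mcmc = test_mcmc(), seed = 3)
  g <- fit$draws[, "gamma.c.d_su0.1"]
  ci <- quantile(g, c(0.025, 0.975))
  expect_lt(ci[1], -0.6)
  expect_gt(ci[2], -0.6)
  expect_lt(abs(mean(g) + 0.6), 0.15)
  expect_equal(classify_effect(fit, "c.d_su0.1"), "negative-95")
})

test_that("chains started from different seeds agree within Monte-Carlo error", {
  fx <- make_fixture("negative-slope-east", seed = 5, stations_per_basin = 4)
  f1 <- gibbs_fit(fx$abundance, fx$exposure,
                  model_spec("station-basin-year", "c.d_su0.1"),
                  mcmc = test_mcmc(), seed = 11)
  f2 <- gibbs_fit(fx$abundance, fx$exposure,
                  model_spec("station-basin-year", "c.d_su0.1"),
                  mcmc = test_mcmc(), seed = 222)
  expect_lt(abs(mean(f1$draws[, "gamma.c.d_su0.1"]) -
                mean(f2$draws[, "gamma.c.d_su0.1"])), 0.05)
  # the identified slope mixes well even at these short chain lengths
  expect_lt(f1$psrf[["gamma.c.d_su0.1"]], 1.1)
})

test_that("non-convergence is flagged loudly, never silently", {
  fx <- make_fixture("negative-slope-east", seed = 13, stations_per_basin = 3)
  expect_warning(
    fit <- gibbs_fit(fx$abundance, fx$exposure,
                     model_spec("station-basin-year", "c.d_su0.1"),
                     mcmc = mcmc_settings(n_chains = 2, n_iter = 60, burn_in = 20,
                                          thin = 1), seed = 13),
    "potential scale reduction")
  expect_false(fit$converged)
})

test_that("a single station cannot carry station-level variance", {
  d <- small_data()
  one <- d$abundance$station_id == "Barataria-S1"
  expect_error(gibbs_fit(d$abundance[one, ], d$exposure[one, ],
                         model_spec("station-basin", "c.d_su0.1"),
                         mcmc = test_mcmc()),
               "single station")
})

test_that("DIC and PPL are deterministic and degenerate draws give pD = 0", {
  d <- small_data(sigma = 2)
  fit <- gibbs_fit(d$abundance, d$exposure, model_spec("basin", "c.d_su0.1"),
                   mcmc = test_mcmc(), seed = 4)
  expect_equal(dic(fit), dic(fit))
  expect_equal(ppl(fit), ppl(fit))
  # collapse the posterior to a point: pD = 0 so DIC = D(theta)
  point <- fit
  point$draws <- fit$draws[rep(1, 100), ]
  mu <- oysterthresh:::.linpred_draws(point)[1, ]
  dev <- -2 * sum(dnorm(point$y, mu, sqrt(point$draws[1, "sigma2"]), log = TRUE))
  expect_equal(dic(point), dev, tolerance = 1e-10)
  # and the PPL penalty drops to the pure residual-variance term
  expect_equal(ppl(point),
               unname(sum((point$y - mu)^2) +
                        length(point$y) * point$draws[1, "sigma2"]),
               tolerance = 1e-10)
})

test_that("model comparison applies the two-DIC co-best rule", {
  mk <- function(dic, ppl = 0, levels = "basin") {
    structure(list(spec = model_spec(levels, "c.d_su0.1"), y = c(1, 2, 3),
                   dic = dic, ppl = ppl), class = "oyster_fit")
  }
  fits <- list(mk(100), mk(101.5), mk(110))
  cmp <- compare_models(fits, labels = c("a", "b", "c"))
  expect_equal(cmp$model[cmp$co_best], c("a", "b"))
  expect_equal(cmp$metric[1], "dic")
  # ranking is invariant to input order
  cmp2 <- compare_models(fits[c(3, 1, 2)], labels = c("c", "a", "b"))
  expect_equal(cmp2$model, cmp$model)
  # differing hierarchy levels switch the metric to PPL
  fits2 <- list(mk(100, ppl = 50), mk(90, ppl = 60, levels = "basin-year"))
  cmp3 <- compare_models(fits2, labels = c("a", "b"))
  expect_equal(cmp3$metric[1], "ppl")
  expect_equal(cmp3$model[1], "a")
  expect_equal(sum(cmp3$co_best), 1)
  # single fit ranks as itself
  expect_equal(nrow(compare_models(fits[1], labels = "a")), 1)
  # different responses are rejected
  other <- mk(100); other$y <- c(9, 9, 9)
  expect_error(compare_models(list(fits[[1]], other)), "different response")
})

test_that("sign classification reads equal-tailed credible intervals", {
  base <- fake_fit()
  neg <- base; neg$draws[, "gamma.c.d_su0.1"] <- -abs(rnorm(200))
  expect_equal(classify_effect(neg, "c.d_su0.1"), "negative-95")
  sym <- base; sym$draws[, "gamma.c.d_su0.1"] <- rep(c(-1, 1), 100)
  expect_equal(classify_effect(sym, "c.d_su0.1"), "indeterminate")
  # 95% CI straddles zero but both quartiles are negative
  n50 <- base
  n50$draws <- n50$draws[rep(1, 1000), ]
  n50$draws[, "gamma.c.d_su0.1"] <- c(rep(-2, 20), rep(-1, 950), rep(1, 30))
  expect_equal(classify_effect(n50, "c.d_su0.1"), "negative-50")
  pos <- base; pos$draws[, "gamma.c.d_su0.1"] <- abs(rnorm(200))
  expect_equal(classify_effect(pos, "c.d_su0.1"), "positive-95")
  expect_error(classify_effect(base, "nonexistent"), "no such coefficient")
})

test_that("the quadratic variant detects curvature and ignores its absence", {
  set.seed(9)
  d <- small_data()
  x <- d$exposure$c.d_su0.1
  # true quadratic response
  d$abundance$abundance <- 40 + 0.9 * x - 0.02 * x^2 + rnorm(length(x), 0, 1)
  lin <- gibbs_fit(d$abundance, d$exposure, model_spec("basin", "c.d_su0.1"),
                   mcmc = test_mcmc(), seed = 5)
  quad <- fit_quadratic_variant(d$abundance, d$exposure,
                                model_spec("basin", "c.d_su0.1"),
                                mcmc = test_mcmc(), seed = 5)
  expect_lt(quad$dic, lin$dic - 2)
  expect_lt(abs(mean(quad$draws[, "gamma.c.d_su0.1.sq"]) + 0.02), 0.02)
  # truly linear response: the quadratic term buys nothing decisive
  d2 <- small_data(sigma = 1, gamma = -0.5, seed = 10)
  lin2 <- gibbs_fit(d2$abundance, d2$exposure, model_spec("basin", "c.d_su0.1"),
                    mcmc = test_mcmc(), seed = 6)
  quad2 <- fit_quadratic_variant(d2$abundance, d2$exposure,
                                 model_spec("basin", "c.d_su0.1"),
                                 mcmc = test_mcmc(), seed = 6)
  expect_gt(quad2$dic, lin2$dic - 2)
})
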
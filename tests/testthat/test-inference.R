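test_that("settings are validated, including the retained-draw floor", {
  expect_error(mcmc_settings(n_chains = 1L), "n_chains")
  expect_error(mcmc_settings(n_iterations = 1000L, n_burnin = 2000L), "n_iterations")
  expect_error(mcmc_settings(n_iterations = 1200L, n_burnin = 1000L, thin = 5L),
               "at least 100")
  s <- mcmc_settings(n_iterations = 1500L, n_burnin = 1000L, thin = 5L)
  expect_s3_class(s, "mcmc_settings")
})

test_that("with the likelihood disabled the sampler reproduces the prior", {
  # flat prior, K = 6: every mean ~ 1/6
  ds <- generate_scenario(6L, study_proxies(), rep(1 / 6, 6), seed = 2L)$dataset
  fit <- suppressWarnings(
    sample_posterior(ds, settings = mcmc_settings(seed = 4L), use_likelihood = FALSE))
  means <- colMeans(pooled_draws(fit))
  expect_lt(max(abs(means - 1 / 6)), 0.02)

  # constrained prior: sampler means match rejection-sampling means within
  # 3 Monte-Carlo standard errors
  ids <- source_ids(ds)
  ps <- diet_prior_set(ds$target$taxon_id,
                       constraints = list(rank_constraint(ids[1:4])),
                       excluded_sources = character())
  fit_c <- suppressWarnings(
    sample_posterior(ds, ps, fast_settings(seed = 5L), use_likelihood = FALSE))
  mc <- colMeans(pooled_draws(fit_c))
  ref <- prior_predictive_means(ps, ids, n_draws = 40000L, seed = 6L)
  se <- apply(pooled_draws(fit_c), 2L, stats::sd) /
    sqrt(unname(fit_c$diagnostics$ess))
  expect_true(all(abs(mc - ref[ids]) < pmax(3 * se, 0.02)))
})

test_that("a symmetric two-source system splits 50/50", {
  px <- toy_proxy("x", offset = 0, offset_sd = 0)
  ds <- mixing_dataset(list(px),
                       list(toy_source("a", c(x = -5), sds = 0),
                            toy_source("b", c(x = 5), sds = 0)),
                       toy_source("t", c(x = 0), sds = 0.2))
  fit <- suppressWarnings(sample_posterior(ds, settings = fast_settings(seed = 7L)))
  sm <- summarize_posterior(fit)
  expect_equal(sm$mean, c(50, 50), tolerance = 3)
  expect_equal(sum(sm$mean), 100, tolerance = 0.1)
})

test_that("marginal posterior means agree with dense grid enumeration on toy systems", {
  # three sources, two proxies, pinned latents: the sampler must match
  # brute-force likelihood-weighted averaging over a 0.01-step simplex grid
  set.seed(21)
  worst <- 0
  for (rep in 1:5) {
    means_x <- sort(runif(3, -10, 10))
    means_y <- runif(3, 0, 8)
    ds <- mixing_dataset(
      list(toy_proxy("x", offset = 0.5), toy_proxy("y", offset = 1)),
      list(toy_source("a", c(x = means_x[1], y = means_y[1])),
           toy_source("b", c(x = means_x[2], y = means_y[2])),
           toy_source("c", c(x = means_x[3], y = means_y[3]))),
      toy_source("t", c(x = mean(means_x) + 0.5 + rnorm(1, 0, 0.5),
                        y = mean(means_y) + 1 + rnorm(1, 0, 0.5)),
                 sds = c(0.8, 0.8)))
    oracle <- grid_posterior_means(ds, h = 0.01)
    fit <- suppressWarnings(sample_posterior(ds, settings = fast_settings(seed = rep)))
    got <- colMeans(pooled_draws(fit))
    worst <- max(worst, max(abs(got - oracle)))
  }
  expect_lt(worst, 0.02)
})

test_that("chains are reproducible bit-for-bit and respect constraints", {
  ds <- generate_scenario(4L, study_proxies(c("d13C", "d15N")), c(0.4, 0.3, 0.2, 0.1),
                          seed = 3L)$dataset
  ids <- source_ids(ds)
  ps <- diet_prior_set(ds$target$taxon_id,
                       constraints = list(rank_constraint(ids[c(1, 2)])))
  f1 <- suppressWarnings(sample_posterior(ds, ps, fast_settings(seed = 9L)))
  f2 <- suppressWarnings(sample_posterior(ds, ps, fast_settings(seed = 9L)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(sample_posterior(ds, ps, fast_settings(seed = 10L)))
  expect_false(identical(f1$draws, f3$draws))
  # every retained draw is admissible and on the simplex
  d <- pooled_draws(f1)
  expect_true(all(abs(rowSums(d) - 1) < 1e-10))
  expect_true(all(d[, ids[1]] > d[, ids[2]]))
})

test_that("posterior summaries report means, medians and central intervals on the % scale", {
  # constant chain: degenerate summary
  const <- matrix(rep(c(0.6, 0.4), each = 200), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  sm <- summarize_posterior(fake_chains(list(const, const)))
  expect_equal(sm$mean, c(60, 40))
  expect_equal(sm$median, c(60, 40))
  expect_equal(sm$sd, c(0, 0))
  expect_equal(sm$ci95_low, sm$ci95_high)

  # Beta(2,2)-distributed first coordinate: known quantiles
  set.seed(33)
  x <- rbeta(200000, 2, 2)
  draws <- cbind(a = x, b = 1 - x)
  sm2 <- summarize_posterior(fake_chains(list(draws)))
  expect_equal(sm2$mean[1], 50, tolerance = 0.5)
  expect_equal(sm2$ci95_low[1], 100 * qbeta(0.025, 2, 2), tolerance = 0.5)
  expect_equal(sm2$ci95_high[1], 100 * qbeta(0.975, 2, 2), tolerance = 0.5)
  expect_equal(sm2$ci68_low[1], 100 * qbeta(0.16, 2, 2), tolerance = 0.5)
  # nesting: ci95 contains ci68 contains median
  expect_true(all(sm2$ci95_low <= sm2$ci68_low & sm2$ci68_low <= sm2$median &
                  sm2$median <= sm2$ci68_high & sm2$ci68_high <= sm2$ci95_high))
  expect_error(summarize_posterior(fake_chains(list(draws[1:10, ]))), "100")
})

test_that("convergence diagnostics detect agreement and disagreement", {
  set.seed(44)
  x <- cbind(a = rbeta(1000, 2, 3)); x <- cbind(x, b = 1 - x[, 1])
  same <- fake_chains(list(x, x))
  rep_same <- convergence_report(same)
  expect_equal(rep_same$rhat, c(1, 1), tolerance = 0.01)

  # disjoint supports: R-hat far above 1.1
  lo <- cbind(a = runif(500, 0, 0.1)); lo <- cbind(lo, b = 1 - lo[, 1])
  hi <- cbind(a = runif(500, 0.9, 1)); hi <- cbind(hi, b = 1 - hi[, 1])
  rep_bad <- convergence_report(fake_chains(list(lo, hi)))
  expect_gt(rep_bad$rhat[1], 3)

  # independent draws: ESS close to the number of retained draws
  ind <- fake_chains(list(x, cbind(a = rbeta(1000, 2, 3), b = runif(1000))))
  expect_gt(min(convergence_report(ind)$ess), 1600)

  # sample_posterior surfaces poor convergence as a warning, not an error
  ds <- mixing_dataset(list(toy_proxy("x")),
                       list(toy_source("a", c(x = -5)), toy_source("b", c(x = 5))),
                       toy_source("t", c(x = 0), sds = 0.2))
  expect_warning(
    sample_posterior(ds, settings = mcmc_settings(n_iterations = 1600L,
                                                  n_burnin = 1000L, thin = 1L,
                                                  min_ess = 10000L, seed = 1L)),
    "diagnostics")
})

test_that("structural errors are raised before sampling", {
  ds <- mixing_dataset(list(toy_proxy("x")),
                       list(toy_source("a", c(x = -5)), toy_source("b", c(x = 5))),
                       toy_source("t", c(x = 0), sds = 0))
  # zero target SD cannot feed a Gaussian likelihood
  expect_error(sample_posterior(ds, settings = fast_settings()), "positive target SD")
  # infeasible prior fails before any chain runs
  bad <- diet_prior_set("t", constraints = list(rank_constraint(c("a", "b")),
                                                rank_constraint(c("b", "a"))))
  ds2 <- mixing_dataset(list(toy_proxy("x")),
                        list(toy_source("a", c(x = -5)), toy_source("b", c(x = 5))),
                        toy_source("t", c(x = 0), sds = 0.3))
  expect_error(sample_posterior(ds2, bad, fast_settings()), "infeasible")
})
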
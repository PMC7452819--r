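test_that("mixing prediction matches hand-computed convex combinations", {
  px <- toy_proxy("d13C", offset = 0.5)
  # one source: prediction is source + offset
  ds1 <- mixing_dataset(list(px),
                        list(toy_source("a", c(d13C = -24.14)),
                             toy_source("b", c(d13C = -24.14))),
                        toy_source("t", c(d13C = -23)))
  st <- latent_state(c(1, 0), ds1)
  expect_equal(predict_target_proxy(st, ds1, 1L), -24.14 + 0.5)
  # identical offset-shifted sources: p is unidentifiable in the mean
  ds2 <- mixing_dataset(list(toy_proxy("x", offset = 0)),
                        list(toy_source("a", c(x = 10)), toy_source("b", c(x = 10))),
                        toy_source("t", c(x = 10)))
  for (p1 in c(0, 0.3, 1))
    expect_equal(predict_target_proxy(latent_state(c(p1, 1 - p1), ds2), ds2, 1L), 10)
  # equal concentrations, equal split
  ds3 <- mixing_dataset(list(px),
                        list(toy_source("a", c(d13C = -24)), toy_source("b", c(d13C = -20))),
                        toy_source("t", c(d13C = -22)))
  expect_equal(predict_target_proxy(latent_state(c(0.5, 0.5), ds3), ds3, 1L), -21.5)
  # concentration weighting: a near-zero %C source barely contributes
  ds4 <- mixing_dataset(list(toy_proxy("d13C")),
                        list(toy_source("a", c(d13C = -24), pct_c = 60),
                             toy_source("b", c(d13C = -20), pct_c = 0.11)),
                        toy_source("t", c(d13C = -22)),
                        concentration_dependent = TRUE)
  expect_equal(predict_target_proxy(latent_state(c(0.5, 0.5), ds4), ds4, 1L),
               (0.5 * 60 * -24 + 0.5 * 0.11 * -20) / (0.5 * 60 + 0.5 * 0.11),
               tolerance = 1e-12)
})

test_that("degenerate mixtures and dimension mismatches are rejected", {
  ds <- mixing_dataset(list(toy_proxy("x", basis = "carbon")),
                       list(toy_source("a", c(x = 1), pct_c = 0, pct_n = 5),
                            toy_source("b", c(x = 2), pct_c = 50)),
                       toy_source("t", c(x = 1.5)),
                       concentration_dependent = TRUE)
  st <- latent_state(c(1, 0), ds)  # all mass on the zero-%C source
  expect_error(predict_target_proxy(st, ds, 1L), "degenerate|concentration weight")
  expect_error(predict_target_proxy(st, ds, 3L), "unknown proxy")
  expect_error(latent_state(c(0.5, 0.5, 0), ds), "length")
  expect_error(latent_state(c(0.7, 0.7), ds), "sum to 1")
})

test_that("log-density reduces to Gaussian terms and penalises misfit quadratically", {
  # shared-offset dataset, all SDs 1, target equal to the predicted mixture:
  # each of the (target + 2 sources + 1 offset) standard-normal terms
  # contributes -log(2*pi)/2
  px <- toy_proxy("x", offset = 1, offset_sd = 1)
  mk <- function(target_mean) mixing_dataset(
    list(px),
    list(toy_source("a", c(x = -2), sds = 1), toy_source("b", c(x = 2), sds = 1)),
    toy_source("t", stats::setNames(target_mean, "x"), sds = 1),
    offset_mode = "shared")
  ds <- mk(1)  # 0.5*(-2+1) + 0.5*(2+1) = 1
  st <- latent_state(c(0.5, 0.5), ds)
  expect_equal(log_density(st, ds), 4 * (-0.5 * log(2 * pi)))
  # observing the target 1 SD off the prediction costs exactly 1/2
  ds_off <- mk(2)
  expect_equal(log_density(st, ds) - log_density(latent_state(c(0.5, 0.5), ds_off), ds_off),
               0.5)
  # per-source mode has one offset term per source
  ds_ps <- mixing_dataset(
    list(px),
    list(toy_source("a", c(x = -2), sds = 1), toy_source("b", c(x = 2), sds = 1)),
    toy_source("t", c(x = 1), sds = 1), offset_mode = "per_source")
  expect_equal(log_density(latent_state(c(0.5, 0.5), ds_ps), ds_ps),
               5 * (-0.5 * log(2 * pi)))
  # violating an active rank constraint yields -Inf
  ps <- diet_prior_set("t", constraints = list(rank_constraint(c("a", "b"))))
  expect_identical(log_density(latent_state(c(0.2, 0.8), ds), ds, ps), -Inf)
  expect_true(is.finite(log_density(latent_state(c(0.8, 0.2), ds), ds, ps)))
})

test_that("pinned latents (SD = 0) contribute nothing at their mean, -Inf away from it", {
  px <- toy_proxy("x", offset = 0, offset_sd = 0)
  ds <- mixing_dataset(list(px),
                       list(toy_source("a", c(x = -2), sds = 0),
                            toy_source("b", c(x = 2), sds = 0)),
                       toy_source("t", c(x = 0), sds = 1))
  st <- latent_state(c(0.5, 0.5), ds)
  expect_equal(log_density(st, ds), dnorm(0, 0, 1, log = TRUE))
  moved <- latent_state(c(0.5, 0.5), ds,
                        source_values = matrix(c(-1, 2), ncol = 1))
  expect_identical(log_density(moved, ds), -Inf)
})

test_that("predictions are convex and permutation-equivariant", {
  set.seed(101)
  for (rep in 1:20) {
    K <- sample(2:5, 1)
    means <- round(runif(K, -30, 40), 2)
    off <- round(runif(1, -2, 2), 2)
    ds <- mixing_dataset(list(toy_proxy("x", offset = off)),
                         lapply(seq_len(K), function(i)
                           toy_source(paste0("s", i), c(x = means[i]),
                                      pct_c = runif(1, 1, 90))),
                         toy_source("t", c(x = 0)),
                         concentration_dependent = sample(c(TRUE, FALSE), 1))
    g <- rexp(K); p <- g / sum(g)
    mu <- predict_target_proxy(latent_state(p, ds), ds, 1L)
    expect_gte(mu, min(means + off) - 1e-9)
    expect_lte(mu, max(means + off) + 1e-9)
    # permuting sources and p together changes nothing
    perm <- sample(K)
    ds_p <- mixing_dataset(ds$proxies, ds$sources[perm], ds$target,
                           concentration_dependent = ds$concentration_dependent)
    expect_equal(predict_target_proxy(latent_state(p[perm], ds_p), ds_p, 1L), mu)
    expect_equal(log_density(latent_state(p[perm], ds_p), ds_p),
                 log_density(latent_state(p, ds), ds))
  }
})

test_that("equal concentrations make concentration dependence a no-op", {
  set.seed(7)
  srcs <- lapply(1:4, function(i)
    toy_source(paste0("s", i), c(x = runif(1, -5, 5), y = runif(1, 0, 10)),
               pct_c = 33.3, pct_n = 7.7))
  tgt <- toy_source("t", c(x = 0, y = 5))
  pxs <- list(toy_proxy("x", basis = "carbon"), toy_proxy("y", basis = "nitrogen"))
  ds_cd <- mixing_dataset(pxs, srcs, tgt, concentration_dependent = TRUE)
  ds_eq <- mixing_dataset(pxs, srcs, tgt, concentration_dependent = FALSE)
  for (rep in 1:10) {
    g <- rexp(4); p <- g / sum(g)
    for (j in 1:2)
      expect_equal(predict_target_proxy(latent_state(p, ds_cd), ds_cd, j),
                   predict_target_proxy(latent_state(p, ds_eq), ds_eq, j),
                   tolerance = 1e-12)
  }
})

test_that("the model is location-invariant per proxy: shifting sources up equals shifting the target down", {
  mk <- function(source_shift, target_shift) {
    mixing_dataset(list(toy_proxy("x", offset = 0.5, offset_sd = 1)),
                   list(toy_source("a", c(x = -3 + source_shift), sds = 1),
                        toy_source("b", c(x = 4 + source_shift), sds = 1)),
                   toy_source("t", c(x = 1 + target_shift), sds = 2))
  }
  for (cshift in c(-3, 1.7)) {
    ds_up <- mk(cshift, 0)     # sources moved up by c
    ds_down <- mk(0, -cshift)  # target moved down by c instead
    p <- c(0.3, 0.7)
    # with latents at their (shifted) means, the two densities agree
    expect_equal(log_density(latent_state(p, ds_up), ds_up),
                 log_density(latent_state(p, ds_down), ds_down))
  }
})
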
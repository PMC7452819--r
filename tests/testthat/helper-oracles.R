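# Independent oracles used by the tests. Everything here recomputes model
# quantities from first principles (plain arithmetic on the data tables),
# deliberately not via the package's model functions.

# all points of the K-simplex on a grid with step h (rows sum to 1)
simplex_grid <- function(k, h) {
  n <- round(1 / h)
  if (k == 2L) {
    a <- 0:n
    return(cbind(a, n - a) / n)
  }
  pts <- do.call(expand.grid, rep(list(0:n), k - 1L))
  pts <- as.matrix(pts[rowSums(pts) <= n, , drop = FALSE])
  unname(cbind(pts, n - rowSums(pts)) / n)
}

# Brute-force marginal posterior means of diet proportions by dense grid
# enumeration, for datasets with PINNED latents (all source and offset SDs
# zero): likelihood(p) = prod_j N(T_j | mu_j(p), Tsd_j) with
# mu_j(p) = sum_i p_i w_ij (S_ij + off_j) / sum_i p_i w_ij.
grid_posterior_means <- function(dataset, h = 0.01, prior_set = NULL) {
  ids <- names(dataset$sources)
  K <- length(ids)
  pj <- names(dataset$proxies)
  S <- t(vapply(dataset$sources, function(s) s$proxy_mean[pj], numeric(length(pj))))
  S <- matrix(S, nrow = K)
  off <- vapply(dataset$proxies, `[[`, 0, "offset_mean")
  W <- if (dataset$concentration_dependent) {
    vapply(dataset$proxies, function(pr)
      vapply(dataset$sources, function(s)
        if (pr$element_basis == "carbon") s$conc_carbon else s$conc_nitrogen, 0),
      numeric(K))
  } else matrix(1, K, length(pj))
  W <- matrix(W, nrow = K)
  Tm <- vapply(pj, function(j) dataset$target$proxy_mean[[j]], 0)
  Tsd <- vapply(pj, function(j) dataset$target$proxy_sd[[j]], 0)

  P <- simplex_grid(K, h)
  colnames(P) <- ids
  P <- P[rowSums(P %*% W) > 0, , drop = FALSE]
  if (!is.null(prior_set)) {
    keep <- apply(P, 1L, function(p) is_admissible(p, prior_set))
    P <- P[keep, , drop = FALSE]
  }
  ll <- 0
  for (j in seq_along(pj)) {
    A <- t(t(P) * W[, j])
    A <- A / rowSums(A)
    mu <- as.vector(A %*% (S[, j] + off[j]))
    ll <- ll + stats::dnorm(Tm[j], mu, Tsd[j], log = TRUE)
  }
  w <- exp(ll - max(ll))
  stats::setNames(colSums(P * w) / sum(w), ids)
}

# quick proxy/taxon builders for toy systems (single proxy name "x" etc.)
toy_proxy <- function(name = "x", offset = 0, offset_sd = 0, basis = "carbon") {
  proxy_spec(name, offset, offset_sd, basis)
}

toy_source <- function(id, means, sds = 0, pct_c = 50, pct_n = 10) {
  pj <- names(means)
  taxon_profile(id, proxy_mean = means,
                proxy_sd = stats::setNames(rep_len(sds, length(means)), pj),
                conc_carbon = pct_c, conc_nitrogen = pct_n)
}

# hand-build a posterior_chains object around given draw matrices
fake_chains <- function(draw_list, ids = colnames(draw_list[[1L]])) {
  structure(list(draws = lapply(draw_list, function(d) {
                   colnames(d) <- ids; d
                 }),
                 acceptance_rate = rep(NA_real_, length(draw_list)),
                 source_ids = ids,
                 settings = NULL, prior_set = NULL, use_likelihood = TRUE),
            class = "posterior_chains")
}

# Monte-Carlo expectation of sorted uniform-simplex coordinates (the
# brute-force oracle for rank-chain prior means)
sorted_simplex_means <- function(k, n = 200000L, seed = 42L) {
  set.seed(seed)
  g <- matrix(stats::rexp(n * k), ncol = k)
  p <- g / rowSums(g)
  colMeans(t(apply(p, 1L, sort, decreasing = TRUE)))
}

# small MCMC settings for fast unit-test fits
fast_settings <- function(seed = 1L, n_chains = 2L) {
  mcmc_settings(n_chains = n_chains, n_iterations = 8000L, n_burnin = 2000L,
                thin = 3L, seed = seed)
}
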
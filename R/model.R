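#' Expected target value of one proxy under a latent state
#'
#' The mixing equation: the consumer's expected signal on proxy j is the
#' concentration-weighted convex combination of the offset-shifted latent
#' source signals,
#' \deqn{\mu_j = \sum_i p_i w_{ij} (s_{ij} + d_j) / \sum_i p_i w_{ij},}
#' where \eqn{w_{ij}} is source i's concentration of the proxy's element
#' basis when the dataset is concentration-dependent and 1 otherwise,
#' \eqn{s_{ij}} the latent source signal and \eqn{d_j} the realized trophic
#' discrimination offset. The result always lies between the smallest and
#' largest offset-shifted source signal.
#'
#' @param state A [latent_state()].
#' @param dataset The [mixing_dataset()].
#' @param proxy_index Integer index (or name) of the proxy.
#' @return Expected target value, per mil.
#' @export
predict_target_proxy <- function(state, dataset, proxy_index) {
  stopifnot(inherits(state, "latent_state"), inherits(dataset, "mixing_dataset"))
  j <- if (is.character(proxy_index)) match(proxy_index, names(dataset$proxies))
       else as.integer(proxy_index)
  if (is.na(j) || j < 1L || j > length(dataset$proxies))
    stop("unknown proxy index", call. = FALSE)
  K <- n_sources(dataset)
  if (length(state$p) != K || nrow(state$source_values) != K)
    stop("latent state dimensions do not match the dataset", call. = FALSE)
  m <- .dataset_matrices(dataset)
  w <- state$p * m$W[, j]
  tot <- sum(w)
  if (tot <= 0)
    stop(sprintf("degenerate mixture for proxy '%s': total concentration weight is 0",
                 names(dataset$proxies)[j]), call. = FALSE)
  d <- if (is.matrix(state$offsets)) state$offsets[, j] else state$offsets[j]
  sum(w * (state$source_values[, j] + d)) / tot
}

#' Joint log-density of a latent state
#'
#' Sums the Gaussian log-density terms of the mixing model: the target
#' observation given the predicted mixture (per proxy), the latent source
#' signals given their measured means and SDs, and the realized trophic
#' discrimination offsets given their TDF distributions. A term whose SD is
#' 0 pins the quantity: it contributes nothing when the value equals its
#' mean and `-Inf` otherwise. When a `prior_set` is supplied its truncated
#' Dirichlet log-density on `p` is added, so a state violating a rank
#' constraint scores `-Inf`.
#'
#' @inheritParams predict_target_proxy
#' @param prior_set Optional [diet_prior_set()].
#' @return Log-density; `-Inf` when a hard constraint is violated.
#' @export
log_density <- function(state, dataset, prior_set = NULL) {
  stopifnot(inherits(state, "latent_state"), inherits(dataset, "mixing_dataset"))
  m <- .dataset_matrices(dataset)
  K <- n_sources(dataset); J <- length(dataset$proxies)
  if (length(state$p) != K || !identical(dim(state$source_values), c(K, J)))
    stop("latent state dimensions do not match the dataset", call. = FALSE)
  ld <- 0
  # target observation terms
  for (j in seq_len(J)) {
    mu <- predict_target_proxy(state, dataset, j)
    ld <- ld + .gauss_term(m$Tmean[j], mu, m$Tsd[j])
    if (!is.finite(ld)) return(-Inf)
  }
  # latent source signals
  for (j in seq_len(J)) for (i in seq_len(K)) {
    ld <- ld + .gauss_term(state$source_values[i, j], m$S[i, j], m$Ssd[i, j])
    if (!is.finite(ld)) return(-Inf)
  }
  # realized discrimination offsets: one term per proxy in shared mode,
  # one per source x proxy in per-source mode
  for (j in seq_len(J)) {
    dj <- if (is.matrix(state$offsets)) state$offsets[, j] else state$offsets[j]
    for (d in dj) {
      ld <- ld + .gauss_term(d, m$offset_mean[j], m$offset_sd[j])
      if (!is.finite(ld)) return(-Inf)
    }
  }
  if (!is.null(prior_set))
    ld <- ld + prior_log_density(state$p, prior_set)
  unname(ld)
}

# Gaussian log-density with SD = 0 meaning "pinned": 0 if exactly at the
# mean, -Inf otherwise.
.gauss_term <- function(x, mean, sd) {
  x <- unname(x); mean <- unname(mean); sd <- unname(sd)
  if (sd == 0) return(if (isTRUE(all.equal(x, mean, tolerance = 1e-12))) 0 else -Inf)
  stats::dnorm(x, mean, sd, log = TRUE)
}
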
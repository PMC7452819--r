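#' Assemble a mixing dataset
#'
#' A mixing dataset ties together the proxies, the K >= 2 candidate food
#' sources, and one consumer (target) whose diet proportions are to be
#' estimated. Every profile must carry a mean and SD for every active
#' proxy. When `concentration_dependent` is `TRUE`, each proxy's mixing is
#' weighted by the sources' concentration of that proxy's element basis
#' (%C for carbon-based proxies, %N for nitrogen-based ones); otherwise all
#' sources are weighted equally.
#'
#' `offset_mode` controls how trophic discrimination offsets are realized:
#' `"per_source"` (default) draws an independent offset for every source on
#' every proxy, so offset uncertainty partially averages out across a
#' mixture; `"shared"` draws a single offset per proxy that shifts the
#' whole mixture at once, a more conservative (more diffuse) model.
#'
#' @param proxies List of [proxy_spec] objects.
#' @param sources List of [taxon_profile] objects (unique taxon ids).
#' @param target A [taxon_profile]; must not be among the sources.
#' @param concentration_dependent Logical flag.
#' @param offset_mode `"per_source"` or `"shared"`.
#' @return An object of class `mixing_dataset`.
#' @export
mixing_dataset <- function(proxies, sources, target,
                           concentration_dependent = FALSE,
                           offset_mode = c("per_source", "shared")) {
  offset_mode <- match.arg(offset_mode)
  if (inherits(proxies, "proxy_spec")) proxies <- list(proxies)
  stopifnot(length(proxies) >= 1L, all(vapply(proxies, inherits, TRUE, "proxy_spec")))
  if (inherits(sources, "taxon_profile")) sources <- list(sources)
  stopifnot(all(vapply(sources, inherits, TRUE, "taxon_profile")),
            inherits(target, "taxon_profile"),
            is.logical(concentration_dependent), length(concentration_dependent) == 1L)
  if (length(sources) < 2L)
    stop("a mixing dataset needs at least 2 sources", call. = FALSE)
  names(proxies) <- vapply(proxies, `[[`, "", "name")
  if (anyDuplicated(names(proxies)))
    stop("duplicate proxy names", call. = FALSE)
  ids <- vapply(sources, `[[`, "", "taxon_id")
  if (anyDuplicated(ids))
    stop("duplicate source taxon ids", call. = FALSE)
  if (target$taxon_id %in% ids)
    stop(sprintf("target '%s' also appears as a source", target$taxon_id), call. = FALSE)
  names(sources) <- ids
  for (prof in c(sources, list(target))) {
    missing <- setdiff(names(proxies), names(prof$proxy_mean))
    if (length(missing))
      stop(sprintf("taxon '%s' lacks proxy values for: %s",
                   prof$taxon_id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(proxies = proxies, sources = sources, target = target,
         concentration_dependent = concentration_dependent,
         offset_mode = offset_mode),
    class = "mixing_dataset"
  )
}

#' @export
print.mixing_dataset <- function(x, ...) {
  cat(sprintf("<mixing_dataset> target %s | %d sources (%s) | proxies %s | %s\n",
              x$target$taxon_id, length(x$sources),
              paste(names(x$sources), collapse = ", "),
              paste(names(x$proxies), collapse = "+"),
              paste(if (x$concentration_dependent) "concentration-dependent"
                    else "equal weights",
                    x$offset_mode, "offsets", sep = ", ")))
  invisible(x)
}

#' Number of sources / source labels of a mixing dataset
#' @param dataset A [mixing_dataset].
#' @return `n_sources()`: integer K; `source_ids()`: character vector.
#' @export
n_sources <- function(dataset) length(dataset$sources)

#' @rdname n_sources
#' @export
source_ids <- function(dataset) names(dataset$sources)

# Dense matrix view used by the model and the sampler.
# Rows = sources (K), columns = proxies (J), all in dataset order.
.dataset_matrices <- function(dataset) {
  pj <- names(dataset$proxies)
  ids <- names(dataset$sources)
  S <- t(vapply(dataset$sources, function(s) s$proxy_mean[pj], numeric(length(pj))))
  Ssd <- t(vapply(dataset$sources, function(s) s$proxy_sd[pj], numeric(length(pj))))
  if (length(pj) == 1L) {  # vapply drops to vector-shaped matrices consistently
    S <- matrix(S, ncol = 1L); Ssd <- matrix(Ssd, ncol = 1L)
  }
  dimnames(S) <- dimnames(Ssd) <- list(ids, pj)
  basis <- vapply(dataset$proxies, `[[`, "", "element_basis")
  W <- if (dataset$concentration_dependent) {
    vapply(basis, function(b) vapply(dataset$sources, .taxon_conc, 0, basis = b),
           numeric(length(ids)))
  } else {
    matrix(1, nrow = length(ids), ncol = length(pj))
  }
  W <- matrix(W, nrow = length(ids), dimnames = list(ids, pj))
  list(
    S = S, Ssd = Ssd, W = W,
    Tmean = vapply(dataset$proxies, function(p) dataset$target$proxy_mean[[p$name]], 0),
    Tsd   = vapply(dataset$proxies, function(p) dataset$target$proxy_sd[[p$name]], 0),
    offset_mean = vapply(dataset$proxies, `[[`, 0, "offset_mean"),
    offset_sd   = vapply(dataset$proxies, `[[`, 0, "offset_sd")
  )
}

#' Construct a latent state for the mixing model
#'
#' A latent state holds a diet-proportion vector together with realized
#' values for the latent true source signals and the per-proxy trophic
#' discrimination offsets. [log_density()] scores such a state;
#' [sample_posterior()] explores them by MCMC.
#'
#' @param p Numeric diet proportions, length K, summing to 1.
#' @param dataset The [mixing_dataset] the state refers to.
#' @param source_values K x J matrix of latent source signals (per mil);
#'   defaults to the observed source means.
#' @param offsets Realized TDF offsets: a length-J vector when the dataset
#'   is in `"shared"` offset mode (one offset per proxy), or a K x J
#'   matrix in `"per_source"` mode (one per source and proxy); a vector
#'   given in per-source mode is recycled across sources. Defaults to the
#'   TDF means.
#' @return An object of class `latent_state`.
#' @export
latent_state <- function(p, dataset, source_values = NULL, offsets = NULL) {
  K <- n_sources(dataset); J <- length(dataset$proxies)
  p <- validate_diet(p, K)
  m <- .dataset_matrices(dataset)
  if (is.null(source_values)) source_values <- m$S
  if (is.null(offsets)) offsets <- m$offset_mean
  source_values <- as.matrix(source_values)
  if (!identical(dim(source_values), c(K, J)))
    stop(sprintf("`source_values` must be a %d x %d matrix", K, J), call. = FALSE)
  if (dataset$offset_mode == "per_source") {
    if (is.matrix(offsets)) {
      if (!identical(dim(offsets), c(K, J)))
        stop(sprintf("`offsets` must be a %d x %d matrix in per-source mode", K, J),
             call. = FALSE)
    } else {
      if (length(offsets) != J)
        stop(sprintf("`offsets` must have length %d (or be a %d x %d matrix)",
                     J, K, J), call. = FALSE)
      offsets <- matrix(offsets, nrow = K, ncol = J, byrow = TRUE)
    }
  } else {
    if (is.matrix(offsets) || length(offsets) != J)
      stop(sprintf("`offsets` must have length %d in shared mode", J), call. = FALSE)
    offsets <- as.numeric(offsets)
  }
  structure(list(p = stats::setNames(p, source_ids(dataset)),
                 source_values = source_values,
                 offsets = offsets),
            class = "latent_state")
}

#' Validate a diet-proportion vector
#'
#' Checks that `p` lies on the K-simplex: entries in `[0, 1]` and summing
#' to 1 within `1e-10`.
#'
#' @param p Numeric vector of proportions.
#' @param k Expected length (optional).
#' @return `p`, invisibly normalised to numeric.
#' @export
validate_diet <- function(p, k = NULL) {
  p <- as.numeric(p)
  if (!is.null(k) && length(p) != k)
    stop(sprintf("diet vector has length %d, expected %d", length(p), k), call. = FALSE)
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("diet proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-10)
    stop(sprintf("diet proportions must sum to 1 (got %.12f)", sum(p)), call. = FALSE)
  pmin(pmax(p, 0), 1)
}
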
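#' Rank-order constraint on diet proportions
#'
#' Encodes a strict preference ordering among food sources, e.g. prey
#' preferences inferred from DNA metabarcoding: the first source must
#' contribute strictly more to the diet than the second, and so on down the
#' chain. Ties have zero probability under any continuous prior, so no
#' margin parameter is needed.
#'
#' @param ordered_sources Character vector of >= 2 distinct source labels,
#'   highest preference first.
#' @return An object of class `rank_constraint`.
#' @examples
#' rank_constraint(c("AM1", "AM2", "H", "C"))
#' @export
rank_constraint <- function(ordered_sources) {
  ordered_sources <- as.character(ordered_sources)
  if (length(ordered_sources) < 2L || anyDuplicated(ordered_sources))
    stop("a rank constraint needs >= 2 distinct source labels", call. = FALSE)
  structure(list(ordered_sources = ordered_sources), class = "rank_constraint")
}

#' @export
print.rank_constraint <- function(x, ...) {
  cat("<rank_constraint>", paste(x$ordered_sources, collapse = " > "), "\n")
  invisible(x)
}

#' Prior information for one target's diet
#'
#' Collects rank-order constraints, hard source exclusions (a source that
#' cannot be eaten at all, e.g. the consumer itself when cannibalism is
#' ruled out), and Dirichlet concentration parameters. The implied prior on
#' the diet simplex is Dirichlet(`alpha`) over the non-excluded sources,
#' truncated to the region where every constraint's proportions are
#' strictly decreasing along its order.
#'
#' @param target_id Label of the consumer this prior applies to.
#' @param constraints List of [rank_constraint] objects (possibly empty).
#' @param excluded_sources Character vector of sources forced to
#'   proportion 0; may not appear in any constraint.
#' @param alpha Named positive numeric vector of Dirichlet parameters, or
#'   `NULL` for the uniform Dirichlet(1, ..., 1).
#' @return An object of class `diet_prior_set`.
#' @export
diet_prior_set <- function(target_id, constraints = list(),
                           excluded_sources = character(), alpha = NULL) {
  stopifnot(is.character(target_id), length(target_id) == 1L)
  if (inherits(constraints, "rank_constraint")) constraints <- list(constraints)
  stopifnot(all(vapply(constraints, inherits, TRUE, "rank_constraint")))
  excluded_sources <- unique(as.character(excluded_sources))
  in_constraints <- unlist(lapply(constraints, `[[`, "ordered_sources"))
  clash <- intersect(excluded_sources, in_constraints)
  if (length(clash))
    stop(sprintf("excluded sources may not appear in constraints: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  if (!is.null(alpha)) {
    if (is.null(names(alpha)) || any(!is.finite(alpha)) || any(alpha <= 0))
      stop("`alpha` must be a named vector of strictly positive values", call. = FALSE)
  }
  structure(list(target_id = target_id, constraints = constraints,
                 excluded_sources = excluded_sources, alpha = alpha),
            class = "diet_prior_set")
}

#' @export
print.diet_prior_set <- function(x, ...) {
  cat(sprintf("<diet_prior_set> target %s: %d constraint(s)", x$target_id,
              length(x$constraints)))
  if (length(x$excluded_sources))
    cat(", excluded:", paste(x$excluded_sources, collapse = ", "))
  cat("\n")
  for (ct in x$constraints)
    cat(" ", paste(ct$ordered_sources, collapse = " > "), "\n")
  invisible(x)
}

#' Build a prior set from a long-format preference table
#'
#' The table has one row per (target, constraint, rank) with columns
#' `target_id`, `constraint` (an index or label distinguishing multiple
#' orderings for the same target), `rank` (1 = most preferred), and
#' `source_id`. Rows for other targets are ignored. The target itself is
#' always added to `excluded_sources` (no self-consumption); a row that
#' ranks the target within its own preference chain is a contradiction and
#' raises an error.
#'
#' @param target_id The consumer to build the prior for.
#' @param prior_table A data.frame as described above; an empty or `NULL`
#'   table yields an unconstrained prior with only the self-exclusion.
#' @param known_taxa Optional character vector of valid taxon labels; if
#'   given, any unknown label in the table raises an error listing the
#'   valid ones.
#' @return A [diet_prior_set].
#' @export
build_prior_set <- function(target_id, prior_table = NULL, known_taxa = NULL) {
  if (is.null(prior_table) || nrow(prior_table) == 0L)
    return(diet_prior_set(target_id, excluded_sources = target_id))
  needed <- c("target_id", "constraint", "rank", "source_id")
  if (!all(needed %in% names(prior_table)))
    stop("prior table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  if (!is.null(known_taxa)) {
    bad <- setdiff(unique(c(prior_table$target_id, prior_table$source_id)), known_taxa)
    if (length(bad))
      stop(sprintf("unknown taxa in prior table: %s (valid: %s)",
                   paste(bad, collapse = ", "), paste(known_taxa, collapse = ", ")),
           call. = FALSE)
  }
  rows <- prior_table[prior_table$target_id == target_id, , drop = FALSE]
  constraints <- lapply(split(rows, rows$constraint), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    if (target_id %in% d$source_id)
      stop(sprintf("prior table ranks target '%s' within its own preference chain",
                   target_id), call. = FALSE)
    rank_constraint(d$source_id)
  })
  diet_prior_set(target_id, constraints = unname(constraints),
                 excluded_sources = target_id)
}

#' Test whether a diet vector satisfies a prior set
#'
#' `TRUE` iff every rank constraint's proportions are strictly decreasing
#' along its order and every excluded source has proportion exactly 0.
#' Constraint labels absent from `p` are ignored (they refer to taxa not in
#' this dataset, e.g. the excluded target itself never is).
#'
#' @param p Named diet-proportion vector (names are source labels).
#' @param prior_set A [diet_prior_set].
#' @return Logical scalar.
#' @export
is_admissible <- function(p, prior_set) {
  if (is.null(names(p)))
    stop("`p` must be named by source", call. = FALSE)
  for (ex in intersect(prior_set$excluded_sources, names(p)))
    if (p[[ex]] != 0) return(FALSE)
  for (ct in prior_set$constraints) {
    chain <- intersect(ct$ordered_sources, names(p))
    if (length(chain) < 2L) next
    v <- as.numeric(p[chain])
    if (any(diff(v) >= 0)) return(FALSE)
  }
  TRUE
}

#' Log-density of the truncated-Dirichlet diet prior
#'
#' Dirichlet(`alpha`) log-density over the non-excluded sources, returning
#' `-Inf` whenever [is_admissible()] is false. The density is not
#' renormalised for the truncation: it is used inside MCMC, where the
#' truncation constant cancels.
#'
#' @inheritParams is_admissible
#' @return Log-density (possibly `-Inf`).
#' @examples
#' # uniform prior on the K-simplex has constant density (K-1)!
#' ps <- diet_prior_set("tgt")
#' prior_log_density(c(a = 0.2, b = 0.3, c = 0.5), ps)  # == log(2)
#' @export
prior_log_density <- function(p, prior_set) {
  if (!is_admissible(p, prior_set)) return(-Inf)
  active <- setdiff(names(p), prior_set$excluded_sources)
  pa <- as.numeric(p[active])
  alpha <- .resolve_alpha(prior_set, active)
  if (any(pa == 0 & alpha > 1)) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum(((alpha - 1) * log(pa))[alpha != 1])
}

.resolve_alpha <- function(prior_set, active) {
  if (is.null(prior_set$alpha)) return(rep(1, length(active)))
  missing <- setdiff(active, names(prior_set$alpha))
  if (length(missing))
    stop(sprintf("prior alphas missing for: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  as.numeric(prior_set$alpha[active])
}

#' Monte-Carlo means of the truncated diet prior
#'
#' Characterises the prior implied by a [diet_prior_set] by rejection
#' sampling: Dirichlet(`alpha`) draws over the non-excluded sources are
#' kept when admissible, and per-source mean proportions over the kept
#' draws are returned (excluded sources get exactly 0). Useful to verify a
#' constraint encoding before fitting, and as the reference for
#' prior-recovery checks of the sampler.
#'
#' @param prior_set A [diet_prior_set].
#' @param ids Character vector of source labels of the dataset the prior
#'   will apply to.
#' @param n_draws Number of Dirichlet proposals (>= 1).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Named numeric vector of mean proportions summing to 1.
#' @export
prior_predictive_means <- function(prior_set, ids, n_draws = 20000L, seed = 1L) {
  stopifnot(n_draws >= 1L)
  draws <- sample_prior(prior_set, ids, n_draws = n_draws, seed = seed,
                        n_attempts = n_draws)
  colMeans(draws)
}

#' Draw admissible diet vectors from the prior
#'
#' Rejection sampler behind [prior_predictive_means()]; also used to
#' initialise MCMC chains. Draws Dirichlet(`alpha`) proposals over the
#' non-excluded sources and keeps admissible ones until `n_draws` have been
#' collected or `n_attempts` proposals have been spent.
#'
#' @inheritParams prior_predictive_means
#' @param n_attempts Maximum number of proposals; if no admissible draw is
#'   found the prior is reported as infeasible.
#' @return Matrix of admissible draws (rows) with one column per source.
#' @export
sample_prior <- function(prior_set, ids, n_draws = 1L, seed = NULL,
                         n_attempts = 200000L) {
  stopifnot(is.character(ids), length(ids) >= 2L)
  active <- setdiff(ids, prior_set$excluded_sources)
  if (length(active) < 2L)
    stop("fewer than 2 non-excluded sources", call. = FALSE)
  alpha <- .resolve_alpha(prior_set, active)
  run <- function() {
    kept <- matrix(numeric(0), ncol = length(ids), dimnames = list(NULL, ids))
    block <- max(1000L, n_draws)
    spent <- 0L
    while (nrow(kept) < n_draws && spent < n_attempts) {
      m <- min(block, n_attempts - spent)
      g <- matrix(stats::rgamma(m * length(active), shape = alpha),
                  nrow = m, byrow = TRUE)
      pa <- g / rowSums(g)
      full <- matrix(0, nrow = m, ncol = length(ids), dimnames = list(NULL, ids))
      full[, active] <- pa
      # vectorised admissibility: excluded columns are 0 by construction,
      # so only the strict chains need checking
      ok <- rep(TRUE, m)
      for (ct in prior_set$constraints) {
        chain <- intersect(ct$ordered_sources, ids)
        if (length(chain) < 2L) next
        for (k in 2L:length(chain))
          ok <- ok & full[, chain[k - 1L]] > full[, chain[k]]
      }
      kept <- rbind(kept, full[ok, , drop = FALSE])
      spent <- spent + m
    }
    kept
  }
  kept <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  if (nrow(kept) == 0L)
    stop(sprintf("prior for target '%s' appears infeasible: no admissible draw in %d attempts",
                 prior_set$target_id, n_attempts), call. = FALSE)
  kept[seq_len(min(nrow(kept), n_draws)), , drop = FALSE]
}

#' Informative Dirichlet parameters from diet fractions
#'
#' Turns externally estimated diet fractions (e.g. relative read
#' proportions from metabarcoding) into Dirichlet concentration parameters
#' `alpha = concentration * fractions / sum(fractions)`, for use as the
#' `alpha` of a [diet_prior_set]. Larger `concentration` means a more
#' informative prior. All alphas are floored at `floor_alpha` so no source
#' is given an improper (zero) parameter.
#'
#' @param fractions Named non-negative numeric vector of diet fractions.
#' @param concentration Total Dirichlet concentration (sum of alphas).
#' @param floor_alpha Minimum per-source alpha.
#' @return Named numeric vector of alphas.
#' @export
informative_alphas <- function(fractions, concentration = 10, floor_alpha = 0.2) {
  stopifnot(!is.null(names(fractions)), all(fractions >= 0), sum(fractions) > 0,
            concentration > 0)
  pmax(concentration * fractions / sum(fractions), floor_alpha)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
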
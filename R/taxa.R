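#' Define a taxon's isotopic profile
#'
#' Bundles one taxon's per-proxy mean and standard deviation (per mil) with
#' its bulk elemental concentrations (%C, %N of dry mass). The same
#' structure serves as a food source or as a consumer (target) in a
#' [mixing_dataset()].
#'
#' @param taxon_id Taxon label.
#' @param proxy_mean Named numeric vector of per-proxy means (per mil).
#' @param proxy_sd Named numeric vector of per-proxy standard deviations
#'   (per mil, >= 0), names matching `proxy_mean`.
#' @param conc_carbon,conc_nitrogen Percent of dry mass in `[0, 100]`; at
#'   least one must be positive.
#' @return An object of class `taxon_profile`.
#' @examples
#' taxon_profile("AM1",
#'   proxy_mean = c(d13C = -24.14, d15N = 10.71),
#'   proxy_sd   = c(d13C = 0.30,  d15N = 0.30),
#'   conc_carbon = 57.7, conc_nitrogen = 2.8)
#' @export
taxon_profile <- function(taxon_id, proxy_mean, proxy_sd,
                          conc_carbon = 0, conc_nitrogen = 0) {
  stopifnot(is.character(taxon_id), length(taxon_id) == 1L, nzchar(taxon_id))
  if (is.null(names(proxy_mean)) || is.null(names(proxy_sd)))
    stop("`proxy_mean` and `proxy_sd` must be named by proxy", call. = FALSE)
  if (!setequal(names(proxy_mean), names(proxy_sd)))
    stop("`proxy_mean` and `proxy_sd` must cover the same proxies", call. = FALSE)
  proxy_sd <- proxy_sd[names(proxy_mean)]
  if (any(!is.finite(proxy_mean)))
    stop(sprintf("non-finite proxy mean for taxon '%s'", taxon_id), call. = FALSE)
  if (any(!is.finite(proxy_sd)) || any(proxy_sd < 0))
    stop(sprintf("proxy SDs for taxon '%s' must be finite and >= 0", taxon_id),
         call. = FALSE)
  for (conc in list(conc_carbon, conc_nitrogen)) {
    if (!is.numeric(conc) || length(conc) != 1L || !is.finite(conc) ||
        conc < 0 || conc > 100)
      stop("concentrations must be single values in [0, 100]", call. = FALSE)
  }
  if (conc_carbon <= 0 && conc_nitrogen <= 0)
    stop(sprintf("taxon '%s' needs at least one positive concentration", taxon_id),
         call. = FALSE)
  structure(
    list(taxon_id = taxon_id,
         proxy_mean = proxy_mean, proxy_sd = proxy_sd,
         conc_carbon = conc_carbon, conc_nitrogen = conc_nitrogen),
    class = "taxon_profile"
  )
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> %s  (%%C %.2f, %%N %.2f)\n",
              x$taxon_id, x$conc_carbon, x$conc_nitrogen))
  for (j in names(x$proxy_mean))
    cat(sprintf("  %-5s %8.2f +/- %.2f permil\n", j, x$proxy_mean[[j]], x$proxy_sd[[j]]))
  invisible(x)
}

# concentration of a proxy's element basis for one taxon
.taxon_conc <- function(profile, basis) {
  switch(basis, carbon = profile$conc_carbon, nitrogen = profile$conc_nitrogen)
}
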
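#' Write / read a mixing dataset as delimited text
#'
#' The on-disk form mirrors the bundled study files: an isotope table with
#' one row per taxon x proxy (`taxon_id`, `role`, `proxy`, `mean`, `sd`)
#' and a concentrations table (`taxon_id`, `pct_C`, `pct_N`). Synthetic
#' and real datasets round-trip through the same format. Proxy
#' definitions (TDFs, element basis) are written to a third small table so
#' a dataset file set is self-contained.
#'
#' @param dataset A [mixing_dataset()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; files are `<stem>_isotopes.tsv`,
#'   `<stem>_concentrations.tsv`, `<stem>_proxies.tsv`.
#' @return `write_dataset`: the directory, invisibly. `read_dataset`: a
#'   [mixing_dataset()].
#' @export
write_dataset <- function(dataset, dir, stem = "dataset") {
  stopifnot(inherits(dataset, "mixing_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- c(dataset$sources, list(dataset$target))
  roles <- c(rep("source", length(dataset$sources)), "target")
  pj <- names(dataset$proxies)
  iso <- do.call(rbind, lapply(seq_along(taxa), function(i)
    data.frame(taxon_id = taxa[[i]]$taxon_id, role = roles[i], proxy = pj,
               mean = as.numeric(taxa[[i]]$proxy_mean[pj]),
               sd = as.numeric(taxa[[i]]$proxy_sd[pj]))))
  conc <- data.frame(taxon_id = vapply(taxa, `[[`, "", "taxon_id"),
                     pct_C = vapply(taxa, `[[`, 0, "conc_carbon"),
                     pct_N = vapply(taxa, `[[`, 0, "conc_nitrogen"))
  prox <- data.frame(proxy = pj,
                     offset_mean = vapply(dataset$proxies, `[[`, 0, "offset_mean"),
                     offset_sd = vapply(dataset$proxies, `[[`, 0, "offset_sd"),
                     element_basis = vapply(dataset$proxies, `[[`, "", "element_basis"),
                     concentration_dependent = dataset$concentration_dependent,
                     offset_mode = dataset$offset_mode)
  utils::write.table(iso, file.path(dir, paste0(stem, "_isotopes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(conc, file.path(dir, paste0(stem, "_concentrations.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prox, file.path(dir, paste0(stem, "_proxies.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, stem = "dataset") {
  iso <- utils::read.delim(file.path(dir, paste0(stem, "_isotopes.tsv")))
  conc <- utils::read.delim(file.path(dir, paste0(stem, "_concentrations.tsv")))
  prox <- utils::read.delim(file.path(dir, paste0(stem, "_proxies.tsv")))
  proxies <- lapply(seq_len(nrow(prox)), function(i)
    proxy_spec(prox$proxy[i], prox$offset_mean[i], prox$offset_sd[i],
               prox$element_basis[i]))
  taxa <- lapply(split(iso, iso$taxon_id), function(d) {
    cc <- conc[conc$taxon_id == d$taxon_id[1L], ]
    taxon_profile(d$taxon_id[1L],
                  proxy_mean = stats::setNames(d$mean, d$proxy),
                  proxy_sd = stats::setNames(d$sd, d$proxy),
                  conc_carbon = cc$pct_C, conc_nitrogen = cc$pct_N)
  })
  target_id <- unique(iso$taxon_id[iso$role == "target"])
  if (length(target_id) != 1L)
    stop("dataset files must contain exactly one target", call. = FALSE)
  mixing_dataset(proxies, taxa[setdiff(names(taxa), target_id)],
                 taxa[[target_id]],
                 concentration_dependent = isTRUE(prox$concentration_dependent[1L]),
                 offset_mode = if ("offset_mode" %in% names(prox))
                   prox$offset_mode[1L] else "per_source")
}

#' Write a posterior summary table
#'
#' Delimited long-format summary (`target`, `source`, `mean`, `sd`,
#' `median`, `ci68_low`, `ci68_high`, `ci95_low`, `ci95_high`), percent
#' scale, values rounded to two decimals as conventional for reported diet
#' proportions.
#'
#' @param summary A `posterior_summary` (from [summarize_posterior()]).
#' @param target_id Target label recorded in the first column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_posterior_summary <- function(summary, target_id, path) {
  out <- cbind(target = target_id, summary)
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], round, digits = 2L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a key = value run configuration file
#'
#' Plain-text configuration with one `key = value` (or `key: value`) pair
#' per line; `#` starts a comment. Recognised keys: `design`,
#' `prior_mode`, `concentration_dependent`, `n_chains`, `n_iterations`,
#' `n_burnin`, `thin`, `seed`, `step_scale`. Unknown keys raise an error.
#'
#' @param path Config file path.
#' @return list with elements `design` (a [design_config()] when `design`
#'   is present) and `settings` (an [mcmc_settings()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lines[vapply(kv, length, 0L) != 2L]
  if (length(bad))
    stop("malformed config line(s): ", paste(bad, collapse = "; "), call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- c("design", "prior_mode", "concentration_dependent", "n_chains",
             "n_iterations", "n_burnin", "thin", "seed", "step_scale")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  get <- function(k, default) if (k %in% keys) vals[[match(k, keys)]] else default
  settings <- mcmc_settings(
    n_chains = as.integer(get("n_chains", 4L)),
    n_iterations = as.integer(get("n_iterations", 30000L)),
    n_burnin = as.integer(get("n_burnin", 10000L)),
    thin = as.integer(get("thin", 5L)),
    seed = as.integer(get("seed", 20170711L)),
    step_scale = as.numeric(get("step_scale", 0.35)))
  design <- if ("design" %in% keys) {
    design_config(get("design", NULL),
                  concentration_dependent =
                    as.logical(get("concentration_dependent", "TRUE")),
                  prior_mode = get("prior_mode", "rank_truncation"))
  } else NULL
  list(design = design, settings = settings)
}
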
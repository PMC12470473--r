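#' Municipal population density
#'
#' @param population resident count (persons).
#' @param surface_ha municipal surface in hectares (> 0).
#' @return inhabitants per hectare (vectorised).
#' @export
population_density <- function(population, surface_ha) {
  if (any(surface_ha <= 0)) stop("surface_ha must be > 0", call. = FALSE)
  population / surface_ha
}

#' Configuration of the province-stratified permutation test
#'
#' @param iterations number of permutation iterations B (default 499).
#' @param alpha significance level (default 0.05).
#' @param statistic summary compared between detected and null sets:
#'   `"mean_log10_density"` (default; mean of log10(density + epsilon)),
#'   `"mean_density"`, or `"median_density"`.
#' @param min_n minimum number of newly detected municipalities for a year to
#'   be tested (default 3; a first-invasion year with only a couple of seed
#'   municipalities is skipped).
#' @param seed integer RNG seed, or `NULL` for the session RNG. Per-year
#'   substreams are derived from (seed, year) so adding a year to an analysis
#'   never perturbs the others.
#' @param epsilon additive guard inside the log10, protecting
#'   zero-population municipalities (default 1e-9).
#' @param replace_fallback if `TRUE`, a province whose non-detected pool is
#'   smaller than its detected count is resampled with replacement and the
#'   result flagged (`with_replacement` element of the result); the default
#'   is an error.
#' @return classed list `permutation_config`.
#' @export
permutation_config <- function(iterations = 499L, alpha = 0.05,
                               statistic = c("mean_log10_density",
                                             "mean_density", "median_density"),
                               min_n = 3L, seed = NULL, epsilon = 1e-9,
                               replace_fallback = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(iterations >= 1, alpha > 0, alpha < 1, min_n >= 1)
  structure(list(iterations = as.integer(iterations), alpha = alpha,
                 statistic = statistic, min_n = as.integer(min_n),
                 seed = seed, epsilon = epsilon,
                 replace_fallback = isTRUE(replace_fallback)),
            class = "permutation_config")
}

# Deterministic per-year substream seed; exact in double arithmetic and
# reduced into 32-bit range only at the end.
year_seed <- function(seed, year) {
  as.integer((as.numeric(seed) * 1048573 + as.numeric(year) * 127 + 1) %%
               2147483629)
}

density_statistic <- function(densities, statistic, epsilon = 1e-9) {
  switch(statistic,
         mean_log10_density = mean(log10(densities + epsilon)),
         mean_density = mean(densities),
         median_density = stats::median(densities))
}

#' Province-stratified null sample
#'
#' Draws, from the pool of non-detected municipalities, a random set of the
#' same size and the same per-province composition as the detected set,
#' without replacement within each province. This preserves the provincial
#' (spatial) structure of the detected set so that the permutation null
#' controls for regional heterogeneity.
#'
#' @param detected data frame of detected municipalities (needs `code` and
#'   `province` columns).
#' @param pool data frame of candidate non-detected municipalities (same
#'   columns).
#' @param replace_fallback if `TRUE`, a province whose pool is smaller than
#'   its detected count is sampled with replacement and the result is flagged
#'   via the `"with_replacement"` attribute; the default is an error.
#' @return rows of `pool` forming the null sample; per-province counts equal
#'   those of `detected` exactly.
#' @export
stratified_null_sample <- function(detected, pool, replace_fallback = FALSE) {
  if (nrow(detected) == 0) return(pool[0, , drop = FALSE])
  need <- table(detected$province)
  pieces <- vector("list", length(need))
  flagged <- FALSE
  for (i in seq_along(need)) {
    prov <- names(need)[i]
    k <- as.integer(need[[i]])
    cand <- which(pool$province == prov)
    if (length(cand) < k) {
      if (!replace_fallback) {
        stop(sprintf("insufficient null pool in province '%s': need %d, have %d",
                     prov, k, length(cand)), call. = FALSE)
      }
      flagged <- TRUE
      pieces[[i]] <- cand[sample.int(length(cand), k, replace = TRUE)]
    } else if (length(cand) == k) {
      pieces[[i]] <- cand
    } else {
      pieces[[i]] <- cand[sample.int(length(cand), k)]
    }
  }
  out <- pool[unlist(pieces), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "with_replacement") <- flagged
  out
}

#' Permutation test of population density for one detection year
#'
#' Tests, one-sided, whether the municipalities newly detected in `year` have
#' higher population density than expected by chance, against a null built by
#' repeatedly drawing province-matched sets of the same size from the pool of
#' municipalities with no detection of the species in any year up to `year`.
#' The p-value uses the add-one convention `(1 + #\{null >= observed\}) /
#' (1 + B)`, so with B = 499 its floor is 0.002; ties count against
#' significance.
#'
#' @param year calendar year to test (must hold at least one new detection).
#' @param attributions output of [attribution_table()] for one species (or
#'   filtered to one species).
#' @param registry municipality registry.
#' @param config [permutation_config()].
#' @param species species token (default `"albopictus"`).
#' @return classed list `permutation_result`: `year`, `n_detected`,
#'   `observed_stat`, `null_stats` (length B), `p_value`, `significant`.
#' @export
permutation_test_year <- function(year, attributions, registry,
                                  config = permutation_config(),
                                  species = "albopictus") {
  att <- attributions[attributions$species == species, , drop = FALSE]
  det_codes <- att$municipality_code[!is.na(att$first_year) & att$first_year == year]
  if (length(det_codes) == 0) {
    stop("no new detections in year ", year, call. = FALSE)
  }
  ever_codes <- att$municipality_code[!is.na(att$first_year) & att$first_year <= year]
  detected <- registry[registry$code %in% det_codes, , drop = FALSE]
  pool <- registry[!registry$code %in% ever_codes, , drop = FALSE]

  dens_det <- population_density(detected$population, detected$surface_ha)
  observed <- density_statistic(dens_det, config$statistic, config$epsilon)

  if (!is.null(config$seed)) set.seed(year_seed(config$seed, year))
  pool_dens <- population_density(pool$population, pool$surface_ha)
  # Pre-index the pool by province once; the B-loop only samples indices.
  need <- table(detected$province)
  prov_idx <- lapply(names(need), function(p) which(pool$province == p))
  ks <- as.integer(need)
  short <- which(lengths(prov_idx) < ks)
  with_replacement <- length(short) > 0
  if (with_replacement && !config$replace_fallback) {
    stop(sprintf("insufficient null pool in province '%s': need %d, have %d",
                 names(need)[short[1]], ks[short[1]],
                 length(prov_idx[[short[1]]])), call. = FALSE)
  }
  B <- config$iterations
  null_stats <- numeric(B)
  for (b in seq_len(B)) {
    idx <- unlist(lapply(seq_along(ks), function(i) {
      cand <- prov_idx[[i]]
      if (length(cand) < ks[i]) {
        cand[sample.int(length(cand), ks[i], replace = TRUE)]
      } else if (length(cand) == ks[i]) {
        cand
      } else {
        cand[sample.int(length(cand), ks[i])]
      }
    }), use.names = FALSE)
    null_stats[b] <- density_statistic(pool_dens[idx], config$statistic,
                                       config$epsilon)
  }
  p <- (1 + sum(null_stats >= observed)) / (1 + B)
  structure(list(year = year, n_detected = nrow(detected),
                 observed_stat = observed, null_stats = null_stats,
                 p_value = p, significant = p < config$alpha,
                 with_replacement = with_replacement),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Province-stratified permutation test, year %d\n", x$year))
  cat(sprintf("  n detected: %d, observed statistic: %.4f\n",
              x$n_detected, x$observed_stat))
  cat(sprintf("  p = %.4g (%d iterations)%s\n", x$p_value,
              length(x$null_stats), if (x$significant) " *" else ""))
  invisible(x)
}

#' Run the density permutation test over all eligible years
#'
#' One test per calendar year with at least `min_n` newly detected
#' municipalities, pooled across surveillance strategies. Years below the
#' threshold (typically the first invasion year, with only a couple of seed
#' municipalities) are skipped.
#'
#' @inheritParams permutation_test_year
#' @param year_range optional inclusive `c(first, last)` restriction.
#' @return data frame `year`, `n_detected`, `observed_stat`, `p_value`,
#'   `significant`; the full `permutation_result` objects are attached as the
#'   `"results"` attribute.
#' @export
run_density_tests <- function(attributions, registry,
                              config = permutation_config(),
                              year_range = NULL, species = "albopictus") {
  att <- attributions[attributions$species == species, , drop = FALSE]
  years <- sort(unique(att$first_year[!is.na(att$first_year)]))
  if (!is.null(year_range)) {
    years <- years[years >= year_range[1] & years <= year_range[2]]
  }
  n_by_year <- vapply(years, function(y)
    sum(att$first_year == y, na.rm = TRUE), integer(1))
  years <- years[n_by_year >= config$min_n]
  results <- lapply(years, function(y)
    permutation_test_year(y, att, registry, config, species = species))
  out <- data.frame(
    year = years,
    n_detected = vapply(results, `[[`, integer(1), "n_detected"),
    observed_stat = vapply(results, `[[`, numeric(1), "observed_stat"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    significant = vapply(results, `[[`, logical(1), "significant")
  )
  attr(out, "results") <- results
  out
}
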
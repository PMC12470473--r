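#' Configuration of a synthetic municipality registry
#'
#' The generated world mimics the structural features of a national
#' municipal registry that the analyses rely on: municipalities scattered
#' over a bounding box, grouped into spatially contiguous provinces
#' (nearest-seed partition, so province stratification is a genuine spatial
#' control), with heavy-tailed log-normal populations and surfaces.
#'
#' @param n_municipalities number of municipalities.
#' @param n_provinces number of provinces (<= n_municipalities).
#' @param bbox named numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param pop_meanlog,pop_sdlog log-normal population parameters (default
#'   median 5000 inhabitants with sdlog 1.4, a heavy right tail of cities).
#' @param area_meanlog,area_sdlog log-normal surface parameters in hectares
#'   (default median 3000 ha).
#' @param seed integer RNG seed.
#' @return classed list `world_config`.
#' @export
world_config <- function(n_municipalities = 250L, n_provinces = 6L,
                         bbox = c(lat_min = 39, lat_max = 42,
                                  lon_min = -2, lon_max = 2),
                         pop_meanlog = log(5000), pop_sdlog = 1.4,
                         area_meanlog = log(3000), area_sdlog = 0.6,
                         seed = 1L) {
  stopifnot(n_provinces <= n_municipalities, n_provinces >= 1,
            bbox[["lat_min"]] < bbox[["lat_max"]],
            bbox[["lon_min"]] < bbox[["lon_max"]],
            pop_sdlog >= 0, area_sdlog >= 0)
  structure(list(n_municipalities = as.integer(n_municipalities),
                 n_provinces = as.integer(n_provinces), bbox = bbox,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 seed = seed),
            class = "world_config")
}

#' Generate a synthetic municipality registry
#'
#' @param config [world_config()].
#' @return validated registry (see [as_registry()]); deterministic under the
#'   config seed.
#' @examples
#' reg <- generate_world(world_config(n_municipalities = 20, n_provinces = 3,
#'                                    seed = 42))
#' table(reg$province)
#' @export
generate_world <- function(config = world_config()) {
  set.seed(config$seed)
  n <- config$n_municipalities
  b <- config$bbox
  lat <- stats::runif(n, b[["lat_min"]], b[["lat_max"]])
  lon <- stats::runif(n, b[["lon_min"]], b[["lon_max"]])
  pop <- round(stats::rlnorm(n, config$pop_meanlog, config$pop_sdlog))
  area <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  seeds <- sample.int(n, config$n_provinces)
  prov <- vapply(seq_len(n), function(i) {
    d <- sphere_distance(lat[i], lon[i], lat[seeds], lon[seeds])
    which.min(d)
  }, integer(1))
  prov[seeds] <- seq_along(seeds)  # each seed anchors its own province
  df <- data.frame(
    code = sprintf("M%04d", seq_len(n)),
    name = sprintf("Municipality %04d", seq_len(n)),
    province = sprintf("P%02d", prov),
    autonomous_community = sprintf("AC%02d", 1 + (prov - 1) %/% 2),
    surface_ha = area,
    population = pop,
    centroid_lat = lat,
    centroid_lon = lon,
    stringsAsFactors = FALSE
  )
  as_registry(df)
}

#' Configuration of the stochastic colonisation process
#'
#' Invasion proceeds by stratified dispersal: short-range contagion from
#' already colonised municipalities through an exponential distance kernel,
#' plus rare long-distance jumps (the human-transport pathway). The
#' `density_bias` exponent beta weights both pathways towards densely
#' populated municipalities; `beta = 0` is the density-unbiased null
#' scenario in which colonisation is blind to demography.
#'
#' @param seed_codes codes of the initially colonised municipalities;
#'   `NULL` picks the most populous municipality (a port-city analogue).
#' @param years simulation horizon (vector of consecutive calendar years).
#' @param local_scale_km kernel range lambda in km (contagion decays as
#'   `exp(-d/lambda)`).
#' @param jump_rate expected number of long-distance jumps per year.
#' @param density_bias exponent beta applied to relative population density
#'   in the contagion term and to population in the jump-target weights.
#' @param contagion contagion constant `c`; `NULL` (default) calibrates it so
#'   the expected first-year spread from the seed set is about one
#'   municipality, keeping default scenarios at desk scale.
#' @param seed integer RNG seed.
#' @return classed list `invasion_config`.
#' @export
invasion_config <- function(seed_codes = NULL, years = 2004:2016,
                            local_scale_km = 15, jump_rate = 0.5,
                            density_bias = 0, contagion = NULL, seed = 1L) {
  stopifnot(local_scale_km > 0, jump_rate >= 0, density_bias >= 0,
            length(years) >= 1)
  structure(list(seed_codes = seed_codes, years = as.integer(years),
                 local_scale_km = local_scale_km, jump_rate = jump_rate,
                 density_bias = density_bias, contagion = contagion,
                 seed = seed),
            class = "invasion_config")
}

# Calibrate the contagion constant so the expected number of municipalities
# colonised in the first year from the seed set is ~1.
calibrate_contagion <- function(K, w) {
  expected <- function(cc) sum(1 - exp(-cc * K * w))
  hi <- 1e9
  if (expected(hi) < 1) return(hi)
  stats::uniroot(function(cc) expected(cc) - 1, c(1e-12, hi),
                 tol = 1e-10)$root
}

#' Simulate the colonisation process
#'
#' Each year, an uncolonised municipality `i` is colonised with probability
#' `1 - exp(-c * K_i * w_i)` where `K_i` sums the exponential kernel
#' `exp(-d_ij / lambda)` over colonised municipalities `j` and `w_i` is its
#' relative population density raised to `density_bias`. Independently,
#' a Poisson number of long-distance jumps (mean `jump_rate`) colonise
#' municipalities drawn with weight `population^density_bias`. Colonisation
#' is absorbing. Deterministic under the config seed.
#'
#' @param registry municipality registry (typically [generate_world()]).
#' @param config [invasion_config()].
#' @return data frame `code`, `colonized_year` (`NA` = never colonised
#'   within the horizon), with the simulated years attached as the
#'   `"years"` attribute.
#' @export
simulate_invasion <- function(registry, config = invasion_config()) {
  set.seed(config$seed)
  n <- nrow(registry)
  years <- config$years
  seed_codes <- config$seed_codes
  if (is.null(seed_codes)) {
    seed_codes <- registry$code[which.max(registry$population)]
  }
  seed_idx <- match(seed_codes, registry$code)
  if (anyNA(seed_idx)) stop("seed municipality not in registry", call. = FALSE)

  D <- outer(seq_len(n), seq_len(n), function(i, j)
    sphere_distance(registry$centroid_lat[i], registry$centroid_lon[i],
                    registry$centroid_lat[j], registry$centroid_lon[j]))
  kernel <- exp(-D / config$local_scale_km)
  diag(kernel) <- 0

  dens <- population_density(registry$population, registry$surface_ha)
  w <- (dens / mean(dens))^config$density_bias
  jump_w <- registry$population^config$density_bias

  colonized_year <- rep(NA_integer_, n)
  colonized_year[seed_idx] <- years[1]

  cc <- config$contagion
  if (is.null(cc)) {
    col0 <- !is.na(colonized_year)
    K0 <- colSums(kernel[col0, , drop = FALSE])
    K0[col0] <- 0
    cc <- calibrate_contagion(K0[!col0], w[!col0])
  }

  for (y in years[-1]) {
    col <- !is.na(colonized_year)
    open <- which(!col)
    if (length(open) == 0) break
    K <- colSums(kernel[col, open, drop = FALSE])
    p <- 1 - exp(-cc * K * w[open])
    hit <- open[stats::runif(length(open)) < p]
    n_jumps <- stats::rpois(1, config$jump_rate)
    if (n_jumps > 0) {
      still_open <- setdiff(open, hit)
      if (length(still_open) > 0) {
        k <- min(n_jumps, length(still_open))
        jw <- jump_w[still_open]
        jhit <- if (length(still_open) == 1) still_open else
          sample(still_open, k, prob = if (all(jw == 0)) NULL else jw)
        hit <- c(hit, jhit)
      }
    }
    colonized_year[hit] <- y
  }
  out <- data.frame(code = registry$code, colonized_year = colonized_year,
                    stringsAsFactors = FALSE)
  attr(out, "years") <- years
  out
}

#' Configuration of the dual observation process
#'
#' Two imperfect surveillance strategies observe the true colonisation
#' state. Field sampling is proximity-targeted: from `field_start_year`, a
#' colonised municipality is checked (with per-year success
#' `field_detect_prob`) only if it lies within `field_radius_km` of a
#' municipality already detected in an earlier year, or is one of the
#' initial entry-point municipalities monitored from the start. Citizen
#' reporting is population-weighted and unconstrained by distance: from
#' `citizen_start_year` every colonised municipality is detected each year
#' with probability `1 - exp(-citizen_rate * population)`, floored at
#' `citizen_detect_floor`.
#'
#' @param field_radius_km monitoring radius around known positives (km).
#' @param field_detect_prob per-year field detection probability in
#'   monitored colonised municipalities.
#' @param citizen_rate per-capita yearly reporting intensity.
#' @param citizen_detect_floor minimum per-municipality yearly citizen
#'   detection probability.
#' @param field_start_year,citizen_start_year first year each strategy
#'   operates (defaults 2004 and 2014, the historical onsets).
#' @param seed integer RNG seed, independent of the invasion seed so the
#'   truth is unchanged when only the observation stream is re-drawn.
#' @return classed list `surveillance_config`.
#' @export
surveillance_config <- function(field_radius_km = 20, field_detect_prob = 0.6,
                                citizen_rate = 5e-5,
                                citizen_detect_floor = 0.02,
                                field_start_year = 2004,
                                citizen_start_year = 2014, seed = 2L) {
  stopifnot(field_radius_km > 0,
            field_detect_prob >= 0, field_detect_prob <= 1,
            citizen_rate >= 0,
            citizen_detect_floor >= 0, citizen_detect_floor <= 1)
  structure(list(field_radius_km = field_radius_km,
                 field_detect_prob = field_detect_prob,
                 citizen_rate = citizen_rate,
                 citizen_detect_floor = citizen_detect_floor,
                 field_start_year = as.integer(field_start_year),
                 citizen_start_year = as.integer(citizen_start_year),
                 seed = seed),
            class = "surveillance_config")
}

#' Simulate dual-strategy surveillance over a known invasion
#'
#' @param registry municipality registry.
#' @param truth output of [simulate_invasion()] on the same registry.
#' @param config [surveillance_config()].
#' @param species species token recorded on the output (default
#'   `"albopictus"`).
#' @return long detection records (one per municipality with at least one
#'   detection): `municipality_code`, `species`, `field_year`,
#'   `field_source` (`"simulated"`), `citizen_year`, `documented_sequence`
#'   (`NA`). No detection year ever precedes the true colonisation year.
#' @export
simulate_surveillance <- function(registry, truth,
                                  config = surveillance_config(),
                                  species = "albopictus") {
  set.seed(config$seed)
  years <- attr(truth, "years")
  if (is.null(years)) years <- sort(unique(stats::na.omit(truth$colonized_year)))
  n <- nrow(registry)
  ty <- truth$colonized_year[match(registry$code, truth$code)]

  D <- outer(seq_len(n), seq_len(n), function(i, j)
    sphere_distance(registry$centroid_lat[i], registry$centroid_lon[i],
                    registry$centroid_lat[j], registry$centroid_lon[j]))
  entry_points <- which(!is.na(ty) & ty == min(ty, na.rm = TRUE))

  field_year <- rep(NA_integer_, n)
  citizen_year <- rep(NA_integer_, n)
  p_cit <- pmax(config$citizen_detect_floor,
                1 - exp(-config$citizen_rate * registry$population))

  for (y in years) {
    colonized <- !is.na(ty) & ty <= y
    if (y >= config$field_start_year) {
      known_prev <- which((!is.na(field_year) & field_year < y) |
                            (!is.na(citizen_year) & citizen_year < y))
      monitored <- rep(FALSE, n)
      monitored[entry_points] <- TRUE
      if (length(known_prev) > 0) {
        monitored <- monitored |
          (apply(D[known_prev, , drop = FALSE], 2, min) <= config$field_radius_km)
      }
      cand <- which(colonized & is.na(field_year) & monitored)
      if (length(cand) > 0) {
        hit <- cand[stats::runif(length(cand)) < config$field_detect_prob]
        field_year[hit] <- y
      }
    }
    if (y >= config$citizen_start_year) {
      cand <- which(colonized & is.na(citizen_year))
      if (length(cand) > 0) {
        hit <- cand[stats::runif(length(cand)) < p_cit[cand]]
        citizen_year[hit] <- y
      }
    }
  }
  keep <- !is.na(field_year) | !is.na(citizen_year)
  records <- data.frame(
    municipality_code = registry$code[keep],
    species = species,
    field_year = field_year[keep],
    field_source = ifelse(is.na(field_year[keep]), NA_character_, "simulated"),
    citizen_year = citizen_year[keep],
    documented_sequence = NA_character_,
    stringsAsFactors = FALSE
  )
  validate_detections(records, registry,
                      field_min = min(years), citizen_min = min(years),
                      year_max = max(years))
}
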
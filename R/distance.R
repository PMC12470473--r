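# Sphere radius (km) matching the WGS84 equatorial radius, the conventional
# default of spherical Vincenty implementations.
SPHERE_RADIUS_KM <- 6378.137

#' Great-circle distance on a sphere
#'
#' Spherical distance via the numerically stable Vincenty arctangent
#' formulation (exact on the sphere; well conditioned for both near-zero and
#' near-antipodal separations, unlike the plain arccosine form).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised,
#'   recycled).
#' @param radius_km sphere radius in kilometres (default 6378.137, the WGS84
#'   equatorial radius).
#' @return distance(s) in kilometres.
#' @examples
#' sphere_distance(0, 0, 1, 0)    # one degree of arc ~ 111.32 km
#' sphere_distance(0, 0, 0, 180)  # antipodal ~ 20037.51 km
#' @export
sphere_distance <- function(lat1, lon1, lat2, lon2,
                            radius_km = SPHERE_RADIUS_KM) {
  check_coords <- function(lat, lon) {
    if (any(lat < -90 | lat > 90, na.rm = TRUE)) {
      stop("latitude outside [-90, 90]", call. = FALSE)
    }
    if (any(lon < -180 | lon > 180, na.rm = TRUE)) {
      stop("longitude outside [-180, 180]", call. = FALSE)
    }
  }
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  p1 <- lat1 * rad; p2 <- lat2 * rad
  dl <- (lon2 - lon1) * rad
  num <- sqrt((cos(p2) * sin(dl))^2 +
                (cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))^2)
  den <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  radius_km * atan2(num, den)
}

#' Planar centroid of a polygon in geographic coordinates
#'
#' Area-weighted centroid computed in a local Lambert cylindrical equal-area
#' projection centred on the geometry (so small administrative polygons are
#' treated as planar figures with correct area weighting), then inverted back
#' to WGS84. Multi-part geometries are combined by signed-area weighting, so
#' a part with three times the area pulls the centroid three times harder.
#'
#' @param polygon a two-column matrix of (lon, lat) vertices for a single
#'   ring, or a list of such matrices for a multi-part geometry. Rings need
#'   not be explicitly closed.
#' @return named numeric `c(lat = ..., lon = ...)`.
#' @export
polygon_centroid <- function(polygon) {
  rings <- if (is.list(polygon) && !is.data.frame(polygon)) polygon else list(polygon)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop("degenerate polygon ring", call. = FALSE)
    # drop an explicit closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    if (nrow(r) < 3) stop("degenerate polygon ring", call. = FALSE)
    r
  })
  all_pts <- do.call(rbind, rings)
  lon0 <- mean(range(all_pts[, 1]))
  lat0 <- mean(range(all_pts[, 2]))
  rad <- pi / 180
  k <- cos(lat0 * rad)
  if (k <= 0) stop("degenerate polygon at the pole", call. = FALSE)
  project <- function(r) {
    cbind(x = (r[, 1] - lon0) * rad * k, y = sin(r[, 2] * rad) / k)
  }
  total_a <- 0; cx <- 0; cy <- 0
  for (r in rings) {
    p <- project(r)
    xi <- p[, 1]; yi <- p[, 2]
    xj <- c(xi[-1], xi[1]); yj <- c(yi[-1], yi[1])
    cross <- xi * yj - xj * yi
    a <- sum(cross) / 2
    if (abs(a) < .Machine$double.eps) next
    cx <- cx + sum((xi + xj) * cross) / 6
    cy <- cy + sum((yi + yj) * cross) / 6
    total_a <- total_a + a
  }
  if (abs(total_a) < .Machine$double.eps) {
    stop("degenerate polygon: zero area", call. = FALSE)
  }
  cx <- cx / total_a; cy <- cy / total_a
  c(lat = asin(pmin(1, pmax(-1, cy * k))) / rad, lon = cx / (rad * k) + lon0)
}

#' Municipality centroids from a GeoJSON file
#'
#' Reads a WGS84 GeoJSON `FeatureCollection` of municipal polygons and
#' returns the geometric centroid of each feature. The feature property
#' naming the municipality code is configurable.
#'
#' @param path GeoJSON file.
#' @param code_property name of the feature property holding the LAU2 code
#'   (default `"code"`).
#' @return data frame `code`, `centroid_lat`, `centroid_lon`.
#' @export
centroids_from_geojson <- function(path, code_property = "code") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(gj$features, function(f) {
    code <- f$properties[[code_property]]
    if (is.null(code)) stop("feature without property '", code_property, "'",
                            call. = FALSE)
    geom <- f$geometry
    ring_to_matrix <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    }
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates[1], ring_to_matrix),
      MultiPolygon = lapply(geom$coordinates, function(poly)
        ring_to_matrix(poly[[1]])),
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    ctr <- polygon_centroid(rings)
    data.frame(code = as.character(code), centroid_lat = ctr[["lat"]],
               centroid_lon = ctr[["lon"]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' External reference points for distance assignment
#'
#' A reference point is a known positive location outside the registry (for
#' instance an established population just across a national border) that can
#' serve as the nearest previous positive when no prior in-registry positive
#' exists nearby. It becomes usable for detections in years after
#' `active_from_year`.
#'
#' @param label character labels.
#' @param lat,lon decimal-degree coordinates.
#' @param active_from_year first calendar year the population is considered
#'   present at the point.
#' @return data frame classed `aedes_reference_points`.
#' @examples
#' # an established population across the Portuguese border, present from 2017
#' reference_points("border population", 41.20683, -8.28486, 2017)
#' @export
reference_points <- function(label, lat, lon, active_from_year) {
  stopifnot(length(label) == length(lat), length(lat) == length(lon),
            length(lon) == length(active_from_year))
  if (any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    stop("reference point coordinates out of range", call. = FALSE)
  }
  structure(data.frame(label = as.character(label), lat = lat, lon = lon,
                       active_from_year = as.integer(active_from_year),
                       stringsAsFactors = FALSE),
            class = c("aedes_reference_points", "data.frame"))
}

#' Distance to the nearest previously positive municipality
#'
#' For a municipality newly detected in `year`, the great-circle distance
#' from its centroid to the closest municipality first detected in any year
#' up to `year - 1` ("positive up to the previous year"), or to an external
#' reference point already active. Same-year positives are never reference
#' candidates. Ties are broken towards the smallest code; the distance value
#' is unaffected.
#'
#' @param code municipality code of the new detection.
#' @param year its first-detection year.
#' @param positives data frame `code`, `first_year` of all positive
#'   municipalities (any strategy).
#' @param registry municipality registry (centroids).
#' @param refs optional [reference_points()].
#' @return one-row data frame: `municipality_code`, `year`, `distance_km`,
#'   `reference_code`, `excluded`, `exclusion_reason`. With no prior positive
#'   and no active reference the record is excluded with reason
#'   `"no prior positives"`.
#' @export
nearest_previous_positive <- function(code, year, positives, registry,
                                      refs = NULL) {
  i <- match(code, registry$code)
  if (is.na(i)) stop("code not in registry: ", code, call. = FALSE)
  prior <- positives[!is.na(positives$first_year) &
                       positives$first_year <= year - 1 &
                       positives$code != code, , drop = FALSE]
  cand_lat <- numeric(0); cand_lon <- numeric(0); cand_id <- character(0)
  if (nrow(prior) > 0) {
    j <- match(prior$code, registry$code)
    if (anyNA(j)) stop("positive code not in registry", call. = FALSE)
    cand_lat <- registry$centroid_lat[j]
    cand_lon <- registry$centroid_lon[j]
    cand_id <- prior$code
  }
  if (!is.null(refs) && nrow(refs) > 0) {
    act <- refs[refs$active_from_year <= year - 1, , drop = FALSE]
    cand_lat <- c(cand_lat, act$lat)
    cand_lon <- c(cand_lon, act$lon)
    cand_id <- c(cand_id, act$label)
  }
  if (length(cand_id) == 0) {
    return(data.frame(municipality_code = code, year = year,
                      distance_km = NA_real_, reference_code = NA_character_,
                      excluded = TRUE, exclusion_reason = "no prior positives",
                      stringsAsFactors = FALSE))
  }
  d <- sphere_distance(registry$centroid_lat[i], registry$centroid_lon[i],
                       cand_lat, cand_lon)
  ord <- order(d, cand_id)
  best <- ord[1]
  data.frame(municipality_code = code, year = year, distance_km = d[best],
             reference_code = cand_id[best], excluded = FALSE,
             exclusion_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Nearest-previous-positive distances for all new detections of a species
#'
#' Builds one distance record per positively attributed municipality
#' (categories 1-4). The record's `strategy` is the first-detection strategy;
#' simultaneous (category 3) municipalities get `strategy = NA` and are
#' flagged by the `"simultaneous"` exclusion rule before any comparison.
#'
#' @param attributions output of [attribution_table()].
#' @param registry municipality registry.
#' @param species species token (default `"albopictus"`).
#' @param refs optional [reference_points()].
#' @return data frame `municipality_code`, `year`, `strategy`,
#'   `distance_km`, `reference_code`, `excluded`, `exclusion_reason`, classed
#'   `aedes_distances`.
#' @export
detection_distances <- function(attributions, registry, species = "albopictus",
                                refs = NULL) {
  att <- attributions[attributions$species == species &
                        attributions$category %in% 1:4, , drop = FALSE]
  att <- att[order(att$first_year, att$municipality_code), , drop = FALSE]
  positives <- data.frame(code = att$municipality_code,
                          first_year = att$first_year,
                          stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(att)), function(r) {
    rec <- nearest_previous_positive(att$municipality_code[r],
                                     att$first_year[r], positives, registry,
                                     refs = refs)
    strat <- att$first_strategy[r]
    rec$strategy <- if (identical(strat, "simultaneous")) NA_character_ else strat
    rec
  })
  out <- do.call(rbind, rows)
  out <- out[, c("municipality_code", "year", "strategy", "distance_km",
                 "reference_code", "excluded", "exclusion_reason")]
  rownames(out) <- NULL
  class(out) <- unique(c("aedes_distances", class(out)))
  out
}

#' Exclusion rules for the distance analysis
#'
#' Rules flag records that must not enter the strategy comparison; flagged
#' records are retained with their reason, never deleted. Supported rules:
#' \describe{
#'   \item{`simultaneous`}{exclude simultaneous (category 3) detections,
#'     whose strategy is ambiguous.}
#'   \item{`seed_years`}{years whose detections have no meaningful prior
#'     reference (the initial invasion year); reason `"no prior reference"`.}
#'   \item{`named_codes`}{a named list mapping a reason label to municipality
#'     codes (e.g. a suspected independent introduction far from the front).}
#'   \item{`eradicated_codes`}{codes whose detected populations are
#'     officially eradicated; reason `"eradicated"`.}
#' }
#'
#' @param simultaneous logical (default `TRUE`).
#' @param seed_years integer vector of years (default empty).
#' @param named_codes named list of character vectors (default empty).
#' @param eradicated_codes character vector (default empty).
#' @return classed list `aedes_exclusion_rules`.
#' @export
exclusion_rules <- function(simultaneous = TRUE, seed_years = integer(),
                            named_codes = list(),
                            eradicated_codes = character()) {
  if (length(named_codes) > 0 &&
      (is.null(names(named_codes)) || any(!nzchar(names(named_codes))))) {
    stop("named_codes must be a named list of code vectors", call. = FALSE)
  }
  structure(list(simultaneous = isTRUE(simultaneous),
                 seed_years = as.integer(seed_years),
                 named_codes = lapply(named_codes, as.character),
                 eradicated_codes = as.character(eradicated_codes)),
            class = "aedes_exclusion_rules")
}

#' Read exclusion rules from YAML
#'
#' The YAML file may contain keys `simultaneous`, `seed_years`,
#' `named_codes` (a mapping of reason label to code list) and
#' `eradicated_codes`; any other key is a configuration error.
#'
#' @param path YAML file.
#' @return [exclusion_rules()] object.
#' @export
read_exclusion_rules <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("simultaneous", "seed_years", "named_codes", "eradicated_codes")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown exclusion rule(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  exclusion_rules(
    simultaneous = if (is.null(y$simultaneous)) TRUE else y$simultaneous,
    seed_years = if (is.null(y$seed_years)) integer() else unlist(y$seed_years),
    named_codes = if (is.null(y$named_codes)) list() else
      lapply(y$named_codes, unlist),
    eradicated_codes = if (is.null(y$eradicated_codes)) character() else
      unlist(y$eradicated_codes)
  )
}

#' Apply exclusion rules to distance records
#'
#' @param records output of [detection_distances()].
#' @param rules [exclusion_rules()] object.
#' @return the records with `excluded`/`exclusion_reason` updated; already
#'   excluded records keep their original reason.
#' @export
apply_exclusions <- function(records, rules = exclusion_rules()) {
  if (!inherits(rules, "aedes_exclusion_rules")) {
    stop("rules must be built with exclusion_rules()", call. = FALSE)
  }
  flag <- function(records, hit, reason) {
    hit <- hit & !records$excluded
    records$excluded[hit] <- TRUE
    records$exclusion_reason[hit] <- reason
    records
  }
  if (rules$simultaneous) {
    records <- flag(records, is.na(records$strategy), "simultaneous")
  }
  if (length(rules$seed_years) > 0) {
    records <- flag(records, records$year %in% rules$seed_years,
                    "no prior reference")
  }
  for (label in names(rules$named_codes)) {
    records <- flag(records,
                    records$municipality_code %in% rules$named_codes[[label]],
                    label)
  }
  if (length(rules$eradicated_codes) > 0) {
    records <- flag(records,
                    records$municipality_code %in% rules$eradicated_codes,
                    "eradicated")
  }
  records
}

#' Compare detection distances between surveillance strategies
#'
#' On non-excluded records only: a two-sample t-test of distance by strategy
#' (Welch by default; `var_equal = TRUE` gives the pooled-variance Student
#' variant), a two-way ANOVA with year and strategy as factors plus their
#' interaction (sequential sums of squares, year entered first), and
#' Tukey-Kramer adjusted pairwise contrasts on the year-by-strategy cells.
#'
#' @param records distance records after [apply_exclusions()].
#' @param var_equal assume equal group variances in the t-test (default
#'   `FALSE`, Welch).
#' @param log_distance analyse `log10(distance_km + 1)` instead of raw
#'   kilometres (default `FALSE`).
#' @return classed list `strategy_comparison`: group sizes and mean distances
#'   (always in raw km), `t_statistic`, `t_p_value`, `anova_table`,
#'   `tukey_pairs`, and the fitted `aov` object.
#' @export
compare_strategies <- function(records, var_equal = FALSE,
                               log_distance = FALSE) {
  keep <- !records$excluded & records$strategy %in% c("field", "citizen") &
    !is.na(records$distance_km)
  d <- records[keep, , drop = FALSE]
  n_by <- table(factor(d$strategy, levels = c("field", "citizen")))
  if (any(n_by < 2)) {
    stop("need at least 2 non-excluded records per strategy", call. = FALSE)
  }
  d$strategy <- factor(d$strategy, levels = c("field", "citizen"))
  d$year_f <- factor(d$year)
  d$response <- if (log_distance) log10(d$distance_km + 1) else d$distance_km

  tt <- stats::t.test(response ~ strategy, data = d, var.equal = var_equal)
  fit <- stats::aov(response ~ year_f * strategy, data = d)
  anova_table <- stats::anova(fit)
  tukey <- tryCatch(stats::TukeyHSD(fit, which = "year_f:strategy"),
                    error = function(e) NULL)
  structure(list(
    n_field = as.integer(n_by[["field"]]),
    n_citizen = as.integer(n_by[["citizen"]]),
    mean_field_km = mean(d$distance_km[d$strategy == "field"]),
    mean_citizen_km = mean(d$distance_km[d$strategy == "citizen"]),
    t_statistic = unname(tt$statistic),
    t_p_value = tt$p.value,
    anova_table = anova_table,
    tukey_pairs = if (is.null(tukey)) NULL else tukey[["year_f:strategy"]],
    fit = fit,
    log_distance = log_distance
  ), class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Detection-distance comparison by surveillance strategy\n")
  cat(sprintf("  field:   n = %4d, mean distance %6.2f km\n",
              x$n_field, round_half_up(x$mean_field_km, 2)))
  cat(sprintf("  citizen: n = %4d, mean distance %6.2f km\n",
              x$n_citizen, round_half_up(x$mean_citizen_km, 2)))
  cat(sprintf("  t = %.3f, p = %.4g\n", x$t_statistic, x$t_p_value))
  cat("  two-way ANOVA (year, strategy, interaction):\n")
  print(x$anova_table)
  invisible(x)
}
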
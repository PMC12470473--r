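# Shared fixtures built in code: a tiny deterministic registry, detection
# builders, and an independent haversine oracle.

make_registry <- function(n = 6, provinces = c("P1", "P2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- if (is.null(seed)) seq(40, 41, length.out = n) else runif(n, 39, 42)
  lon <- if (is.null(seed)) seq(0, 1, length.out = n) else runif(n, -2, 2)
  as_registry(data.frame(
    code = sprintf("T%03d", seq_len(n)),
    name = sprintf("Town %d", seq_len(n)),
    province = rep_len(provinces, n),
    autonomous_community = "AC1",
    surface_ha = seq(1000, 1000 + 100 * (n - 1), length.out = n),
    population = seq(5000, 5000 + 2000 * (n - 1), length.out = n),
    centroid_lat = lat,
    centroid_lon = lon,
    stringsAsFactors = FALSE
  ))
}

make_records <- function(codes, field_year = NA, citizen_year = NA,
                         species = "albopictus", documented_sequence = NA) {
  n <- length(codes)
  validate_detections(data.frame(
    municipality_code = codes,
    species = rep_len(species, n),
    field_year = as.integer(rep_len(field_year, n)),
    field_source = rep_len("own data", n),
    citizen_year = as.integer(rep_len(citizen_year, n)),
    documented_sequence = as.character(rep_len(documented_sequence, n)),
    stringsAsFactors = FALSE
  ))
}

# Independent great-circle oracle: haversine formula, same sphere radius.
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6378.137) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# Attribution frame straight from a truth table (perfect observation),
# used to feed analysis stages with known ground truth.
truth_attribution <- function(truth, species = "albopictus") {
  data.frame(
    municipality_code = truth$code,
    species = species,
    category = ifelse(is.na(truth$colonized_year), 5L, 1L),
    first_year = truth$colonized_year,
    first_strategy = ifelse(is.na(truth$colonized_year), NA_character_, "field"),
    stringsAsFactors = FALSE
  )
}
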
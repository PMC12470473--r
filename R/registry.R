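#' @keywords internal
"_PACKAGE"

#' Species tracked by the surveillance pipeline
#'
#' The three invasive *Aedes* species under municipal surveillance in Spain:
#' the Asian tiger mosquito (*Ae. albopictus*), the yellow-fever mosquito
#' (*Ae. aegypti*) and the Asian bush mosquito (*Ae. japonicus*). Species
#' tokens are lowercase specific epithets; any other token is a hard error
#' throughout the package.
#'
#' @format Character vector of length 3.
#' @export
AEDES_SPECIES <- c("albopictus", "aegypti", "japonicus")

# Required columns of a municipality registry CSV.
REGISTRY_COLUMNS <- c(
  "code", "name", "province", "autonomous_community",
  "surface_ha", "population", "centroid_lat", "centroid_lon"
)

#' Validate and class a municipality registry
#'
#' A registry is a data frame with one row per municipality (LAU2 unit):
#' administrative code, name, province, autonomous community, surface in
#' hectares, resident population, and WGS84 centroid coordinates in decimal
#' degrees. An optional `eradicated_species` column holds a
#' semicolon-separated list of species tokens whose detected populations are
#' officially considered eradicated in that municipality (the listing retains
#' the detection; analyses may exclude it).
#'
#' @param df data frame with at least the columns
#'   `code,name,province,autonomous_community,surface_ha,population,centroid_lat,centroid_lon`.
#' @return the validated data frame with class `aedes_registry` prepended.
#' @details Invariants enforced: unique codes; `surface_ha > 0`;
#'   `population >= 0`; latitudes in \[-90, 90\]; longitudes in \[-180, 180\];
#'   eradicated-species tokens among [AEDES_SPECIES].
#' @seealso [load_registry()]
#' @export
as_registry <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("registry schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$code <- as.character(df$code)
  for (col in c("surface_ha", "population", "centroid_lat", "centroid_lon")) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0) {
        stop(sprintf("registry parse error: non-numeric %s at row %d (value '%s')",
                     col, bad[1], v[bad[1]]), call. = FALSE)
      }
      df[[col]] <- num
    }
    if (anyNA(df[[col]])) {
      stop(sprintf("registry parse error: missing %s at row %d",
                   col, which(is.na(df[[col]]))[1]), call. = FALSE)
    }
  }
  dup <- duplicated(df$code)
  if (any(dup)) {
    stop("registry validation error: duplicate code(s) ",
         paste(unique(df$code[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(df$surface_ha <= 0)) {
    stop("registry validation error: surface_ha must be > 0 (row ",
         which(df$surface_ha <= 0)[1], ")", call. = FALSE)
  }
  if (any(df$population < 0)) {
    stop("registry validation error: population must be >= 0 (row ",
         which(df$population < 0)[1], ")", call. = FALSE)
  }
  if (any(df$centroid_lat < -90 | df$centroid_lat > 90)) {
    stop("registry validation error: centroid_lat outside [-90, 90]", call. = FALSE)
  }
  if (any(df$centroid_lon < -180 | df$centroid_lon > 180)) {
    stop("registry validation error: centroid_lon outside [-180, 180]", call. = FALSE)
  }
  if (!is.null(df$eradicated_species)) {
    tokens <- unlist(strsplit(df$eradicated_species[!is.na(df$eradicated_species)], ";"))
    tokens <- trimws(tokens[nzchar(trimws(tokens))])
    unknown <- setdiff(tokens, AEDES_SPECIES)
    if (length(unknown) > 0) {
      stop("registry validation error: unknown eradicated species token(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else {
    df$eradicated_species <- NA_character_
  }
  rownames(df) <- NULL
  class(df) <- unique(c("aedes_registry", class(df)))
  df
}

#' Read a municipality registry from CSV
#'
#' @param path path to a UTF-8 CSV file with header columns
#'   `code,name,province,autonomous_community,surface_ha,population,centroid_lat,centroid_lon`
#'   (plus an optional `eradicated_species` column).
#' @return a validated registry (see [as_registry()]).
#' @examples
#' path <- system.file("extdata", "mini_registry.csv", package = "aedespread")
#' reg <- load_registry(path)
#' nrow(reg)
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8")
  as_registry(df)
}

# Wide detection-table column names for one species.
species_columns <- function(species) {
  c(paste0(species, "_field_year"),
    paste0(species, "_field_source"),
    paste0(species, "_citizen_year"))
}

#' Validate a long table of detection records
#'
#' A detection record is one (municipality, species) pair with the year of
#' first detection by field sampling and/or by citizen science. Field
#' surveillance of invasive *Aedes* in Spain starts in 2004 (first
#' *Ae. albopictus* record); the citizen-science platform operates from 2014,
#' so citizen years before that are invalid. A record must carry at least one
#' of the two years; absence of a year means "not detected by that strategy",
#' never zero.
#'
#' @param records data frame with columns `municipality_code`, `species`,
#'   `field_year`, `field_source`, `citizen_year`, and optionally
#'   `documented_sequence` (one of `"field"`, `"citizen"` or `NA`; an
#'   override used only for same-year detections whose chronological order is
#'   documented).
#' @param registry registry the codes must resolve in, or `NULL` to skip the
#'   referential check.
#' @param field_min,citizen_min,year_max inclusive calendar-year bounds
#'   (defaults 2004, 2014 and 2024).
#' @return the validated records, invisibly classed `aedes_detections`.
#' @export
validate_detections <- function(records, registry = NULL,
                                field_min = 2004, citizen_min = 2014,
                                year_max = 2024) {
  needed <- c("municipality_code", "species", "field_year", "field_source",
              "citizen_year")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("detections schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$documented_sequence)) {
    records$documented_sequence <- rep(NA_character_, nrow(records))
  }
  records$municipality_code <- as.character(records$municipality_code)
  records$species <- as.character(records$species)
  records$field_source <- as.character(records$field_source)
  records$field_year <- suppressWarnings(as.integer(records$field_year))
  records$citizen_year <- suppressWarnings(as.integer(records$citizen_year))

  unknown_sp <- setdiff(unique(records$species), AEDES_SPECIES)
  if (length(unknown_sp) > 0) {
    stop("detections validation error: unknown species token(s) ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)
  }
  no_year <- is.na(records$field_year) & is.na(records$citizen_year)
  if (any(no_year)) {
    stop("detections validation error: record without any detection year (row ",
         which(no_year)[1], ")", call. = FALSE)
  }
  bad_field <- which(!is.na(records$field_year) &
                       (records$field_year < field_min | records$field_year > year_max))
  if (length(bad_field) > 0) {
    stop(sprintf("detections validation error: field_year %d outside [%d, %d] (row %d)",
                 records$field_year[bad_field[1]], field_min, year_max, bad_field[1]),
         call. = FALSE)
  }
  bad_cit <- which(!is.na(records$citizen_year) &
                     (records$citizen_year < citizen_min | records$citizen_year > year_max))
  if (length(bad_cit) > 0) {
    stop(sprintf("detections validation error: citizen_year %d outside [%d, %d] (row %d)",
                 records$citizen_year[bad_cit[1]], citizen_min, year_max, bad_cit[1]),
         call. = FALSE)
  }
  bad_seq <- which(!is.na(records$documented_sequence) &
                     !records$documented_sequence %in% c("field", "citizen"))
  if (length(bad_seq) > 0) {
    stop("detections validation error: documented_sequence must be 'field' or 'citizen' (row ",
         bad_seq[1], ")", call. = FALSE)
  }
  dup <- duplicated(records[, c("municipality_code", "species")])
  if (any(dup)) {
    stop("detections validation error: duplicate (municipality, species) pair for code ",
         records$municipality_code[which(dup)[1]], call. = FALSE)
  }
  if (!is.null(registry)) {
    unknown <- setdiff(records$municipality_code, registry$code)
    if (length(unknown) > 0) {
      stop("detections referential error: code(s) not in registry: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  rownames(records) <- NULL
  class(records) <- unique(c("aedes_detections", class(records)))
  records
}

#' Read a wide per-municipality detection table
#'
#' The on-disk layout has one row per municipality and, for each species
#' `S` of [AEDES_SPECIES], three data columns `S_field_year`,
#' `S_field_source`, `S_citizen_year` (nine data columns in all). A fourth
#' optional column `S_documented_sequence` carries the strategy override for
#' documented same-year cases. The table is unpivoted into one long record
#' per (municipality, species) holding at least one detection year; empty
#' cells are absent values, never zeroes.
#'
#' @param path CSV path (UTF-8).
#' @param registry registry used for referential validation (every code in
#'   the file must exist there); `NULL` skips the check.
#' @inheritParams validate_detections
#' @return long validated data frame of detection records.
#' @examples
#' reg <- load_registry(system.file("extdata", "mini_registry.csv",
#'                                  package = "aedespread"))
#' det <- load_detections(system.file("extdata", "mini_detections.csv",
#'                                    package = "aedespread"), reg)
#' det[, c("municipality_code", "species", "field_year", "citizen_year")]
#' @export
load_detections <- function(path, registry = NULL,
                            field_min = 2004, citizen_min = 2014,
                            year_max = 2024) {
  if (!file.exists(path)) stop("detections file not found: ", path, call. = FALSE)
  wide <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                          fileEncoding = "UTF-8")
  if (is.null(wide$code)) {
    stop("detections schema error: missing column 'code'", call. = FALSE)
  }
  out <- list()
  for (sp in AEDES_SPECIES) {
    cols <- species_columns(sp)
    present <- intersect(cols, names(wide))
    if (length(present) == 0) next
    fy <- if (cols[1] %in% names(wide)) wide[[cols[1]]] else NA_character_
    fs <- if (cols[2] %in% names(wide)) wide[[cols[2]]] else NA_character_
    cy <- if (cols[3] %in% names(wide)) wide[[cols[3]]] else NA_character_
    ds_col <- paste0(sp, "_documented_sequence")
    ds <- if (ds_col %in% names(wide)) wide[[ds_col]] else NA_character_
    blank_to_na <- function(x) {
      x <- rep_len(as.character(x), nrow(wide))
      x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA_character_
      x
    }
    fy <- blank_to_na(fy); fs <- blank_to_na(fs)
    cy <- blank_to_na(cy); ds <- blank_to_na(ds)
    keep <- !is.na(fy) | !is.na(cy)
    if (!any(keep)) next
    out[[sp]] <- data.frame(
      municipality_code = wide$code[keep],
      species = sp,
      field_year = suppressWarnings(as.integer(fy[keep])),
      field_source = fs[keep],
      citizen_year = suppressWarnings(as.integer(cy[keep])),
      documented_sequence = ds[keep],
      stringsAsFactors = FALSE
    )
  }
  records <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    municipality_code = character(), species = character(),
    field_year = integer(), field_source = character(),
    citizen_year = integer(), documented_sequence = character(),
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  validate_detections(records, registry,
                      field_min = field_min, citizen_min = citizen_min,
                      year_max = year_max)
}

#' Write detection records back to the wide CSV layout
#'
#' Inverse of [load_detections()]: `load_detections(write_detections(x))`
#' reproduces `x` exactly, including absent years (written as empty cells).
#' The `S_documented_sequence` column is emitted only for species where at
#' least one record carries an override.
#'
#' @param records long detection records (see [validate_detections()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(records, path) {
  codes <- sort(unique(records$municipality_code))
  wide <- data.frame(code = codes, stringsAsFactors = FALSE)
  for (sp in AEDES_SPECIES) {
    sub <- records[records$species == sp, , drop = FALSE]
    idx <- match(codes, sub$municipality_code)
    cols <- species_columns(sp)
    fmt <- function(x) ifelse(is.na(x), "", as.character(x))
    wide[[cols[1]]] <- fmt(sub$field_year[idx])
    wide[[cols[2]]] <- fmt(sub$field_source[idx])
    wide[[cols[3]]] <- fmt(sub$citizen_year[idx])
    ds <- sub$documented_sequence[idx]
    if (any(!is.na(ds))) wide[[paste0(sp, "_documented_sequence")]] <- fmt(ds)
  }
  ok <- tryCatch({
    utils::write.csv(wide, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing detections: ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}
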
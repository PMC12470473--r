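#' Classify first detections into the five surveillance categories
#'
#' Each (municipality, species) pair falls into one of five categories:
#' 1. positive by field sampling only;
#' 2. positive by citizen science only;
#' 3. positive by both strategies in the same year (simultaneous);
#' 4. positive by both strategies in different years;
#' 5. no detection.
#'
#' The first detection year is the earlier of the two strategy years and the
#' first strategy is the one holding it. Same-year cases are attributed to
#' `"simultaneous"` unless a `documented_sequence` override names the
#' strategy whose chronological priority is documented.
#'
#' @param field_year,citizen_year integer vectors of detection years
#'   (`NA` = not detected by that strategy). Recycled to a common length.
#' @param documented_sequence optional override (`"field"`, `"citizen"` or
#'   `NA`), applied only where both years are present and equal.
#' @return data frame with columns `category` (integer 1-5), `first_year`
#'   (integer, `NA` for category 5) and `first_strategy` (`"field"`,
#'   `"citizen"`, `"simultaneous"`, or `NA` for category 5).
#' @examples
#' classify_detection(field_year = c(2016, 2019, 2018, NA),
#'                    citizen_year = c(NA, 2015, 2018, NA))
#' @export
classify_detection <- function(field_year = NA, citizen_year = NA,
                               documented_sequence = NA) {
  n <- max(length(field_year), length(citizen_year), length(documented_sequence))
  fy <- rep_len(as.integer(field_year), n)
  cy <- rep_len(as.integer(citizen_year), n)
  ds <- rep_len(as.character(documented_sequence), n)

  category <- integer(n)
  category[!is.na(fy) & is.na(cy)] <- 1L
  category[is.na(fy) & !is.na(cy)] <- 2L
  both <- !is.na(fy) & !is.na(cy)
  category[both & fy == cy] <- 3L
  category[both & fy != cy] <- 4L
  category[is.na(fy) & is.na(cy)] <- 5L

  first_year <- pmin(fy, cy, na.rm = TRUE)
  first_year[category == 5L] <- NA_integer_

  first_strategy <- rep(NA_character_, n)
  first_strategy[category == 1L] <- "field"
  first_strategy[category == 2L] <- "citizen"
  first_strategy[category == 3L] <- "simultaneous"
  ov <- category == 3L & !is.na(ds)
  first_strategy[ov] <- ds[ov]
  f4 <- category == 4L
  first_strategy[f4] <- ifelse(fy[f4] < cy[f4], "field", "citizen")

  data.frame(category = category, first_year = first_year,
             first_strategy = first_strategy, stringsAsFactors = FALSE)
}

#' Attribute every registry municipality for each species
#'
#' Expands the detection records over the full registry so that, per species,
#' the five category counts partition the registry: municipalities without a
#' record are category 5 (no detection).
#'
#' @param records validated detection records (at most one per
#'   (municipality, species); see [validate_detections()]).
#' @param registry municipality registry (see [as_registry()]).
#' @param species species to attribute (default all of [AEDES_SPECIES]).
#' @return data frame with one row per (registry municipality, species):
#'   `municipality_code`, `species`, `category`, `first_year`,
#'   `first_strategy`, classed `aedes_attribution`.
#' @examples
#' reg <- load_registry(system.file("extdata", "mini_registry.csv",
#'                                  package = "aedespread"))
#' det <- load_detections(system.file("extdata", "mini_detections.csv",
#'                                    package = "aedespread"), reg)
#' att <- attribution_table(det, reg, species = "albopictus")
#' table(att$category)
#' @export
attribution_table <- function(records, registry, species = AEDES_SPECIES) {
  stopifnot(inherits(registry, "aedes_registry") || is.data.frame(registry))
  unknown_sp <- setdiff(species, AEDES_SPECIES)
  if (length(unknown_sp) > 0) {
    stop("unknown species token(s): ", paste(unknown_sp, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(records[, c("municipality_code", "species")])
  if (any(dup)) {
    stop("duplicate (municipality, species) record for code ",
         records$municipality_code[which(dup)[1]], call. = FALSE)
  }
  out <- lapply(species, function(sp) {
    sub <- records[records$species == sp, , drop = FALSE]
    idx <- match(registry$code, sub$municipality_code)
    cls <- classify_detection(sub$field_year[idx], sub$citizen_year[idx],
                              sub$documented_sequence[idx])
    data.frame(municipality_code = registry$code, species = sp, cls,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- unique(c("aedes_attribution", class(res)))
  res
}

#' Category counts per species
#'
#' @param attributions output of [attribution_table()].
#' @return data frame with one row per species and columns `category_1` ..
#'   `category_5`, plus `positive` (categories 1-4 summed).
#' @export
category_counts <- function(attributions) {
  species <- unique(attributions$species)
  rows <- lapply(species, function(sp) {
    sub <- attributions[attributions$species == sp, ]
    counts <- vapply(1:5, function(k) sum(sub$category == k), integer(1))
    data.frame(species = sp,
               category_1 = counts[1], category_2 = counts[2],
               category_3 = counts[3], category_4 = counts[4],
               category_5 = counts[5], positive = sum(counts[1:4]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
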
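#' Round half away from zero
#'
#' Reporting convention for percentages and distances: exact halves round
#' away from zero (so 31.75 reports as 31.8), unlike [round()]'s banker's
#' rounding. Internal computations always keep full precision; this applies
#' only at the reporting layer.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Annual and cumulative spread counts
#'
#' Tabulates, per calendar year, the number of municipalities first detected
#' by each strategy (field, citizen science, simultaneous) and the cumulative
#' number, surface area (hectares) and resident population of municipalities
#' detected up to and including that year.
#'
#' @param attributions output of [attribution_table()].
#' @param registry municipality registry supplying surface and population.
#' @param species single species token.
#' @param year_range optional inclusive `c(first, last)` year bounds; an
#'   attributed first detection outside the range is an error. Defaults to
#'   the observed range.
#' @return data frame with columns `year`, `new_field`, `new_citizen`,
#'   `new_simultaneous`, `new_total`, `cumulative_municipalities`,
#'   `cumulative_surface_ha`, `cumulative_population`.
#' @examples
#' reg <- load_registry(system.file("extdata", "mini_registry.csv",
#'                                  package = "aedespread"))
#' det <- load_detections(system.file("extdata", "mini_detections.csv",
#'                                    package = "aedespread"), reg)
#' att <- attribution_table(det, reg, species = "albopictus")
#' yearly_counts(att, reg, "albopictus")
#' @export
yearly_counts <- function(attributions, registry, species,
                          year_range = NULL) {
  stopifnot(length(species) == 1)
  sub <- attributions[attributions$species == species &
                        attributions$category != 5L, , drop = FALSE]
  if (nrow(sub) == 0) {
    if (is.null(year_range)) {
      return(data.frame(year = integer(), new_field = integer(),
                        new_citizen = integer(), new_simultaneous = integer(),
                        new_total = integer(),
                        cumulative_municipalities = integer(),
                        cumulative_surface_ha = numeric(),
                        cumulative_population = numeric()))
    }
    years <- seq(year_range[1], year_range[2])
    return(data.frame(year = years, new_field = 0L, new_citizen = 0L,
                      new_simultaneous = 0L, new_total = 0L,
                      cumulative_municipalities = 0L,
                      cumulative_surface_ha = 0, cumulative_population = 0))
  }
  if (is.null(year_range)) year_range <- range(sub$first_year)
  if (any(sub$first_year < year_range[1] | sub$first_year > year_range[2])) {
    stop("first detection year outside requested year range", call. = FALSE)
  }
  years <- seq(year_range[1], year_range[2])
  idx <- match(sub$municipality_code, registry$code)
  if (anyNA(idx)) stop("attribution code not found in registry", call. = FALSE)
  count_by <- function(strategy) {
    tab <- table(factor(sub$first_year[sub$first_strategy == strategy],
                        levels = years))
    as.integer(tab)
  }
  new_field <- count_by("field")
  new_citizen <- count_by("citizen")
  new_simultaneous <- count_by("simultaneous")
  surf <- vapply(years, function(y)
    sum(registry$surface_ha[idx][sub$first_year <= y]), numeric(1))
  pop <- vapply(years, function(y)
    sum(registry$population[idx][sub$first_year <= y]), numeric(1))
  cum_n <- cumsum(new_field + new_citizen + new_simultaneous)
  data.frame(
    year = years,
    new_field = new_field,
    new_citizen = new_citizen,
    new_simultaneous = new_simultaneous,
    new_total = new_field + new_citizen + new_simultaneous,
    cumulative_municipalities = cum_n,
    cumulative_surface_ha = surf,
    cumulative_population = pop
  )
}

# Accept either a yearly_counts frame (summed over `period`) or a bare
# numeric c(field, citizen, simultaneous) triple.
strategy_totals <- function(counts, period = NULL) {
  if (is.data.frame(counts)) {
    if (!is.null(period)) {
      counts <- counts[counts$year >= period[1] & counts$year <= period[2], ]
    }
    c(field = sum(counts$new_field),
      citizen = sum(counts$new_citizen),
      simultaneous = sum(counts$new_simultaneous))
  } else {
    stopifnot(is.numeric(counts), length(counts) == 3)
    c(field = counts[[1]], citizen = counts[[2]], simultaneous = counts[[3]])
  }
}

#' Strategy shares of municipal first detections
#'
#' Computes the citizen-science share of first detections over a period:
#' the citizen-only share (citizen-first detections / total) and the
#' citizen-involved share ((citizen-first + simultaneous) / total).
#'
#' @param counts either a [yearly_counts()] frame or a numeric triple
#'   `c(field, citizen, simultaneous)` of first-detection counts.
#' @param period optional inclusive `c(first, last)` years when `counts` is a
#'   yearly frame.
#' @return list with full-precision proportions `citizen_only_share`,
#'   `citizen_involved_share`, `field_share`, `simultaneous_share`, the
#'   `total` count, and `citizen_only_pct`/`citizen_involved_pct` rounded
#'   half-up to one decimal for reporting.
#' @examples
#' # shares over the 2014-2024 overlap of the two strategies
#' strategy_shares(c(field = 930, citizen = 335, simultaneous = 98))
#' @export
strategy_shares <- function(counts, period = NULL) {
  tot <- strategy_totals(counts, period)
  total <- sum(tot)
  if (total == 0) stop("undefined share: no detections in period", call. = FALSE)
  res <- list(
    citizen_only_share = tot[["citizen"]] / total,
    citizen_involved_share = (tot[["citizen"]] + tot[["simultaneous"]]) / total,
    field_share = tot[["field"]] / total,
    simultaneous_share = tot[["simultaneous"]] / total,
    total = total
  )
  res$citizen_only_pct <- round_half_up(100 * res$citizen_only_share, 1)
  res$citizen_involved_pct <- round_half_up(100 * res$citizen_involved_share, 1)
  res
}

#' Mean annual number of municipal first detections
#'
#' Average number of municipalities first detected per calendar year over an
#' inclusive period, summing the selected strategies. When quoting a
#' per-strategy rate, simultaneous detections are conventionally counted in
#' both strategies' numerators (each strategy did make the finding that
#' year), so the two rates deliberately double-count category-3 cases.
#'
#' @inheritParams strategy_shares
#' @param period inclusive `c(first, last)` calendar years; the denominator
#'   is `last - first + 1`.
#' @param strategies subset of `c("field", "citizen", "simultaneous")` summed
#'   in the numerator.
#' @return municipalities per year (numeric scalar).
#' @examples
#' counts <- data.frame(year = 2014, new_field = 930, new_citizen = 335,
#'                      new_simultaneous = 98)
#' mean_annual_rate(counts, c(2014, 2024), c("field", "simultaneous"))
#' @export
mean_annual_rate <- function(counts, period,
                             strategies = c("field", "citizen", "simultaneous")) {
  stopifnot(length(period) == 2)
  n_years <- period[2] - period[1] + 1
  if (n_years < 1) stop("empty period", call. = FALSE)
  strategies <- match.arg(strategies, c("field", "citizen", "simultaneous"),
                          several.ok = TRUE)
  tot <- strategy_totals(counts, period)
  sum(tot[strategies]) / n_years
}

#' Coefficient of determination of the annual detection trend
#'
#' Ordinary least-squares fit of the annual series against calendar year;
#' returns the R-squared. By default the response is the annual number of
#' newly detected municipalities; `on = "cumulative"` fits the cumulative
#' municipality count instead.
#'
#' @param counts [yearly_counts()] frame.
#' @param period optional inclusive year bounds.
#' @param on `"new"` (default) or `"cumulative"`.
#' @return R-squared in \[0, 1\]; a zero-variance response returns 0 by
#'   convention.
#' @export
linear_trend_r2 <- function(counts, period = NULL, on = c("new", "cumulative")) {
  on <- match.arg(on)
  if (!is.null(period)) {
    counts <- counts[counts$year >= period[1] & counts$year <= period[2], ]
  }
  if (nrow(counts) < 3) stop("need at least 3 years for a trend fit", call. = FALSE)
  y <- if (on == "new") counts$new_total else counts$cumulative_municipalities
  if (stats::var(y) == 0) return(0)
  fit <- stats::lm(y ~ year, data = data.frame(year = counts$year, y = y))
  1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
}

#' Mutual confirmation between surveillance strategies
#'
#' Among municipalities first detected by one strategy, counts how many were
#' later confirmed by the other (category 4) and the mean confirmation delay
#' in years. `n_first` counts all municipalities first found by the chosen
#' strategy with a first-detection year inside `period` (by default the
#' 2014-2024 window in which both strategies operate).
#'
#' @param records validated detection records for one species.
#' @param direction `"citizen_first"` or `"field_first"`.
#' @param period inclusive first-year window (default `c(2014, 2024)`).
#' @return list `n_first`, `n_confirmed`, `confirmed_share`,
#'   `mean_delay_years` (`NA` when nothing was confirmed).
#' @examples
#' rec <- data.frame(municipality_code = c("A", "B"), species = "albopictus",
#'                   field_year = c(2017, 2018), field_source = "own data",
#'                   citizen_year = c(2015, 2016))
#' confirmation_stats(validate_detections(rec), "citizen_first")
#' @export
confirmation_stats <- function(records, direction = c("citizen_first", "field_first"),
                               period = c(2014, 2024)) {
  direction <- match.arg(direction)
  cls <- classify_detection(records$field_year, records$citizen_year,
                            records$documented_sequence)
  first_strat <- if (direction == "citizen_first") "citizen" else "field"
  in_period <- !is.na(cls$first_year) &
    cls$first_year >= period[1] & cls$first_year <= period[2]
  firsts <- in_period & cls$first_strategy == first_strat
  confirmed <- firsts & cls$category == 4L
  delay <- if (direction == "citizen_first") {
    records$field_year - records$citizen_year
  } else {
    records$citizen_year - records$field_year
  }
  n_conf <- sum(confirmed)
  list(
    n_first = sum(firsts),
    n_confirmed = n_conf,
    confirmed_share = if (sum(firsts) > 0) n_conf / sum(firsts) else NA_real_,
    mean_delay_years = if (n_conf > 0) mean(delay[confirmed]) else NA_real_
  )
}

#' Pearson correlation of annual field vs citizen first detections
#'
#' Correlates the yearly number of field-first and citizen-first municipal
#' detections (simultaneous detections excluded from both series).
#'
#' @param counts [yearly_counts()] frame.
#' @param period optional inclusive year bounds.
#' @return Pearson r, or `NA` when either series has zero variance.
#' @export
yearly_correlation <- function(counts, period = NULL) {
  if (!is.null(period)) {
    counts <- counts[counts$year >= period[1] & counts$year <= period[2], ]
  }
  if (nrow(counts) < 3) stop("need at least 3 years for a correlation", call. = FALSE)
  if (stats::var(counts$new_field) == 0 || stats::var(counts$new_citizen) == 0) {
    return(NA_real_)
  }
  stats::cor(counts$new_field, counts$new_citizen)
}
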
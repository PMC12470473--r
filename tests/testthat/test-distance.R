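test_that("sphere distance matches closed forms and rejects bad input", {
  expect_equal(sphere_distance(40, 1, 40, 1), 0)
  expect_equal(sphere_distance(0, 0, 1, 0), pi * 6378.137 / 180,
               tolerance = 1e-10)
  expect_equal(sphere_distance(0, 0, 0, 180), pi * 6378.137,
               tolerance = 1e-10)
  expect_error(sphere_distance(95, 0, 0, 0), "latitude")
  expect_error(sphere_distance(0, 200, 0, 0), "longitude")
})

test_that("sphere distance agrees with the haversine oracle on random pairs", {
  set.seed(101)
  n <- 1000
  lat1 <- runif(n, -89, 89); lon1 <- runif(n, -180, 180)
  lat2 <- runif(n, -89, 89); lon2 <- runif(n, -180, 180)
  a <- sphere_distance(lat1, lon1, lat2, lon2)
  b <- haversine_km(lat1, lon1, lat2, lon2)
  expect_lt(max(abs(a - b) / pmax(b, 1e-12)), 1e-9)
})

test_that("sphere distance is symmetric and satisfies the triangle inequality", {
  set.seed(7)
  for (i in 1:50) {
    p <- matrix(c(runif(3, -89, 89), runif(3, -180, 180)), ncol = 2)
    dab <- sphere_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    dba <- sphere_distance(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    dac <- sphere_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    dcb <- sphere_distance(p[3, 1], p[3, 2], p[2, 1], p[2, 2])
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("polygon centroids follow the planar composite formula", {
  sq <- function(x0, y0, s) cbind(c(x0, x0 + s, x0 + s, x0),
                                  c(y0, y0, y0 + s, y0 + s))
  ctr <- polygon_centroid(sq(0, 0, 1))
  expect_equal(unname(ctr["lon"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(ctr["lat"]), 0.5, tolerance = 1e-4)
  # triangle: mean of vertices in the small-extent planar limit
  tri <- cbind(c(0, 0.1, 0), c(0, 0, 0.1))
  ctr <- polygon_centroid(tri)
  expect_equal(unname(ctr["lon"]), 0.1 / 3, tolerance = 1e-6)
  expect_equal(unname(ctr["lat"]), 0.1 / 3, tolerance = 1e-6)
  # two disjoint squares, one with 3x the area: centroid pulled 3:1
  s <- 0.1 * sqrt(3)
  ctr <- polygon_centroid(list(sq(0, 0, 0.1), sq(0.2, 0, s)))
  expect_equal(unname(ctr["lon"]), (0.05 + 3 * (0.2 + s / 2)) / 4,
               tolerance = 1e-5)
  expect_equal(unname(ctr["lat"]), (0.05 + 3 * (s / 2)) / 4,
               tolerance = 1e-5)
  expect_error(polygon_centroid(cbind(c(0, 1), c(0, 1))), "degenerate")
})

test_that("GeoJSON polygons yield per-feature centroids", {
  path <- withr::local_tempfile(fileext = ".geojson")
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(code = "A1"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(
                             list(0, 0), list(0.2, 0), list(0.2, 0.2),
                             list(0, 0.2), list(0, 0))))),
      list(type = "Feature",
           properties = list(code = "B2"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(
                             list(1, 1), list(1.1, 1), list(1, 1.1),
                             list(1, 1)))))
    ))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  ctr <- centroids_from_geojson(path)
  expect_equal(ctr$code, c("A1", "B2"))
  expect_equal(ctr$centroid_lon[1], 0.1, tolerance = 1e-5)
  expect_equal(ctr$centroid_lat[1], 0.1, tolerance = 1e-5)
  expect_equal(ctr$centroid_lon[2], 1 + 0.1 / 3, tolerance = 1e-5)
})

test_that("sphere distance matches geosphere's spherical Vincenty", {
  set.seed(55)
  n <- 200
  lat1 <- runif(n, -85, 85); lon1 <- runif(n, -180, 180)
  lat2 <- runif(n, -85, 85); lon2 <- runif(n, -180, 180)
  ref <- geosphere::distVincentySphere(cbind(lon1, lat1), cbind(lon2, lat2),
                                       r = 6378137) / 1000
  expect_equal(sphere_distance(lat1, lon1, lat2, lon2), ref,
               tolerance = 1e-9)
})

test_that("nearest previous positive uses cumulative prior years only", {
  reg <- as_registry(data.frame(
    code = c("A", "B", "C"), name = "x", province = "P",
    autonomous_community = "AC", surface_ha = 100, population = 1000,
    centroid_lat = c(40, 41, 42), centroid_lon = 0))
  pos <- data.frame(code = c("A", "B", "C"), first_year = c(2005, 2010, 2010))
  rec <- nearest_previous_positive("B", 2010, pos, reg)
  expect_equal(rec$reference_code, "A")  # C is same-year: not a candidate
  expect_equal(rec$distance_km, pi * 6378.137 / 180, tolerance = 1e-9)
  # no prior positive and no reference point: excluded
  rec <- nearest_previous_positive("A", 2005, pos, reg)
  expect_true(rec$excluded)
  expect_equal(rec$exclusion_reason, "no prior positives")
  # an external reference point fills the gap once active
  refs <- reference_points("AcrossTheBorder", 41.20683, -8.28486, 2017)
  rec <- nearest_previous_positive("A", 2005, pos, reg, refs = refs)
  expect_true(rec$excluded)
  rec <- nearest_previous_positive("A", 2023,
                                   data.frame(code = "A", first_year = 2023),
                                   reg, refs = refs)
  expect_equal(rec$reference_code, "AcrossTheBorder")
  expect_equal(rec$distance_km,
               sphere_distance(40, 0, 41.20683, -8.28486))
})

test_that("nearest previous positive matches exhaustive minimisation", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    reg <- make_registry(n, provinces = c("P1", "P2", "P3"), seed = i + 500)
    first_year <- sample(c(2004:2010, NA), n, replace = TRUE)
    if (all(is.na(first_year))) first_year[1] <- 2004
    pos <- data.frame(code = reg$code, first_year = first_year)
    target <- sample(which(!is.na(first_year)), 1)
    y <- first_year[target]
    rec <- nearest_previous_positive(reg$code[target], y, pos, reg)
    prior <- which(!is.na(first_year) & first_year <= y - 1 &
                     seq_len(n) != target)
    if (length(prior) == 0) {
      expect_true(rec$excluded)
    } else {
      d <- vapply(prior, function(j)
        sphere_distance(reg$centroid_lat[target], reg$centroid_lon[target],
                        reg$centroid_lat[j], reg$centroid_lon[j]), numeric(1))
      expect_equal(rec$distance_km, min(d), tolerance = 1e-12)
    }
  }
})

test_that("exclusion rules flag records without deleting them", {
  reg <- make_registry(6, seed = 12)
  rec <- rbind(
    make_records("T001", field_year = 2004),
    make_records("T002", field_year = 2006),
    make_records("T003", citizen_year = 2015),
    make_records("T004", field_year = 2016, citizen_year = 2016),
    make_records("T005", field_year = 2008)
  )
  att <- attribution_table(rec, reg, species = "albopictus")
  d <- detection_distances(att, reg)
  rules <- exclusion_rules(simultaneous = TRUE, seed_years = 2004,
                           named_codes = list("independent introduction" = "T005"))
  d2 <- apply_exclusions(d, rules)
  expect_equal(nrow(d2), nrow(d))  # nothing deleted
  expect_equal(d2$exclusion_reason[d2$municipality_code == "T004"],
               "simultaneous")
  expect_equal(d2$exclusion_reason[d2$municipality_code == "T001"],
               "no prior positives")  # already excluded, reason kept
  expect_equal(d2$exclusion_reason[d2$municipality_code == "T005"],
               "independent introduction")
  expect_true(all(d2$exclusion_reason[d2$excluded] != ""))
  # toggling rules changes only flagged rows
  d3 <- apply_exclusions(d, exclusion_rules(simultaneous = FALSE))
  changed <- d3$excluded != d2$excluded
  expect_true(all(d3$municipality_code[changed] %in% c("T004", "T005")))
})

test_that("unknown exclusion rule names are a configuration error", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("orihuela_rule: [X1]", path)
  expect_error(read_exclusion_rules(path), "unknown exclusion rule")
  writeLines(c("simultaneous: true", "seed_years: [2004]",
               "named_codes:", "  suspected independent introduction: [X1, X2]"),
             path)
  rules <- read_exclusion_rules(path)
  expect_equal(rules$seed_years, 2004L)
  expect_equal(rules$named_codes[["suspected independent introduction"]],
               c("X1", "X2"))
})

test_that("strategy comparison reproduces the textbook two-sample t-test", {
  rec <- data.frame(
    municipality_code = sprintf("M%d", 1:6), year = rep(c(2014, 2015), 3),
    strategy = rep(c("field", "citizen"), each = 3),
    distance_km = c(1, 2, 3, 4, 5, 6),
    reference_code = "r", excluded = FALSE, exclusion_reason = NA)
  cmp <- compare_strategies(rec)
  # hand-computed Welch statistic: (1-4 ... means 2 vs 5, s^2 = 1 each, n = 3)
  se <- sqrt(1 / 3 + 1 / 3)
  expect_equal(cmp$t_statistic, (2 - 5) / se, tolerance = 1e-12)
  expect_equal(cmp$t_p_value, 2 * pt(-3 / se, df = 4), tolerance = 1e-12)
  expect_equal(cmp$mean_field_km, 2)
  expect_equal(cmp$mean_citizen_km, 5)
  # identical groups: t = 0, p = 1
  rec2 <- rec; rec2$distance_km <- rep(c(1, 2, 3), 2)
  cmp2 <- compare_strategies(rec2)
  expect_equal(cmp2$t_statistic, 0)
  expect_equal(cmp2$t_p_value, 1)
})

test_that("ANOVA sequential sums of squares decompose the total", {
  set.seed(31)
  n <- 60
  rec <- data.frame(
    municipality_code = sprintf("M%d", 1:n),
    year = sample(2014:2016, n, replace = TRUE),
    strategy = sample(c("field", "citizen"), n, replace = TRUE),
    distance_km = rexp(n, 1 / 15),
    reference_code = "r", excluded = FALSE, exclusion_reason = NA)
  cmp <- compare_strategies(rec)
  tab <- cmp$anova_table
  total_ss <- sum((rec$distance_km - mean(rec$distance_km))^2)
  expect_equal(sum(tab[["Sum Sq"]]), total_ss, tolerance = 1e-8)
  expect_setequal(rownames(tab),
                  c("year_f", "strategy", "year_f:strategy", "Residuals"))
  expect_true(!is.null(cmp$tukey_pairs))
})

test_that("excluded records never enter the strategy comparison", {
  rec <- data.frame(
    municipality_code = sprintf("M%d", 1:8),
    year = rep(c(2014, 2015), 4),
    strategy = rep(c("field", "citizen"), each = 4),
    distance_km = c(1, 2, 3, 1000, 4, 5, 6, 2000),
    reference_code = "r",
    excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    exclusion_reason = c(NA, NA, NA, "simultaneous", NA, NA, NA, "eradicated"))
  cmp <- compare_strategies(rec)
  expect_equal(cmp$mean_field_km, 2)
  expect_equal(cmp$mean_citizen_km, 5)
  expect_equal(cmp$n_field, 3)
  rec$strategy[rec$strategy == "citizen"] <- "field"
  expect_error(compare_strategies(rec), "per strategy")
})
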
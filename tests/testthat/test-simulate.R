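test_that("world generation is deterministic and respects its configuration", {
  cfg <- world_config(n_municipalities = 30, n_provinces = 3, seed = 42)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  expect_equal(nrow(w1), 30)
  expect_equal(length(unique(w1$province)), 3)
  b <- cfg$bbox
  expect_true(all(w1$centroid_lat >= b["lat_min"] & w1$centroid_lat <= b["lat_max"]))
  # one municipality per province when n_provinces = n
  w3 <- generate_world(world_config(n_municipalities = 8, n_provinces = 8, seed = 1))
  expect_equal(length(unique(w3$province)), 8)
  # degenerate population law: all populations equal exp(mu)
  w4 <- generate_world(world_config(n_municipalities = 10, n_provinces = 2,
                                    pop_meanlog = log(5000), pop_sdlog = 0,
                                    seed = 2))
  expect_true(all(w4$population == 5000))
})

test_that("provinces are spatially contiguous (nearest-seed partition)", {
  w <- generate_world(world_config(n_municipalities = 120, n_provinces = 4,
                                   seed = 17))
  # each province is a spatial cluster: its mean within-province pairwise
  # distance is below the global mean pairwise distance
  D <- outer(seq_len(nrow(w)), seq_len(nrow(w)), function(i, j)
    sphere_distance(w$centroid_lat[i], w$centroid_lon[i],
                    w$centroid_lat[j], w$centroid_lon[j]))
  overall <- mean(D[upper.tri(D)])
  for (p in unique(w$province)) {
    idx <- which(w$province == p)
    within <- D[idx, idx][upper.tri(D[idx, idx])]
    expect_lt(mean(within), overall)
  }
})

test_that("a vanishing kernel with no jumps never spreads beyond the seeds", {
  reg <- generate_world(world_config(n_municipalities = 40, n_provinces = 2,
                                     seed = 3))
  truth <- simulate_invasion(reg, invasion_config(
    local_scale_km = 1e-6, jump_rate = 0, years = 2004:2012, seed = 4))
  expect_equal(sum(!is.na(truth$colonized_year)), 1)
})

test_that("population-weighted jumps colonise large municipalities first", {
  reg <- generate_world(world_config(n_municipalities = 100, n_provinces = 4,
                                     seed = 5))
  truth <- simulate_invasion(reg, invasion_config(
    local_scale_km = 1e-6, jump_rate = 5, density_bias = 1,
    years = 2004:2015, seed = 6))
  col <- !is.na(truth$colonized_year)
  expect_gt(sum(col), 20)
  # earlier colonisation year should associate with larger population
  rho <- cor(truth$colonized_year[col],
             reg$population[match(truth$code, reg$code)][col],
             method = "spearman")
  expect_lt(rho, 0)
})

test_that("invasion is deterministic and the surveillance stream is independent", {
  reg <- generate_world(world_config(n_municipalities = 60, n_provinces = 3,
                                     seed = 8))
  icfg <- invasion_config(years = 2004:2012, seed = 9)
  t1 <- simulate_invasion(reg, icfg)
  t2 <- simulate_invasion(reg, icfg)
  expect_identical(t1, t2)
  s1 <- simulate_surveillance(reg, t1, surveillance_config(seed = 10,
                                                           citizen_start_year = 2008))
  s2 <- simulate_surveillance(reg, t1, surveillance_config(seed = 10,
                                                           citizen_start_year = 2008))
  s3 <- simulate_surveillance(reg, t1, surveillance_config(seed = 11,
                                                           citizen_start_year = 2008))
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))  # different observation draw, same truth
})

test_that("no detection year precedes the true colonisation year", {
  for (s in 1:5) {
    reg <- generate_world(world_config(n_municipalities = 80, n_provinces = 3,
                                       seed = s))
    truth <- simulate_invasion(reg, invasion_config(years = 2004:2012,
                                                    seed = s + 50))
    rec <- simulate_surveillance(reg, truth,
                                 surveillance_config(seed = s + 100,
                                                     citizen_start_year = 2006))
    ty <- truth$colonized_year[match(rec$municipality_code, truth$code)]
    expect_true(all(is.na(rec$field_year) | rec$field_year >= ty))
    expect_true(all(is.na(rec$citizen_year) | rec$citizen_year >= ty))
  }
})

test_that("perfect unbounded field surveillance detects every colonised municipality", {
  reg <- generate_world(world_config(n_municipalities = 50, n_provinces = 2,
                                     seed = 13))
  truth <- simulate_invasion(reg, invasion_config(years = 2004:2010, seed = 14))
  rec <- simulate_surveillance(reg, truth, surveillance_config(
    field_radius_km = 1e6, field_detect_prob = 1,
    citizen_rate = 0, citizen_detect_floor = 0, seed = 15))
  col <- truth[!is.na(truth$colonized_year), ]
  expect_setequal(rec$municipality_code, col$code)
  cls <- classify_detection(rec$field_year, rec$citizen_year)
  expect_true(all(cls$category == 1L))
  ty <- col$colonized_year[match(rec$municipality_code, col$code)]
  expect_true(all(rec$field_year <= ty + 1))  # detected the year after at latest
})

test_that("a citizen-only configuration yields only category-2 detections", {
  reg <- generate_world(world_config(n_municipalities = 50, n_provinces = 2,
                                     seed = 16))
  truth <- simulate_invasion(reg, invasion_config(years = 2004:2010, seed = 17))
  rec <- simulate_surveillance(reg, truth, surveillance_config(
    field_detect_prob = 0, citizen_rate = 1e-3, citizen_detect_floor = 0.3,
    citizen_start_year = 2004, seed = 18))
  expect_gt(nrow(rec), 0)
  cls <- classify_detection(rec$field_year, rec$citizen_year)
  expect_true(all(cls$category == 2L))
})
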
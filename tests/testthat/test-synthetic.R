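test_that("aligned equal-size ZIP grid nests tracts one-to-one", {
  cfg <- sim_config(urban_nx = 4, urban_ny = 4, urban_cell = 1,
                    rural_nx = 0, zip_cell = 1, zip_offset = 0,
                    n_counties = 2, n_cov = 2, beta_true = c(0, 0),
                    cov_rural_loading = c(0, 0))
  geo <- generate_geography(cfg)
  xw <- build_crosswalk(geo, "areal")
  entries_per_zip <- table(xw$zip_id)
  expect_true(all(entries_per_zip == 1))
  expect_true(all(xw$proportion == 1))
})

test_that("half-cell offset makes interior ZIPs straddle 4 tracts equally", {
  cfg <- sim_config(urban_nx = 5, urban_ny = 5, urban_cell = 1,
                    rural_nx = 0, zip_cell = 1, zip_offset = 0.5,
                    n_counties = 2, n_cov = 2, beta_true = c(0, 0),
                    cov_rural_loading = c(0, 0))
  geo <- generate_geography(cfg)
  xw <- build_crosswalk(geo, "areal")
  counts <- table(xw$zip_id)
  interior <- names(counts)[counts == 4]
  expect_gt(length(interior), 0)
  four <- xw[xw$zip_id %in% interior, ]
  expect_true(all(abs(four$proportion - 0.25) < 1e-12))
  # interior 1x1 ZIP offset by half a cell covers 4 quarter-tracts
  expect_equal(length(interior), 4 * 4)
})

test_that("ZIPs tile the region: overlaps sum to the total area", {
  for (s in 1:2) {
    geo <- generate_geography(small_config(seed = s))
    expect_equal(sum(geo$overlap$overlap_km2), sum(geo$tracts$area_km2),
                 tolerance = 1e-9)
    # and per tract, the ZIP pieces reassemble the tract exactly
    per_tract <- tapply(geo$overlap$overlap_km2, geo$overlap$tract_id, sum)
    expect_equal(as.vector(per_tract[geo$tracts$tract_id]),
                 geo$tracts$area_km2, tolerance = 1e-9)
  }
})

test_that("truth generation honors degenerate and correlated settings", {
  cfg <- small_config(sigma_u = 0, sigma_v = 0, sigma_w = 0, sigma_g = 0,
                      beta_true = c(0, 0, 0, 0), alpha = 0.3)
  geo <- generate_geography(cfg)
  truth <- generate_panel_truth(geo, cfg, seed = 10)
  expect_true(all(abs(truth$theta - exp(0.3)) < 1e-12))

  # ICAR field is centered
  cfg2 <- small_config()
  geo2 <- generate_geography(cfg2)
  truth2 <- generate_panel_truth(geo2, cfg2, seed = 11)
  expect_lt(abs(mean(truth2$u)), 1e-10)
  expect_lt(abs(mean(truth2$g)), 1e-10)

  # empirical pairwise covariate correlation approaches the target
  cfg3 <- sim_config(urban_nx = 32, urban_ny = 32, urban_cell = 1,
                     rural_nx = 0, n_counties = 4, n_cov = 6,
                     beta_true = rep(0, 6), cov_rural_loading = rep(0, 6),
                     cov_rho = 0.3)
  geo3 <- generate_geography(cfg3)
  truth3 <- generate_panel_truth(geo3, cfg3, seed = 12)
  X <- as.matrix(truth3$covariates[, -1])
  cors <- cor(X)[upper.tri(diag(6))]
  expect_lt(abs(mean(cors) - 0.3), 0.05)
})

test_that("record generation inverts aggregation and matches its intensity", {
  cfg <- small_config(seed = 4)
  geo <- generate_geography(cfg)
  truth <- generate_panel_truth(geo, cfg, seed = 21)
  rec <- generate_records(geo, truth, cfg, seed = 22)
  panel <- aggregate_counts(rec, geo, truth$years)
  expect_equal(panel$Y, attr(rec, "Y"))

  lambda <- sum(truth$E * truth$theta)
  expect_lt(abs(nrow(rec) - lambda), 3 * sqrt(lambda) + 1)

  # zero rate -> zero records
  cfg0 <- small_config(base_rate = 1e-12)
  truth0 <- generate_panel_truth(geo, cfg0, seed = 23)
  rec0 <- generate_records(geo, truth0, cfg0, seed = 24)
  expect_equal(nrow(rec0), 0)
})

test_that("missingness is area-driven and vanishes in the no-missing limit", {
  cfg <- small_config(seed = 9)
  geo <- generate_geography(cfg)
  truth <- generate_panel_truth(geo, cfg, seed = 31)
  rec <- generate_records(geo, truth, cfg, seed = 32)

  # constant mechanism: overall fraction near the target probability
  cfg_flat <- small_config(miss_a = qlogis(0.2), miss_b = 0, zip_drop = 0)
  m1 <- apply_missingness(rec, geo, cfg_flat, seed = 33)
  phat <- mean(is.na(m1$tract_id))
  expect_lt(abs(phat - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(rec)))

  # rural (large-area) tracts lose identifiers more often
  m2 <- apply_missingness(rec, geo, cfg, seed = 34)
  urb <- geo$tracts$urban[match(m2$.true_tract, geo$tract_ids)]
  expect_gt(mean(is.na(m2$tract_id[!urb])), mean(is.na(m2$tract_id[urb])))

  # a -> -Inf: pipeline reduces to complete data
  cfg_none <- small_config(miss_a = -1e9, miss_b = 0, zip_drop = 0)
  m3 <- apply_missingness(rec, geo, cfg_none, seed = 35)
  expect_false(anyNA(m3$tract_id))

  # audit column is present but ignored by analysis readers
  panel <- aggregate_counts(m3, geo, truth$years)
  expect_equal(sum(panel$Y), nrow(m3))
})

test_that("the generator is deterministic under the master seed", {
  s1 <- simulate_study(small_config(seed = 13))
  s2 <- simulate_study(small_config(seed = 13))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$beta, s2$truth$beta)
  s3 <- simulate_study(small_config(seed = 14))
  expect_false(identical(s1$records, s3$records))
})

test_that("simulation export writes all interface files", {
  sim <- simulate_study(small_config(seed = 15))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  files <- c("tracts.csv", "adjacency.csv", "overlap.csv", "records.csv",
             "covariates.csv", "county_covariates.csv", "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  geo2 <- read_geography(file.path(dir, "tracts.csv"),
                         file.path(dir, "adjacency.csv"),
                         file.path(dir, "overlap.csv"))
  expect_equal(geo2$tract_ids, sim$geo$tract_ids)
  expect_equal(nrow(geo2$tract_adjacency), nrow(sim$geo$tract_adjacency))
  rec2 <- read_records(file.path(dir, "records.csv"))
  expect_equal(nrow(rec2), nrow(sim$records))
  expect_equal(sum(is.na(rec2$tract_id)), sum(is.na(sim$records$tract_id)))
})
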
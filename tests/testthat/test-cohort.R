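test_that("aggregation zero-fills the tract-year grid and conserves totals", {
  geo <- grid2x2_geography()
  rec <- data.frame(
    record_id = sprintf("R%d", 1:4),
    year = c(2005L, 2005L, 2005L, 2005L),
    zip_id = "Z1",
    tract_id = c("T1", "T1", "T1", "T2"))
  panel <- aggregate_counts(rec, geo, 2004:2006)
  expect_equal(dim(panel$Y), c(4, 3))
  expect_equal(panel$Y["T1", "2005"], 3)
  expect_equal(panel$Y["T2", "2005"], 1)
  expect_equal(sum(panel$Y), 4)
  expect_equal(sum(panel$Y[, c("2004", "2006")]), 0)

  empty <- aggregate_counts(rec[0, ], geo, 2004:2006)
  expect_true(all(empty$Y == 0))

  expect_error(aggregate_counts(transform(rec, year = 1990L), geo,
                                2004:2006), "outside")
  expect_error(aggregate_counts(transform(rec, tract_id = NA), geo,
                                2004:2006), "lack a tract")
})

test_that("record-level round trip conserves the total count", {
  sim <- simulate_study(small_config(seed = 2))
  panel <- aggregate_counts(sim$records_complete, sim$geo, sim$truth$years)
  expect_equal(sum(panel$Y), nrow(sim$records_complete))
  expect_equal(panel$Y, attr(sim$records_complete, "Y"))
})

test_that("time-invariant expected counts scale population by the pooled rate", {
  # 10,000 visits over 10 years, total population 100,000
  # -> rate 0.01 per person-year; a tract of 500 people gets E = 5
  geo <- geography(
    tracts = data.frame(tract_id = c("T1", "T2"), county_id = "C1",
                        area_km2 = 1, population = c(500, 99500)),
    tract_adjacency = data.frame(id_a = "T1", id_b = "T2"),
    overlap = data.frame(tract_id = c("T1", "T2"), zip_id = "Z1",
                         overlap_km2 = c(1, 1)))
  panel <- aggregate_counts(
    data.frame(record_id = "R0", year = 2001L, zip_id = "Z1",
               tract_id = "T1")[0, ], geo, 2001:2010)
  panel$Y[] <- 0L
  panel$Y["T2", ] <- 1000L
  panel <- compute_expected(panel)
  expect_equal(unname(panel$E["T1"]), 5.0)
  # conservation: sum_i E_i * n_years = sum_ik Y_ik
  expect_equal(sum(panel$E) * ncol(panel$Y), sum(panel$Y))

  # single tract holding all population gets the mean annual count
  geo1 <- geography(
    tracts = data.frame(tract_id = "T1", county_id = "C1", area_km2 = 1,
                        population = 777),
    tract_adjacency = data.frame(id_a = character(), id_b = character()),
    overlap = data.frame(tract_id = "T1", zip_id = "Z1", overlap_km2 = 1))
  p1 <- aggregate_counts(
    data.frame(record_id = sprintf("R%d", 1:30),
               year = rep(2001:2003, each = 10), zip_id = "Z1",
               tract_id = "T1"), geo1, 2001:2003)
  p1 <- compute_expected(p1)
  expect_equal(unname(p1$E), 10)

  # annual mode conserves each year's total
  p2 <- compute_expected(panel, mode = "annual")
  expect_equal(colSums(p2$E), colSums(panel$Y) + 0)
})

test_that("zero-population tracts get E = 0 with a warning", {
  geo <- twotract_geography(pop = c(0, 1000))
  rec <- data.frame(record_id = "R1", year = 2001L, zip_id = "Z1",
                    tract_id = "T2")
  panel <- aggregate_counts(rec, geo, 2001L)
  expect_warning(panel <- compute_expected(panel), "zero-population")
  expect_equal(unname(panel$E["T1"]), 0)
})

test_that("propmiss averages per-year imputed fractions over the year grid", {
  geo <- twotract_geography()
  mk <- function(tract, year, imputed) {
    data.frame(record_id = sprintf("R%d", seq_along(tract)), year = year,
               zip_id = "Z1", tract_id = tract, imputed = imputed)
  }
  # T1: 2 imputed of 4 in each of two years -> 0.5
  rec <- mk(rep("T1", 8), rep(2001:2002, each = 4),
            rep(c(TRUE, TRUE, FALSE, FALSE), 2))
  pm <- compute_propmiss(rec, geo, 2001:2002)
  expect_equal(pm$propmiss[pm$tract_id == "T1"], 0.5)
  expect_equal(pm$propmiss[pm$tract_id == "T2"], 0)  # empty tract-years

  # {year1: 1/2, year2: 0/2} -> (0.5 + 0)/2 = 0.25
  rec2 <- mk(rep("T1", 4), c(2001, 2001, 2002, 2002),
             c(TRUE, FALSE, FALSE, FALSE))
  pm2 <- compute_propmiss(rec2, geo, 2001:2002)
  expect_equal(pm2$propmiss[pm2$tract_id == "T1"], 0.25)

  # complete-case data: identically zero
  cc <- complete_case_filter(mk(rep("T1", 3), 2001, FALSE))
  pm3 <- compute_propmiss(cc, geo, 2001:2002)
  expect_true(all(pm3$propmiss == 0))
  expect_true(all(pm3$propmiss >= 0 & pm3$propmiss <= 1))
})

test_that("design preparation centers columns and builds interactions", {
  geo <- geography(
    tracts = data.frame(tract_id = c("T1", "T2", "T3"), county_id = "C1",
                        area_km2 = 1, population = 10),
    tract_adjacency = data.frame(id_a = c("T1", "T2"),
                                 id_b = c("T2", "T3")),
    overlap = data.frame(tract_id = c("T1", "T2", "T3"), zip_id = "Z1",
                         overlap_km2 = 1))
  panel <- aggregate_counts(
    data.frame(record_id = "R1", year = 2001L, zip_id = "Z1",
               tract_id = "T1"), geo, 2001L)
  covs <- data.frame(tract_id = c("T1", "T2", "T3"),
                     a = c(1, 2, 3), b = c(2, 1, 0))
  p <- prepare_design(panel, covs, covariate_names = c("a", "b"),
                      interaction_pairs = list(c("a", "b")))
  expect_equal(unname(p$X1[, "a"]), c(-1, 0, 1))
  expect_equal(unname(p$X1[, "b"]), c(1, 0, -1))
  expect_equal(unname(p$X1[, "a:b"]), c(-1, 0, -1))
  expect_lt(max(abs(colMeans(p$X1[, c("a", "b")]))), 1e-10)

  # centering-then-interacting differs from interacting-then-centering
  raw_inter <- covs$a * covs$b
  centered_after <- raw_inter - mean(raw_inter)
  expect_false(isTRUE(all.equal(unname(p$X1[, "a:b"]), centered_after)))

  expect_error(
    prepare_design(panel, covs, covariate_names = "a",
                   interaction_pairs = list(c("a", "b"))),
    "not included as main effects")
  expect_error(
    prepare_design(panel, covs, covariate_names = "zzz"),
    "not found")
})

test_that("panel export writes the long-format grid", {
  sim <- simulate_study(small_config(seed = 3))
  panel <- build_panel(sim$records_complete, sim)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  df <- read.csv(path)
  expect_equal(nrow(df), nrow(panel$Y) * ncol(panel$Y))
  expect_equal(sum(df$count), sum(panel$Y))
  expect_true(all(c("expected", "cov01") %in% names(df)))
})
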
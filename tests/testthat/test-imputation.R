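make_records <- function(tract, zip = "Z1", year = 2001L) {
  data.frame(record_id = sprintf("R%d", seq_along(tract)),
             year = year, zip_id = zip, tract_id = tract,
             stringsAsFactors = FALSE)
}

test_that("assignment follows the half-open cumulative intervals", {
  geo <- twotract_geography()          # crosswalk (T1 .75, T2 .25)
  xw <- build_crosswalk(geo, "areal")

  rec <- make_records(c(NA, "T7", NA, NA))
  out <- assign_missing_tracts(rec, xw, seed = 1,
                               .uniforms = c(0.8, 0.74, 0.75))
  expect_equal(out$tract_id, c("T2", "T7", "T1", "T2"))
  expect_equal(out$imputed, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$record_id, rec$record_id)  # order preserved

  # single-tract ZIP: any draw lands in the only interval
  geo1 <- twotract_geography(overlap = c(3, 0))
  xw1 <- build_crosswalk(geo1, "areal")
  out1 <- assign_missing_tracts(make_records(c(NA, NA)), xw1, seed = 1,
                                .uniforms = c(0.001, 0.999))
  expect_equal(out1$tract_id, c("T1", "T1"))
})

test_that("records lacking both identifiers are dropped with a count", {
  geo <- twotract_geography()
  xw <- build_crosswalk(geo, "areal")
  rec <- make_records(c(NA, "T1", NA), zip = c("Z1", NA, NA))
  expect_warning(out <- assign_missing_tracts(rec, xw, seed = 3),
                 "dropped")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_dropped"), 1)
  # record with tract but no ZIP is retained unchanged
  expect_true("R2" %in% out$record_id)

  # ZIP absent from the crosswalk is a data-integrity error
  expect_error(
    assign_missing_tracts(make_records(NA, zip = "Z99"), xw, seed = 1),
    "Z99")
})

test_that("assignment is deterministic and conserves records", {
  sim <- simulate_study(small_config(seed = 5))
  xw <- build_crosswalk(sim$geo, "areal")
  a <- suppressWarnings(assign_missing_tracts(sim$records, xw, seed = 42))
  b <- suppressWarnings(assign_missing_tracts(sim$records, xw, seed = 42))
  expect_identical(a$tract_id, b$tract_id)
  expect_false(anyDuplicated(a$record_id) > 0)
  n_unusable <- sum(is.na(sim$records$tract_id) & is.na(sim$records$zip_id))
  expect_equal(nrow(a), nrow(sim$records) - n_unusable)
  expect_false(anyNA(a$tract_id))
  # already-present tracts untouched
  keep <- !is.na(sim$records$tract_id)
  expect_identical(
    a$tract_id[match(sim$records$record_id[keep], a$record_id)],
    sim$records$tract_id[keep])
})

test_that("replicates share non-missing records and vary the rest", {
  sim <- simulate_study(small_config(seed = 6))
  xw <- build_crosswalk(sim$geo, "areal")
  reps <- suppressWarnings(
    replicate_assignments(sim$records, xw, n_replicates = 5,
                          base_seed = 11))
  expect_length(reps, 5)
  expect_true(all(vapply(reps, nrow, 0L) == nrow(reps[[1]])))
  one <- suppressWarnings(assign_missing_tracts(sim$records, xw, seed = 11))
  expect_identical(reps[[1]]$tract_id, one$tract_id)

  imp <- reps[[1]]$imputed
  same <- vapply(reps[-1], function(r)
    all(r$tract_id[!imp] == reps[[1]]$tract_id[!imp]), TRUE)
  expect_true(all(same))
  differ <- vapply(reps[-1], function(r)
    any(r$tract_id[imp] != reps[[1]]$tract_id[imp]), TRUE)
  expect_true(any(differ))

  # a single-tract ZIP pins its assignments in every replicate
  single <- xw$zip_id[!(xw$zip_id %in% xw$zip_id[duplicated(xw$zip_id)])]
  if (length(single)) {
    z <- single[1]
    target <- xw$tract_id[xw$zip_id == z][1]
    in_z <- reps[[1]]$imputed & reps[[1]]$zip_id == z
    if (any(in_z)) {
      for (r in reps) expect_true(all(r$tract_id[in_z] == target))
    }
  }
})

test_that("complete-case filter keeps only originally complete records", {
  rec <- make_records(c(rep("T1", 80), rep(NA, 20)))
  out <- suppressMessages(complete_case_filter(rec))
  expect_equal(nrow(out), 80)
  expect_equal(attr(out, "n_removed"), 20)
  expect_true(all(!out$imputed))

  # identity when nothing is missing
  full <- make_records(rep("T1", 5))
  expect_equal(nrow(complete_case_filter(full)), 5)

  # imputed records count as originally missing
  geo <- twotract_geography()
  xw <- build_crosswalk(geo, "areal")
  ass <- assign_missing_tracts(make_records(c(NA, "T1")), xw, seed = 2)
  cc <- suppressMessages(complete_case_filter(ass))
  expect_equal(cc$record_id, "R2")

  expect_warning(complete_case_filter(make_records(c(NA, NA))),
                 "removed all")
})

test_that("missingness stratification computes column percentages", {
  rec <- make_records(c("T1", NA, "T1", NA, NA, "T1", "T1", "T1"))
  rec$race <- c("W", "B", "B", "B", "W", "W", "B", "W")
  out <- summarize_missingness(rec, "race")
  sizes <- attr(out, "group_sizes")
  expect_equal(unname(sizes["missing"]), 3)
  expect_equal(unname(sizes["complete"]), 5)
  gm <- out[out$group == "missing" & out$category == "B", ]
  expect_equal(gm$count, 2)
  expect_equal(gm$percent, 66.7)  # round(100*2/3, 1)

  expect_error(summarize_missingness(rec, "payor"), "unknown attribute")

  # empty missing group: no division error, complete column intact
  full <- make_records(rep("T1", 4))
  full$sex <- c("F", "M", "M", "M")
  out2 <- summarize_missingness(full, "sex")
  expect_true(all(out2$group == "complete"))
  expect_equal(out2$percent[out2$category == "M"], 75)
})

test_that("empirical assignment frequencies match crosswalk proportions", {
  geo <- twotract_geography()
  xw <- build_crosswalk(geo, "areal")
  n <- 20000
  rec <- make_records(rep(NA_character_, n))
  out <- assign_missing_tracts(rec, xw, seed = 99)
  freq <- table(out$tract_id) / n
  tv <- 0.5 * (abs(freq[["T1"]] - 0.75) + abs(freq[["T2"]] - 0.25))
  expect_lt(tv, 0.02)
})

test_that("areal weighting favors rural tracts more than population weighting", {
  geo <- generate_geography(small_config(seed = 8))
  rural <- geo$tracts$tract_id[!geo$tracts$urban]
  share <- function(xw) {
    # expected share of one missing record per ZIP landing in a rural tract
    per_zip <- tapply(xw$proportion * (xw$tract_id %in% rural),
                      xw$zip_id, sum)
    mean(per_zip)
  }
  s_areal <- share(build_crosswalk(geo, "areal"))
  s_pop <- share(build_crosswalk(geo, "population"))
  expect_gt(s_areal, s_pop)
})

test_that("records CSV round-trips with empty-field missing encoding", {
  rec <- make_records(c("T1", NA), zip = c("Z1", NA))
  rec$imputed <- c(FALSE, TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_identical(back$tract_id, rec$tract_id)
  expect_identical(back$zip_id, rec$zip_id)
  expect_identical(back$imputed, rec$imputed)
  expect_identical(back$year, rec$year)
})
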
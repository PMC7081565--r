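# Shared fixtures: all built in code, no files.

# 2x2 rook grid of unit tracts in one county, one ZIP covering everything
grid2x2_geography <- function() {
  geography(
    tracts = data.frame(
      tract_id = c("T1", "T2", "T3", "T4"),
      county_id = "C1",
      area_km2 = 1,
      population = c(100, 200, 300, 400)
    ),
    tract_adjacency = data.frame(
      id_a = c("T1", "T1", "T2", "T3"),
      id_b = c("T2", "T3", "T4", "T4")
    ),
    overlap = data.frame(
      tract_id = c("T1", "T2", "T3", "T4"),
      zip_id = "Z1",
      overlap_km2 = 1
    )
  )
}

# two-tract geography behind the worked crosswalk examples
twotract_geography <- function(pop = c(100, 900), area = c(3, 1),
                               overlap = c(3, 1)) {
  geography(
    tracts = data.frame(tract_id = c("T1", "T2"), county_id = "C1",
                        area_km2 = area, population = pop),
    tract_adjacency = data.frame(id_a = "T1", id_b = "T2"),
    overlap = data.frame(tract_id = c("T1", "T2"), zip_id = "Z1",
                         overlap_km2 = overlap)
  )
}

# small mixed urban/rural configuration for fast model fits
small_config <- function(...) {
  args <- list(urban_nx = 8, urban_ny = 6, urban_cell = 1,
               rural_nx = 4, rural_ny = 2, rural_cell = 3,
               zip_cell = 2, zip_offset = 0.5,
               n_counties = 4, n_years = 5,
               n_cov = 4, beta_true = c(0.4, -0.4, 0, 0),
               cov_rural_loading = rep(0, 4))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# build a ready-to-fit panel from complete (or assigned) records
build_panel <- function(records, sim, covariate_names = NULL,
                        interaction_pairs = list()) {
  if (is.null(covariate_names)) {
    covariate_names <- setdiff(names(sim$truth$covariates), "tract_id")
  }
  panel <- aggregate_counts(records, sim$geo, sim$truth$years)
  panel <- suppressWarnings(compute_expected(panel))
  prepare_design(panel, sim$truth$covariates, sim$truth$county_covariates,
                 covariate_names = covariate_names,
                 county_covariate_names = "ccov1",
                 interaction_pairs = interaction_pairs)
}

# independent oracle: 1-D grid quadrature for the intercept-only
# posterior p(alpha | Y) with Poisson(E * exp(alpha)) likelihood and
# Normal(0, 1/alpha_prec) prior
quad_alpha_posterior <- function(Y, E, alpha_prec = 1e-3,
                                 lo = -10, hi = 10, n_grid = 40001) {
  grid <- seq(lo, hi, length.out = n_grid)
  logpost <- vapply(grid, function(a) {
    sum(stats::dpois(Y, E * exp(a), log = TRUE)) +
      stats::dnorm(a, 0, 1 / sqrt(alpha_prec), log = TRUE)
  }, 0)
  wts <- exp(logpost - max(logpost))
  wts <- wts / sum(wts)
  m <- sum(grid * wts)
  list(mean = m, sd = sqrt(sum((grid - m)^2 * wts)), grid = grid,
       weights = wts)
}

# minimal intercept-only panel with given counts/expecteds, one tract
# per observation (single year)
cellwise_panel <- function(Y, E) {
  n <- length(Y)
  ids <- sprintf("T%d", seq_len(n))
  geo <- geography(
    tracts = data.frame(tract_id = ids, county_id = "C1", area_km2 = 1,
                        population = 1000),
    tract_adjacency = if (n > 1) {
      data.frame(id_a = ids[-n], id_b = ids[-1])
    } else data.frame(id_a = character(), id_b = character()),
    overlap = data.frame(tract_id = ids, zip_id = "Z1", overlap_km2 = 1)
  )
  m <- sum(Y)
  records <- data.frame(
    record_id = sprintf("R%d", seq_len(m)),
    year = rep(2001L, m),
    zip_id = rep("Z1", m),
    tract_id = rep(ids, Y),
    stringsAsFactors = FALSE
  )
  panel <- aggregate_counts(records, geo, 2001L)
  panel$E <- stats::setNames(E, ids)  # fixed oracle expecteds
  panel$expected_mode <- "fixed"
  panel
}
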
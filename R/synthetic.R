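#' Configuration for the synthetic misaligned-geography study generator
#'
#' The generator emulates the structure of record-level ED-visit data
#' joined to a misaligned areal system: a region tiled by rectangular
#' census tracts that are small and dense in an urban sub-region and
#' large and sparse in a rural one (tract area inversely related to
#' population density), ZIP-code rectangles offset by half a cell so that
#' most ZIPs straddle several tracts, counties as contiguous vertical
#' bands, spatio-temporally structured Poisson counts driven by
#' correlated tract covariates and multiscale random effects, and
#' rural-biased missingness of the tract identifier (about 20% of
#' records overall at the defaults, with a small fraction also losing
#' the ZIP).
#'
#' Default magnitudes: ~0.01 events per person-year baseline rate with
#' ~1000 persons per tract (so ~10 events per tract-year), 10 study
#' years, 10 exchangeably correlated covariates (pairwise correlation
#' 0.3) of which three carry effects of magnitude 0.4 on the log-risk
#' scale and seven are null.
#'
#' @param urban_nx,urban_ny,urban_cell urban tract grid and cell size
#'   (km).
#' @param rural_nx,rural_ny,rural_cell rural tract grid and cell size;
#'   `urban_ny * urban_cell` must equal `rural_ny * rural_cell` so the
#'   two blocks tile one rectangle.  Set `rural_nx = 0` for a uniform
#'   region.
#' @param zip_cell,zip_offset ZIP rectangle size and grid offset (km); a
#'   half-cell offset misaligns ZIPs with tracts.
#' @param n_counties number of contiguous county bands.
#' @param n_years number of study years (years `2001, 2002, ...`).
#' @param n_cov number of tract covariates; `cov_rho` their pairwise
#'   correlation; `beta_true` their true log-risk effects;
#'   `cov_rural_loading` per-covariate loading on standardized log tract
#'   area (builds covariates with an urban/rural gradient).
#' @param beta2_true true effect of the single county covariate.
#' @param sigma_u,sigma_v,sigma_w,sigma_g random-effect scales (tract
#'   ICAR, tract IID, county ICAR, temporal random walk).
#' @param alpha baseline log relative risk.
#' @param base_rate events per person-year; `pop_mean`, `pop_sd` tract
#'   population distribution.
#' @param miss_a,miss_b intercept and per-km2-area slope of the logit of
#'   P(tract identifier missing); `miss_b > 0` gives rural-dominated
#'   missingness.  Defaults give ~12% missing in 1 km2 urban tracts and
#'   ~47% in 9 km2 rural tracts (~20% overall).
#' @param zip_drop fraction of records additionally losing the ZIP.
#' @param seed master seed; stage sub-seeds are derived by fixed offsets.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(urban_nx = 13, urban_ny = 12, urban_cell = 1,
                       rural_nx = 11, rural_ny = 4, rural_cell = 3,
                       zip_cell = 3, zip_offset = 0.5,
                       n_counties = 8, n_years = 10,
                       n_cov = 10, cov_rho = 0.3,
                       beta_true = c(0.4, -0.4, 0.4, rep(0, 7)),
                       cov_rural_loading = rep(0, n_cov),
                       beta2_true = 0,
                       sigma_u = 0.3, sigma_v = 0.1, sigma_w = 0.15,
                       sigma_g = 0.1, alpha = 0,
                       base_rate = 0.01, pop_mean = 1000, pop_sd = 150,
                       miss_a = -2.23, miss_b = 0.234, zip_drop = 0.04,
                       seed = 1) {
  stopifnot(urban_nx >= 0, rural_nx >= 0, urban_nx + rural_nx > 0,
            urban_cell > 0, rural_cell > 0, zip_cell > 0,
            n_counties >= 1, n_years >= 1,
            length(beta_true) == n_cov,
            length(cov_rural_loading) == n_cov,
            all(abs(cov_rural_loading) <= 1),
            base_rate > 0, pop_mean > 0, zip_drop >= 0, zip_drop < 1)
  if (urban_nx > 0 && rural_nx > 0 &&
      abs(urban_ny * urban_cell - rural_ny * rural_cell) > 1e-9) {
    stop("urban and rural blocks must have equal height ",
         "(urban_ny * urban_cell == rural_ny * rural_cell)")
  }
  structure(as.list(environment()), class = "sim_config")
}

# rectangles as data.frame(x0, x1, y0, y1)
rect_grid <- function(nx, ny, cell, x_origin = 0) {
  if (nx == 0 || ny == 0) {
    return(data.frame(x0 = numeric(), x1 = numeric(),
                      y0 = numeric(), y1 = numeric()))
  }
  gx <- x_origin + (seq_len(nx) - 1) * cell
  gy <- (seq_len(ny) - 1) * cell
  data.frame(x0 = rep(gx, ny), x1 = rep(gx, ny) + cell,
             y0 = rep(gy, each = nx), y1 = rep(gy, each = nx) + cell)
}

#' Generate a misaligned synthetic geography
#'
#' Builds the tract/ZIP/county system of the configuration: rectangular
#' tracts (fine urban cells, coarse rural cells) tiling one region, ZIP
#' rectangles on an offset grid clipped to the region (so ZIPs tile the
#' region and overlap areas sum exactly to the region area), counties as
#' vertical bands of tracts, and rook adjacency.  Overlap areas come from
#' exact rectangle intersection; no polygon clipping is involved.
#' Populations are drawn around `pop_mean` irrespective of tract area, so
#' population density is inversely proportional to tract area.
#'
#' @param config a [sim_config()].
#' @return A [geography()] object; the tract table carries the rectangle
#'   coordinates and an `urban` flag.
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ur <- rect_grid(config$urban_nx, config$urban_ny, config$urban_cell)
  rr <- rect_grid(config$rural_nx, config$rural_ny, config$rural_cell,
                  x_origin = config$urban_nx * config$urban_cell)
  rects <- rbind(ur, rr)
  n <- nrow(rects)
  urban <- c(rep(TRUE, nrow(ur)), rep(FALSE, nrow(rr)))
  tract_id <- sprintf("T%03d", seq_len(n))
  area <- (rects$x1 - rects$x0) * (rects$y1 - rects$y0)

  W <- max(rects$x1); H <- max(rects$y1)
  # ZIP grid: offset cut lines clipped to the region bounds
  cuts <- function(lim) {
    inner <- seq(config$zip_offset, lim, by = config$zip_cell)
    inner <- inner[inner > 1e-9 & inner < lim - 1e-9]
    c(0, inner, lim)
  }
  zx <- cuts(W); zy <- cuts(H)
  nzx <- length(zx) - 1; nzy <- length(zy) - 1
  zips <- data.frame(x0 = rep(zx[-length(zx)], nzy),
                     x1 = rep(zx[-1], nzy),
                     y0 = rep(zy[-length(zy)], each = nzx),
                     y1 = rep(zy[-1], each = nzx))
  zip_id <- sprintf("Z%03d", seq_len(nrow(zips)))

  # exact rectangle-intersection overlap areas
  ov <- do.call(rbind, lapply(seq_len(nrow(zips)), function(z) {
    wx <- pmin(rects$x1, zips$x1[z]) - pmax(rects$x0, zips$x0[z])
    wy <- pmin(rects$y1, zips$y1[z]) - pmax(rects$y0, zips$y0[z])
    a <- pmax(0, wx) * pmax(0, wy)
    hit <- a > 1e-12
    if (!any(hit)) return(NULL)
    data.frame(tract_id = tract_id[hit], zip_id = zip_id[z],
               overlap_km2 = a[hit], stringsAsFactors = FALSE)
  }))
  if (length(setdiff(zip_id, unique(ov$zip_id)))) {
    stop("configuration yields ZIP(s) with no tract overlap")
  }

  # rook adjacency: shared boundary segment of positive length
  eps <- 1e-9
  edges <- NULL
  for (a_ in seq_len(n - 1)) {
    b_ <- (a_ + 1):n
    xov <- pmin(rects$x1[b_], rects$x1[a_]) - pmax(rects$x0[b_], rects$x0[a_])
    yov <- pmin(rects$y1[b_], rects$y1[a_]) - pmax(rects$y0[b_], rects$y0[a_])
    touch <- (abs(xov) < eps & yov > eps) | (abs(yov) < eps & xov > eps)
    if (any(touch)) {
      edges <- rbind(edges, data.frame(id_a = tract_id[a_],
                                       id_b = tract_id[b_][touch],
                                       stringsAsFactors = FALSE))
    }
  }

  # counties: vertical bands by tract centroid
  cx <- (rects$x0 + rects$x1) / 2
  band <- pmin(config$n_counties,
               pmax(1, ceiling(cx / (W / config$n_counties))))
  county_id <- sprintf("C%02d", band)

  pop <- with_seed(config$seed + 11L, {
    pmax(50L, as.integer(round(stats::rnorm(n, config$pop_mean,
                                            config$pop_sd))))
  })

  geography(
    tracts = data.frame(tract_id = tract_id, county_id = county_id,
                        area_km2 = area, population = pop,
                        urban = urban, x0 = rects$x0, x1 = rects$x1,
                        y0 = rects$y0, y1 = rects$y1,
                        stringsAsFactors = FALSE),
    tract_adjacency = edges,
    overlap = ov
  )
}

# draw a sum-to-zero intrinsic CAR field with realized sd `sigma`
ricar <- function(n, edges, sigma) {
  if (sigma == 0 || n < 2) return(numeric(n))
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges] <- 1
    A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  L <- diag(rowSums(A)) - A
  eig <- eigen(L, symmetric = TRUE)
  pos <- eig$values > 1e-8
  if (!any(pos)) return(numeric(n))
  x <- as.vector(eig$vectors[, pos, drop = FALSE] %*%
                   (stats::rnorm(sum(pos)) / sqrt(eig$values[pos])))
  x <- x - mean(x)
  if (stats::sd(x) > 0) x <- x * sigma / stats::sd(x)
  x
}

#' Generate true model parameters, covariates and latent risks
#'
#' Draws tract covariates with exchangeable pairwise correlation
#' `cov_rho` (optionally loaded on standardized log tract area to give
#' them an urban/rural gradient), one standard-normal county covariate,
#' multiscale random effects (`u` intrinsic CAR on tracts, `v` IID, `w`
#' intrinsic CAR on counties, `g` first-order random walk over years,
#' each centered), and assembles the latent relative risks
#' `theta[i, k] = exp(alpha + u + v + w + g + X beta + X_j beta2)` with
#' expected counts `E_i = base_rate * population_i`.
#'
#' @param geo a [generate_geography()] result.
#' @param config the [sim_config()].
#' @param seed stage seed.
#' @return list (`truth`): covariate tables, true coefficients, random
#'   effects, `theta`, `E`, and the study `years`.
#' @export
generate_panel_truth <- function(geo, config, seed) {
  stopifnot(inherits(geo, "geography"), inherits(config, "sim_config"))
  n <- length(geo$tract_ids)
  years <- 2000L + seq_len(config$n_years)
  with_seed(seed, {
    # exchangeably correlated covariates, optional rural loading
    z <- stats::rnorm(n)
    a_std <- as.vector(scale(log(geo$tracts$area_km2)))
    if (any(!is.finite(a_std))) a_std <- numeric(n)
    X <- sapply(seq_len(config$n_cov), function(m) {
      base <- sqrt(config$cov_rho) * z +
        sqrt(1 - config$cov_rho) * stats::rnorm(n)
      lam <- config$cov_rural_loading[m]
      lam * a_std + sqrt(1 - lam^2) * base
    })
    colnames(X) <- sprintf("cov%02d", seq_len(config$n_cov))

    n_j <- length(geo$county_ids)
    X2 <- matrix(stats::rnorm(n_j), n_j, 1,
                 dimnames = list(geo$county_ids, "ccov1"))

    te <- cbind(match(geo$tract_adjacency$id_a, geo$tract_ids),
                match(geo$tract_adjacency$id_b, geo$tract_ids))
    ce <- cbind(match(geo$county_adjacency$id_a, geo$county_ids),
                match(geo$county_adjacency$id_b, geo$county_ids))
    u <- ricar(n, te, config$sigma_u)
    v <- if (config$sigma_v > 0) stats::rnorm(n, 0, config$sigma_v)
         else numeric(n)
    w <- ricar(n_j, ce, config$sigma_w)
    g <- if (config$sigma_g > 0) {
      gg <- cumsum(stats::rnorm(config$n_years, 0, config$sigma_g))
      gg - mean(gg)
    } else numeric(config$n_years)

    eta_i <- config$alpha + u + v + w[match(geo$tracts$county_id,
                                            geo$county_ids)] +
      as.vector(X %*% config$beta_true) +
      as.vector(X2 %*% config$beta2_true)[match(geo$tracts$county_id,
                                                geo$county_ids)]
    theta <- exp(outer(eta_i, g, `+`))
    dimnames(theta) <- list(geo$tract_ids, as.character(years))

    list(
      covariates = data.frame(tract_id = geo$tract_ids, X,
                              stringsAsFactors = FALSE),
      county_covariates = data.frame(county_id = geo$county_ids,
                                     ccov1 = X2[, 1],
                                     stringsAsFactors = FALSE),
      beta = stats::setNames(config$beta_true, colnames(X)),
      beta2 = stats::setNames(config$beta2_true, "ccov1"),
      alpha = config$alpha, u = u, v = v, w = w, g = g,
      theta = theta,
      E = config$base_rate * geo$tracts$population,
      years = years
    )
  })
}

#' Generate record-level events from the latent risks
#'
#' Draws `Y[i, k] ~ Poisson(E_i * theta[i, k])` and emits one record per
#' event carrying the true tract, a ZIP sampled among the ZIPs covering
#' the tract (probability proportional to the tract's overlap with each),
#' the year, and categorical attributes (race, sex, age, payor, facility
#' urbanicity) drawn from urbanicity-dependent distributions so that
#' missingness stratification shows realistic urban/rural gradients.
#'
#' @param geo,truth,config generator objects.
#' @param seed stage seed.
#' @return record data.frame; the drawn count matrix is attached as
#'   attribute `Y`.
#' @export
generate_records <- function(geo, truth, config, seed) {
  with_seed(seed, {
    n <- length(geo$tract_ids)
    n_k <- length(truth$years)
    Y <- matrix(stats::rpois(n * n_k, truth$E * as.vector(truth$theta)),
                n, n_k, dimnames = dimnames(truth$theta))
    total <- sum(Y)
    tract <- rep(rep(geo$tract_ids, n_k), as.vector(Y))
    year <- rep(rep(truth$years, each = n), as.vector(Y))

    # ZIP of the billing address: proportional to tract-in-ZIP overlap
    ovl <- split(geo$overlap[, c("zip_id", "overlap_km2")],
                 geo$overlap$tract_id)
    zip <- character(total)
    for (tid in unique(tract)) {
      sel <- tract == tid
      tab <- ovl[[tid]]
      zip[sel] <- if (nrow(tab) == 1) tab$zip_id else
        sample(tab$zip_id, sum(sel), replace = TRUE,
               prob = tab$overlap_km2 / sum(tab$overlap_km2))
    }

    urban <- geo$tracts$urban[match(tract, geo$tract_ids)]
    if (is.null(urban)) urban <- rep(TRUE, total)
    draw_cat <- function(p_urban, p_rural, labels) {
      out <- character(total)
      for (grp in c(TRUE, FALSE)) {
        sel <- urban == grp
        if (any(sel)) {
          out[sel] <- sample(labels, sum(sel), replace = TRUE,
                             prob = if (grp) p_urban else p_rural)
        }
      }
      out
    }
    race <- draw_cat(c(0.27, 0.65, 0.08), c(0.20, 0.75, 0.05),
                     c("White", "AfricanAmerican", "Other"))
    payor <- draw_cat(c(0.60, 0.27, 0.12, 0.01), c(0.66, 0.22, 0.11, 0.01),
                      c("Governmental", "Private", "SelfPay", "Other"))
    sex <- sample(c("Male", "Female"), total, replace = TRUE,
                  prob = c(0.58, 0.42))
    age <- sample(5:19, total, replace = TRUE,
                  prob = stats::dgeom(0:14, 0.12))
    fac_rural <- stats::runif(total) < ifelse(urban, 0.10, 0.80)

    out <- data.frame(
      record_id = sprintf("R%07d", seq_len(max(total, 0))),
      year = as.integer(year),
      zip_id = zip,
      tract_id = tract,
      race = race, sex = sex, age = as.integer(age), payor = payor,
      facility_urbanicity = ifelse(fac_rural, "Rural", "Urban"),
      stringsAsFactors = FALSE
    )
    attr(out, "Y") <- Y
    out
  })
}

#' Delete tract identifiers with a rural-biased mechanism
#'
#' Each record's tract identifier is deleted with probability
#' `plogis(miss_a + miss_b * area_km2(tract))`; a positive area slope
#' makes missingness more common in large (rural) tracts, mimicking the
#' non-standard rural address structures that defeat geocoding.  A small
#' configured fraction of records additionally loses the ZIP (these
#' cannot be assigned and are dropped downstream).  The true tract is
#' retained in a hidden audit column `.true_tract` for validation only;
#' no analysis operation reads it.
#'
#' @param records records from [generate_records()].
#' @param geo,config generator objects.
#' @param seed stage seed.
#' @return The records with `tract_id` (and some `zip_id`) set to `NA`.
#' @export
apply_missingness <- function(records, geo, config, seed) {
  with_seed(seed, {
    area <- geo$tracts$area_km2[match(records$tract_id, geo$tract_ids)]
    p_miss <- stats::plogis(config$miss_a + config$miss_b * area)
    miss <- stats::runif(nrow(records)) < p_miss
    records$.true_tract <- records$tract_id
    records$tract_id[miss] <- NA
    if (config$zip_drop > 0) {
      records$zip_id[stats::runif(nrow(records)) < config$zip_drop] <- NA
    }
    records
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining geography, truth, records and
#' missingness with sub-seeds derived from the master seed by fixed
#' offsets, so a configuration is fully reproducible from its seed.
#'
#' @param config a [sim_config()].
#' @return list with `geo`, `truth`, `records_complete` (before
#'   missingness), `records` (after), and `config`.
#' @export
simulate_study <- function(config) {
  geo <- generate_geography(config)
  truth <- generate_panel_truth(geo, config, seed = config$seed + 1L)
  rec <- generate_records(geo, truth, config, seed = config$seed + 2L)
  recm <- apply_missingness(rec, geo, config, seed = config$seed + 3L)
  list(geo = geo, truth = truth, records_complete = rec,
       records = recm, config = config)
}

#' Write a simulated study to CSV/JSON files
#'
#' Writes `tracts.csv`, `adjacency.csv`, `overlap.csv`, `records.csv`,
#' `covariates.csv`, `county_covariates.csv` and `truth.json` into a
#' directory, matching the reader interfaces of the analysis modules.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(sim$geo$tracts, p("tracts.csv"), row.names = FALSE)
  utils::write.csv(sim$geo$tract_adjacency, p("adjacency.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$geo$overlap, p("overlap.csv"), row.names = FALSE)
  write_records(sim$records, p("records.csv"))
  utils::write.csv(sim$truth$covariates, p("covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$county_covariates,
                   p("county_covariates.csv"), row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(alpha = truth$alpha, beta = as.list(truth$beta),
         beta2 = as.list(truth$beta2), years = truth$years,
         seed = sim$config$seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
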
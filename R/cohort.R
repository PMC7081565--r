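#' Aggregate event records to a tract-by-year count panel
#'
#' Builds the outcome of the small-area analysis: `Y[i, k]`, the number of
#' visit records in tract `i` and year `k`, zero-filled over the complete
#' grid of geography tracts and configured study years.  Every record must
#' carry a tract identifier (run [assign_missing_tracts()] or
#' [complete_case_filter()] first).
#'
#' @param records record data.frame with `tract_id` and `year`.
#' @param geo a [geography()] object; its tract set defines the panel rows.
#' @param years integer vector of study years (the panel columns).
#' @return An object of class `panel_data`: list with the count matrix
#'   `Y` (tracts x years), the geography, year vector, and county index.
#' @export
aggregate_counts <- function(records, geo, years) {
  stopifnot(inherits(geo, "geography"))
  records <- as.data.frame(records)
  years <- sort(as.integer(years))
  tract <- as.character(records$tract_id)
  tract[!is.na(tract) & tract == ""] <- NA
  if (anyNA(tract)) {
    stop(sum(is.na(tract)), " record(s) lack a tract identifier; impute ",
         "or filter before aggregation")
  }
  bad <- setdiff(unique(tract), geo$tract_ids)
  if (length(bad)) stop("records reference unknown tract ids: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  yr <- as.integer(records$year)
  if (any(!yr %in% years)) {
    stop("record year(s) outside the configured study window: ",
         paste(utils::head(setdiff(unique(yr), years), 5), collapse = ", "))
  }
  Y <- table(factor(tract, levels = geo$tract_ids),
             factor(yr, levels = years))
  Y <- matrix(as.integer(Y), nrow = length(geo$tract_ids),
              dimnames = list(geo$tract_ids, as.character(years)))
  structure(list(
    Y = Y,
    geo = geo,
    years = years,
    tract_county = match(geo$tracts$county_id, geo$county_ids),
    E = NULL,
    X1 = NULL, x1_names = character(),
    X2 = NULL, x2_names = character(),
    center_means = numeric()
  ), class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("<panel_data>", nrow(x$Y), "tracts x", ncol(x$Y), "years;",
      sum(x$Y), "events")
  if (!is.null(x$E)) cat("; expected counts set")
  if (!is.null(x$X1)) cat(";", length(x$x1_names), "tract covariates")
  if (!is.null(x$X2)) cat(";", length(x$x2_names), "county covariates")
  cat("\n")
  invisible(x)
}

#' Expected counts from the region-wide reference rate
#'
#' Internal-standardization offsets for the Poisson model: the observed
#' average annual region-wide visit rate times the tract population, so
#' the fitted relative risk is against the region-wide average.  The
#' default, time-invariant form uses the rate pooled over all study years
#' (`rate = (sum_ik Y_ik / n_years) / sum_i pop_i`, `E_i = rate * pop_i`),
#' a stabilized choice for space-time data; the `"annual"` alternative
#' uses the year-specific rate, giving `E_ik = rate_k * pop_i`.
#'
#' Tracts with zero population receive `E = 0` and are excluded from the
#' model likelihood downstream; a warning reports how many.
#'
#' @param panel a `panel_data` from [aggregate_counts()].
#' @param mode `"time_invariant"` (default) or `"annual"`.
#' @return The panel with `E` set (vector over tracts, or tracts x years
#'   matrix in annual mode) and `expected_mode` recorded.
#' @export
compute_expected <- function(panel, mode = c("time_invariant", "annual")) {
  stopifnot(inherits(panel, "panel_data"))
  mode <- match.arg(mode)
  pop <- panel$geo$tracts$population
  if (sum(pop) <= 0) stop("total population must be positive")
  zero <- pop == 0
  if (any(zero)) {
    warning(sum(zero), " zero-population tract(s) get E = 0 and are ",
            "excluded from the model likelihood")
  }
  if (mode == "time_invariant") {
    rate <- (sum(panel$Y) / ncol(panel$Y)) / sum(pop)
    panel$E <- rate * pop
    names(panel$E) <- panel$geo$tract_ids
  } else {
    rate_k <- colSums(panel$Y) / sum(pop)
    panel$E <- outer(pop, rate_k)
    dimnames(panel$E) <- dimnames(panel$Y)
  }
  panel$expected_mode <- mode
  panel
}

#' Average annual proportion of missing tract identifiers per tract
#'
#' For each tract, the mean over study years of the fraction of that
#' tract-year's records whose identifier was imputed (i.e., originally
#' missing).  Tract-years with no records contribute 0, so the statistic
#' is an average annual proportion over the fixed year grid.  Used as the
#' `propmiss` covariate; it is identically 0 on complete-case data.
#'
#' @param records records after assignment, carrying `imputed` flags and
#'   complete `tract_id`.
#' @param geo a [geography()] object.
#' @param years integer vector of study years.
#' @return data.frame with columns `tract_id`, `propmiss` (in `[0, 1]`).
#' @export
compute_propmiss <- function(records, geo, years) {
  stopifnot(inherits(geo, "geography"))
  records <- as.data.frame(records)
  if (!"imputed" %in% names(records)) {
    stop("records lack the `imputed` flag; run assign_missing_tracts() ",
         "or complete_case_filter() first")
  }
  years <- sort(as.integer(years))
  ft <- factor(as.character(records$tract_id), levels = geo$tract_ids)
  fy <- factor(as.integer(records$year), levels = years)
  tot <- table(ft, fy)
  imp <- table(ft[records$imputed], fy[records$imputed])
  frac <- ifelse(tot > 0, as.numeric(imp) / pmax(1, as.numeric(tot)), 0)
  frac <- matrix(frac, nrow = length(geo$tract_ids))
  data.frame(tract_id = geo$tract_ids,
             propmiss = rowMeans(frac),
             stringsAsFactors = FALSE)
}

#' Attach mean-centered covariates and interactions to a panel
#'
#' Expands tract-level (optionally tract-year) and county-level covariate
#' tables onto the panel's tract-year grid, mean-centers every column over
#' the modeled tract-years, and builds requested interaction columns as
#' elementwise products of the two *centered* parents (named `"A:B"`).
#' Centering before interacting keeps main effects interpretable at
#' average covariate levels; the two orders are not equivalent and the
#' centered-parents order is the one used.
#'
#' County-level columns are centered with tract-year weights (each county
#' weighted by its number of modeled tract-years) so that the full design
#' has column means of zero over the grid.
#'
#' @param panel a `panel_data`.
#' @param tract_covariates data.frame keyed by `tract_id` (plus optional
#'   `year` for time-varying measures) holding tract-level columns.
#' @param county_covariates optional data.frame keyed by `county_id`.
#' @param covariate_names tract-level column names to include.
#' @param county_covariate_names county-level column names to include.
#' @param interaction_pairs list of length-2 character vectors; both
#'   parents must appear in `covariate_names` (hierarchy rule).
#' @return The panel with `X1` (tract-year design, cells ordered tract
#'   fastest within year), `X2` (county design), name vectors, and the
#'   centering means recorded.
#' @export
prepare_design <- function(panel, tract_covariates = NULL,
                           county_covariates = NULL,
                           covariate_names = character(),
                           county_covariate_names = character(),
                           interaction_pairs = list()) {
  stopifnot(inherits(panel, "panel_data"))
  n_i <- nrow(panel$Y); n_k <- ncol(panel$Y)
  ncell <- n_i * n_k
  center_means <- numeric()

  X1 <- NULL
  if (length(covariate_names)) {
    tract_covariates <- as.data.frame(tract_covariates)
    missing_cols <- setdiff(covariate_names, names(tract_covariates))
    if (length(missing_cols)) {
      stop("tract covariate(s) not found: ",
           paste(missing_cols, collapse = ", "))
    }
    time_varying <- "year" %in% names(tract_covariates)
    X1 <- matrix(0, ncell, length(covariate_names),
                 dimnames = list(NULL, covariate_names))
    for (nm in covariate_names) {
      if (time_varying) {
        key <- paste(as.character(tract_covariates$tract_id),
                     tract_covariates$year)
        grid_key <- paste(rep(panel$geo$tract_ids, n_k),
                          rep(panel$years, each = n_i))
        v <- tract_covariates[[nm]][match(grid_key, key)]
      } else {
        v0 <- tract_covariates[[nm]][match(panel$geo$tract_ids,
                                    as.character(tract_covariates$tract_id))]
        v <- rep(v0, n_k)
      }
      if (anyNA(v)) stop("covariate `", nm, "` is missing for some ",
                         "tract(-year)s on the panel grid")
      m <- mean(v)
      center_means[nm] <- m
      X1[, nm] <- v - m
    }
  }

  X2 <- NULL
  if (length(county_covariate_names)) {
    county_covariates <- as.data.frame(county_covariates)
    missing_cols <- setdiff(county_covariate_names, names(county_covariates))
    if (length(missing_cols)) {
      stop("county covariate(s) not found: ",
           paste(missing_cols, collapse = ", "))
    }
    idx <- match(panel$geo$county_ids,
                 as.character(county_covariates$county_id))
    if (anyNA(idx)) stop("county covariates missing for some counties")
    wt <- tabulate(panel$tract_county, length(panel$geo$county_ids)) * n_k
    X2 <- matrix(0, length(panel$geo$county_ids),
                 length(county_covariate_names),
                 dimnames = list(panel$geo$county_ids,
                                 county_covariate_names))
    for (nm in county_covariate_names) {
      v <- county_covariates[[nm]][idx]
      if (anyNA(v)) stop("county covariate `", nm, "` has missing values")
      m <- sum(v * wt) / sum(wt)
      center_means[nm] <- m
      X2[, nm] <- v - m
    }
  }

  if (length(interaction_pairs)) {
    for (pair in interaction_pairs) {
      if (length(pair) != 2) stop("interaction pairs must have length 2")
      absent <- setdiff(pair, covariate_names)
      if (length(absent)) {
        stop("interaction parent(s) not included as main effects: ",
             paste(absent, collapse = ", "))
      }
      nm <- paste(pair, collapse = ":")
      col <- X1[, pair[1]] * X1[, pair[2]]
      X1 <- cbind(X1, col)
      colnames(X1)[ncol(X1)] <- nm
    }
  }

  panel$X1 <- X1
  panel$x1_names <- if (is.null(X1)) character() else colnames(X1)
  panel$X2 <- X2
  panel$x2_names <- if (is.null(X2)) character() else colnames(X2)
  panel$center_means <- center_means
  panel
}

#' Export a panel as a long-format CSV
#'
#' One row per tract-year with the count, expected count and covariate
#' columns (centered values, as modeled).
#'
#' @param panel a prepared `panel_data`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  n_i <- nrow(panel$Y); n_k <- ncol(panel$Y)
  df <- data.frame(
    tract_id = rep(rownames(panel$Y), n_k),
    year = rep(panel$years, each = n_i),
    count = as.vector(panel$Y),
    stringsAsFactors = FALSE
  )
  if (!is.null(panel$E)) {
    df$expected <- if (is.matrix(panel$E)) as.vector(panel$E)
                   else rep(panel$E, n_k)
  }
  if (!is.null(panel$X1)) df <- cbind(df, as.data.frame(panel$X1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
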
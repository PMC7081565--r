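#' Construct a misaligned areal system
#'
#' A `geography` holds the two analysis scales (census tracts nested in
#' counties) together with a coarser, spatially misaligned unit (ZIP codes)
#' described only through a tract-by-ZIP overlap-area table.  No polygon
#' geometry is required: overlap areas are consumed precomputed, so the
#' object is sufficient to build assignment crosswalks and spatial
#' adjacency structures without any GIS dependency.
#'
#' @param tracts data.frame with columns `tract_id`, `county_id`,
#'   `area_km2` (> 0) and `population` (>= 0).  Additional columns (e.g.
#'   `urban`, rectangle coordinates from the synthetic generator) are
#'   carried along untouched.
#' @param tract_adjacency data.frame with columns `id_a`, `id_b`.  Each
#'   undirected edge may be listed once, or the full symmetric relation may
#'   be given (every edge in both directions); a partially symmetric list
#'   is rejected as an asymmetric adjacency.
#' @param overlap data.frame with columns `tract_id`, `zip_id`,
#'   `overlap_km2` (>= 0).  Per tract, overlaps must not exceed the tract
#'   area (equality when the ZIPs tile the region).
#' @param county_adjacency optional data.frame like `tract_adjacency` over
#'   county ids.  When `NULL` it is derived from tract adjacency: two
#'   counties are neighbors when any of their tracts are.
#' @param area_tol relative tolerance for the overlap-vs-area check.
#'
#' @return An object of class `geography`.
#' @seealso [build_crosswalk()], [validate_geography()], [read_geography()]
#' @export
geography <- function(tracts, tract_adjacency, overlap,
                      county_adjacency = NULL, area_tol = 1e-6) {
  req <- c("tract_id", "county_id", "area_km2", "population")
  if (!all(req %in% names(tracts))) {
    stop("`tracts` must have columns: ", paste(req, collapse = ", "))
  }
  tracts <- as.data.frame(tracts, stringsAsFactors = FALSE)
  tracts$tract_id <- as.character(tracts$tract_id)
  tracts$county_id <- as.character(tracts$county_id)
  if (anyDuplicated(tracts$tract_id)) stop("duplicated tract ids")
  if (any(!is.finite(tracts$area_km2)) || any(tracts$area_km2 <= 0)) {
    stop("tract areas must be positive")
  }
  if (any(!is.finite(tracts$population)) || any(tracts$population < 0)) {
    stop("tract populations must be nonnegative")
  }

  tract_ids <- tracts$tract_id
  county_ids <- sort(unique(tracts$county_id))
  tract_edges <- normalize_edges(tract_adjacency, tract_ids, "tract")

  overlap <- as.data.frame(overlap, stringsAsFactors = FALSE)
  if (!all(c("tract_id", "zip_id", "overlap_km2") %in% names(overlap))) {
    stop("`overlap` must have columns tract_id, zip_id, overlap_km2")
  }
  overlap$tract_id <- as.character(overlap$tract_id)
  overlap$zip_id <- as.character(overlap$zip_id)
  bad <- setdiff(overlap$tract_id, tract_ids)
  if (length(bad)) stop("overlap references unknown tract ids: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(!is.finite(overlap$overlap_km2)) || any(overlap$overlap_km2 < 0)) {
    stop("overlap areas must be nonnegative")
  }
  tot <- tapply(overlap$overlap_km2, overlap$tract_id, sum)
  area <- tracts$area_km2[match(names(tot), tract_ids)]
  over <- tot > area * (1 + area_tol) + area_tol
  if (any(over)) {
    stop("total ZIP overlap exceeds tract area for tract(s): ",
         paste(utils::head(names(tot)[over], 5), collapse = ", "))
  }

  if (is.null(county_adjacency)) {
    ca <- unique(data.frame(
      id_a = pmin(tracts$county_id[match(tract_edges$id_a, tract_ids)],
                  tracts$county_id[match(tract_edges$id_b, tract_ids)]),
      id_b = pmax(tracts$county_id[match(tract_edges$id_a, tract_ids)],
                  tracts$county_id[match(tract_edges$id_b, tract_ids)]),
      stringsAsFactors = FALSE))
    ca <- ca[ca$id_a != ca$id_b, , drop = FALSE]
    county_edges <- ca[order(ca$id_a, ca$id_b), , drop = FALSE]
    rownames(county_edges) <- NULL
  } else {
    county_edges <- normalize_edges(county_adjacency, county_ids, "county")
  }

  structure(list(
    tracts = tracts,
    tract_ids = tract_ids,
    zip_ids = sort(unique(overlap$zip_id)),
    county_ids = county_ids,
    tract_adjacency = tract_edges,
    county_adjacency = county_edges,
    overlap = overlap
  ), class = "geography")
}

# Canonicalize an undirected edge list: accepts once-listed edges or the
# full symmetric relation; rejects partial symmetry and self loops.
normalize_edges <- function(edges, ids, what) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  if (!all(c("id_a", "id_b") %in% names(edges))) {
    stop(what, " adjacency must have columns id_a, id_b")
  }
  a <- as.character(edges$id_a); b <- as.character(edges$id_b)
  bad <- setdiff(c(a, b), ids)
  if (length(bad)) stop(what, " adjacency references unknown ids: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  if (any(a == b)) stop(what, " adjacency contains self loops")
  key <- paste(a, b, sep = "\r")
  rkey <- paste(b, a, sep = "\r")
  if (anyDuplicated(key)) stop(what, " adjacency lists an edge twice")
  has_rev <- rkey %in% key
  if (any(has_rev)) {
    # symmetric-representation input: require full symmetry
    if (!all(has_rev)) {
      miss <- which(!has_rev)[1]
      stop("asymmetric ", what, " adjacency: edge (", a[miss], ", ",
           b[miss], ") has no reverse entry")
    }
    keep <- a < b
    a <- a[keep]; b <- b[keep]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  o <- order(lo, hi)
  out <- data.frame(id_a = lo[o], id_b = hi[o], stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$id_a, out$id_b, sep = "\r"))) {
    stop(what, " adjacency lists an edge twice")
  }
  rownames(out) <- NULL
  out
}

#' @export
print.geography <- function(x, ...) {
  cat("<geography>", length(x$tract_ids), "tracts,",
      length(x$zip_ids), "ZIPs,", length(x$county_ids), "counties;",
      nrow(x$tract_adjacency), "tract edges\n")
  invisible(x)
}

#' Validate a geography and summarize its structure
#'
#' Re-checks the structural invariants (one county per tract, symmetric
#' irreflexive adjacency, overlaps bounded by tract areas) and reports
#' counts useful as a data-entry diagnostic: isolated tracts (no adjacency)
#' and tracts with zero population (excluded from model likelihoods
#' downstream).
#'
#' @param geo a [geography()] object.
#' @return A list of class `geography_report` with elements `n_tracts`,
#'   `n_zips`, `n_counties`, `n_tract_edges`, `isolated_tracts`,
#'   `zero_population_tracts`.
#' @export
validate_geography <- function(geo) {
  stopifnot(inherits(geo, "geography"))
  # reconstructing triggers all constructor invariant checks
  geography(geo$tracts, geo$tract_adjacency, geo$overlap,
            geo$county_adjacency)
  touched <- unique(c(geo$tract_adjacency$id_a, geo$tract_adjacency$id_b))
  isolated <- setdiff(geo$tract_ids, touched)
  zeropop <- geo$tracts$tract_id[geo$tracts$population == 0]
  structure(list(
    n_tracts = length(geo$tract_ids),
    n_zips = length(geo$zip_ids),
    n_counties = length(geo$county_ids),
    n_tract_edges = nrow(geo$tract_adjacency),
    isolated_tracts = isolated,
    zero_population_tracts = zeropop
  ), class = "geography_report")
}

#' @export
print.geography_report <- function(x, ...) {
  cat("Geography:", x$n_tracts, "tracts |", x$n_zips, "ZIPs |",
      x$n_counties, "counties |", x$n_tract_edges, "tract edges\n")
  cat("  isolated tracts:", length(x$isolated_tracts),
      "| zero-population tracts:", length(x$zero_population_tracts), "\n")
  invisible(x)
}

#' Build a tract-in-ZIP assignment crosswalk
#'
#' For every ZIP code, computes the proportion of the ZIP attributable to
#' each overlapping census tract and orders the entries into a saved list
#' with running cumulative proportions.  The cumulative intervals are the
#' assignment probabilities used by [assign_missing_tracts()].
#'
#' Two weighting modes are provided.  In `"areal"` mode the proportion of
#' tract `t` in ZIP `z` is `overlap(t, z) / sum_t' overlap(t', z)`: because
#' tract areas are inversely related to population density, areal weights
#' favor large rural tracts and so reconstruct rural-dominated missingness
#' patterns.  In `"population"` mode the weight is the population of the
#' overlapped piece under a uniform-density approximation,
#' `population(t) * overlap(t, z) / area(t)`, normalized within the ZIP;
#' population weights favor dense urban tracts.  Zero-weight tracts
#' (e.g., unpopulated tracts in population mode) are dropped from the
#' ZIP's entry list; affected ZIPs are recorded in the `dropped` attribute.
#'
#' Entries are ordered by descending proportion with ties broken by
#' ascending tract id, so the crosswalk is a pure function of the
#' geography and mode.
#'
#' @param geo a [geography()] object.
#' @param mode `"areal"` or `"population"`.
#' @return data.frame of class `crosswalk` with columns `zip_id`, `rank`,
#'   `tract_id`, `proportion`, `cumulative`, and attributes `mode` and
#'   `dropped` (data.frame of zero-weight (zip, tract) pairs removed).
#' @export
build_crosswalk <- function(geo, mode = c("areal", "population")) {
  stopifnot(inherits(geo, "geography"))
  mode <- match.arg(mode)
  ov <- geo$overlap[geo$overlap$overlap_km2 > 0, , drop = FALSE]
  if (nrow(ov) == 0) stop("no positive overlaps: cannot build crosswalk")
  idx <- match(ov$tract_id, geo$tract_ids)
  w <- if (mode == "areal") {
    ov$overlap_km2
  } else {
    geo$tracts$population[idx] * ov$overlap_km2 / geo$tracts$area_km2[idx]
  }
  keep <- w > 0
  dropped <- data.frame(zip_id = ov$zip_id[!keep],
                        tract_id = ov$tract_id[!keep],
                        stringsAsFactors = FALSE)
  zips_all <- unique(ov$zip_id)
  ov <- ov[keep, , drop = FALSE]
  w <- w[keep]
  lost <- setdiff(zips_all, unique(ov$zip_id))
  if (length(lost)) {
    stop("ZIP(s) with zero total assignment weight in ", mode, " mode: ",
         paste(utils::head(lost, 5), collapse = ", "))
  }
  # deterministic ordering: by zip, then descending weight, then tract id
  o <- order(ov$zip_id, -w, ov$tract_id, method = "radix")
  ov <- ov[o, , drop = FALSE]
  w <- w[o]
  tot <- stats::ave(w, ov$zip_id, FUN = sum)
  prop <- w / tot
  out <- data.frame(
    zip_id = ov$zip_id,
    rank = stats::ave(prop, ov$zip_id, FUN = seq_along),
    tract_id = ov$tract_id,
    proportion = prop,
    cumulative = stats::ave(prop, ov$zip_id, FUN = cumsum),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, mode = mode, dropped = dropped,
            class = c("crosswalk", "data.frame"))
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("<crosswalk>", length(unique(x$zip_id)), "ZIPs,", nrow(x), "entries,",
      "mode:", attr(x, "mode"), "\n")
  NextMethod()
}

#' Read a geography from its three CSV tables
#'
#' @param tracts_csv path to `tracts.csv` (tract_id, county_id, area_km2,
#'   population).
#' @param adjacency_csv path to `adjacency.csv` (id_a, id_b; one row per
#'   undirected edge).
#' @param overlap_csv path to `overlap.csv` (tract_id, zip_id, overlap_km2).
#' @return A [geography()] object.
#' @export
read_geography <- function(tracts_csv, adjacency_csv, overlap_csv) {
  geography(
    utils::read.csv(tracts_csv, colClasses = c(tract_id = "character",
                                               county_id = "character")),
    utils::read.csv(adjacency_csv, colClasses = "character"),
    utils::read.csv(overlap_csv, colClasses = c(tract_id = "character",
                                                zip_id = "character"))
  )
}

#' Write / read a crosswalk as CSV
#'
#' @param xwalk a [build_crosswalk()] result.
#' @param path output CSV path.
#' @return `write_crosswalk()` returns `path` invisibly; `read_crosswalk()`
#'   returns a `crosswalk` data.frame.
#' @export
write_crosswalk <- function(xwalk, path) {
  df <- as.data.frame(xwalk)
  df$mode <- attr(xwalk, "mode")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crosswalk
#' @export
read_crosswalk <- function(path) {
  df <- utils::read.csv(path, colClasses = c(zip_id = "character",
                                             tract_id = "character"))
  mode <- if ("mode" %in% names(df)) df$mode[1] else "areal"
  df$mode <- NULL
  structure(df, mode = mode,
            dropped = data.frame(zip_id = character(),
                                 tract_id = character()),
            class = c("crosswalk", "data.frame"))
}
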
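#' Stochastically assign missing tract identifiers from a crosswalk
#'
#' Implements the assignment step of the geographic identifier algorithm:
#' for every record whose ZIP code is known but whose census tract is
#' missing, a uniform random number on `[0, 1)` is drawn and the tract
#' whose half-open cumulative-proportion interval `[c_{m-1}, c_m)` contains
#' it becomes the imputed identifier.  Records that already carry a tract
#' are returned unchanged with `imputed = FALSE`.  Records lacking both a
#' valid ZIP and a tract cannot be assigned and are dropped; their count is
#' attached as attribute `n_dropped` and reported in a warning (these
#' mirror the small fraction of real records without a valid ZIP).
#'
#' One random stream, seeded by `seed`, is consumed in input record order,
#' so assignments are fully reproducible and order-auditable.  A record
#' with a ZIP absent from the crosswalk is a hard error: crosswalk
#' completeness is treated as a data-integrity requirement, not a reason
#' to silently lose records.
#'
#' @param records data.frame with columns `record_id`, `year`, `zip_id`,
#'   `tract_id` (NA when missing) plus arbitrary attribute columns.
#' @param xwalk a [build_crosswalk()] result covering every ZIP that
#'   appears on a record with a missing tract.
#' @param seed integer seed for the assignment stream.
#' @param .uniforms optional numeric vector of uniforms (one per record
#'   needing assignment, in input order) substituted for the random
#'   stream; intended for diagnostics and worked examples.
#' @return The records with `tract_id` filled and a logical `imputed`
#'   column; row order matches the input (minus dropped rows).
#' @export
assign_missing_tracts <- function(records, xwalk, seed, .uniforms = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records)
  for (col in c("zip_id", "tract_id")) {
    if (!col %in% names(records)) stop("records lack column `", col, "`")
    records[[col]] <- as.character(records[[col]])
    records[[col]][!is.na(records[[col]]) & records[[col]] == ""] <- NA
  }
  no_tract <- is.na(records$tract_id)
  no_zip <- is.na(records$zip_id)
  drop <- no_tract & no_zip
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    warning(n_dropped, " record(s) without a valid ZIP or tract were dropped")
    records <- records[!drop, , drop = FALSE]
    no_tract <- no_tract[!drop]
  }
  records$imputed <- FALSE
  todo <- which(no_tract)
  if (length(todo)) {
    zips <- records$zip_id[todo]
    unknown <- setdiff(unique(zips), unique(xwalk$zip_id))
    if (length(unknown)) {
      stop("ZIP(s) on records with missing tract are absent from the ",
           "crosswalk: ", paste(utils::head(unknown, 5), collapse = ", "))
    }
    if (is.null(.uniforms)) {
      r <- with_seed(seed, stats::runif(length(todo)))
    } else {
      if (length(.uniforms) != length(todo)) {
        stop("`.uniforms` must have one value per record needing assignment (",
             length(todo), ")")
      }
      r <- .uniforms
    }
    cw <- split(xwalk[, c("tract_id", "cumulative")], xwalk$zip_id)
    assigned <- character(length(todo))
    for (z in unique(zips)) {
      zi <- which(zips == z)
      entry <- cw[[z]]
      m <- findInterval(r[zi], entry$cumulative) + 1L
      m[m > nrow(entry)] <- nrow(entry)
      assigned[zi] <- entry$tract_id[m]
    }
    records$tract_id[todo] <- assigned
    records$imputed[todo] <- TRUE
  }
  rownames(records) <- NULL
  attr(records, "n_dropped") <- n_dropped
  records
}

#' Independent replicate assignment datasets
#'
#' Repeats [assign_missing_tracts()] with seeds `base_seed + 0, ...,
#' base_seed + n_replicates - 1`, producing independent assignment
#' datasets (the sensitivity-analysis replicates).  Non-missing records
#' are identical across replicates; each record with a missing tract may
#' land in a different tract of its known ZIP in each replicate.
#'
#' @inheritParams assign_missing_tracts
#' @param n_replicates number of datasets (>= 1).
#' @param base_seed integer seed of the first replicate.
#' @return A list of record data.frames, one per replicate.
#' @export
replicate_assignments <- function(records, xwalk, n_replicates, base_seed) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates) - 1L, function(off) {
    assign_missing_tracts(records, xwalk, seed = base_seed + off)
  })
}

#' Complete-case filter: drop records with missing tract identifiers
#'
#' The conventional alternative to geographic imputation: keep only
#' records whose census tract was originally present.  If the input
#' carries an `imputed` column (i.e., has already been through
#' assignment), imputed records count as originally missing and are
#' removed.
#'
#' @param records record data.frame.
#' @return The retained records with `imputed = FALSE`; the number removed
#'   is attached as attribute `n_removed` and reported via a message
#'   (warning when nothing remains).
#' @export
complete_case_filter <- function(records) {
  records <- as.data.frame(records)
  tract <- as.character(records$tract_id)
  tract[!is.na(tract) & tract == ""] <- NA
  orig <- !is.na(tract)
  if ("imputed" %in% names(records)) orig <- orig & !records$imputed
  n_removed <- sum(!orig)
  out <- records[orig, , drop = FALSE]
  out$imputed <- rep(FALSE, nrow(out))
  if (nrow(out) == 0) {
    warning("complete-case filter removed all ", n_removed, " records")
  } else if (n_removed > 0) {
    message("complete-case filter removed ", n_removed, " record(s)")
  }
  rownames(out) <- NULL
  attr(out, "n_removed") <- n_removed
  out
}

#' Stratify record attributes by tract-identifier missingness
#'
#' Compares records whose census tract identifier is missing against those
#' with a complete identifier, attribute by attribute: per-category counts
#' and column percentages (100 * count / group size, rounded to one
#' decimal) within each group.  This is the standard descriptive check of
#' whether geographic missingness is differential with respect to, e.g.,
#' race, payor, or the urbanicity of the admitting facility.
#'
#' A record counts as "missing" when its tract is absent or was imputed
#' (the `imputed` flag marks an originally missing identifier).  Records
#' without a valid ZIP are included; their count is also attached as
#' attribute `n_invalid_zip` so tabulations before and after dropping them
#' can both be reported.
#'
#' @param records record data.frame.
#' @param attribute_names character vector of attribute columns to
#'   stratify; each must exist on the records.
#' @return Long-format data.frame (`attribute`, `category`, `group`,
#'   `count`, `percent`) with attributes `group_sizes` (named numeric) and
#'   `n_invalid_zip`.
#' @export
summarize_missingness <- function(records, attribute_names) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(attribute_names, names(records))
  if (length(missing_cols)) {
    stop("unknown attribute(s): ", paste(missing_cols, collapse = ", "))
  }
  tract <- as.character(records$tract_id)
  tract[!is.na(tract) & tract == ""] <- NA
  miss <- is.na(tract)
  if ("imputed" %in% names(records)) miss <- miss | records$imputed
  group <- ifelse(miss, "missing", "complete")
  sizes <- c(missing = sum(miss), complete = sum(!miss))
  zip <- if ("zip_id" %in% names(records)) as.character(records$zip_id)
         else rep(NA_character_, nrow(records))
  zip[!is.na(zip) & zip == ""] <- NA
  out <- do.call(rbind, lapply(attribute_names, function(a) {
    vals <- as.character(records[[a]])
    cats <- sort(unique(vals))
    do.call(rbind, lapply(c("missing", "complete"), function(g) {
      n <- sizes[[g]]
      if (n == 0) return(NULL)
      cnt <- table(factor(vals[group == g], levels = cats))
      data.frame(attribute = a, category = cats, group = g,
                 count = as.integer(cnt),
                 percent = round(100 * as.integer(cnt) / n, 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  attr(out, "n_invalid_zip") <- sum(is.na(zip))
  out
}

#' Write / read record tables as CSV
#'
#' Missing identifiers are encoded as empty fields.  The hidden audit
#' column written by the synthetic generator (`.true_tract`) is preserved
#' by `write_records()` but never consumed by any analysis operation.
#'
#' @param records record data.frame.
#' @param path CSV path.
#' @return `write_records()` returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("zip_id", "tract_id")) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA
  }
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  if ("imputed" %in% names(df)) df$imputed <- df$imputed %in% c("TRUE", "true", "1")
  df
}
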
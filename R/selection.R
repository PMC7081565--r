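#' Gibbs variable selection with Bernoulli entry parameters
#'
#' Fits the hierarchical Poisson model with a binary entry parameter
#' `phi_m` multiplying each candidate coefficient (Kuo-Mallick form): the
#' linear-predictor term for candidate `m` is `phi_m * beta_m * x_m`.
#' Each sweep updates every `phi_m` from its Bernoulli full conditional
#' (the likelihood ratio of the included vs excluded predictor times the
#' prior odds `p / (1 - p)`), draws coefficients of excluded candidates
#' from the pseudo-prior (their prior by default), and updates the shared
#' inclusion probability conjugately,
#' `p | phi ~ Beta(0.5 + sum(phi), 0.5 + M - sum(phi))` under its
#' Beta(0.5, 0.5) prior.  All candidates are updated jointly every sweep
#' (all-at-once selection, no stepwise entry), which lets the shared `p`
#' adjust automatically for multiplicity.
#'
#' Forced-in covariates (demographic/weather controls and any main effect
#' required for interpretability) carry no entry parameter and are always
#' present.
#'
#' @param panel prepared `panel_data` (all candidate columns centered).
#' @param spec a [model_spec()]; its covariate lists are ignored in favor
#'   of `candidates` and `forced_in`.
#' @param candidates character names of candidate tract-level design
#'   columns (main effects and/or interaction columns).
#' @param forced_in character names always included (no `phi`).
#' @param county_covariates optional county-level names (forced in).
#' @param pseudo_prior optional list with named numeric `mean` and `sd`
#'   giving a tuned pseudo-prior for excluded coefficients (e.g., from a
#'   pilot run); default is the coefficient prior itself.
#' @return list with `inclusion` (data.frame: `candidate`, `phi_mean`,
#'   `selected`), `p_mean`, and `samples` (a `bhm_samples` whose `phi`
#'   matrix holds the entry-parameter draws).
#' @export
fit_gvs <- function(panel, spec, candidates, forced_in = character(),
                    county_covariates = character(),
                    pseudo_prior = NULL) {
  stopifnot(inherits(panel, "panel_data"), inherits(spec, "bhm_spec"))
  if (length(candidates) < 1) stop("need at least one candidate")
  dup <- intersect(candidates, forced_in)
  if (length(dup)) stop("candidate(s) duplicated in forced_in: ",
                        paste(dup, collapse = ", "))
  missing_cols <- setdiff(c(candidates, forced_in), panel$x1_names)
  if (length(missing_cols)) stop("column(s) not in panel design: ",
                                 paste(missing_cols, collapse = ", "))
  # candidates must be centered: the excluded state means "at the mean"
  mcheck <- colMeans(panel$X1[, candidates, drop = FALSE])
  if (any(abs(mcheck) > 1e-6)) {
    stop("non-centered candidate column(s): ",
         paste(candidates[abs(mcheck) > 1e-6], collapse = ", "))
  }
  spec$tract_covariates <- c(forced_in, candidates)
  spec$county_covariates <- county_covariates
  gvs <- list(candidates = candidates,
              pseudo_mean = pseudo_prior$mean,
              pseudo_sd = pseudo_prior$sd)
  chains <- lapply(seq_len(spec$mcmc$chains), function(ch) {
    mcmc_engine(panel, spec, gvs = gvs,
                chain_seed = spec$mcmc$seed + 1000L * (ch - 1L))
  })
  samples <- combine_chains(chains, spec, gvs = gvs)
  phi_mean <- colMeans(samples$phi)
  inclusion <- data.frame(candidate = candidates,
                          phi_mean = phi_mean[candidates],
                          selected = phi_mean[candidates] > 0.5,
                          row.names = NULL, stringsAsFactors = FALSE)
  list(inclusion = inclusion, p_mean = mean(samples$p_incl),
       samples = samples)
}

#' Conjugate Beta full conditional of the shared inclusion probability
#'
#' `p | phi ~ Beta(a + sum(phi), b + M - sum(phi))` under a Beta(a, b)
#' prior (default Beta(0.5, 0.5)).
#'
#' @param phi 0/1 vector of entry parameters.
#' @param prior_a,prior_b Beta prior parameters.
#' @return list with `shape1`, `shape2`, and the conditional `mean`.
#' @export
inclusion_fullcond <- function(phi, prior_a = 0.5, prior_b = 0.5) {
  stopifnot(all(phi %in% c(0, 1)))
  s1 <- prior_a + sum(phi)
  s2 <- prior_b + length(phi) - sum(phi)
  list(shape1 = s1, shape2 = s2, mean = s1 / (s1 + s2))
}

#' Select variables by the posterior-inclusion threshold rule
#'
#' Keeps candidates whose posterior mean entry parameter is strictly
#' greater than the threshold (default 0.5, i.e., included in more than
#' half the posterior samples).  Candidate order is preserved.
#'
#' @param phi_means named numeric vector of posterior mean `phi` (in
#'   `[0, 1]`), or the `inclusion` data.frame from [fit_gvs()].
#' @param threshold strict cutoff.
#' @return character vector of selected names.
#' @export
select_variables <- function(phi_means, threshold = 0.5) {
  if (is.data.frame(phi_means)) {
    phi_means <- stats::setNames(phi_means$phi_mean, phi_means$candidate)
  }
  if (any(phi_means < 0 | phi_means > 1)) {
    stop("phi means must lie in [0, 1]")
  }
  names(phi_means)[phi_means > threshold]
}

#' Majority-consensus selection across replicate assignment datasets
#'
#' Variable selection is run independently on each replicate assignment
#' dataset; the consensus keeps variables selected in strictly more than
#' half of the datasets.  With the strict-majority rule at both stages
#' the final roster is invariant to dataset order.
#'
#' @param per_dataset_selected list of character vectors (one per
#'   dataset).
#' @return character vector of consensus names, in first-appearance
#'   order.
#' @export
consensus_selection <- function(per_dataset_selected) {
  stopifnot(length(per_dataset_selected) >= 1)
  all_names <- unique(unlist(per_dataset_selected))
  n <- length(per_dataset_selected)
  counts <- vapply(all_names, function(nm)
    sum(vapply(per_dataset_selected, function(s) nm %in% s, TRUE)), 0L)
  all_names[counts > n / 2]
}

#' Assemble the final model specification from consensus selection
#'
#' The final model is the forced-in block plus the consensus candidates.
#' For any selected interaction `"A:B"`, both parent main effects are
#' added even when not themselves selected, to keep the interaction
#' interpretable.
#'
#' @param base_spec the [model_spec()] holding the forced-in block (its
#'   `tract_covariates` / `county_covariates`) and MCMC/prior settings.
#' @param consensus_names consensus candidates from
#'   [consensus_selection()].
#' @param panel optional `panel_data` used to verify the columns exist.
#' @return A [model_spec()] for the final model.
#' @export
build_final_spec <- function(base_spec, consensus_names, panel = NULL) {
  stopifnot(inherits(base_spec, "bhm_spec"))
  extra <- character()
  for (nm in consensus_names) {
    if (grepl(":", nm, fixed = TRUE)) {
      extra <- c(extra, strsplit(nm, ":", fixed = TRUE)[[1]])
    }
  }
  final <- unique(c(base_spec$tract_covariates, consensus_names, extra))
  # parents precede their interactions in the design order
  ord <- c(final[!grepl(":", final, fixed = TRUE)],
           final[grepl(":", final, fixed = TRUE)])
  if (!is.null(panel)) {
    missing_cols <- setdiff(ord, panel$x1_names)
    if (length(missing_cols)) stop("column(s) not in panel design: ",
                                   paste(missing_cols, collapse = ", "))
  }
  base_spec$tract_covariates <- ord
  base_spec
}

#' Export selection / consensus tables as CSV
#'
#' @param inclusion the `inclusion` data.frame from [fit_gvs()].
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_selection <- function(inclusion, path) {
  utils::write.csv(inclusion, path, row.names = FALSE)
  invisible(path)
}
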
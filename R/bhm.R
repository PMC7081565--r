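#' Specify a spatio-temporal hierarchical Poisson model
#'
#' Describes one member of the model ladder for tract-year counts
#' `Y[i, k] ~ Poisson(E_i * theta[i, k])` with
#' `log theta[i, k] = alpha + u_i + v_i + w_j + g_k + beta1' X[i, k] +
#' beta2' X[j]`, where `u` is an intrinsic CAR (Besag) spatial effect on
#' the tract adjacency, `v` an exchangeable tract effect (together a BYM
#' convolution), `w` an intrinsic CAR effect on the county adjacency,
#' and `g` a temporal trend (first-order random walk by default,
#' exchangeable year effects via `g_type = "iid"`).
#'
#' Coefficients have zero-centered normal priors whose shared precision
#' (and every random-effect precision) carries a Gamma(shape 2, scale 1)
#' hyperprior on the precision scale; `prior_on = "variance"` instead
#' reads that Gamma as a prior on the variance, sampled by
#' Metropolis-Hastings since conjugacy is lost.
#'
#' @param effects character subset of `c("u", "v", "w", "g")`.
#' @param tract_covariates names of tract(-year) design columns (the
#'   `beta1` block; must exist in the panel's `X1`).
#' @param county_covariates names of county design columns (`beta2`).
#' @param g_type `"rw1"` or `"iid"` temporal structure.
#' @param prior list from [prior_settings()].
#' @param mcmc list from [mcmc_settings()].
#' @return An object of class `bhm_spec`.
#' @export
model_spec <- function(effects = c("u", "v", "w", "g"),
                       tract_covariates = character(),
                       county_covariates = character(),
                       g_type = c("rw1", "iid"),
                       prior = prior_settings(),
                       mcmc = mcmc_settings()) {
  bad <- setdiff(effects, c("u", "v", "w", "g"))
  if (length(bad)) stop("unknown random effect(s): ", paste(bad, collapse = ", "))
  structure(list(
    effects = effects,
    tract_covariates = tract_covariates,
    county_covariates = county_covariates,
    g_type = match.arg(g_type),
    prior = prior,
    mcmc = mcmc
  ), class = "bhm_spec")
}

#' @rdname model_spec
#' @param tau_shape,tau_scale Gamma hyperprior shape and scale for all
#'   precision parameters (coefficient blocks and random effects).
#' @param prior_on `"precision"` (default; conjugate) or `"variance"`.
#' @param alpha_prec fixed prior precision of the intercept (a diffuse
#'   normal; 0.001 corresponds to sd ~ 31.6 on the log-risk scale).
#' @export
prior_settings <- function(tau_shape = 2, tau_scale = 1,
                           prior_on = c("precision", "variance"),
                           alpha_prec = 1e-3) {
  list(tau_shape = tau_shape, tau_scale = tau_scale,
       prior_on = match.arg(prior_on), alpha_prec = alpha_prec)
}

#' @rdname model_spec
#' @param n_iter total MCMC iterations per chain.
#' @param n_burnin iterations discarded (adaptation happens only here).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of independent chains (seeds offset by 1000).
#' @param seed master seed of the first chain.
#' @export
mcmc_settings <- function(n_iter = 4000, n_burnin = 2000, thin = 2,
                          chains = 1, seed = 1) {
  stopifnot(n_iter > n_burnin, thin >= 1, chains >= 1)
  list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
       thin = as.integer(thin), chains = as.integer(chains),
       seed = as.integer(seed))
}

#' @export
print.bhm_spec <- function(x, ...) {
  cat("<bhm_spec> effects:", if (length(x$effects)) paste(x$effects, collapse = "+") else "none",
      "| tract covariates:", length(x$tract_covariates),
      "| county covariates:", length(x$county_covariates),
      "| g:", x$g_type, "\n")
  invisible(x)
}

# ---- likelihood ------------------------------------------------------------

# Cell bookkeeping shared by the likelihood and the sampler.  Cells with
# E = 0 (zero-population tracts) are excluded from the likelihood.
panel_cells <- function(panel) {
  if (is.null(panel$E)) stop("panel has no expected counts; run compute_expected()")
  n_i <- nrow(panel$Y); n_k <- ncol(panel$Y)
  Ecell <- if (is.matrix(panel$E)) as.vector(panel$E) else rep(panel$E, n_k)
  keep <- Ecell > 0
  list(
    n_i = n_i, n_k = n_k, n_j = length(panel$geo$county_ids),
    keep = keep,
    Y = as.vector(panel$Y)[keep],
    logE = log(Ecell[keep]),
    tract_of = rep(seq_len(n_i), n_k)[keep],
    year_of = rep(seq_len(n_k), each = n_i)[keep],
    county_of = panel$tract_county[rep(seq_len(n_i), n_k)[keep]]
  )
}

# sum of x within integer groups 1..n (empty groups contribute 0)
agg_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Poisson log-likelihood of a model state
#'
#' Evaluates `sum_ik [Y log(mu) - mu - log(Y!)]` with
#' `mu[i, k] = E_i exp(alpha + u_i + v_i + w_j + g_k + beta1'X + beta2'X_j)`
#' over the modeled cells (cells with `E = 0` are excluded).
#'
#' @param panel a prepared `panel_data` with expected counts.
#' @param state named list of parameter values: `alpha` (scalar), and
#'   optionally `u`, `v` (tract vectors), `w` (county vector), `g` (year
#'   vector), `beta1`, `beta2` (coefficient vectors matching the design).
#'   Missing components default to zero.
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(panel, state) {
  cells <- panel_cells(panel)
  eta <- state_eta(panel, cells, state)
  if (any(!is.finite(eta))) {
    b <- which(!is.finite(eta))[1]
    stop("non-finite linear predictor at tract ",
         panel$geo$tract_ids[cells$tract_of[b]], ", year ",
         panel$years[cells$year_of[b]])
  }
  mu <- exp(cells$logE + eta)
  sum(cells$Y * (cells$logE + eta) - mu - lgamma(cells$Y + 1))
}

state_eta <- function(panel, cells, state) {
  g0 <- function(x, n) if (is.null(x)) numeric(n) else x
  n_i <- cells$n_i
  eta <- rep(g0(state$alpha, 1), length(cells$Y))
  eta <- eta + g0(state$u, n_i)[cells$tract_of] +
    g0(state$v, n_i)[cells$tract_of] +
    g0(state$w, cells$n_j)[cells$county_of] +
    g0(state$g, cells$n_k)[cells$year_of]
  if (!is.null(state$beta1) && length(state$beta1)) {
    eta <- eta + as.vector(panel$X1[cells$keep, , drop = FALSE] %*% state$beta1)
  }
  if (!is.null(state$beta2) && length(state$beta2)) {
    eta <- eta + as.vector(panel$X2 %*% state$beta2)[cells$county_of]
  }
  eta
}

#' Unnormalized intrinsic CAR (Besag) log density
#'
#' `(n - c)/2 * log(tau) - (tau / 2) * sum_(a, b in edges) (x_a - x_b)^2`,
#' where `c` is the number of connected components of the adjacency graph
#' (the rank deficiency of the intrinsic precision).  On a disconnected
#' graph the density is invariant to per-component shifts; sum-to-zero is
#' enforced per component and the component count reported via a message.
#'
#' @param values numeric vector of effects.
#' @param edges two-column matrix/data.frame of edge indices (1-based) or
#'   ids matching `names(values)`.
#' @param precision positive CAR precision `tau`.
#' @return The unnormalized log density; attribute `quad` carries the
#'   pairwise-difference quadratic form.
#' @export
icar_logdensity <- function(values, edges, precision) {
  stopifnot(precision > 0)
  edges <- as.matrix(edges)
  if (!is.numeric(edges)) {
    if (is.null(names(values))) stop("id edges need named `values`")
    edges <- cbind(match(edges[, 1], names(values)),
                   match(edges[, 2], names(values)))
  }
  storage.mode(edges) <- "integer"
  n <- length(values)
  comp <- graph_components(n, edges)
  ncomp <- max(comp)
  if (ncomp > 1) {
    message("ICAR graph has ", ncomp, " connected components; ",
            "sum-to-zero applies per component")
  }
  for (cc in seq_len(ncomp)) {
    sel <- comp == cc
    values[sel] <- values[sel] - mean(values[sel])
  }
  q <- if (nrow(edges)) sum((values[edges[, 1]] - values[edges[, 2]])^2) else 0
  structure((n - ncomp) / 2 * log(precision) - precision / 2 * q,
            quad = q)
}

#' Closed-form Gamma full conditional for an ICAR / exchangeable precision
#'
#' With a Gamma(shape, scale) prior on the precision and a Gaussian
#' Markov random field of rank `n - c`, the full conditional is
#' Gamma(shape + (n - c) / 2, rate = 1/scale + quad/2) where `quad` is
#' the pairwise-difference quadratic form (or sum of squares for an
#' exchangeable effect, with `c = 0`).
#'
#' @param values effect vector.
#' @param edges edge matrix as in [icar_logdensity()], or `NULL` for an
#'   exchangeable (IID) effect.
#' @param prior_shape,prior_scale Gamma hyperprior parameters.
#' @return list with `shape` and `rate` of the Gamma full conditional.
#' @export
precision_fullcond <- function(values, edges = NULL, prior_shape = 2,
                               prior_scale = 1) {
  n <- length(values)
  if (is.null(edges)) {
    q <- sum(values^2)
    rank <- n
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
    comp <- graph_components(n, edges)
    q <- if (nrow(edges)) sum((values[edges[, 1]] - values[edges[, 2]])^2) else 0
    rank <- n - max(comp)
  }
  list(shape = prior_shape + rank / 2, rate = 1 / prior_scale + q / 2)
}

# ---- the Metropolis-within-Gibbs engine ------------------------------------

# Shared by sample_posterior() (gvs = NULL) and fit_gvs().
# gvs: list(candidates = character names among the combined coefficient
#           columns, pseudo_mean, pseudo_sd (optional pseudo-prior))
mcmc_engine <- function(panel, spec, gvs = NULL, chain_seed = NULL) {
  cells <- panel_cells(panel)
  n_i <- cells$n_i; n_k <- cells$n_k; n_j <- cells$n_j
  Yv <- cells$Y
  tract_of <- cells$tract_of; year_of <- cells$year_of
  county_of <- cells$county_of
  nkept <- length(Yv)

  # --- design ---
  miss1 <- setdiff(spec$tract_covariates, panel$x1_names)
  if (length(miss1)) stop("tract covariate(s) not in panel design: ",
                          paste(miss1, collapse = ", "))
  miss2 <- setdiff(spec$county_covariates, panel$x2_names)
  if (length(miss2)) stop("county covariate(s) not in panel design: ",
                          paste(miss2, collapse = ", "))
  X1 <- if (length(spec$tract_covariates)) {
    panel$X1[cells$keep, spec$tract_covariates, drop = FALSE]
  } else matrix(0, nkept, 0)
  X2cell <- if (length(spec$county_covariates)) {
    panel$X2[county_of, spec$county_covariates, drop = FALSE]
  } else matrix(0, nkept, 0)
  Xall <- cbind(X1, X2cell)
  coef_names <- c(spec$tract_covariates, spec$county_covariates)
  colnames(Xall) <- coef_names
  p <- ncol(Xall)
  block2 <- c(rep(FALSE, length(spec$tract_covariates)),
              rep(TRUE, length(spec$county_covariates)))

  # --- GVS bookkeeping ---
  is_cand <- rep(FALSE, p)
  if (!is.null(gvs)) {
    ci <- match(gvs$candidates, coef_names)
    if (anyNA(ci)) stop("GVS candidate(s) not in model covariates: ",
                        paste(gvs$candidates[is.na(ci)], collapse = ", "))
    is_cand[ci] <- TRUE
  }
  cand_idx <- which(is_cand)
  M <- length(cand_idx)
  if (p > 0) {
    # a constant candidate is legitimate (likelihood-free; phi mixes to
    # its prior), a constant forced column is a design error
    sds <- apply(Xall, 2, stats::sd)
    bad <- sds == 0 & !is_cand
    if (any(bad)) stop("zero-variance covariate column(s): ",
                       paste(coef_names[bad], collapse = ", "))
  }

  # --- adjacency structures ---
  use <- c(u = "u" %in% spec$effects, v = "v" %in% spec$effects,
           w = "w" %in% spec$effects, g = "g" %in% spec$effects)
  te <- cbind(match(panel$geo$tract_adjacency$id_a, panel$geo$tract_ids),
              match(panel$geo$tract_adjacency$id_b, panel$geo$tract_ids))
  storage.mode(te) <- "integer"
  ce <- cbind(match(panel$geo$county_adjacency$id_a, panel$geo$county_ids),
              match(panel$geo$county_adjacency$id_b, panel$geo$county_ids))
  storage.mode(ce) <- "integer"
  ge <- if (n_k > 1) cbind(seq_len(n_k - 1), 2:n_k) else
    matrix(integer(), 0, 2)

  setup_icar <- function(n, edges) {
    A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                              j = c(edges[, 2], edges[, 1]),
                              x = 1, dims = c(n, n))
    comp <- graph_components(n, edges)
    color <- graph_coloring(n, edges)
    list(A = A, deg = as.vector(Matrix::rowSums(A)),
         comp = comp, ncomp = max(comp),
         colors = split(seq_len(n), color), edges = edges)
  }
  icar_u <- if (use["u"]) setup_icar(n_i, te)
  icar_w <- if (use["w"]) setup_icar(n_j, ce)
  icar_g <- if (use["g"] && spec$g_type == "rw1") setup_icar(n_k, ge)

  # --- aggregates fixed over the run ---
  Ysum_t <- agg_sum(Yv, tract_of, n_i)
  Ysum_j <- agg_sum(Yv, county_of, n_j)
  Ysum_k <- agg_sum(Yv, year_of, n_k)
  sumY <- sum(Yv)
  Yx <- if (p > 0) as.vector(crossprod(Xall, Yv)) else numeric(0)

  # --- priors ---
  a0 <- spec$prior$tau_shape
  rate0 <- 1 / spec$prior$tau_scale
  prior_on_var <- identical(spec$prior$prior_on, "variance")
  alpha_prec <- spec$prior$alpha_prec

  mc <- spec$mcmc
  if (is.null(chain_seed)) chain_seed <- mc$seed
  S <- floor((mc$n_iter - mc$n_burnin) / mc$thin)
  if (S < 1) stop("no post-burn-in draws would be stored")

  # variance-reading precision update (non-conjugate): MH on log(tau)
  update_tau_var <- function(tau, rankq, q) {
    ltau <- log(tau)
    prop <- ltau + stats::rnorm(1, 0, 0.5)
    lp <- function(lt) {
      t <- exp(lt)
      rankq / 2 * lt - t * q / 2 + (-a0 - 1) * lt - rate0 / t + lt
    }
    if (log(stats::runif(1)) < lp(prop) - lp(ltau)) exp(prop) else tau
  }
  update_tau <- function(tau, rankq, q) {
    if (prior_on_var) update_tau_var(tau, rankq, q)
    else stats::rgamma(1, shape = a0 + rankq / 2, rate = rate0 + q / 2)
  }

  with_seed(chain_seed, {
    # --- state ---
    alpha <- log((sumY + 0.5) / sum(exp(cells$logE)))
    beta <- numeric(p)
    u <- numeric(n_i); v <- numeric(n_i); w <- numeric(n_j); g <- numeric(n_k)
    phi <- rep(1L, p)
    p_incl <- 0.5
    tau <- c(u = 1, v = 1, w = 1, g = 1, beta = 1)
    eta_re <- function() u[tract_of] + v[tract_of] + w[county_of] + g[year_of]
    xb <- function() if (p > 0) as.vector(Xall %*% (beta * phi)) else 0
    mu <- exp(cells$logE + alpha + eta_re() + xb())

    # --- proposal scales ---
    s_alpha <- 0.05
    s_beta <- rep(0.1, p)
    s_u <- rep(0.1, n_i); s_v <- rep(0.1, n_i)
    s_w <- rep(0.1, n_j); s_g <- rep(0.1, n_k)
    clamp <- function(s) pmin(pmax(s, 1e-3), 5)

    # --- storage ---
    st <- list(
      alpha = numeric(S),
      beta = matrix(0, S, p, dimnames = list(NULL, coef_names)),
      tau = matrix(0, S, 5, dimnames = list(NULL, names(tau))),
      u = matrix(0, S, n_i), v = matrix(0, S, n_i),
      w = matrix(0, S, n_j), g = matrix(0, S, n_k),
      phi = matrix(0L, S, M,
                   dimnames = list(NULL, coef_names[cand_idx])),
      p_incl = numeric(S),
      cell_loglik = matrix(0, S, nkept)
    )
    acc <- c(alpha = 0, beta = 0, u = 0, v = 0, w = 0, g = 0)
    acc_n <- c(alpha = 0, beta = 0, u = 0, v = 0, w = 0, g = 0)
    s_idx <- 0L

    for (iter in seq_len(mc$n_iter)) {
      adapting <- iter <= mc$n_burnin
      gam <- if (adapting) min(0.05, 2 / sqrt(iter)) else 0
      track <- !adapting

      # -- intercept --
      delta <- stats::rnorm(1, 0, s_alpha)
      logr <- delta * sumY - sum(mu) * (exp(delta) - 1) -
        alpha_prec / 2 * ((alpha + delta)^2 - alpha^2)
      ok <- log(stats::runif(1)) < logr
      if (ok) { alpha <- alpha + delta; mu <- mu * exp(delta) }
      if (adapting) s_alpha <- clamp(s_alpha * exp(gam * ((ok) - 0.4)))
      if (track) { acc["alpha"] <- acc["alpha"] + ok; acc_n["alpha"] <- acc_n["alpha"] + 1 }

      # -- coefficients (and pseudo-prior draws for excluded candidates) --
      if (p > 0) {
        for (m in seq_len(p)) {
          if (is_cand[m] && phi[m] == 0L) {
            pm <- if (!is.null(gvs$pseudo_mean)) gvs$pseudo_mean[[coef_names[m]]] else 0
            ps <- if (!is.null(gvs$pseudo_sd)) gvs$pseudo_sd[[coef_names[m]]] else
              1 / sqrt(tau["beta"])
            beta[m] <- stats::rnorm(1, pm, ps)
            next
          }
          x <- Xall[, m]
          delta <- stats::rnorm(1, 0, s_beta[m])
          efac <- exp(delta * x)
          logr <- delta * Yx[m] - sum(mu * (efac - 1)) -
            tau["beta"] / 2 * ((beta[m] + delta)^2 - beta[m]^2)
          ok <- log(stats::runif(1)) < logr
          if (ok) { beta[m] <- beta[m] + delta; mu <- mu * efac }
          if (adapting) s_beta[m] <- clamp(s_beta[m] * exp(gam * ((ok) - 0.4)))
          if (track) { acc["beta"] <- acc["beta"] + ok; acc_n["beta"] <- acc_n["beta"] + 1 }
        }
      }

      # -- entry parameters (all candidates, jointly each sweep) --
      if (M > 0) {
        lodds_p <- log(p_incl) - log1p(-p_incl)
        for (m in cand_idx) {
          x <- Xall[, m]; b <- beta[m]
          if (phi[m] == 1L) {
            mu0 <- mu * exp(-b * x)
            ll_diff <- b * Yx[m] - (sum(mu) - sum(mu0))
            if (stats::runif(1) >= stats::plogis(lodds_p + ll_diff)) {
              phi[m] <- 0L; mu <- mu0
            }
          } else {
            mu1 <- mu * exp(b * x)
            ll_diff <- b * Yx[m] - (sum(mu1) - sum(mu))
            if (stats::runif(1) < stats::plogis(lodds_p + ll_diff)) {
              phi[m] <- 1L; mu <- mu1
            }
          }
        }
        p_incl <- stats::rbeta(1, 0.5 + sum(phi[cand_idx]),
                               0.5 + M - sum(phi[cand_idx]))
      }

      # -- tract ICAR effect u (color-blocked Metropolis) --
      if (use["u"]) {
        musum_t <- agg_sum(mu, tract_of, n_i)
        for (sites in icar_u$colors) {
          s_nb <- as.vector(icar_u$A %*% u)[sites]
          delta <- stats::rnorm(length(sites), 0, s_u[sites])
          uo <- u[sites]
          logr <- Ysum_t[sites] * delta - musum_t[sites] * (exp(delta) - 1) -
            tau["u"] / 2 * (icar_u$deg[sites] * (2 * uo * delta + delta^2) -
                              2 * delta * s_nb)
          ok <- log(stats::runif(length(sites))) < logr
          if (any(ok)) {
            u[sites[ok]] <- uo[ok] + delta[ok]
            fac <- rep(1, n_i); fac[sites[ok]] <- exp(delta[ok])
            mu <- mu * fac[tract_of]
            musum_t[sites[ok]] <- musum_t[sites[ok]] * exp(delta[ok])
          }
          if (adapting) s_u[sites] <- clamp(s_u[sites] * exp(gam * (ok - 0.4)))
          if (track) { acc["u"] <- acc["u"] + sum(ok); acc_n["u"] <- acc_n["u"] + length(ok) }
        }
      }

      # -- exchangeable tract effect v (conditionally independent sites) --
      if (use["v"]) {
        musum_t <- agg_sum(mu, tract_of, n_i)
        delta <- stats::rnorm(n_i, 0, s_v)
        logr <- Ysum_t * delta - musum_t * (exp(delta) - 1) -
          tau["v"] / 2 * (2 * v * delta + delta^2)
        ok <- log(stats::runif(n_i)) < logr
        if (any(ok)) {
          v[ok] <- v[ok] + delta[ok]
          fac <- rep(1, n_i); fac[ok] <- exp(delta[ok])
          mu <- mu * fac[tract_of]
        }
        if (adapting) s_v <- clamp(s_v * exp(gam * (ok - 0.4)))
        if (track) { acc["v"] <- acc["v"] + sum(ok); acc_n["v"] <- acc_n["v"] + n_i }
      }

      # -- county ICAR effect w --
      if (use["w"]) {
        musum_j <- agg_sum(mu, county_of, n_j)
        for (sites in icar_w$colors) {
          s_nb <- as.vector(icar_w$A %*% w)[sites]
          delta <- stats::rnorm(length(sites), 0, s_w[sites])
          wo <- w[sites]
          logr <- Ysum_j[sites] * delta - musum_j[sites] * (exp(delta) - 1) -
            tau["w"] / 2 * (icar_w$deg[sites] * (2 * wo * delta + delta^2) -
                              2 * delta * s_nb)
          ok <- log(stats::runif(length(sites))) < logr
          if (any(ok)) {
            w[sites[ok]] <- wo[ok] + delta[ok]
            fac <- rep(1, n_j); fac[sites[ok]] <- exp(delta[ok])
            mu <- mu * fac[county_of]
            musum_j[sites[ok]] <- musum_j[sites[ok]] * exp(delta[ok])
          }
          if (adapting) s_w[sites] <- clamp(s_w[sites] * exp(gam * (ok - 0.4)))
          if (track) { acc["w"] <- acc["w"] + sum(ok); acc_n["w"] <- acc_n["w"] + length(ok) }
        }
      }

      # -- temporal trend g --
      if (use["g"]) {
        musum_k <- agg_sum(mu, year_of, n_k)
        if (spec$g_type == "rw1") {
          for (sites in icar_g$colors) {
            s_nb <- as.vector(icar_g$A %*% g)[sites]
            delta <- stats::rnorm(length(sites), 0, s_g[sites])
            go <- g[sites]
            logr <- Ysum_k[sites] * delta - musum_k[sites] * (exp(delta) - 1) -
              tau["g"] / 2 * (icar_g$deg[sites] * (2 * go * delta + delta^2) -
                                2 * delta * s_nb)
            ok <- log(stats::runif(length(sites))) < logr
            if (any(ok)) {
              g[sites[ok]] <- go[ok] + delta[ok]
              fac <- rep(1, n_k); fac[sites[ok]] <- exp(delta[ok])
              mu <- mu * fac[year_of]
              musum_k[sites[ok]] <- musum_k[sites[ok]] * exp(delta[ok])
            }
            if (adapting) s_g[sites] <- clamp(s_g[sites] * exp(gam * (ok - 0.4)))
            if (track) { acc["g"] <- acc["g"] + sum(ok); acc_n["g"] <- acc_n["g"] + length(ok) }
          }
        } else {
          delta <- stats::rnorm(n_k, 0, s_g)
          logr <- Ysum_k * delta - musum_k * (exp(delta) - 1) -
            tau["g"] / 2 * (2 * g * delta + delta^2)
          ok <- log(stats::runif(n_k)) < logr
          if (any(ok)) {
            g[ok] <- g[ok] + delta[ok]
            fac <- rep(1, n_k); fac[ok] <- exp(delta[ok])
            mu <- mu * fac[year_of]
          }
          if (adapting) s_g <- clamp(s_g * exp(gam * (ok - 0.4)))
          if (track) { acc["g"] <- acc["g"] + sum(ok); acc_n["g"] <- acc_n["g"] + n_k }
        }
      }

      # -- sum-to-zero re-centering, removed mean absorbed into alpha --
      if (use["u"]) {
        mg <- mean(u); alpha <- alpha + mg
        for (cc in seq_len(icar_u$ncomp)) {
          sel <- icar_u$comp == cc
          u[sel] <- u[sel] - mean(u[sel])
        }
        alpha <- alpha + mean(u)  # zero unless multi-component rounding
      }
      if (use["w"]) {
        mg <- mean(w); alpha <- alpha + mg
        for (cc in seq_len(icar_w$ncomp)) {
          sel <- icar_w$comp == cc
          w[sel] <- w[sel] - mean(w[sel])
        }
      }
      if (use["g"]) {
        mg <- mean(g); alpha <- alpha + mg; g <- g - mg
      }
      # per-component centering on a disconnected graph shifts alpha + u
      # within components; refresh mu so the state stays coherent
      if ((use["u"] && icar_u$ncomp > 1) || (use["w"] && icar_w$ncomp > 1)) {
        mu <- exp(cells$logE + alpha + eta_re() + xb())
      }

      # -- conjugate precision updates --
      if (use["u"]) {
        q <- sum((u[icar_u$edges[, 1]] - u[icar_u$edges[, 2]])^2)
        tau["u"] <- update_tau(tau["u"], n_i - icar_u$ncomp, q)
      }
      if (use["v"]) tau["v"] <- update_tau(tau["v"], n_i, sum(v^2))
      if (use["w"]) {
        q <- sum((w[icar_w$edges[, 1]] - w[icar_w$edges[, 2]])^2)
        tau["w"] <- update_tau(tau["w"], n_j - icar_w$ncomp, q)
      }
      if (use["g"]) {
        if (spec$g_type == "rw1") {
          tau["g"] <- update_tau(tau["g"], n_k - 1, sum(diff(g)^2))
        } else {
          tau["g"] <- update_tau(tau["g"], n_k, sum(g^2))
        }
      }
      if (p > 0) tau["beta"] <- update_tau(tau["beta"], p, sum(beta^2))

      # -- hygiene: refresh mu, check for divergence --
      if (iter %% 200 == 0 || iter == mc$n_iter) {
        mu <- exp(cells$logE + alpha + eta_re() + xb())
      }
      if (!is.finite(sum(mu))) {
        stop("posterior diverged (non-finite rate) at iteration ", iter)
      }

      # -- store --
      if (iter > mc$n_burnin && (iter - mc$n_burnin) %% mc$thin == 0) {
        s_idx <- s_idx + 1L
        st$alpha[s_idx] <- alpha
        if (p > 0) st$beta[s_idx, ] <- beta
        st$tau[s_idx, ] <- tau
        st$u[s_idx, ] <- u; st$v[s_idx, ] <- v
        st$w[s_idx, ] <- w; st$g[s_idx, ] <- g
        if (M > 0) { st$phi[s_idx, ] <- phi[cand_idx]; st$p_incl[s_idx] <- p_incl }
        st$cell_loglik[s_idx, ] <- stats::dpois(Yv, mu, log = TRUE)
      }
    }

    st$accept_rate <- ifelse(acc_n > 0, acc / acc_n, NA)
    st$cells <- cells[c("keep", "tract_of", "year_of", "n_i", "n_k", "n_j")]
    st$coef_names <- coef_names
    st$block2 <- block2
    st$seed <- chain_seed
    st
  })
}

#' Fit the hierarchical Poisson model by Metropolis-within-Gibbs
#'
#' Adaptive random-walk Metropolis updates for the intercept, coefficient
#' blocks and every random-effect vector (CAR effects updated in graph-
#' coloring blocks so sites within a block are conditionally independent),
#' conjugate Gamma updates for all precisions, and sum-to-zero
#' re-centering of `u`, `w` and `g` after every sweep with the removed
#' mean absorbed into the intercept.  Proposal scales adapt toward an
#' acceptance rate of about 0.4 during burn-in only, preserving detailed
#' balance afterwards.
#'
#' @param panel prepared `panel_data` (counts, expected counts, design).
#' @param spec a [model_spec()].
#' @return An object of class `bhm_samples`: per-iteration draws of the
#'   intercept, coefficients, random effects and precisions, per-cell
#'   log-likelihoods (for CPO/LPML), acceptance rates, convergence
#'   diagnostics (`rhat`, `ess`) and the seed/spec fingerprint.
#' @export
sample_posterior <- function(panel, spec) {
  stopifnot(inherits(panel, "panel_data"), inherits(spec, "bhm_spec"))
  chains <- lapply(seq_len(spec$mcmc$chains), function(ch) {
    mcmc_engine(panel, spec, gvs = NULL,
                chain_seed = spec$mcmc$seed + 1000L * (ch - 1L))
  })
  combine_chains(chains, spec)
}

combine_chains <- function(chains, spec, gvs = NULL) {
  S1 <- length(chains[[1]]$alpha)
  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  out <- list(
    alpha = unlist(lapply(chains, `[[`, "alpha")),
    beta = bind("beta"),
    tau = bind("tau"),
    u = bind("u"), v = bind("v"), w = bind("w"), g = bind("g"),
    phi = bind("phi"),
    p_incl = unlist(lapply(chains, `[[`, "p_incl")),
    cell_loglik = bind("cell_loglik"),
    chain = rep(seq_along(chains), each = S1),
    accept_rate = chains[[1]]$accept_rate,
    cells = chains[[1]]$cells,
    coef_names = chains[[1]]$coef_names,
    block2 = chains[[1]]$block2,
    spec = spec,
    gvs = gvs,
    seed = spec$mcmc$seed
  )
  # convergence diagnostics on the chain-level scalar parameters
  per_chain <- function(getter) lapply(chains, getter)
  diag_params <- c(list(alpha = per_chain(function(c) c$alpha)),
                   if (ncol(out$beta) > 0)
                     stats::setNames(lapply(seq_len(ncol(out$beta)), function(m)
                       per_chain(function(c) c$beta[, m])), colnames(out$beta)))
  out$rhat <- vapply(diag_params, split_rhat, 0)
  out$ess <- vapply(diag_params, function(ch)
    sum(vapply(ch, effective_size, 0)), 0)
  high <- out$rhat[!is.na(out$rhat) & out$rhat > 1.05]
  if (length(high)) {
    warning("potential scale reduction above 1.05 for: ",
            paste(names(high), collapse = ", "))
  }
  class(out) <- "bhm_samples"
  out
}

#' @export
print.bhm_samples <- function(x, ...) {
  cat("<bhm_samples>", length(x$alpha), "draws,",
      length(unique(x$chain)), "chain(s),",
      length(x$coef_names), "coefficients\n")
  invisible(x)
}

#' Posterior summary table
#'
#' @param object a `bhm_samples`.
#' @param ... unused.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5` for the intercept, coefficients and precisions (matching the
#'   usual reporting of coefficient estimate, standard deviation and 95%
#'   credible interval).
#' @export
summary.bhm_samples <- function(object, ...) {
  draws <- cbind(alpha = object$alpha, object$beta, object$tau)
  tau_cols <- (ncol(draws) - ncol(object$tau) + 1):ncol(draws)
  colnames(draws)[tau_cols] <- paste0("tau_", colnames(object$tau))
  qs <- t(apply(draws, 2, stats::quantile, c(0.025, 0.975)))
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             q2.5 = qs[, 1], q97.5 = qs[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export posterior draws / summaries as CSV
#'
#' @param samples a `bhm_samples`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_posterior_summary <- function(samples, path) {
  utils::write.csv(summary(samples), path, row.names = FALSE)
  invisible(path)
}

# ---- CPO / LPML ------------------------------------------------------------

#' Conditional predictive ordinates and LPML
#'
#' CPO for each modeled tract-year via the harmonic-mean identity
#' `CPO_ik = [ (1/S) sum_s 1 / f(Y_ik | theta_ik^(s)) ]^(-1)`, computed in
#' log space with a stable log-sum-exp.  The model-fit scalar is computed
#' from average annual CPO values per census tract:
#' `LPML = sum_i log( (1/K) sum_k CPO_ik )` (method `"tract_annual"`,
#' the default).  Alternatives: `"annual_sum"` averages the yearly sums of
#' log CPO over years, and `"cellwise"` is the conventional
#' `sum_ik log CPO_ik`.  Less-negative LPML indicates better
#' cross-validated fit; LPML values are comparable only across models fit
#' to the same dataset.
#'
#' @param panel the prepared `panel_data` the samples were fit to.
#' @param samples a `bhm_samples` with at least 100 stored draws.
#' @param method LPML aggregation rule (see above).
#' @return An object of class `bhm_fitstats`: list with `cpo` (tracts x
#'   years matrix, `NA` for excluded cells), `cpo_tract` (tract-averaged
#'   CPO), `lpml`, and `method`.
#' @export
compute_cpo_lpml <- function(panel, samples,
                             method = c("tract_annual", "annual_sum",
                                        "cellwise")) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "bhm_samples"))
  S <- nrow(samples$cell_loglik)
  if (S < 100) stop("need at least 100 post-burn-in draws for CPO (have ",
                    S, ")")
  ll <- samples$cell_loglik
  # log CPO = -log mean exp(-loglik), column-wise, stable
  neg <- -ll
  mx <- apply(neg, 2, max)
  logcpo <- -(mx + log(colMeans(exp(sweep(neg, 2, mx)))))
  if (any(!is.finite(logcpo))) {
    warning(sum(!is.finite(logcpo)), " CPO value(s) underflowed")
  }
  cells <- samples$cells
  cpo <- matrix(NA_real_, cells$n_i, cells$n_k,
                dimnames = dimnames(panel$Y))
  cpo[cbind(cells$tract_of, cells$year_of)] <- exp(logcpo)
  active <- rowSums(!is.na(cpo)) > 0
  cpo_tract <- rowMeans(cpo, na.rm = TRUE)
  lpml <- switch(method,
    tract_annual = sum(log(cpo_tract[active])),
    annual_sum = mean(colSums(log(cpo), na.rm = TRUE)),
    cellwise = sum(log(cpo), na.rm = TRUE)
  )
  structure(list(cpo = cpo, cpo_tract = cpo_tract, lpml = lpml,
                 method = method), class = "bhm_fitstats")
}

#' @export
print.bhm_fitstats <- function(x, ...) {
  cat("<bhm_fitstats> LPML =", format(x$lpml, digits = 6),
      "(", x$method, ")\n")
  invisible(x)
}

#' Fit several model specifications and rank them by LPML
#'
#' Fits each specification to the same panel with the same seed policy
#' and returns the within-dataset LPML ladder, ranked from best
#' (least-negative) to worst.  LPML values are meaningful only within a
#' dataset; never compare across datasets.
#'
#' @param panel prepared `panel_data`.
#' @param specs named list of [model_spec()] objects (>= 2).
#' @param method LPML aggregation rule, see [compute_cpo_lpml()].
#' @return data.frame (`model`, `lpml`, `rank`, `failed`), best first;
#'   the fitted samples are attached as attribute `fits`.
#' @export
compare_models <- function(panel, specs, method = "tract_annual") {
  stopifnot(length(specs) >= 2)
  if (is.null(names(specs))) names(specs) <- paste0("model", seq_along(specs))
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  lpml <- rep(NA_real_, length(specs))
  failed <- rep(FALSE, length(specs))
  for (ii in seq_along(specs)) {
    res <- tryCatch({
      fit <- sample_posterior(panel, specs[[ii]])
      list(fit = fit,
           lpml = compute_cpo_lpml(panel, fit, method = method)$lpml)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[ii] <- TRUE
      warning("model `", names(specs)[ii], "` failed: ",
              conditionMessage(res))
    } else {
      fits[[ii]] <- res$fit
      lpml[ii] <- res$lpml
    }
  }
  out <- data.frame(model = names(specs), lpml = lpml,
                    failed = failed, stringsAsFactors = FALSE)
  out <- out[order(-out$lpml, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
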
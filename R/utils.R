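# Internal numerical and RNG utilities.

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring
# the caller's stream afterwards.  All package randomness flows through
# this so that library calls never perturb user RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Connected components of an undirected graph given as an integer edge
# matrix (2 columns) over nodes 1..n.  Returns integer component labels.
graph_components <- function(n, edges) {
  comp <- integer(n)
  if (n == 0) return(comp)
  nbr <- vector("list", n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in nbr[[v]]) {
        if (comp[u] == 0L) {
          comp[u] <- cur
          queue <- c(queue, u)
        }
      }
    }
  }
  comp
}

# Greedy proper coloring (largest-degree-first).  Nodes sharing a color
# have no edge between them, so their full conditionals are independent
# given the rest and can be Metropolis-updated in one vectorized step.
graph_coloring <- function(n, edges) {
  if (n == 0) return(integer(0))
  nbr <- vector("list", n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      nbr[[a]] <- c(nbr[[a]], b)
      nbr[[b]] <- c(nbr[[b]], a)
    }
  }
  deg <- lengths(nbr)
  color <- integer(n)
  for (v in order(-deg)) {
    used <- color[nbr[[v]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    color[v] <- k
  }
  color
}

# Effective sample size via the initial positive sequence of
# autocovariances (Geyer-style truncation on paired sums).
effective_size <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(n)
  acf_est <- stats::acf(x, lag.max = min(n - 2, 500), plot = FALSE,
                        demean = TRUE)$acf[, 1, 1]
  rho <- acf_est[-1]
  npair <- floor(length(rho) / 2)
  s <- 0
  for (m in seq_len(npair)) {
    pair <- rho[2 * m - 1] + rho[2 * m]
    if (pair < 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

# Split-half potential scale reduction factor for a single chain (or
# stacked chains given as a list of vectors).
split_rhat <- function(x) {
  chains <- if (is.list(x)) x else list(x)
  halves <- unlist(lapply(chains, function(v) {
    n <- floor(length(v) / 2)
    list(v[seq_len(n)], v[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt((n - 1) / n + B / (n * W))
}
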
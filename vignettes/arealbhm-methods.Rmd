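---
title: "Methods: geographic identifier assignment and the spatio-temporal hierarchical model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geographic identifier assignment and the spatio-temporal hierarchical model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arealbhm)
```

# The problem

Ecologic health studies aggregate record-level events (here:
emergency-department visits) to small areas — census tracts — to relate
annual visit risk to neighborhood conditions.  Administrative records,
however, often carry only a coarser, spatially misaligned unit (the ZIP
code of the billing address) for a sizable minority of records, because
non-standard address structures defeat tract-level geocoding.  Such
failures are concentrated in rural areas, so the two conventional
escapes — dropping incomplete records, or scaling the whole analysis up
to ZIP codes or counties — either bias the study against rural
subpopulations or destroy the neighborhood resolution the study exists
for.  `arealbhm` instead keeps every record by assigning a tract
stochastically from what is known (the ZIP), and propagates that
choice through a hierarchical model designed to be robust to
tract-level assignment error.

# The assignment algorithm

For each ZIP `z` and overlapping tract `t`, a crosswalk stores the
proportion

* **areal mode**: `p(t | z) = overlap(t, z) / sum_t' overlap(t', z)`;
* **population mode**: `w(t, z) = pop(t) * overlap(t, z) / area(t)`
  (the population of the overlapped piece under uniform density),
  normalized within `z`.

Entries are ordered by descending proportion, ties broken by ascending
tract id, and cumulated.  The ordering rule makes the crosswalk a pure
function of the geography and mode, so saved crosswalks are replicable
byte for byte.  Each record with a known ZIP and missing tract draws
`r ~ Uniform[0, 1)` from a stream seeded per dataset and consumed in
input record order; the half-open interval `[c_(m-1), c_m)` containing
`r` determines the tract.  Half-open intervals with `r < 1` make the
assignment exhaustive and non-overlapping without edge cases.

Areal weighting is the primary mode: census tract area is inversely
related to population density, so area-proportional assignment sends
more imputed records to large rural tracts, matching the rural tilt of
the missingness mechanism.  Population weighting — the natural
alternative — systematically routes records to dense urban tracts and
serves as a sensitivity contrast.  Records with neither a valid ZIP nor
a tract cannot be assigned; they are dropped with a logged count (never
silently).  A ZIP that appears on a record but not in the crosswalk is
a hard error: crosswalk completeness is a data-integrity requirement.

Because the assignment is stochastic, the package fits every
downstream analysis on several replicate assignment datasets (seeds
`base, base + 1, ...`) and reports consistency across them, rather than
pooling as in covariate multiple imputation — the identifier is the
*basis of the outcome counts*, not a covariate, and refitting a full
selection model per replicate is the honest (if costly) propagation.

# Panel construction

Records are aggregated to tract-by-year counts `Y[i, k]`, zero-filled
over the full grid.  Expected counts use internal standardization:
`E_i = rate * pop_i` with the region-wide average annual rate pooled
over all study years.  A time-invariant `E_i` is the default because a
stabilized offset is preferable for space-time data; an annual variant
(`rate_k` per year) is available for sensitivity.  Tracts with zero
population get `E = 0` and are excluded from the likelihood with a loud
warning — they carry no information and would otherwise force infinite
relative risks.

Two derived covariates matter:

* `propmiss`: per tract, the average over years of the fraction of that
  tract-year's records whose identifier was imputed.  Empty tract-years
  contribute zero, making it an average *annual* proportion over the
  fixed year grid.  It is identically zero on complete-case data and is
  therefore omitted from complete-case designs.
* interactions: products of the two **centered** parents, named
  `"A:B"`.  Centering before interacting is deliberate — the two orders
  differ, and centered parents keep main effects interpretable at
  average covariate levels.  Interactions without both parents as main
  effects are rejected (hierarchy rule).

All design columns are mean-centered over the modeled tract-years;
county-level columns are centered with tract-year weights so the full
design has zero column means.

# The hierarchical model

```
Y_ik ~ Poisson(mu_ik),  mu_ik = E_i * theta_ik
log(theta_ik) = alpha + u_i + v_i + w_j + g_k + beta1' X_ik + beta2' X_j
```

* `u` — intrinsic CAR (Besag) on the binary tract adjacency: the
  conditional prior of `u_i` is normal around the mean of its
  neighbors.  Together with the exchangeable `v` this is the standard
  BYM convolution.  The smoothing in `u` is also what makes the
  workflow robust to assignment error: a record imputed to the wrong
  tract *within its ZIP* lands in a spatially adjacent tract, and the
  smoothed field absorbs the small miss.
* `w` — intrinsic CAR on the county adjacency, absorbing unmeasured
  confounding at the coarser administrative scale.
* `g` — temporal trend.  The default is a first-order random walk
  (adjacent years similar); exchangeable year effects are available via
  `g_type = "iid"` since either reading of "a temporal trend effect" is
  defensible, and the choice is left to the analyst.
* Coefficients have zero-centered normal priors with a shared precision
  `tau_beta`; all precisions (`tau_u`, `tau_v`, `tau_w`, `tau_g`,
  `tau_beta`) carry Gamma(shape 2, scale 1) hyperpriors **on the
  precision scale** (mean 2, weakly informative).  A configuration
  switch `prior_on = "variance"` instead interprets the Gamma as a
  prior on the variance; that reading loses conjugacy and is sampled by
  a Metropolis step on `log(tau)`.
* The intercept has a fixed diffuse normal prior (precision `1e-3`,
  i.e. sd ≈ 31.6 on the log-risk scale) — proper, so degenerate
  single-cell posteriors used in oracle checks are well defined.

Intrinsic CAR priors are improper along constant shifts, and any
constant can move between `alpha`, `u`, `w` and `g` without changing
the likelihood.  Identifiability is imposed by sum-to-zero re-centering
of `u`, `w` and `g` after every sweep, with the removed mean absorbed
into the intercept (on a disconnected adjacency graph the centering is
per component and the rate vector is refreshed afterwards).

## Sampler

Inference is adaptive Metropolis-within-Gibbs:

* scalar random-walk updates for the intercept and each coefficient;
* random-effect vectors updated in *graph-coloring blocks*: a proper
  coloring of the adjacency graph partitions sites into classes with no
  internal edges, so within a class the full conditionals are mutually
  independent given the rest and an entire class is proposed, accepted
  and rejected as one vectorized step.  This gives single-site
  Metropolis semantics at vectorized cost (a rook-grid tract graph
  needs 2 colors; the county band graph 2; the year chain 2);
* conjugate Gamma draws for every precision, with shape
  `prior_shape + (n - c)/2` (rank of the intrinsic precision, `c` =
  number of graph components) and rate `1/prior_scale + quad/2`;
* proposal scales adapt by Robbins–Monro toward an acceptance rate of
  about 0.4 **during burn-in only**, so the post-burn-in kernel is
  fixed and detailed balance holds for every stored draw;
* the rate vector `mu` is maintained incrementally (each accepted block
  multiplies the affected cells by `exp(delta)`) and refreshed from the
  state every 200 sweeps to stop floating-point drift; a non-finite
  posterior aborts with the iteration number.

Split-chain potential scale reduction and effective sample sizes are
computed for the scalar parameters; values above 1.05 warn (never
hard-fail).  The slowly mixing component is typically the intercept,
which trades off against the random-effect levels; chains of a few
thousand sweeps suffice for coefficients, while intercept-focused
summaries warrant longer runs or multiple chains.

## Model fit: CPO and LPML

The conditional predictive ordinate of a cell is estimated from `S`
posterior draws by the harmonic-mean identity
`CPO_ik = [ (1/S) sum_s 1/f(Y_ik | theta_ik^(s)) ]^(-1)`, computed in
log space with log-sum-exp.  The package's headline fit statistic
aggregates by **average annual CPO per tract**:
`LPML = sum_i log( (1/K) sum_k CPO_ik )`.  Two alternatives are
offered by flag — the conventional `sum_ik log CPO_ik` and the mean
over years of within-year sums — because the tract-annual rule is one
of two defensible readings of "average annual CPO per census tract";
the package commits to the tract-average form and exposes the others.
LPML is comparable only across models fit to the *same* dataset;
`compare_models()` therefore never ranks across datasets.

# Gibbs variable selection

Selection uses entry parameters in the Kuo–Mallick form: the linear
predictor carries `phi_m * beta_m * x_m` with `phi_m ∈ {0, 1}`.  Each
sweep updates every `phi_m` from its Bernoulli full conditional (the
likelihood ratio of the included vs excluded predictor times the prior
odds `p/(1-p)`), draws `beta_m` for excluded candidates from the
pseudo-prior, and updates the shared inclusion probability conjugately,
`p | phi ~ Beta(0.5 + sum(phi), 0.5 + M - sum(phi))`.  All candidates
are updated at every sweep — an all-at-once scheme, deliberately not
stepwise, so partial models never generate omitted-variable confounding
during selection, and the shared `p` shrinks adaptively with the number
of null candidates (automatic multiplicity adjustment).

The pseudo-prior defaults to the coefficient prior
`N(0, 1/tau_beta)` — the simplest scheme consistent with entry
parameters.  When candidates are strong and the prior is too diffuse
for good flip rates, a tuned pseudo-prior (mean/sd per candidate, e.g.
from a pilot run) can be supplied.  `phi` starts at all-ones: burn-in
from the full model explores the joint space symmetrically.  Forced-in
columns (demographic and weather controls, any main effect kept for
interpretability) carry no `phi`.

Decision rules: a candidate is selected when its posterior mean `phi`
strictly exceeds 0.5; across replicate assignment datasets the final
roster keeps candidates selected in strictly more than half of the
replicates.  Both rules are strict majorities, so the pipeline's final
selection is invariant to dataset ordering.  The final model adds the
parent main effects of any selected interaction even if not themselves
selected.

Degenerate candidates are tolerated by design: a constant (zero
after centering) candidate contributes no likelihood, its `phi`
mixes to the prior mean 0.5, and it is correctly not selected; a
constant *forced* column, by contrast, is a design error and rejected
before sampling.

# The synthetic generator

The generator emulates the structure of the motivating data so every
stage is testable without restricted records:

* **Geography** — rectangular tracts tiling one region: an urban block
  of small cells and a rural block of larger cells (default 1 km vs
  3 km, 156 + 44 = 200 tracts), so tract area is inversely proportional
  to population density (populations are drawn around a common mean of
  1000 irrespective of area).  ZIP rectangles sit on a grid offset by
  half a cell and clipped to the region, so they tile it exactly and
  most ZIPs straddle several tracts; overlaps are exact rectangle
  intersections, which provides genuine misalignment without polygon
  clipping.  Counties are contiguous vertical bands; adjacency is rook.
* **Risks** — covariates with exchangeable pairwise correlation 0.3,
  optionally loaded on standardized log tract area to create
  urban/rural gradients; random effects drawn from the model's own
  families (`u`, `w` intrinsic CAR via the Laplacian eigenbasis,
  scaled to a target realized sd; `v` IID; `g` a centered random walk);
  baseline rate 0.01 events per person-year (about 10 events per
  tract-year), 10 study years.  Default effects: three covariates at
  magnitude 0.4 on the log scale, seven null.
* **Records** — one row per Poisson event carrying the true tract, a
  ZIP drawn proportionally to the tract's overlap with the ZIPs
  covering it, and categorical attributes (race, sex, age, payor,
  facility urbanicity) from urbanicity-dependent distributions, so
  missing-vs-complete stratifications show realistic gradients.
* **Missingness** — each record loses its tract with probability
  `plogis(a + b * area)`; the defaults (`a = -2.23`, `b = 0.234`) give
  about 12% missing in 1-km² urban tracts and 47% in 9-km² rural
  tracts, about 20% overall, with 4% of records additionally losing
  the ZIP.  Missingness depends on geography only — a
  missing-at-random-given-geography stance — not on the outcome; the
  logistic-in-area form is a modeling choice for testing, not a claim
  about any real dataset.  The pre-deletion tract is kept in a hidden
  audit column (`.true_tract`) for validation only; no analysis
  operation reads it.

What the generator does *not* emulate: real street-network address
error, ZIP boundary instability over time (one geometry is frozen, as
an analysis would freeze one tract vintage), outcome-dependent
missingness, and within-tract population heterogeneity.  Passing tests
therefore demonstrate correctness of the algorithms under a known,
well-behaved mechanism — not robustness to every failure mode of real
administrative data.

# Verification design and problem sizes

The test suite pairs every non-trivial computation with an independent
oracle: assignment frequencies against crosswalk proportions
(total-variation distance and chi-square goodness of fit), the sampler
against 1-D grid quadrature on a degenerate single-cell model, the
harmonic-mean LPML against brute-force leave-one-out quadrature on a
six-cell panel, precision and inclusion-probability full conditionals
against enumerated closed forms, and the ICAR density against its
dense-matrix quadratic form.  Statistical operating characteristics
are checked at sizes chosen to finish in minutes: selection at the
default 200 tracts × 10 years over five replicates; coverage on twenty
72-tract × 5-year simulations at reduced chain length (1500 sweeps);
and the complete-case-vs-imputation bias contrast on ten replicates
with a rural-loaded effect of +0.4 — complete-case fits attenuate it
because deleting rural records deflates rural counts relative to their
expecteds, while areal imputation keeps the records and the estimate
near truth.

# Known limitations

* Individual-level covariates cannot enter the tract-aggregated Poisson
  likelihood; attribute stratifications are descriptive only.
* The harmonic-mean CPO estimator is noisy for extreme cells; CPO
  underflow is flagged, and cells with `E = 0` are excluded rather than
  stabilized.
* Single-chain default: `mcmc_settings(chains = 2)` is recommended for
  publication-grade diagnostics.
* LPML values are never comparable across datasets (different record
  sets change the likelihood's support); the pipeline enforces this by
  reporting per-dataset ladders only.
* The intrinsic CAR is used with binary rook adjacency; irregular
  real-world adjacencies (islands) are handled by per-component
  centering, but alternative weight schemes are not implemented.
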
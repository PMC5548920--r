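# Synthetic benchmark generator: ground-truth phosphorylation-cascade
# estimation problems, arbitrary-unit noisy data with replicate gains,
# and manifold-structured estimate clouds.  These emulate the *shape* of
# the published test problems (observables x free parameters 1x10, 8x10,
# 8x74; two stimulus conditions; 38 or 112 data points; normalisation by
# average) without reproducing the original models or data.

#' Benchmark specification
#'
#' @param n_tiers cascade depth (one active form per tier).
#' @param n_observables number of observables; each is the sum of the
#'   active forms of a contiguous block of tiers.
#' @param p_free number of kinetic parameters flagged free (the rest are
#'   fixed at their true values).
#' @param n_conditions 2 (high/low stimulus dose) or 3 (adds a
#'   knock-down of the tier-1 total).
#' @param n_replicates replicates per measured point, each with its own
#'   arbitrary-unit gain.
#' @param n_times measurement times per condition (uniform grid on
#'   `[0, t_end]`).
#' @param t_end end of the measurement window (model time units).
#' @param noise error-model pair `c(s_a, s_b)`; `c(0, 0)` is noiseless.
#' @param replicate_gain_range range the per-(observable, replicate)
#'   arbitrary-unit gains are drawn from.
#' @param feedback include a negative feedback from the last tier onto
#'   the tier-1 activation.
#' @param bound_decades half-width (in decades) of the search box around
#'   the true values.  The benchmark default of 1.5 decades either side
#'   models the order-of-magnitude prior knowledge a modeller typically
#'   has about rate constants, and keeps the ground-truth basin
#'   reachable by a small number of restarts; the general-purpose
#'   problem default ([ode_problem()]) remains 3 decades.
#' @param seed integer seed; all randomness (parameter draw, gains,
#'   noise) flows from it through named streams.
#' @export
benchmark_spec <- function(n_tiers = 5L, n_observables = 1L, p_free = 10L,
                           n_conditions = 2L, n_replicates = 1L,
                           n_times = 19L, t_end = 20,
                           noise = c(0, 0),
                           replicate_gain_range = c(0.5, 2),
                           feedback = FALSE, bound_decades = 1.5,
                           seed = 1L) {
  stopifnot(n_tiers >= 1L, n_observables >= 1L, n_observables <= n_tiers,
            n_conditions %in% 2:3, n_replicates >= 1L, n_times >= 2L,
            all(replicate_gain_range > 0), length(noise) == 2L,
            all(noise >= 0))
  kin_total <- 3L * n_tiers + feedback
  if (p_free > kin_total)
    stop("p_free (", p_free, ") exceeds the ", kin_total,
         " kinetic parameters of a ", n_tiers, "-tier cascade",
         call. = FALSE)
  structure(list(n_tiers = as.integer(n_tiers),
                 n_observables = as.integer(n_observables),
                 p_free = as.integer(p_free),
                 n_conditions = as.integer(n_conditions),
                 n_replicates = as.integer(n_replicates),
                 n_times = as.integer(n_times), t_end = t_end,
                 noise = noise,
                 replicate_gain_range = replicate_gain_range,
                 feedback = feedback, bound_decades = bound_decades,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Named benchmark presets
#'
#' Presets sized after the published test-problem shapes:
#' `"styx-like"` (1 observable, 10 free parameters, 38 data points),
#' `"egfhrg-small"` (8 observables, 10 free, 112 points) and
#' `"egfhrg-large"` (8 observables, 74 free, 112 points).  Two stimulus
#' conditions and normalisation by average throughout.  The default data
#' are noiseless with arbitrary replicate gains (the ground-truth
#' recovery setting); pass `noise` to add measurement error.
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param noise,n_replicates overrides forwarded to [benchmark_spec()].
#' @export
benchmark_preset <- function(name = c("styx-like", "egfhrg-small",
                                      "egfhrg-large"),
                             seed = 1L, noise = c(0, 0),
                             n_replicates = 1L) {
  name <- match.arg(name)
  switch(name,
    "styx-like" = benchmark_spec(n_tiers = 5L, n_observables = 1L,
                                 p_free = 10L, n_times = 19L,
                                 noise = noise, n_replicates = n_replicates,
                                 seed = seed),
    "egfhrg-small" = benchmark_spec(n_tiers = 8L, n_observables = 8L,
                                    p_free = 10L, n_times = 7L,
                                    noise = noise,
                                    n_replicates = n_replicates,
                                    seed = seed),
    "egfhrg-large" = benchmark_spec(n_tiers = 25L, n_observables = 8L,
                                    p_free = 74L, n_times = 7L,
                                    noise = noise,
                                    n_replicates = n_replicates,
                                    seed = seed))
}

# Ordering of the kinetic parameters used when flagging the first p_free
# as free: kact_1, kdeg_1, km_1, kact_2, ... so the free set spans tiers.
cascade_param_order <- function(n_tiers, feedback) {
  base <- as.vector(t(cbind(paste0("kact_", seq_len(n_tiers)),
                            paste0("kdeg_", seq_len(n_tiers)),
                            paste0("km_", seq_len(n_tiers)))))
  if (feedback) c(base, "kfb") else base
}

#' Build a ground-truth cascade estimation problem
#'
#' Constructs a phosphorylation cascade: tier 1 is activated by the
#' stimulus, every later tier by the active form of the tier above, each
#' with Michaelis-Menten activation kinetics and first-order
#' deactivation:
#' `da_i/dt = kact_i * u_i * (tot_i - a_i) / (km_i + tot_i - a_i)
#'  - kdeg_i * a_i`, where `u_1` is the stimulus dose (divided by
#' `1 + kfb * a_T` if the negative feedback is enabled) and
#' `u_i = a_(i-1)` downstream.  True kinetic constants are drawn
#' log-uniformly from tier-realistic ranges (kact in `[0.5, 2]`, km in
#' `[0.2, 1]`, kdeg in `[0.1, 0.5]`, totals fixed at 1).  Conditions are
#' a high dose (1) and a low dose (0.25), plus optionally a knock-down
#' that scales the tier-1 total to 0.2.  Observables are sums of the
#' active forms of contiguous tier blocks; measurement data are
#' generated at `theta_true` via [generate_data()].
#'
#' @param spec a [benchmark_spec()].
#' @return list with `problem` (an [ode_problem()]) and `truth` (list
#'   with `theta_true`, `gains`, `seed`).
#' @export
make_cascade_problem <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  T_ <- spec$n_tiers
  set.seed(spec$seed)  # stream 1: true parameter draw
  kact <- 10^stats::runif(T_, log10(0.5), log10(2))
  km <- 10^stats::runif(T_, log10(0.2), log10(1))
  kdeg <- 10^stats::runif(T_, log10(0.1), log10(0.5))
  params <- c(stats::setNames(kact, paste0("kact_", seq_len(T_))),
              stats::setNames(km, paste0("km_", seq_len(T_))),
              stats::setNames(kdeg, paste0("kdeg_", seq_len(T_))),
              stats::setNames(rep(1, T_), paste0("tot_", seq_len(T_))),
              stim = 1)
  if (spec$feedback) params <- c(params, kfb = 2)
  states <- stats::setNames(rep(0, T_), paste0("a_", seq_len(T_)))
  input1 <- if (spec$feedback)
    sprintf("stim / (1 + kfb * a_%d)", T_) else "stim"
  rhs <- character(T_)
  for (i in seq_len(T_)) {
    up <- if (i == 1L) input1 else sprintf("a_%d", i - 1L)
    rhs[i] <- sprintf(
      "kact_%d * (%s) * (tot_%d - a_%d) / (km_%d + tot_%d - a_%d) - kdeg_%d * a_%d",
      i, up, i, i, i, i, i, i, i)
  }
  names(rhs) <- names(states)
  # observables: contiguous tier blocks
  blocks <- split(seq_len(T_), sort(rep_len(seq_len(spec$n_observables), T_)))
  observables <- vapply(seq_along(blocks), function(j)
    paste(paste0("a_", blocks[[j]]), collapse = " + "), character(1L))
  names(observables) <- sprintf("obs%d", seq_along(blocks))
  model <- ode_model(states, params, rhs, observables,
                     name = sprintf("cascade-%d-%d", spec$n_observables,
                                    spec$p_free))
  conds <- list(condition("high", c(stim = 1)),
                condition("low", c(stim = 0.25)))
  if (spec$n_conditions == 3L)
    conds <- c(conds, list(condition("knockdown",
                                     c(stim = 1, tot_1 = 0.2))))
  free <- cascade_param_order(T_, spec$feedback)[seq_len(spec$p_free)]
  truth <- list(theta_true = params, seed = spec$seed, gains = NULL)
  # design grid; values filled in by generate_data
  times <- seq(0, spec$t_end, length.out = spec$n_times)
  grid <- expand.grid(
    time = times,
    condition = vapply(conds, `[[`, character(1L), "name"),
    observable = names(observables),
    replicate = sprintf("r%d", seq_len(spec$n_replicates)),
    stringsAsFactors = FALSE)
  grid$value <- 1
  ds0 <- dataset(grid, normalization_spec("average"), normalized = FALSE)
  nom <- params[free]
  bounds <- cbind(lower = nom / 10^spec$bound_decades,
                  upper = nom * 10^spec$bound_decades)
  problem <- ode_problem(model, conds, ds0, free, bounds)
  gen <- generate_data(problem, truth, spec)
  problem$data <- gen$data
  truth$gains <- gen$gains
  list(problem = problem, truth = truth)
}

#' Generate arbitrary-unit data from a ground truth
#'
#' Simulates the problem at `theta_true` on the design grid of the
#' problem's dataset and emits `y_hat = g_r * y * (1 + eps)`, where
#' `g_r` is a per-(observable, replicate) gain drawn log-uniformly from
#' `replicate_gain_range` (emulating arbitrary assay units) and `eps` is
#' Gaussian with standard deviation `(s_a + s_b * y) / max(y, tiny)`, so
#' the absolute/proportional split of the error matches the LL error
#' model.  Noiseless when `s_a = s_b = 0`.
#'
#' @param problem an [ode_problem()] whose dataset supplies the design
#'   grid (condition, observable, time, replicate).
#' @param truth list with `theta_true`.
#' @param spec the [benchmark_spec()] (gains, noise, seed).
#' @return list with `data` (a raw `sysbio_dataset`) and `gains`.
#' @export
generate_data <- function(problem, truth, spec) {
  ds <- problem$data
  sim <- make_simulator(problem)
  y <- sim(truth$theta_true)$y
  gkey <- paste(ds$observable, ds$replicate, sep = "\r")
  groups <- unique(gkey)
  set.seed(spec$seed + 1000L)  # stream 2: replicate gains
  g <- 10^stats::runif(length(groups),
                       log10(spec$replicate_gain_range[1]),
                       log10(spec$replicate_gain_range[2]))
  names(g) <- groups
  gains <- g[gkey]
  set.seed(spec$seed + 2000L)  # stream 3: measurement noise
  s_a <- spec$noise[1]; s_b <- spec$noise[2]
  eps <- if (s_a == 0 && s_b == 0) rep(0, length(y)) else
    stats::rnorm(length(y), 0, (s_a + s_b * y) / pmax(y, 1e-12))
  out <- ds
  out$value <- gains * y * (1 + eps)
  attr(out, "normalized") <- FALSE
  list(data = out, gains = stats::setNames(unname(g), gsub("\r", "/", groups)))
}

#' Generate a manifold-structured estimate cloud
#'
#' Samples `n` points on a `k`-dimensional affine manifold embedded in
#' `p`-dimensional log2-parameter space by a random orthonormal map,
#' with isotropic Gaussian noise (sd `noise_sd`) in the orthogonal
#' complement, then exponentiates to positive estimates.  Latent
#' coordinates are drawn uniform with range `spread` and rescaled to the
#' exact variance `spread^2 / 12` of that uniform, so the per-direction
#' log2 variance is a design constant rather than a sampling draw.
#' The identifiability pipeline applied to the result recovers `k` as
#' the degree of non-identifiability when `spread^2 / 12 > 1` and
#' `noise_sd^2 < 1`.
#'
#' @param p ambient parameter dimension.
#' @param k manifold dimension, `0 <= k <= p`.
#' @param n number of runs (points).
#' @param spread per-direction log2 range of the latent coordinates.
#' @param noise_sd log2 standard deviation of the off-manifold noise.
#' @param seed integer seed.
#' @return an [estimate_ensemble()] of positive estimates.
#' @export
make_manifold_cloud <- function(p, k, n = 96L, spread = 4, noise_sd = 0.05,
                                seed = 1L) {
  if (k > p) stop("k must not exceed p", call. = FALSE)
  stopifnot(p >= 1L, n >= 2L, spread > 0, noise_sd >= 0)
  set.seed(seed)
  U <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
  X <- matrix(0, n, p)
  if (k > 0L) {
    Tm <- matrix(stats::runif(n * k, 0, spread), n, k)
    Tm <- sweep(Tm, 2L, colMeans(Tm))
    # orthonormalise the latent sample so every planted direction carries
    # exactly the variance spread^2/12 of a uniform with range `spread`;
    # sample cross-correlations would otherwise smear the spectrum
    Q <- qr.Q(qr(Tm))
    Tm <- Q * sqrt(n - 1) * (spread / sqrt(12))
    X <- X + Tm %*% t(U[, seq_len(k), drop = FALSE])
  }
  if (k < p && noise_sd > 0) {
    E <- matrix(stats::rnorm(n * (p - k), 0, noise_sd), n, p - k)
    X <- X + E %*% t(U[, (k + 1L):p, drop = FALSE])
  }
  est <- 2^X
  colnames(est) <- sprintf("theta_%d", seq_len(p))
  estimate_ensemble(est, objectives = rep(NA_real_, n),
                    algorithm = "synthetic-manifold",
                    layout = list(kinetic = seq_len(p),
                                  scaling_factors = integer(0),
                                  error_model = integer(0)),
                    seeds = seed)
}
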
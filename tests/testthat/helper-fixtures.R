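# Fixtures built in code: tiny analytic models and miniature cascade
# problems used across the suite.

# One-state exponential decay dx/dt = -k x, x(0) = 1.
decay_model <- function() {
  ode_model(states = c(x = 1), params = c(k = log(2)),
            rhs = c(x = "-k * x"), observables = c(obs = "x"),
            name = "decay")
}

# Conservative two-state transfer A -> B (total A + B invariant).
chain_model <- function() {
  ode_model(states = c(A = 1, B = 0.5), params = c(k1 = 0.8),
            rhs = c(A = "-k1 * A", B = "k1 * A"),
            observables = c(total = "A + B", b = "B"),
            name = "chain")
}

# Linear-in-time model: x(t) = slope * t, so observable values at integer
# times are known exactly; handy for residual arithmetic checks.
ramp_problem <- function(values, times = seq_along(values),
                         scheme = "none") {
  m <- ode_model(states = c(x = 0), params = c(slope = 1),
                 rhs = c(x = "slope"), observables = c(obs = "x"),
                 name = "ramp")
  pts <- data.frame(condition = "base", observable = "obs", time = times,
                    replicate = "r1", value = values)
  ds <- dataset(pts, normalization_spec(scheme), normalized = FALSE)
  ode_problem(m, list(condition("base")), ds, free = "slope",
              bounds = matrix(c(1e-3, 1e3), 1, 2,
                              dimnames = list("slope", NULL)))
}

# Miniature cascade estimation problem (2 tiers, 3 free parameters,
# noiseless): fast enough for per-test objective/jacobian checks.
tiny_cascade <- function(seed = 3L, p_free = 3L, n_times = 5L) {
  spec <- benchmark_spec(n_tiers = 2L, n_observables = 1L,
                         p_free = p_free, n_times = n_times, t_end = 10,
                         seed = seed)
  make_cascade_problem(spec)
}

# Free-vector values set to the ground truth of a cascade problem.
truth_values <- function(pb, spec) {
  fv <- assemble_free_vector(pb$problem, spec)
  v <- fv$values
  kin <- names(v)[fv$layout$kinetic]
  v[kin] <- pb$truth$theta_true[kin]
  v
}
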
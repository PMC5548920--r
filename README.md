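# scalefit

Parameter estimation for ODE models of cell-signalling pathways fitted
to **relative** time-course data — the arbitrary-unit readouts of
immunoblots, multiplexed ELISA or RT-qPCR, which are comparable only
within a replicate.

Mechanistic models simulate concentrations; relative data are unit-less
intensities.  `scalefit` implements, and lets you cross-compare, the two
standard ways of putting the two on one scale when minimising the misfit
of a model `dx/dt = f(x, θ)` with output `y = g(x)`:

* **DNS — data-driven normalisation of the simulations.**  Data are
  normalised by a per-(observable, replicate) reference
  (`ỹ = ŷ / ŷ_ref`; the average, maximum or a control point), and the
  *same rule* is applied to the simulated values (`y / y_ref`) after
  every simulation run.  No extra parameters.
* **SF — scaling factors.**  One estimated multiplier `α_j > 0` per
  observable converts simulations to the data scale
  (`ỹ ≈ α_j · y(θ)`), enlarging the estimation problem by one parameter
  per observable.

Both schemes combine with least-squares (LS) or a Gaussian
log-likelihood (LL) with the two-parameter error model
`σ = s_a + s_b·|μ|`, and with three optimisers that emit directly
comparable traces:

* `levmar_se` — Levenberg–Marquardt with Latin hypercube restarts,
  gradients from forward **sensitivity equations** (an augmented ODE
  system `(p+1)×` the original size);
* `levmar_fd` — the same search with **finite-difference** gradients
  (`p + 1` objective evaluations each);
* `glsdc` — a hybrid **genetic algorithm with diversity control**
  alternating with Powell's derivative-free local search.

The traces record both counting conventions — per-call (an SE gradient
counts 1) and FD-equivalent (every gradient charged `p + 1`) — next to
wall-clock time, so you can see for yourself why counting function
evaluations misrepresents the cost of sensitivity-equation gradients.

A PCA-based analysis quantifies **practical non-identifiability** from
multi-run estimate ensembles: estimates are log-normalised per parameter
against the smallest estimate across runs
(`θ_norm = log2(θ / min θ)`, so 1 = a two-fold change), and the degree
of non-identifiability is the number of principal components with
variance > 1.

Because no real dataset ships with the package, a synthetic benchmark
module generates ground-truth phosphorylation-cascade problems
(Michaelis–Menten activation, first-order deactivation, two stimulus
doses, arbitrary-unit replicate gains, optional error-model noise) in
the published problem shapes: `styx-like` (1 observable × 10 free
parameters, 38 points), `egfhrg-small` (8 × 10, 112 points) and
`egfhrg-large` (8 × 74, 112 points).

## Worked example

Ground-truth recovery on the `styx-like` benchmark with
sensitivity-equation Levenberg–Marquardt under DNS-LS:

```r
library(scalefit)

spec <- benchmark_preset("styx-like", seed = 7)
pb   <- make_cascade_problem(spec)
pb$problem
#> <ode_problem> cascade-1-10: 10 free kinetic parameters, 1 observables,
#>   2 conditions, 38 data points

cfg <- optimizer_config("levmar_se", n_starts = 8,
                        target_objective = 1e-10, seed = 11)
fit <- fit_model(pb$problem, objective_spec("dns", "ls"), cfg)
fit
#> <optimizer_result> best objective 5.447031e-17 (stalled), 5921 objective calls

rel <- abs(fit$best_values[pb$problem$free] -
           pb$truth$theta_true[pb$problem$free]) /
       pb$truth$theta_true[pb$problem$free]
max(rel)
#> 2.03e-06
```

The best of 8 restarts drives the DNS-LS objective to the numerical
floor (`5.4e-17`; the data are noiseless, so the truth attains 0) and
recovers every free kinetic parameter to within `2e-06` relative error.
The per-replicate gains the generator applied to the data never had to
be estimated — the normalisation cancels them, which is the point of
DNS.

Identifiability analysis on a planted estimate cloud:

```r
ens <- make_manifold_cloud(p = 10, k = 2, n = 96, spread = 4,
                           noise_sd = 0.05, seed = 1)
identifiability_report(ens)
#> <identifiability_report> degree of practical non-identifiability: 2 (96 runs, 10 parameters)
#>   PC variances: 1.33, 1.33, 0.00412, 0.00372, 0.00313, 0.00293, 0.00253, 0.00226, ...
```

Two planted directions of log2-variance 1.33 stand above the
variance > 1 threshold; the orthogonal noise (variance ≈ 0.003) does
not, so the reported degree is exactly the manifold dimension `k = 2`.

Command-line wrappers over the same functions live in `inst/cli/`
(`synth.R`, `fit.R`, `experiment.R`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/synth.R", package="scalefit"))')" \
  --preset styx-like --seed 7 --out bench/
```

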
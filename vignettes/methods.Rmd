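---
title: "Fitting ODE signalling models to relative data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting ODE signalling models to relative data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scalefit)
```

## The estimation problem

Signalling-pathway models in this package are ordinary differential
equations

$$\frac{dx}{dt} = f(x, \theta), \qquad y = g(x),$$

with state vector $x$ (typically active protein concentrations), kinetic
parameters $\theta$, and observables $y$ measured through an output
function $g$ (for example, a sum of phosphorylated forms).  Experimental
conditions (stimulus doses, knock-downs) are override maps applied to
copies of $\theta$ and the initial state before integration; the base
model is immutable.

The data come from relative assays (immunoblots, multiplexed ELISA,
RT-qPCR), whose readouts $\hat y_i$ are in arbitrary units and comparable
only within one replicate.  The central design question the package
exists to explore is how to put simulations and such data on one scale:

* **DNS (data-driven normalisation of the simulations).**  The data are
  normalised by a reference within each (observable, replicate) group,
  $\tilde y_i = \hat y_i / \hat y_{\mathrm{ref}}$, where the reference is
  the group's average, maximum, or a designated control point.  The
  *same* rule, over the same (condition, time) points, is applied to the
  simulated values, $\tilde y_i \approx y_i / y_{\mathrm{ref}}$.  The
  simulated reference cannot be fixed a priori — it depends on the
  simulation — so the normalisation is applied after every run.  No new
  parameters are introduced.
* **SF (scaling factors).**  One multiplier $\alpha_j > 0$ per observable
  converts simulations to the data scale,
  $\tilde y_i \approx \alpha_j\, y_i(\theta)$.  The $\alpha_j$ are
  estimated along with $\theta$, enlarging the search space by one
  parameter per observable.

Both schemes combine with two objective forms: least squares (LS), the
sum of squared residuals; and a negative log-likelihood (LL) under
independent Gaussian errors with the two-parameter error model

$$\sigma_i = s_a + s_b\,|\mu_i|,$$

where $\mu_i$ is the model prediction on the fitted scale, $s_a$ the
absolute and $s_b$ the proportional error component, both estimated.  The
LL objective is $\sum_i r_i^2/(2\sigma_i^2) + \ln \sigma_i$ with the
additive constant dropped.  Using the *prediction* rather than the datum
inside $\sigma$ avoids weighting noise by itself.  The free-parameter
vector is laid out deterministically as (kinetic $\theta$, then
$\alpha_j$ if SF, then $s_a, s_b$ if LL): with 10 free kinetic parameters
and 8 observables this gives 10 (DNS-LS), 18 (SF-LS) or 20 (SF-LL)
estimated quantities.

### Recasting LL for Levenberg–Marquardt

LM minimises sums of squares, so the LL objective is rewritten as an
augmented residual vector

$$\rho = \left[\frac{r_i}{\sqrt2\,\sigma_i};\;
  \sqrt{\ln \sigma_i + C_0}\right], \qquad C_0 = 20,$$

whose sum of squares equals the negative log-likelihood plus the constant
$nC_0$ (so it has the same minimiser).  The shift $C_0$ keeps the square
root real for $\sigma_i > e^{-20}$; smaller $\sigma_i$ trigger the
penalty contract below.  Traces and reported objective values subtract
the constant back out.

## Simulation and gradients

Models are declared as arithmetic expressions (`+ - * / ^`, parentheses,
identifiers) over states and parameters.  At build time each model is
compiled into a single R function, and the partial derivatives
$\partial f/\partial x$ and $\partial f/\partial\theta$ are derived
symbolically with `stats::D`.  Simulation uses the stiff solver
`deSolve::lsoda` with relative tolerance `1e-8` and absolute tolerance
`1e-10` by default (configurable per problem); output times are always
the union of measurement times per condition — residuals never
interpolate.

Forward sensitivities integrate the augmented system
$\dot S = (\partial f/\partial x) S + \partial f/\partial \theta$ of
dimension $n_\mathrm{states}\times(p+1)$; only structurally nonzero
Jacobian entries are evaluated.  Finite differences are *not* used inside
the augmented system — that would defeat the comparison between
sensitivity-equation (SE) and finite-difference (FD) gradients that the
framework is built to make.  Initial-state sensitivities are zero for
fixed initial conditions (the benchmark default) and obtained by central
differences of the declared `initial_state` function otherwise.

Residual Jacobians chain through the output map and, for DNS, through
the normalisation by the quotient rule,

$$\frac{\partial (y_i/y_{\mathrm{ref}})}{\partial\theta_k}
 = \frac{y_{\mathrm{ref}}\,\partial y_i/\partial\theta_k
        - y_i\,\partial y_{\mathrm{ref}}/\partial\theta_k}
        {y_{\mathrm{ref}}^2},$$

where $\partial y_{\mathrm{ref}}/\partial\theta_k$ is the same aggregate
(mean, value at the maximising point, or selected point) of the
sensitivities that defined $y_{\mathrm{ref}}$.  SF columns are $-y_i$ on
the rows of the matching observable.

### Evaluation accounting

Two counting conventions are tracked side by side, because they disagree
in a way that matters when comparing gradient types:

* per-call: every objective evaluation counts 1, *including* an SE
  gradient (which solves one — much larger — ODE system);
* FD-equivalent: every gradient is charged $p+1$ evaluations, the cost
  an FD gradient actually pays.

Wall-clock seconds are measured independently of both counts with a
monotonic clock.  On the benchmark problems here an SE gradient costs
*more* wall time than an FD gradient (the augmented system has
$(p+1)\times$ the equations), so per-call counting flatters SE — the
package's `compare_metrics()` puts the three columns side by side to
make that visible.

### Penalty contract

A failed integration, a non-positive simulated reference, or a
non-positive $\sigma_i$ yields the finite objective value `1e10` instead
of an error.  Derivative-free optimisers treat such points as very bad
and move on; LM rejects the trial step and increases damping.  This keeps
every optimiser total over the search box.

## Optimisers

All searches operate in $\log_{10}$ parameter space (positivity for
free), clamped to the bound box.  Scaling factors and error parameters
are bounded to $[10^{-6}, 10^6]$.

**LevMar FD / LevMar SE** — classic damped Gauss–Newton:
$(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\delta = -J^\top r$, with
$\lambda$ divided by 3 on acceptance and doubled on rejection (singular
systems are handled by raising $\lambda$, never by failing).  Termination
on relative objective change (`ftol = 1e-10`), step norm
(`xtol = 1e-10`), 500 iterations per start, or the run budget.  Restarts
come from a log-uniform Latin hypercube (one start per stratum per
dimension, `lhs::randomLHS`).  The two variants differ only in the
residual Jacobian: forward sensitivities (SE) or forward differences of
the residual vector (FD, relative step `1e-6`).

**GLSDC** — a hybrid of a real-coded genetic algorithm and Powell's
derivative-free local search, operating on coordinates normalised to the
unit box of the log-transformed bounds.  Each cycle: one generation of
tournament selection, BLX-0.5 crossover and per-coordinate mutation
(rate $1/p$, Gaussian sd 0.1); then *diversity control* — survivors are
admitted best-first only if at least $\delta = 0.1$ (Euclidean, in the
normalised log space) away from those already admitted, which prevents
the population collapsing onto one basin; then Powell refinement of the
top 3 mutually distinct individuals.  Powell uses the canonical
direction-replacement test (a direction is replaced by the net cycle
displacement only when an extrapolation criterion confirms it is a
genuinely new descent direction) and line searches that bracket outward
from a remembered per-direction step scale before Brent refinement.  The
final 30 % of the budget is reserved for one deep Powell polish of the
incumbent.  The population defaults to $\min(10p, 200)$.  The original
method's internals are not published in detail; this is a
faithful-in-spirit reconstruction, and its hyper-parameters are
documented here rather than hidden.

Every algorithm emits the same trace records (elapsed seconds, per-call
objective count, FD-equivalent count, best objective so far), is
deterministic given its seed, and stops on evaluation or wall-clock
budgets; `convergence_summary()` reduces trace ensembles to 25th/50th/
75th percentiles of the best objective at time cutoffs, with truncated
traces contributing their last (or first) value.

## Practical identifiability from estimate ensembles

Repeated independent runs that all fit the data equally well but
disagree on the parameters reveal practical (a posteriori)
non-identifiability.  Estimates are log-normalised per parameter against
the smallest estimate across runs,

$$\theta_{i,j,\mathrm{norm}} = \log_2\!\left(\theta_{i,j} /
  \min_j \theta_{i,j}\right),$$

so a value of 1 means a two-fold change.  PCA of the column-centred
matrix (runs in rows; no rescaling — the log transform *is* the scaling
step) gives principal directions and variances, and the **degree of
non-identifiability** is the number of variances strictly greater
than 1.  The analysis is restricted to the kinetic segment of the free
vector by default: scaling factors and error parameters are dropped,
since the question is whether the *kinetics* are determined.  Two
conventions were genuinely open and are settled as follows: the baseline
is the per-parameter minimum (the printed formula; a best-run baseline
would differ only by a column shift, which PCA ignores), and columns are
centred (uncentred second moments would mix mean offsets into the
variances).  This analysis measures spread, not sloppiness: it asks how
*large* the uncertain directions are, not how they compare to each
other.

## Synthetic benchmarks

No real signalling dataset ships with the package; a generator builds
ground-truth problems that emulate the *shape* of realistic test
problems while remaining fully known:

* a phosphorylation cascade of `n_tiers` tiers — Michaelis–Menten
  activation of each tier by the one above (tier 1 by the stimulus),
  first-order deactivation, optional negative feedback from the last
  tier onto tier 1;
* true kinetic constants drawn log-uniformly from tier-realistic ranges
  ($k_\mathrm{act} \in [0.5, 2]$, $K_m \in [0.2, 1]$,
  $k_\mathrm{deg} \in [0.1, 0.5]$, totals 1, in the model's
  concentration/time units);
* two stimulus conditions (doses 1 and 0.25), optionally a knock-down
  scaling the tier-1 total to 0.2;
* observables: sums of active forms over contiguous tier blocks;
* data $\hat y = g_r\, y(\theta^*)(1+\varepsilon)$ with per-(observable,
  replicate) gains $g_r$ drawn log-uniformly from $[0.5, 2]$ (emulating
  arbitrary units) and noise sd $(s_a + s_b y)/\max(y, \epsilon)$
  matching the LL error model, so $s_a, s_b$ recovery is testable.
  The preset default is noiseless — the ground-truth-recovery setting in
  which the DNS round trip is exact — with noise opt-in.

Presets mirror published problem shapes: `styx-like` (1 observable, 10
free parameters, 5 tiers, 38 points = 19 times × 2 conditions),
`egfhrg-small` (8 observables, 10 free, 8 tiers, 112 points = 8 × 2 × 7)
and `egfhrg-large` (8 observables, 74 free, 25 tiers, 112 points), all
with normalisation by average.  Time grids are uniform on $[0, 20]$
model time units (the cascades settle on that scale); the original
problems' exact grids are not published, only their totals.

Two bound-box defaults coexist deliberately.  A hand-built
`ode_problem()` defaults to ±3 decades around nominal — an agnostic
search box for a general tool.  The benchmark generator uses ±1.5
decades around the true values (`bound_decades`): a benchmark exists to
verify round-trip recovery at desk scale, and an order-of-magnitude
prior is what a modeller realistically has for rate constants; with a
±3-decade box, 8 local restarts essentially never land in the global
basin of a 10-parameter cascade, and the benchmark would measure basin
luck rather than estimator correctness.

The manifold generator `make_manifold_cloud()` plants estimate clouds of
known intrinsic dimension $k$: latent coordinates (uniform, range
`spread`) are sample-orthonormalised and scaled to carry exactly the
variance $\mathrm{spread}^2/12$ of that uniform, embedded through a
random orthonormal map into log2-parameter space, with isotropic noise
(sd `noise_sd`) in the orthogonal complement, then exponentiated.  With
`spread = 4` each planted direction has log2 variance 1.33 (above the
degree threshold of 1) and the default noise variance 0.0025 is far
below it, so the identifiability pipeline must return exactly $k$.  The
exact-variance construction makes the planted spectrum a design constant
rather than a sampling draw.  What these clouds do *not* emulate:
curvature of real non-identifiable manifolds (the PCA degree is a linear
approximation there), objective-value weighting, or multi-basin
structure.

## Test problem sizes and what passing shows

The suite exercises: closed-form models (exponential decay, conservative
transfer) against analytic solutions; 2-tier cascades for residual,
Jacobian and counting contracts; the 5-tier `styx-like` preset for the
full recovery round trip (all three optimisers, 8 restarts); the 8-tier
`egfhrg-small` preset for the accounting comparison and a monitored
DNS-vs-SF benchmark; and planted manifolds at $p = 10$, $n = 96$.  These
sizes were chosen so the whole suite runs on one CPU in minutes.
Passing them shows the machinery is internally correct and that the
framework's qualitative contrasts (SE vs FD accounting, DNS vs SF
parameter counts) hold on known-truth problems; it does not certify
performance on models with dozens of states, real measurement error, or
model misspecification.

One caveat is worth stating plainly: on the `styx-like` benchmark the
gradient-based variants reach the ground-truth objective floor
($<10^{-16}$), while GLSDC — whose local phase is derivative-free —
stalls around $10^{-7}$ within a 5-minute budget.  The log-space
Gauss–Newton Hessian there has condition number $\sim 10^6$ (10
parameters observed through one summed readout), and a
conjugate-direction method converges only linearly under such
conditioning; reaching the same floor needs evaluation counts that
interpreted-R objective evaluations (~7 ms each) do not allow in
minutes.  This is a budget statement, not a correctness one: on rugged
multimodal landscapes at equal budgets GLSDC beats multistart Powell
(see the optimiser tests), which is precisely the regime hybrid global
methods are for.

## Known limitations

* The expression grammar covers mass-action and Michaelis–Menten style
  rate laws; no `exp`/`log`/Hill-exponent shortcuts (a Hill term can be
  written as a power), no events, delays, or steady-state
  pre-equilibration, and no SBML import.
* Replicates are fitted individually after normalisation (preserving
  per-replicate semantics), never averaged; normalisation groups pool
  conditions within (observable, replicate).  Conventions differ between
  labs; the grouping is a documented default, not configurable per
  condition.
* The LL error-model form $\sigma = s_a + s_b|\mu|$ is an assumption;
  other conventions (log-normal errors, $\sigma$ on the raw scale)
  would change the objective.
* Single-threaded execution; the determinism contract (same seed, same
  trace) is stated for that setting.
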
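test_that("Latin hypercube sampling stratifies each log dimension", {
  bounds <- matrix(rep(c(1e-2, 1e2), each = 2), 2, 2,
                   dimnames = list(c("a", "b"), NULL))
  x <- latin_hypercube_sample(bounds, n = 4, seed = 9)
  expect_equal(dim(x), c(4L, 2L))
  for (j in 1:2) {
    strata <- findInterval(log10(x[, j]), seq(-2, 2, by = 1),
                           rightmost.closed = TRUE)
    expect_setequal(strata, 1:4)  # exactly one point per stratum
  }
  # determinism and the degenerate single-point design
  expect_identical(x, latin_hypercube_sample(bounds, 4, seed = 9))
  x1 <- latin_hypercube_sample(bounds, 1, seed = 2)
  expect_true(all(x1 >= 1e-2 & x1 <= 1e2))
  expect_error(latin_hypercube_sample(cbind(c(-1, 1), c(1, 2)), 4),
               "positive")
})

test_that("Levenberg-Marquardt solves linear least squares to the normal equations", {
  set.seed(5)
  A <- matrix(rnorm(12), 4, 3)
  b <- rnorm(4)
  res_fn <- function(x) as.numeric(A %*% x - b)
  jac_fn <- function(x) list(r = res_fn(x), J = A)
  fit <- levmar_minimize(res_fn, jac_fn, c(0, 0, 0),
                         optimizer_config("levmar_fd"))
  x_star <- solve(crossprod(A), crossprod(A, b))
  expect_equal(fit$x, as.numeric(x_star), tolerance = 1e-8)
  # independent oracle: MINPACK via minpack.lm
  nl <- minpack.lm::nls.lm(par = c(0, 0, 0), fn = res_fn)
  expect_equal(fit$x, unname(coef(nl)), tolerance = 1e-6)
})

test_that("Levenberg-Marquardt minimises Rosenbrock residuals", {
  res_fn <- function(x) c(10 * (x[2] - x[1]^2), 1 - x[1])
  jac_fn <- function(x)
    list(r = res_fn(x), J = matrix(c(-20 * x[1], -1, 10, 0), 2, 2))
  fit <- levmar_minimize(res_fn, jac_fn, c(-1.2, 1),
                         optimizer_config("levmar_fd", max_iter = 200))
  expect_equal(fit$x, c(1, 1), tolerance = 1e-6)
})

test_that("Levenberg-Marquardt recognises a stationary start at once", {
  A <- diag(2)
  res_fn <- function(x) as.numeric(A %*% x)
  jac_fn <- function(x) list(r = res_fn(x), J = A)
  fit <- levmar_minimize(res_fn, jac_fn, c(0, 0),
                         optimizer_config("levmar_fd"))
  expect_lte(fit$iterations, 2L)
  expect_identical(fit$termination, "ftol")
})

test_that("Powell's method finds local minima without derivatives", {
  q1 <- function(x) (x - 3)^2
  ps <- powell_search(q1, 0, lower = -10, upper = 10)
  expect_equal(ps$x, 3, tolerance = 1e-5)
  # idempotent at the optimum
  ps2 <- powell_search(q1, 3, lower = -10, upper = 10)
  expect_equal(ps2$x, 3, tolerance = 1e-6)
  expect_lte(ps2$objective, q1(3) + 1e-12)
  # separable 2-D quadratic: both coordinates recovered
  q2 <- function(x) (x[1] - 1)^2 + 4 * (x[2] + 2)^2
  ps3 <- powell_search(q2, c(0, 0), lower = c(-5, -5), upper = c(5, 5))
  expect_equal(ps3$x, c(1, -2), tolerance = 1e-5)
})

test_that("GLSDC escapes the deceptive well of a double-well landscape", {
  # f(u) = (u^2 - 1)^2 + 0.1 u on u = log10(theta): global minimum near
  # u = -1, a higher local minimum near u = +1
  bounds <- matrix(c(1e-2, 1e2), 1, 2, dimnames = list("th", NULL))
  f <- function(theta) { u <- log10(theta); (u^2 - 1)^2 + 0.1 * u }
  grid <- 10^seq(-2, 2, length.out = 20001)
  u_star <- log10(grid[which.min(vapply(grid, f, numeric(1)))])
  cfg <- optimizer_config("glsdc", max_evals = 2000,
                          population_size = 20, seed = 5)
  res <- glsdc_run(f, bounds, cfg)
  expect_lt(abs(log10(res$best_values) - u_star), 1e-3)
  expect_lt(u_star, 0)  # the oracle confirms the global well is at -1
})

test_that("GLSDC agrees with Powell alone on a convex landscape", {
  bounds <- matrix(c(1e-2, 1e2), 1, 2, dimnames = list("th", NULL))
  f <- function(theta) (log10(theta) - 0.5)^2
  res <- glsdc_run(f, bounds,
                   optimizer_config("glsdc", max_evals = 1500,
                                    population_size = 10, seed = 3))
  ps <- powell_search(function(z) f(10^(-2 + 4 * z)), 0.2,
                      lower = 0, upper = 1)
  expect_equal(log10(res$best_values), 0.5, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(-2 + 4 * ps$x, 0.5, tolerance = 1e-4)
})

test_that("GLSDC trace counts every objective invocation", {
  bounds <- matrix(rep(c(0.1, 10), each = 2), 2, 2,
                   dimnames = list(c("a", "b"), NULL))
  cnt <- evaluation_counter()
  n_true <- 0L
  f <- function(theta) {
    n_true <<- n_true + 1L
    cnt$objective_calls <- cnt$objective_calls + 1L
    sum(log10(theta)^2)
  }
  res <- glsdc_run(f, bounds,
                   optimizer_config("glsdc", max_evals = 400,
                                    population_size = 8, seed = 2), cnt)
  last <- res$trace[nrow(res$trace), ]
  expect_identical(as.integer(last$objective_calls), n_true)
})

test_that("GLSDC beats multistart Powell on a rugged multimodal family", {
  # log-space Rastrigin: dense grid of local minima around a single
  # global basin at u = 0; recombination of good coordinates is exactly
  # what the genetic phase provides and restarts do not
  p <- 5
  bounds <- matrix(rep(c(1e-2, 1e2), each = p), p, 2,
                   dimnames = list(paste0("th", 1:p), NULL))
  rast <- function(theta) {
    u <- log10(theta)
    sum(u^2 + 3 * (1 - cos(2 * pi * u)))
  }
  budget <- 2500
  glsdc_best <- powell_best <- numeric(0)
  for (sd in 1:6) {
    res <- glsdc_run(rast, bounds,
                     optimizer_config("glsdc", max_evals = budget,
                                      population_size = 30, seed = sd))
    glsdc_best <- c(glsdc_best, res$best_objective)
    m <- 0L
    fp <- function(z) { m <<- m + 1L; rast(10^(-2 + z * 4)) }
    starts <- latin_hypercube_sample(bounds, 50, seed = sd)
    best <- Inf
    for (s in seq_len(nrow(starts))) {
      if (m >= budget) break
      z0 <- (log10(starts[s, ]) + 2) / 4
      ps <- powell_search(fp, z0, tol = 1e-10, lower = rep(0, p),
                          upper = rep(1, p), max_cycles = 8)
      best <- min(best, ps$objective)
    }
    powell_best <- c(powell_best, best)
  }
  # global-basin success rate (objective below the first ring of local
  # minima) is strictly higher for GLSDC; GLSDC is never worse
  expect_gt(sum(glsdc_best <= 1), sum(powell_best <= 1))
  expect_true(all(glsdc_best <= powell_best + 1e-9))
})

test_that("fits are seed-deterministic with monotone best-so-far traces", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  for (alg in c("levmar_fd", "levmar_se", "glsdc")) {
    cfg <- optimizer_config(alg, n_starts = 2, max_iter = 30,
                            max_evals = 600, population_size = 10,
                            seed = 4)
    r1 <- fit_model(pb$problem, spec, cfg)
    r2 <- fit_model(pb$problem, spec, cfg)
    expect_identical(r1$best_values, r2$best_values)
    expect_equal(r1$best_objective, r2$best_objective)
    expect_true(all(diff(r1$trace$best_objective) <= 0))
    expect_true(all(diff(r1$trace$elapsed_seconds) >= 0))
  }
})

test_that("a one-start multistart equals a single LM run", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  cfg <- optimizer_config("levmar_fd", n_starts = 1, max_iter = 40,
                          seed = 8)
  res <- multistart_levmar(pb$problem, spec, cfg)
  expect_equal(nrow(res$ensemble$estimates), 1L)
  expect_equal(unname(res$ensemble$estimates[1, ]),
               unname(res$best_values))
  # best_objective is the objective re-evaluated at the best point
  ob <- build_objective(pb$problem, spec)
  expect_equal(ob$objective_fn(res$best_values), res$best_objective,
               tolerance = 1e-10)
})

test_that("convergence summaries follow the cutoff rules", {
  tr <- function(val) data.frame(elapsed_seconds = c(1, 2),
                                 objective_calls = c(1, 2),
                                 fd_equivalent_evals = c(1, 2),
                                 best_objective = c(val, val))
  s <- convergence_summary(list(tr(1), tr(2), tr(3)), cutoffs = c(1.5, 10))
  expect_equal(s$median, c(2, 2))
  # single trace: all percentiles collapse
  s1 <- convergence_summary(list(tr(5)), cutoffs = 3)
  expect_equal(unlist(s1[c("q25", "median", "q75")]), c(5, 5, 5),
               ignore_attr = TRUE)
  # cutoff before the first record uses the first recorded value
  tr2 <- data.frame(elapsed_seconds = c(4, 6), objective_calls = c(1, 2),
                    fd_equivalent_evals = c(1, 2),
                    best_objective = c(9, 3))
  s2 <- convergence_summary(list(tr2), cutoffs = c(1, 5, 7))
  expect_equal(s2$median, c(9, 9, 3))
  expect_error(convergence_summary(list(), 1), "no traces")
})
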
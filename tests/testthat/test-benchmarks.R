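test_that("cascade problems honour the requested shape", {
  pb <- make_cascade_problem(benchmark_preset("styx-like", seed = 2))
  prob <- pb$problem
  expect_length(prob$free, 10L)
  expect_identical(length(unique(prob$data$observable)), 1L)
  expect_identical(nrow(prob$data), 38L)  # 19 times x 2 conditions
  expect_identical(length(prob$conditions), 2L)

  pb8 <- make_cascade_problem(benchmark_spec(n_tiers = 8,
                                             n_observables = 8,
                                             p_free = 10, n_times = 7,
                                             seed = 2))
  expect_identical(nrow(pb8$problem$data), 112L)
  expect_identical(length(unique(pb8$problem$data$observable)), 8L)
  expect_error(benchmark_spec(n_tiers = 2, n_observables = 3),
               "n_observables")
  expect_error(benchmark_spec(n_tiers = 2, p_free = 10), "exceeds")
})

test_that("cascade construction is seed-deterministic", {
  a <- make_cascade_problem(benchmark_spec(seed = 5))
  b <- make_cascade_problem(benchmark_spec(seed = 5))
  expect_identical(a$truth$theta_true, b$truth$theta_true)
  expect_identical(a$problem$data$value, b$problem$data$value)
  c <- make_cascade_problem(benchmark_spec(seed = 6))
  expect_false(identical(a$truth$theta_true, c$truth$theta_true))
})

test_that("true trajectories are finite and non-negative in all conditions", {
  pb <- make_cascade_problem(benchmark_spec(n_conditions = 3, seed = 4))
  prob <- pb$problem
  times <- seq(0, 20, length.out = 11)
  for (cn in names(prob$conditions)) {
    tr <- simulate_model(prob$model, pb$truth$theta_true,
                         prob$conditions[[cn]], times)
    expect_true(all(is.finite(tr$states)))
    expect_true(all(tr$states >= -1e-9))
  }
})

test_that("noiseless unit-gain data equal the simulated observables", {
  spec <- benchmark_spec(n_tiers = 3, p_free = 4, n_times = 6,
                         replicate_gain_range = c(1, 1 + 1e-12), seed = 8)
  pb <- make_cascade_problem(spec)
  sim <- scalefit:::make_simulator(pb$problem)
  y <- sim(pb$truth$theta_true)$y
  expect_equal(pb$problem$data$value, y, tolerance = 1e-9)
})

test_that("noiseless arbitrary-gain data round-trip through DNS to zero", {
  pb <- make_cascade_problem(benchmark_spec(n_tiers = 3, p_free = 4,
                                            n_times = 6,
                                            n_replicates = 2, seed = 13))
  spec <- objective_spec("dns", "ls")
  ob <- build_objective(pb$problem, spec)
  v <- truth_values(pb, spec)
  expect_lt(ob$objective_fn(v), 1e-12)
})

test_that("a scaling factor absorbs the replicate gain exactly", {
  # single replicate: alpha_j set to that observable's gain zeroes SF-LS
  # on raw (unnormalised) data
  pb <- make_cascade_problem(benchmark_spec(n_tiers = 2, p_free = 2,
                                            n_observables = 1,
                                            n_times = 5, seed = 17))
  raw <- as.data.frame(pb$problem$data)
  prob_raw <- ode_problem(pb$problem$model, pb$problem$conditions,
                          dataset(raw, normalization_spec("none")),
                          pb$problem$free, pb$problem$bounds)
  spec <- objective_spec("sf", "ls")
  fv <- assemble_free_vector(prob_raw, spec)
  v <- fv$values
  v[fv$layout$kinetic] <- pb$truth$theta_true[names(v)[fv$layout$kinetic]]
  v[fv$layout$scaling_factors] <- pb$truth$gains[["obs1/r1"]]
  ob <- build_objective(prob_raw, spec)
  expect_lt(ob$objective_fn(v), 1e-12)
})

test_that("generated data satisfy the mean-one invariant after normalisation", {
  pb <- make_cascade_problem(benchmark_spec(n_tiers = 3, p_free = 3,
                                            n_times = 6,
                                            noise = c(0.05, 0.1),
                                            n_replicates = 2, seed = 19))
  nd <- normalize_data(pb$problem$data)
  for (k in unique(paste(nd$observable, nd$replicate))) {
    idx <- paste(nd$observable, nd$replicate) == k
    expect_equal(mean(nd$value[idx]), 1, tolerance = 1e-12)
  }
})

test_that("problems survive a YAML + CSV round trip", {
  pb <- make_cascade_problem(benchmark_spec(n_tiers = 2, p_free = 3,
                                            n_times = 4, seed = 23))
  dir <- withr::local_tempdir()
  write_dataset(pb$problem$data, file.path(dir, "data.csv"))
  write_problem_yaml(pb$problem, file.path(dir, "problem.yaml"))
  prob2 <- read_problem_yaml(file.path(dir, "problem.yaml"))
  expect_equal(prob2$model$params[names(pb$problem$model$params)],
               pb$problem$model$params, tolerance = 1e-12)
  expect_identical(prob2$free, pb$problem$free)
  expect_equal(unname(prob2$bounds), unname(pb$problem$bounds),
               tolerance = 1e-12)
  expect_equal(prob2$data$value, pb$problem$data$value)
  # the reloaded problem simulates to the same objective
  ob1 <- build_objective(pb$problem, objective_spec("dns", "ls"))
  ob2 <- build_objective(prob2, objective_spec("dns", "ls"))
  fv <- assemble_free_vector(pb$problem, objective_spec("dns", "ls"))
  v <- fv$values * 1.2
  expect_equal(ob1$objective_fn(v), ob2$objective_fn(v),
               tolerance = 1e-8)
})
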
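test_that("free-vector layout is deterministic and correctly sized", {
  pb <- tiny_cascade()
  fv <- assemble_free_vector(pb$problem, objective_spec("sf", "ll"))
  expect_named(fv$values, c(pb$problem$free, "alpha_obs1", "s_a", "s_b"))
  expect_equal(fv$layout$kinetic, 1:3)
  expect_equal(fv$layout$scaling_factors, 4L)
  expect_equal(fv$layout$error_model, 5:6)
  expect_true(all(fv$values >= fv$bounds[, "lower"] &
                    fv$values <= fv$bounds[, "upper"]))
  fv_dns <- assemble_free_vector(pb$problem, objective_spec("dns", "ls"))
  expect_length(fv_dns$values, 3L)
})

test_that("SF residuals are data minus scaled simulation", {
  # x(t) = t so y = [1, 2] at t = 1, 2; data [2, 4]
  prob <- ramp_problem(values = c(2, 4), times = c(1, 2), scheme = "none")
  spec <- objective_spec("sf", "ls")
  ob <- build_objective(prob, spec)
  r_exact <- ob$residual_fn(c(slope = 1, alpha_obs = 2))
  expect_equal(unname(r_exact), c(0, 0), tolerance = 1e-9)
  r_unit <- ob$residual_fn(c(slope = 1, alpha_obs = 1))
  expect_equal(unname(r_unit), c(1, 2), tolerance = 1e-9)
  expect_equal(ob$resid_to_objective(r_unit), 5, tolerance = 1e-8)
  # scaling-factor Jacobian column is -y on the observable's rows
  J <- ob$jacobian_se(c(slope = 1, alpha_obs = 1))$J
  expect_equal(unname(J[, 2]), c(-1, -2), tolerance = 1e-7)
})

test_that("DNS residuals vanish for data proportional to the simulation", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  ob <- build_objective(pb$problem, spec)
  v <- truth_values(pb, spec)
  expect_lt(ob$objective_fn(v), 1e-12)
  r <- ob$residual_fn(v)
  expect_lt(max(abs(r)), 1e-6)
  expect_equal(length(r), nrow(pb$problem$data))
})

test_that("DNS-LS is invariant to rescaling a raw replicate group", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  fv <- assemble_free_vector(pb$problem, spec)
  v <- fv$values * 1.7  # arbitrary non-optimal point
  f1 <- build_objective(pb$problem, spec)$objective_fn(v)
  pb2 <- pb
  pb2$problem$data$value <- pb2$problem$data$value * 37.5
  f2 <- build_objective(pb2$problem, spec)$objective_fn(v)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("log-likelihood arithmetic matches the error model", {
  # single data point with zero residual, s_a = 1, s_b = 0 -> 0
  prob1 <- ramp_problem(values = 1, times = 1, scheme = "none")
  specll <- objective_spec("sf", "ll")
  ob1 <- build_objective(prob1, specll)
  expect_equal(ob1$objective_fn(c(slope = 1, alpha_obs = 1,
                                  s_a = 1, s_b = 0)), 0,
               tolerance = 1e-9)
  # residual 1, s_a = 1, s_b = 0 -> 0.5
  prob2 <- ramp_problem(values = 2, times = 1, scheme = "none")
  ob2 <- build_objective(prob2, specll)
  expect_equal(ob2$objective_fn(c(slope = 1, alpha_obs = 1,
                                  s_a = 1, s_b = 0)), 0.5,
               tolerance = 1e-9)
})

test_that("minimising over s_a recovers the RMS residual", {
  # fixed residuals r = (1, 2), s_b = 0: analytic s_a* = sqrt(mean(r^2))
  prob <- ramp_problem(values = c(2, 4), times = c(1, 2), scheme = "none")
  spec <- objective_spec("sf", "ll")
  ob <- build_objective(prob, spec)
  f_of_sa <- function(sa)
    ob$objective_fn(c(slope = 1, alpha_obs = 1, s_a = sa, s_b = 0))
  grid <- seq(0.5, 3, by = 0.001)
  sa_grid <- grid[which.min(vapply(grid, f_of_sa, numeric(1)))]
  expect_equal(sa_grid, sqrt(mean(c(1, 4))), tolerance = 1e-2)
})

test_that("LL with fixed sigma is an affine function of LS", {
  pb <- tiny_cascade()
  n <- nrow(pb$problem$data)
  s_a <- 0.4
  ls_ob <- build_objective(pb$problem, objective_spec("dns", "ls"))
  ll_ob <- build_objective(pb$problem, objective_spec("dns", "ll"))
  fv <- assemble_free_vector(pb$problem, objective_spec("dns", "ls"))
  for (mult in c(0.8, 1.3, 2)) {
    v <- fv$values * mult
    f_ls <- ls_ob$objective_fn(v)
    f_ll <- ll_ob$objective_fn(c(v, s_a = s_a, s_b = 0))
    expect_equal(f_ll, f_ls / (2 * s_a^2) + n * log(s_a),
                 tolerance = 1e-8)
  }
})

test_that("FD gradient uses p + 1 evaluations and is accurate", {
  g <- fd_gradient(function(x) sum(x^2), c(1, -2))
  expect_equal(g, c(2, -4), tolerance = 1e-5)
  expect_equal(fd_gradient(function(x) 5, c(1, 2, 3)), c(0, 0, 0))
  # counting contract on a counted objective
  pb <- tiny_cascade()
  ob <- build_objective(pb$problem, objective_spec("dns", "ls"))
  v <- truth_values(pb, objective_spec("dns", "ls"))
  before <- ob$counter$objective_calls
  fd_gradient(ob$objective_fn, v)
  expect_identical(ob$counter$objective_calls - before, length(v) + 1L)
})

test_that("SE Jacobian agrees with the FD oracle for DNS and SF", {
  pb <- tiny_cascade()
  for (scaling in c("dns", "sf")) {
    spec <- objective_spec(scaling, "ls")
    ob <- build_objective(pb$problem, spec)
    v <- truth_values(pb, spec) * 1.15  # off-optimum, nonzero residuals
    Jse <- ob$jacobian_se(v)$J
    Jfd <- ob$jacobian_fd(v)$J
    expect_lt(max(abs(Jse - Jfd)) / max(abs(Jse)), 1e-4)
  }
  # LL-augmented residual Jacobian too
  specll <- objective_spec("dns", "ll")
  obll <- build_objective(pb$problem, specll)
  vll <- c(truth_values(pb, objective_spec("dns", "ls")) * 1.15,
           s_a = 0.3, s_b = 0.2)
  Jse <- obll$jacobian_se(vll)$J
  Jfd <- obll$jacobian_fd(vll)$J
  expect_lt(max(abs(Jse - Jfd)) / max(abs(Jse)), 1e-4)
})

test_that("counter conventions charge SE gradients 1 call, p + 1 FD-equivalents", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  cnt <- evaluation_counter()
  ob <- build_objective(pb$problem, spec, cnt)
  v <- truth_values(pb, spec)
  p <- length(v)
  ob$jacobian_se(v)
  expect_identical(cnt$objective_calls, 1L)
  expect_identical(cnt$gradient_calls, 1L)
  expect_equal(cnt$fd_equivalent_evals, p + 1)
  ob$jacobian_fd(v)
  expect_identical(cnt$objective_calls, 1L + p + 1L)
  expect_equal(cnt$fd_equivalent_evals, 2 * (p + 1))
  expect_gte(counter_elapsed(cnt), 0)
})

test_that("infeasible parameter sets yield the finite penalty", {
  pb <- tiny_cascade()
  spec <- objective_spec("dns", "ls")
  ob <- build_objective(pb$problem, spec)
  v <- truth_values(pb, spec)
  v[] <- 1e9  # far outside sane kinetics; integration blows up or stalls
  f <- ob$objective_fn(v)
  expect_true(is.finite(f))
})

test_that("SF-LS optimum over alpha matches the closed form", {
  pb <- tiny_cascade()
  spec <- objective_spec("sf", "ls")
  ob <- build_objective(pb$problem, spec)
  fv <- assemble_free_vector(pb$problem, spec)
  v <- truth_values(pb, spec) * 1.2
  # closed form: alpha* = sum(y_tilde * y) / sum(y^2) per observable
  ds <- normalize_data(pb$problem$data)
  sim <- scalefit:::make_simulator(pb$problem)
  th <- pb$problem$model$params
  th[pb$problem$free] <- v[fv$layout$kinetic]
  y <- sim(th)$y
  alpha_closed <- sum(ds$value * y) / sum(y^2)
  f_of_alpha <- function(a) {
    vv <- v
    vv[fv$layout$scaling_factors] <- a
    ob$objective_fn(vv)
  }
  grid <- seq(alpha_closed * 0.5, alpha_closed * 1.5, length.out = 2001)
  a_grid <- grid[which.min(vapply(grid, f_of_alpha, numeric(1)))]
  expect_equal(a_grid, alpha_closed, tolerance = 1e-3)
})
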
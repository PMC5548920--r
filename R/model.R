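# ODE model engine: model/condition containers, stiff simulation and
# forward sensitivities via the augmented system.

#' Define an ODE model
#'
#' Builds an ODE model of the form dx/dt = f(x, theta) with observables
#' y = g(x, theta).  Right-hand sides and output functions are arithmetic
#' expressions over the declared state and parameter names (grammar:
#' `+ - * / ^`, parentheses, identifiers, and `t` for time).  Partial
#' derivatives of `f` with respect to states and parameters are derived
#' symbolically at build time; they drive the sensitivity equations.
#'
#' @param states named numeric vector: state names and default initial
#'   values at time 0.
#' @param params named numeric vector: the full parameter set (free and
#'   fixed) with nominal values.
#' @param rhs named character vector of derivative expressions, one per
#'   state, in the same order as `states`.
#' @param observables named character vector of output-function expressions
#'   over states (and optionally parameters).
#' @param initial_state optional `function(theta, condition)` returning the
#'   initial state vector; when `NULL`, the values in `states` are used
#'   (with any state overrides from the condition applied).
#' @param name model label.
#' @return an object of class `ode_model`.
#' @examples
#' m <- ode_model(states = c(x = 1), params = c(k = log(2)),
#'                rhs = c(x = "-k * x"), observables = c(obs = "x"))
#' tr <- simulate_model(m, c(k = log(2)), condition("ctrl"), times = c(0, 1))
#' tr$states[2, "x"]  # ~ 0.5
#' @export
ode_model <- function(states, params, rhs, observables,
                      initial_state = NULL, name = "model") {
  stopifnot(is.numeric(states), !is.null(names(states)),
            is.numeric(params), !is.null(names(params)))
  state_names <- names(states)
  param_names <- names(params)
  if (anyDuplicated(c(state_names, param_names)))
    stop("state and parameter names must be distinct", call. = FALSE)
  if (!identical(sort(names(rhs)), sort(state_names)))
    stop("rhs must provide exactly one expression per state", call. = FALSE)
  rhs <- rhs[state_names]
  allowed <- c(state_names, param_names, "t")
  rhs_exprs <- lapply(rhs, parse_model_expr, allowed = allowed)
  obs_exprs <- lapply(observables, parse_model_expr, allowed = allowed)
  n <- length(states)
  # Jacobian of f wrt states, as an n x n list-matrix of expressions
  dfdx <- vector("list", n * n)
  dim(dfdx) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dfdx[[i, j]] <- expr_deriv(rhs_exprs[[i]], state_names[j])
  m <- structure(list(
    name = name,
    state_names = state_names, param_names = param_names,
    n_states = n,
    x0 = states, params = params,
    rhs_src = rhs, obs_src = observables,
    rhs_exprs = rhs_exprs, obs_exprs = obs_exprs,
    dfdx = dfdx,
    rhs_fun = compile_rhs_function(state_names, param_names, rhs_exprs),
    initial_state = initial_state,
    cache = new.env(parent = emptyenv())
  ), class = "ode_model")
  m
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, ": ", x$n_states, " states, ",
      length(x$param_names), " parameters, ",
      length(x$obs_exprs), " observables\n", sep = "")
  invisible(x)
}

#' Define an experimental condition
#'
#' A condition names a perturbation of the base model: a map of parameter
#' or initial-state overrides (e.g. a stimulus dose or a knock-down scale)
#' applied to a copy of the parameters and initial state before
#' integration.  The base model is never modified.
#'
#' @param name condition identifier.
#' @param overrides named numeric vector; each name must be a declared
#'   parameter or state.
#' @return an object of class `sim_condition`.
#' @export
condition <- function(name, overrides = numeric(0)) {
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be named", call. = FALSE)
  structure(list(name = name, overrides = overrides),
            class = "sim_condition")
}

# Apply condition overrides to copies of theta and the initial state.
apply_condition <- function(model, theta, cond) {
  stopifnot(inherits(cond, "sim_condition"))
  ov <- cond$overrides
  bad <- setdiff(names(ov), c(model$param_names, model$state_names))
  if (length(bad))
    stop("condition '", cond$name, "' overrides undeclared identifiers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  pk <- intersect(names(ov), model$param_names)
  theta[pk] <- ov[pk]
  if (is.null(model$initial_state)) {
    x0 <- model$x0
  } else {
    x0 <- model$initial_state(theta, cond)
    x0 <- x0[model$state_names]
  }
  sk <- intersect(names(ov), model$state_names)
  x0[sk] <- ov[sk]
  list(theta = theta, x0 = x0)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop("times must be finite numeric", call. = FALSE)
  if (is.unsorted(times, strictly = FALSE) || any(diff(times) <= 0))
    stop("times must be strictly ascending", call. = FALSE)
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  times
}

integration_error <- function(model, theta, cond, detail) {
  stop(structure(class = c("scalefit_integration_error", "error",
                           "condition"),
                 list(message = paste0("integration failed for model '",
                                       model$name, "', condition '",
                                       cond$name, "': ", detail),
                      call = NULL, theta = theta, condition = cond$name)))
}

#' Simulate an ODE model under a condition
#'
#' Integrates the model with a stiff solver (`deSolve::lsoda`) and returns
#' the solution sampled exactly at the requested times.  Condition
#' overrides are applied to copies of the parameters and initial state
#' before integration; integration always starts at time 0.
#'
#' @param model an [ode_model()].
#' @param theta named numeric vector over the full parameter set.
#' @param cond a [condition()].
#' @param times strictly ascending non-negative output times.
#' @param rtol,atol solver tolerances.
#' @return a `trajectory`: list with `times` and a `n_times x n_states`
#'   `states` matrix.
#' @export
simulate_model <- function(model, theta, cond = condition("base"),
                           times, rtol = 1e-8, atol = 1e-10) {
  check_times(times)
  stopifnot(rtol > 0, atol > 0)
  theta <- resolve_theta(model, theta)
  ac <- apply_condition(model, theta, cond)
  pvec <- unname(ac$theta)
  rhs_fun <- model$rhs_fun
  snames <- model$state_names
  func <- function(t, y, parms) list(rhs_fun(t, y, parms))
  tt <- if (times[1L] > 0) c(0, times) else times
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = unname(ac$x0), times = tt,
                                    func = func, parms = pvec,
                                    rtol = rtol, atol = atol)),
    error = function(e) integration_error(model, theta, cond,
                                          conditionMessage(e)))
  if (nrow(out) < length(tt) || any(!is.finite(out)))
    integration_error(model, theta, cond,
                      "solver did not reach all output times (NaN or early stop)")
  keep <- match(times, out[, 1L])
  states <- out[keep, -1L, drop = FALSE]
  colnames(states) <- snames
  structure(list(times = times, states = states), class = "trajectory")
}

resolve_theta <- function(model, theta) {
  if (is.null(names(theta))) {
    if (length(theta) != length(model$param_names))
      stop("theta length must equal the number of declared parameters",
           call. = FALSE)
    names(theta) <- model$param_names
    return(theta)
  }
  miss <- setdiff(model$param_names, names(theta))
  if (length(miss))
    stop("theta is missing parameters: ", paste(miss, collapse = ", "),
         call. = FALSE)
  theta[model$param_names]
}

# Cached compiled augmented-system function for a set of free parameters.
aug_function <- function(model, free) {
  key <- paste0("aug|", paste(free, collapse = "|"))
  cache <- model$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  f <- compile_aug_function(model$state_names, model$param_names,
                            model$rhs_exprs, model$dfdx, free)
  cache[[key]] <- f
  f
}

#' Simulate with forward sensitivities
#'
#' Integrates the augmented system of dimension `n_states * (p + 1)`
#' holding the states together with their partial derivatives with respect
#' to each of `p` free parameters.  The sensitivity right-hand side
#' dS/dt = (df/dx) S + df/dtheta uses the symbolic derivatives computed at
#' model-build time.  Initial sensitivities account for parameter-dependent
#' initial states when an `initial_state` function was declared (zero for
#' fixed initial conditions).
#'
#' @inheritParams simulate_model
#' @param free character vector of free parameter names (subset of the
#'   declared parameters).
#' @return a `sensitivity_trajectory`: list with `trajectory` and a
#'   `n_times x n_states x p` `sensitivities` array (dimnames carry state
#'   and parameter names).
#' @export
simulate_with_sensitivities <- function(model, theta,
                                        cond = condition("base"), times,
                                        free, rtol = 1e-8, atol = 1e-10) {
  check_times(times)
  if (length(free) < 1L) stop("free must be non-empty", call. = FALSE)
  bad <- setdiff(free, model$param_names)
  if (length(bad))
    stop("unknown free parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  theta <- resolve_theta(model, theta)
  ac <- apply_condition(model, theta, cond)
  n <- model$n_states
  p <- length(free)
  aug <- aug_function(model, free)
  pvec <- unname(ac$theta)
  func <- function(t, y, parms) list(aug(t, y, parms))
  S0 <- initial_state_sensitivity(model, theta, cond, free)
  y0 <- c(unname(ac$x0), as.vector(S0))
  tt <- if (times[1L] > 0) c(0, times) else times
  out <- tryCatch(
    suppressWarnings(deSolve::lsoda(y = y0, times = tt, func = func,
                                    parms = pvec, rtol = rtol, atol = atol)),
    error = function(e) integration_error(model, theta, cond,
                                          conditionMessage(e)))
  if (nrow(out) < length(tt) || any(!is.finite(out)))
    integration_error(model, theta, cond, "augmented system failed")
  keep <- match(times, out[, 1L])
  states <- out[keep, 1L + seq_len(n), drop = FALSE]
  colnames(states) <- model$state_names
  sens <- array(out[keep, -(seq_len(n + 1L)), drop = FALSE],
                dim = c(length(times), n, p),
                dimnames = list(NULL, model$state_names, free))
  structure(list(
    trajectory = structure(list(times = times, states = states),
                           class = "trajectory"),
    sensitivities = sens, free = free
  ), class = "sensitivity_trajectory")
}

# d x0 / d theta_free; exact zero for fixed initial conditions, central
# finite differences when initial_state depends on theta.
initial_state_sensitivity <- function(model, theta, cond, free) {
  n <- model$n_states
  p <- length(free)
  S0 <- matrix(0, n, p)
  if (is.null(model$initial_state)) return(S0)
  for (k in seq_len(p)) {
    h <- 1e-7 * max(abs(theta[free[k]]), 1)
    tp <- theta; tp[free[k]] <- tp[free[k]] + h
    tm <- theta; tm[free[k]] <- tm[free[k]] - h
    xp <- apply_condition(model, tp, cond)$x0
    xm <- apply_condition(model, tm, cond)$x0
    S0[, k] <- (xp - xm) / (2 * h)
  }
  S0
}

#' Evaluate an observable along a trajectory
#'
#' Applies the output function y = g(x, theta) row-wise to the states of a
#' trajectory.
#'
#' @param trajectory a `trajectory` from [simulate_model()].
#' @param model the [ode_model()] declaring the output map.
#' @param observable observable name.
#' @param theta named parameter vector (needed only if the output function
#'   references parameters).
#' @return numeric vector, one value per output time.
#' @export
observe <- function(trajectory, model, observable, theta = NULL) {
  ex <- model$obs_exprs[[observable]]
  if (is.null(ex))
    stop("unknown observable '", observable, "'", call. = FALSE)
  plist <- if (is.null(theta)) as.list(model$params) else
    as.list(resolve_theta(model, theta))
  st <- trajectory$states
  cols <- lapply(seq_len(ncol(st)), function(j) st[, j])
  names(cols) <- model$state_names
  v <- eval(ex, c(cols, plist, list(t = trajectory$times)))
  rep_len(v, length(trajectory$times))  # constant g(x) broadcasts
}

# Observable values plus their sensitivities dy/dtheta_free via the chain
# rule dg/dx * S + dg/dtheta.  Returns list(values, dvalues[n_times x p]).
observe_with_sensitivities <- function(straj, model, observable, theta) {
  ex <- model$obs_exprs[[observable]]
  if (is.null(ex))
    stop("unknown observable '", observable, "'", call. = FALSE)
  theta <- resolve_theta(model, theta)
  free <- straj$free
  tr <- straj$trajectory
  n_t <- length(tr$times)
  p <- length(free)
  dgdx <- lapply(model$state_names, function(s) expr_deriv(ex, s))
  dgdp <- lapply(free, function(s) expr_deriv(ex, s))
  plist <- as.list(theta)
  cols <- lapply(seq_len(model$n_states), function(j) tr$states[, j])
  names(cols) <- model$state_names
  env <- c(cols, plist, list(t = tr$times))
  values <- rep_len(eval(ex, env), n_t)
  dvalues <- matrix(0, n_t, p, dimnames = list(NULL, free))
  for (j in seq_len(model$n_states)) {
    gx_j <- rep_len(eval(dgdx[[j]], env), n_t)
    if (all(gx_j == 0)) next
    dvalues <- dvalues +
      gx_j * matrix(straj$sensitivities[, j, ], n_t, p)
  }
  for (k in seq_len(p)) {
    gp_k <- eval(dgdp[[k]], env)
    if (!all(gp_k == 0)) dvalues[, k] <- dvalues[, k] + rep_len(gp_k, n_t)
  }
  list(values = values, dvalues = dvalues)
}
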
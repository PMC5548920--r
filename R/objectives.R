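# Objective machinery: the DNS/SF scaling schemes crossed with the LS/LL
# objective forms, the assembled free-parameter vector, residual Jacobians
# from forward sensitivities, and evaluation/time accounting.

PENALTY <- 1e10  # finite objective value for infeasible parameter sets
LL_C0 <- 20      # shift making the log-sigma term usable as a residual

#' Objective specification
#'
#' @param scaling `"dns"` (data-driven normalisation of the simulations)
#'   or `"sf"` (one estimated scaling factor per observable).
#' @param form `"ls"` (least squares) or `"ll"` (log-likelihood with the
#'   two-parameter error model sigma = s_a + s_b * |mu|).
#' @return an object of class `objective_spec`.
#' @export
objective_spec <- function(scaling = c("dns", "sf"), form = c("ls", "ll")) {
  structure(list(scaling = match.arg(scaling), form = match.arg(form)),
            class = "objective_spec")
}

#' Evaluation and time accounting
#'
#' Tracks objective calls (per-call convention: one full evaluation of the
#' objective, including a sensitivity-equation gradient, counts 1),
#' gradient calls, finite-difference-equivalent evaluations (p + 1 charged
#' per gradient, whether obtained by FD or by sensitivity equations), and
#' wall-clock seconds measured independently of either count.
#'
#' @return an environment of class `evaluation_counter`.
#' @export
evaluation_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$objective_calls <- 0L
  e$gradient_calls <- 0L
  e$fd_equivalent_evals <- 0
  e$t0 <- proc.time()[["elapsed"]]
  class(e) <- "evaluation_counter"
  e
}

#' @export
print.evaluation_counter <- function(x, ...) {
  cat("<evaluation_counter> objective_calls=", x$objective_calls,
      " gradient_calls=", x$gradient_calls,
      " fd_equivalent=", x$fd_equivalent_evals,
      " elapsed=", round(counter_elapsed(x), 3), "s\n", sep = "")
  invisible(x)
}

#' Elapsed wall-clock seconds of a counter
#' @param counter an [evaluation_counter()].
#' @export
counter_elapsed <- function(counter) proc.time()[["elapsed"]] - counter$t0

#' Assemble the free-parameter vector for a scheme/objective combination
#'
#' Layout order: free kinetic parameters, then one scaling factor per
#' observable (SF scheme only), then the error-model parameters
#' (s_a, s_b) (LL form only).  With 10 free kinetic parameters and 8
#' observables this gives lengths 10 (DNS-LS), 18 (SF-LS) and 20 (SF-LL).
#'
#' @param problem an [ode_problem()].
#' @param spec an [objective_spec()].
#' @return a `free_parameter_vector`: list with `values` (named), `layout`
#'   (index vectors `kinetic`, `scaling_factors`, `error_model`) and
#'   `bounds` (matrix, columns lower/upper).
#' @export
assemble_free_vector <- function(problem, spec) {
  if (length(problem$free) < 1L)
    stop("problem declares no free parameters", call. = FALSE)
  obs <- sort(unique(problem$data$observable))
  kin <- problem$free
  values <- sqrt(problem$bounds[, 1] * problem$bounds[, 2])
  names(values) <- kin
  bounds <- problem$bounds
  layout <- list(kinetic = seq_along(kin),
                 scaling_factors = integer(0),
                 error_model = integer(0))
  if (spec$scaling == "sf") {
    a <- rep(1, length(obs))
    names(a) <- paste0("alpha_", obs)
    layout$scaling_factors <- length(values) + seq_along(a)
    values <- c(values, a)
    bounds <- rbind(bounds, matrix(rep(c(1e-6, 1e6), each = length(a)),
                                   ncol = 2,
                                   dimnames = list(names(a), NULL)))
  }
  if (spec$form == "ll") {
    s <- c(s_a = 0.1, s_b = 0.1)
    layout$error_model <- length(values) + seq_along(s)
    values <- c(values, s)
    bounds <- rbind(bounds, matrix(rep(c(1e-6, 1e6), each = 2), ncol = 2,
                                   dimnames = list(names(s), NULL)))
  }
  colnames(bounds) <- c("lower", "upper")
  structure(list(values = values, layout = layout, bounds = bounds,
                 observables = obs),
            class = "free_parameter_vector")
}

# Map dataset rows to simulated observable values (and sensitivities wrt
# the free kinetic parameters).  One integration per condition, at the
# union of that condition's measurement times; no interpolation.
make_simulator <- function(problem) {
  ds <- problem$data
  model <- problem$model
  conds <- unique(ds$condition)
  per_cond <- lapply(conds, function(cn)
    sort(unique(ds$time[ds$condition == cn])))
  names(per_cond) <- conds
  free <- problem$free
  n_rows <- nrow(ds)
  function(theta_full, with_sens = FALSE) {
    y <- numeric(n_rows)
    dY <- if (with_sens)
      matrix(0, n_rows, length(free), dimnames = list(NULL, free))
    for (cn in conds) {
      times <- per_cond[[cn]]
      if (with_sens) {
        straj <- simulate_with_sensitivities(model, theta_full,
                                             problem$conditions[[cn]],
                                             times, free,
                                             rtol = problem$rtol,
                                             atol = problem$atol)
        for (ob in unique(ds$observable[ds$condition == cn])) {
          ov <- observe_with_sensitivities(straj, model, ob, theta_full)
          idx <- which(ds$condition == cn & ds$observable == ob)
          ti <- match(ds$time[idx], times)
          y[idx] <- ov$values[ti]
          dY[idx, ] <- ov$dvalues[ti, , drop = FALSE]
        }
      } else {
        traj <- simulate_model(model, theta_full, problem$conditions[[cn]],
                               times, rtol = problem$rtol,
                               atol = problem$atol)
        for (ob in unique(ds$observable[ds$condition == cn])) {
          idx <- which(ds$condition == cn & ds$observable == ob)
          ti <- match(ds$time[idx], times)
          y[idx] <- observe(traj, model, ob, theta_full)[ti]
        }
      }
    }
    if (with_sens) list(y = y, dY = dY) else list(y = y)
  }
}

# The dataset on the scale the fit sees: normalised once if the directive
# asks for it and the data are still raw.
fitted_dataset <- function(problem) {
  ds <- problem$data
  if (!isTRUE(attr(ds, "normalized")) &&
      attr(ds, "normalization")$scheme != "none")
    ds <- normalize_data(ds)
  ds
}

#' Build the counted objective closures for a problem
#'
#' Returns the residual function, sensitivity-equation and
#' finite-difference Jacobians, and the scalar objective for one
#' scaling-scheme/objective-form combination, all incrementing a shared
#' [evaluation_counter()].  Infeasible parameter sets (failed integration,
#' non-positive simulated reference, non-positive sigma) yield the finite
#' penalty `1e10` rather than an error, so derivative-free optimisers can
#' recover.
#'
#' For the LL form the residual vector is the augmented form
#' `[r_i/(sqrt(2) sigma_i); sqrt(log(sigma_i) + C0)]` whose sum of squares
#' equals the negative log-likelihood up to an additive constant, making
#' the same Levenberg-Marquardt loop applicable to both forms.
#'
#' @param problem an [ode_problem()].
#' @param spec an [objective_spec()].
#' @param counter an [evaluation_counter()] (a fresh one by default).
#' @return list with elements `free` (the assembled
#'   `free_parameter_vector`), `residual_fn(values)`, `jacobian_se(values)`,
#'   `jacobian_fd(values, r0)`, `objective_fn(values)`,
#'   `resid_to_objective(r)`, `predictions(values)` and `counter`.
#' @export
build_objective <- function(problem, spec, counter = evaluation_counter()) {
  free_vec <- assemble_free_vector(problem, spec)
  ds <- fitted_dataset(problem)
  sim <- make_simulator_on(problem, ds)
  y_data <- ds$value
  n <- length(y_data)
  obs_of_row <- match(ds$observable, free_vec$observables)
  model <- problem$model
  theta_base <- model$params
  kin <- problem$free
  lay <- free_vec$layout
  p_total <- length(free_vec$values)

  split_values <- function(values) {
    list(theta = {
      th <- theta_base
      th[kin] <- values[lay$kinetic]
      th
    },
    alpha = if (length(lay$scaling_factors)) values[lay$scaling_factors],
    s = if (length(lay$error_model)) values[lay$error_model])
  }

  # mu_i: prediction on the data scale, plus its Jacobian when asked
  predict_mu <- function(values, with_sens = FALSE) {
    sv <- split_values(values)
    so <- sim(sv$theta, with_sens = with_sens)
    if (spec$scaling == "dns") {
      dn <- dns_normalize(so$y, ds, so$dY)
      mu <- dn$mu
      dmu <- dn$dmu
    } else {
      a_row <- sv$alpha[obs_of_row]
      mu <- a_row * so$y
      dmu <- if (with_sens) {
        d <- a_row * so$dY
        dalpha <- matrix(0, n, length(sv$alpha))
        dalpha[cbind(seq_len(n), obs_of_row)] <- so$y
        cbind(d, dalpha)
      }
    }
    if (with_sens) {
      # pad with zero columns for the error-model segment
      if (length(lay$error_model))
        dmu <- cbind(dmu, matrix(0, n, length(lay$error_model)))
      colnames(dmu) <- names(free_vec$values)
    }
    list(mu = mu, dmu = dmu, s = sv$s)
  }

  n_res <- n * (1L + (spec$form == "ll"))
  penalty_residuals <- function() {
    r <- rep(sqrt(PENALTY / n_res), n_res)
    attr(r, "penalty") <- TRUE
    r
  }

  raw_to_fit_residuals <- function(mu, s) {
    r <- y_data - mu
    if (spec$form == "ls") return(r)
    sigma <- s[["s_a"]] + s[["s_b"]] * abs(mu)
    if (any(sigma <= 0) || any(log(sigma) + LL_C0 <= 0)) return(NULL)
    c(r / (sqrt(2) * sigma), sqrt(log(sigma) + LL_C0))
  }

  resid_to_objective <- function(r) {
    if (isTRUE(attr(r, "penalty"))) return(PENALTY)
    if (spec$form == "ls") sum(r^2) else sum(r^2) - n * LL_C0
  }

  residual_fn <- function(values) {
    counter$objective_calls <- counter$objective_calls + 1L
    counter$fd_equivalent_evals <- counter$fd_equivalent_evals + 1
    pr <- tryCatch(predict_mu(values, with_sens = FALSE),
                   scalefit_integration_error = function(e) NULL,
                   scalefit_normalization_error = function(e) NULL)
    if (is.null(pr)) return(penalty_residuals())
    r <- raw_to_fit_residuals(pr$mu, pr$s)
    if (is.null(r) || any(!is.finite(r))) return(penalty_residuals())
    r
  }

  objective_fn <- function(values) resid_to_objective(residual_fn(values))

  jacobian_se <- function(values) {
    counter$gradient_calls <- counter$gradient_calls + 1L
    counter$objective_calls <- counter$objective_calls + 1L
    counter$fd_equivalent_evals <- counter$fd_equivalent_evals + (p_total + 1)
    pr <- tryCatch(predict_mu(values, with_sens = TRUE),
                   scalefit_integration_error = function(e) NULL,
                   scalefit_normalization_error = function(e) NULL)
    if (is.null(pr))
      return(list(r = penalty_residuals(), J = matrix(0, n_res, p_total)))
    mu <- pr$mu; dmu <- pr$dmu
    if (spec$form == "ls") {
      r <- y_data - mu
      return(list(r = r, J = -dmu))
    }
    s <- pr$s
    sigma <- s[["s_a"]] + s[["s_b"]] * abs(mu)
    r_raw <- y_data - mu
    if (any(sigma <= 0) || any(log(sigma) + LL_C0 <= 0))
      return(list(r = penalty_residuals(), J = matrix(0, n_res, p_total)))
    # dsigma/dv: kinetic & alpha columns via mu, plus the s_a/s_b columns
    dsigma <- s[["s_b"]] * sign(mu) * dmu
    dsigma[, lay$error_model[1L]] <- 1
    dsigma[, lay$error_model[2L]] <- abs(mu)
    J1 <- (-dmu * sigma - r_raw * dsigma) / (sqrt(2) * sigma^2)
    J2 <- dsigma / (2 * sigma * sqrt(log(sigma) + LL_C0))
    r <- c(r_raw / (sqrt(2) * sigma), sqrt(log(sigma) + LL_C0))
    list(r = r, J = rbind(J1, J2))
  }

  jacobian_fd <- function(values, r0 = NULL, h = 1e-6) {
    counter$gradient_calls <- counter$gradient_calls + 1L
    if (is.null(r0)) r0 <- residual_fn(values)
    J <- matrix(0, length(r0), p_total)
    for (k in seq_len(p_total)) {
      hk <- h * max(abs(values[k]), 1)
      vk <- values
      vk[k] <- vk[k] + hk
      rk <- residual_fn(vk)
      J[, k] <- (rk - r0) / hk
    }
    list(r = r0, J = J)
  }

  list(free = free_vec, residual_fn = residual_fn,
       jacobian_se = jacobian_se, jacobian_fd = jacobian_fd,
       objective_fn = objective_fn, resid_to_objective = resid_to_objective,
       predictions = function(values) predict_mu(values, FALSE)$mu,
       spec = spec, counter = counter, n_data = n)
}

# simulator bound to the dataset used for fitting (same rows/order)
make_simulator_on <- function(problem, ds) {
  problem$data <- ds
  make_simulator(problem)
}

# DNS: normalised simulation and (optionally) its Jacobian by the quotient
# rule through the group reference.
dns_normalize <- function(y, ds, dY = NULL) {
  spec <- attr(ds, "normalization")
  if (spec$scheme == "none")
    return(list(mu = y, dmu = dY))
  key <- paste(ds$observable, ds$replicate, sep = "\r")
  mu <- numeric(length(y))
  dmu <- if (!is.null(dY)) matrix(0, nrow(dY), ncol(dY))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (spec$scheme == "average") {
      ref <- mean(y[idx])
      dref <- if (!is.null(dY)) colMeans(dY[idx, , drop = FALSE])
    } else if (spec$scheme == "max") {
      i_max <- idx[which.max(y[idx])]
      ref <- y[i_max]
      dref <- if (!is.null(dY)) dY[i_max, ]
    } else {  # reference_point
      hit <- idx[ds$condition[idx] == spec$reference_condition &
                 ds$time[idx] == spec$reference_time]
      if (length(hit) != 1L)
        stop("reference point not found exactly once in simulated group",
             call. = FALSE)
      ref <- y[hit]
      dref <- if (!is.null(dY)) dY[hit, ]
    }
    if (!is.finite(ref) || ref <= 0)
      stop(structure(class = c("scalefit_normalization_error", "error",
                               "condition"),
                     list(message = "simulated reference <= 0",
                          call = NULL)))
    mu[idx] <- y[idx] / ref
    if (!is.null(dY))
      dmu[idx, ] <- (ref * dY[idx, , drop = FALSE] -
                       outer(y[idx], dref)) / ref^2
  }
  list(mu = mu, dmu = dmu)
}

#' Residuals of a scheme/objective combination
#'
#' Convenience wrapper: the raw residual vector `r_i = y_tilde_i - mu_i`
#' (one entry per data point, dataset order), where `mu` is the
#' DNS-normalised or scaling-factor-scaled simulation.
#'
#' @param values numeric free-parameter values (layout of
#'   [assemble_free_vector()]) or a `free_parameter_vector`.
#' @param problem an [ode_problem()].
#' @param spec an [objective_spec()].
#' @export
fit_residuals <- function(values, problem, spec) {
  ob <- build_objective(problem, spec)
  v <- if (inherits(values, "free_parameter_vector")) values$values else values
  pr <- predict_for(ob, v)
  ds <- fitted_dataset(problem)
  ds$value - pr
}

predict_for <- function(ob, values) ob$predictions(values)

#' Least-squares objective
#' @inheritParams fit_residuals
#' @return sum of squared residuals (or the penalty `1e10` for an
#'   infeasible parameter set).
#' @export
objective_ls <- function(values, problem, spec = objective_spec("dns", "ls")) {
  spec$form <- "ls"
  ob <- build_objective(problem, spec)
  v <- if (inherits(values, "free_parameter_vector")) values$values else values
  ob$objective_fn(v)
}

#' Negative log-likelihood objective
#'
#' Independent Gaussian errors with sigma_i = s_a + s_b * |mu_i|:
#' sum over data points of `r_i^2 / (2 sigma_i^2) + log(sigma_i)`
#' (additive constant dropped).
#'
#' @inheritParams fit_residuals
#' @export
objective_ll <- function(values, problem, spec = objective_spec("dns", "ll")) {
  spec$form <- "ll"
  ob <- build_objective(problem, spec)
  v <- if (inherits(values, "free_parameter_vector")) values$values else values
  ob$objective_fn(v)
}

#' Sensitivity-equation residual Jacobian
#'
#' The Jacobian of the (possibly LL-augmented) residual vector with
#' respect to the free-parameter vector, assembled from forward
#' sensitivities through the output map and, for DNS, through the
#' normalisation quotient rule; scaling-factor columns are `-y_i` on the
#' rows of the matching observable.
#'
#' @inheritParams fit_residuals
#' @return matrix `n_residuals x p`.
#' @export
se_jacobian <- function(values, problem, spec) {
  ob <- build_objective(problem, spec)
  v <- if (inherits(values, "free_parameter_vector")) values$values else values
  ob$jacobian_se(v)$J
}

#' Forward finite-difference gradient of a scalar function
#'
#' `(f(x + h_k e_k) - f(x)) / h_k` with `h_k = h * max(|x_k|, 1)`:
#' exactly `p + 1` evaluations of `f`.  Non-finite probe values are
#' replaced by the penalty value with a warning.
#'
#' @param f scalar function.
#' @param x evaluation point.
#' @param h relative step.
#' @export
fd_gradient <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  if (!is.finite(f0)) stop("objective not finite at x", call. = FALSE)
  g <- numeric(length(x))
  for (k in seq_along(x)) {
    hk <- h * max(abs(x[k]), 1)
    xk <- x
    xk[k] <- xk[k] + hk
    fk <- f(xk)
    if (!is.finite(fk)) {
      warning("non-finite objective at FD probe; using penalty value")
      fk <- PENALTY
    }
    g[k] <- (fk - f0) / hk
  }
  g
}
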
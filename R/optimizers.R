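# Optimisers: Levenberg-Marquardt with Latin hypercube restarts (FD or
# sensitivity-equation gradients) and GLSDC (genetic global phase with
# diversity control alternating with Powell's derivative-free local
# search).  All emit comparable best-so-far traces against both the
# evaluation counters and the wall clock.

#' Optimiser configuration
#'
#' @param algorithm `"levmar_fd"`, `"levmar_se"` or `"glsdc"`.
#' @param max_evals budget on objective calls (per-call convention).
#' @param max_seconds wall-clock budget.
#' @param ftol relative objective-change tolerance.
#' @param xtol step-norm tolerance.
#' @param max_iter per-start Levenberg-Marquardt iteration cap.
#' @param n_starts Latin hypercube restarts (LevMar).
#' @param population_size GLSDC population (default `min(10 p, 200)`).
#' @param target_objective optional early-stop target: the run ends once
#'   the best objective falls at or below it (default `-Inf`, disabled).
#' @param seed integer seed; identical config + problem gives an
#'   identical trace.
#' @export
optimizer_config <- function(algorithm = c("levmar_fd", "levmar_se",
                                           "glsdc"),
                             max_evals = Inf, max_seconds = Inf,
                             ftol = 1e-10, xtol = 1e-10, max_iter = 500L,
                             n_starts = 8L, population_size = NULL,
                             target_objective = -Inf, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(max_evals > 0, max_seconds > 0, ftol > 0, xtol > 0)
  structure(list(algorithm = algorithm, max_evals = max_evals,
                 max_seconds = max_seconds, ftol = ftol, xtol = xtol,
                 max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts),
                 population_size = population_size,
                 target_objective = target_objective,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

budget_exhausted <- function(counter, config) {
  counter$objective_calls >= config$max_evals ||
    counter_elapsed(counter) >= config$max_seconds
}

# Best-so-far trace recorder bound to a counter.
make_trace <- function(counter) {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e$best <- Inf
  e$record <- function(objective, force = FALSE) {
    if (objective < e$best || force) {
      if (objective < e$best) e$best <- objective
      e$rows[[length(e$rows) + 1L]] <- data.frame(
        elapsed_seconds = counter_elapsed(counter),
        objective_calls = counter$objective_calls,
        fd_equivalent_evals = counter$fd_equivalent_evals,
        best_objective = e$best)
    }
    invisible(NULL)
  }
  e$as_df <- function() do.call(rbind, e$rows)
  e
}

#' Log-uniform Latin hypercube sample
#'
#' Stratified design over the bound box: per dimension, exactly one
#' sample falls in each of `n` equal log-width strata.
#'
#' @param bounds `p x 2` matrix of positive (lower, upper) bounds.
#' @param n number of points.
#' @param seed integer seed.
#' @return `n x p` matrix on the natural (exponentiated) scale.
#' @export
latin_hypercube_sample <- function(bounds, n, seed = 1L) {
  stopifnot(n >= 1L, ncol(bounds) == 2L)
  if (any(bounds <= 0))
    stop("log-uniform sampling needs positive bounds", call. = FALSE)
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("need lower < upper per dimension", call. = FALSE)
  p <- nrow(bounds)
  set.seed(seed)
  u <- lhs::randomLHS(n, p)
  lo <- log10(bounds[, 1]); hi <- log10(bounds[, 2])
  x <- 10^(sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`))
  colnames(x) <- rownames(bounds)
  x
}

#' Levenberg-Marquardt minimisation
#'
#' Classic damped Gauss-Newton: solve `(J'J + lambda D) delta = -J'r`
#' with `D = diag(J'J)`; the damping `lambda` decreases multiplicatively
#' on an accepted step and increases on rejection (singular normal
#' equations are handled the same way, never by a crash).  Terminates on
#' `ftol` (relative objective change), `xtol` (step norm), the iteration
#' cap, or the counter budget.  Works in whatever search space the
#' supplied functions define; callers fitting ODE problems pass log10
#' coordinates (see [multistart_levmar()]), which enforces positivity,
#' with steps clamped to the bound box.
#'
#' @param residual_fn function(x) -> residual vector.
#' @param jacobian_fn function(x) -> list(r, J).
#' @param x0 start point.
#' @param config an [optimizer_config()].
#' @param counter shared [evaluation_counter()].
#' @param lower,upper box constraints in the search space.
#' @param resid_to_objective function mapping a residual vector to the
#'   scalar objective (default: sum of squares).
#' @param trace optional trace recorder from the caller.
#' @return list with `x`, `objective`, `iterations`, `termination`.
#' @export
levmar_minimize <- function(residual_fn, jacobian_fn, x0,
                            config = optimizer_config("levmar_fd"),
                            counter = evaluation_counter(),
                            lower = rep(-Inf, length(x0)),
                            upper = rep(Inf, length(x0)),
                            resid_to_objective = function(r) sum(r^2),
                            trace = NULL) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  x <- clamp(x0)
  rJ <- jacobian_fn(x)
  f <- resid_to_objective(rJ$r)
  if (!is.null(trace)) trace$record(f)
  lambda <- 1e-3
  termination <- "max_iter"
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    if (budget_exhausted(counter, config)) { termination <- "budget"; break }
    A <- crossprod(rJ$J)
    g <- crossprod(rJ$J, rJ$r)
    D <- pmax(diag(A), 1e-12)
    accepted <- FALSE
    repeat {
      delta <- tryCatch(solve(A + lambda * diag(D, nrow = length(D)), -g),
                        error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- lambda * 10
        if (lambda > 1e14) { termination <- "stalled"; break }
        next
      }
      x_new <- clamp(x + as.numeric(delta))
      r_new <- residual_fn(x_new)
      f_new <- resid_to_objective(r_new)
      small_step <- sqrt(sum((x_new - x)^2)) <=
        config$xtol * (1 + sqrt(sum(x^2)))
      if (f_new < f) {
        accepted <- TRUE
        improvement <- f - f_new
        x <- x_new
        f <- f_new
        lambda <- max(lambda / 3, 1e-14)
        if (!is.null(trace)) trace$record(f)
        if (improvement <= config$ftol * max(f, 1e-300)) {
          termination <- "ftol"
        } else if (small_step) {
          termination <- "xtol"
        }
        break
      }
      # rejected trial: stationary point if nothing changes any more
      if (abs(f_new - f) <= config$ftol * max(f, 1e-300) && small_step) {
        termination <- "ftol"
        break
      }
      lambda <- lambda * 2
      if (lambda > 1e14) { termination <- "stalled"; break }
      if (budget_exhausted(counter, config)) { termination <- "budget"; break }
    }
    if (termination %in% c("ftol", "xtol", "stalled", "budget")) break
    if (!accepted) break
    rJ <- jacobian_fn(x)
    f <- min(f, resid_to_objective(rJ$r))
  }
  list(x = x, objective = f, iterations = iter, termination = termination)
}

# log10 wrappers around a built objective for bounded positive search.
log_space_functions <- function(ob, variant = c("se", "fd")) {
  variant <- match.arg(variant)
  ln10 <- log(10)
  res_log <- function(u) ob$residual_fn(10^u)
  jac_log <- if (variant == "se") {
    function(u) {
      v <- 10^u
      rJ <- ob$jacobian_se(v)
      rJ$J <- sweep(rJ$J, 2L, v * ln10, `*`)
      rJ
    }
  } else {
    function(u) {
      rJ <- ob$jacobian_fd(10^u)  # h is relative; probe in natural scale
      rJ$J <- sweep(rJ$J, 2L, 10^u * ln10, `*`)
      rJ
    }
  }
  list(residual = res_log, jacobian = jac_log)
}

#' Multistart Levenberg-Marquardt over Latin hypercube starts
#'
#' One LM run per start until the global budget (evaluations or seconds)
#' is exhausted; kinetic parameters (and scaling factors / error
#' parameters) are searched in log10 space within their bounds.  Each
#' completed start contributes a row to the returned ensemble; the trace
#' records the global best over time.
#'
#' @param problem an [ode_problem()].
#' @param spec an [objective_spec()].
#' @param config an [optimizer_config()] with algorithm `levmar_fd` or
#'   `levmar_se`.
#' @param counter shared [evaluation_counter()] (fresh by default).
#' @return an `optimizer_result`; `$ensemble` holds the per-start
#'   [estimate_ensemble()].
#' @export
multistart_levmar <- function(problem, spec, config,
                              counter = evaluation_counter()) {
  stopifnot(config$algorithm %in% c("levmar_fd", "levmar_se"))
  ob <- build_objective(problem, spec, counter)
  variant <- sub("levmar_", "", config$algorithm)
  fns <- log_space_functions(ob, variant)
  bounds <- ob$free$bounds
  starts <- latin_hypercube_sample(bounds, config$n_starts, config$seed)
  lo <- log10(bounds[, 1]); hi <- log10(bounds[, 2])
  trace <- make_trace(counter)
  est <- list(); objs <- numeric(0); terms <- character(0)
  for (s in seq_len(config$n_starts)) {
    if (s > 1L && (budget_exhausted(counter, config) ||
                   (length(objs) && min(objs) <= config$target_objective)))
      break
    u0 <- log10(starts[s, ])
    fit <- levmar_minimize(fns$residual, fns$jacobian, u0, config, counter,
                           lower = lo, upper = hi,
                           resid_to_objective = ob$resid_to_objective,
                           trace = trace)
    est[[length(est) + 1L]] <- 10^fit$x
    objs <- c(objs, fit$objective)
    terms <- c(terms, fit$termination)
  }
  trace$record(min(objs), force = TRUE)
  estimates <- do.call(rbind, est)
  colnames(estimates) <- rownames(bounds)
  best <- which.min(objs)
  ens <- estimate_ensemble(estimates, objs, algorithm = config$algorithm,
                           spec = spec, seeds = config$seed,
                           layout = ob$free$layout)
  structure(list(best_values = estimates[best, ],
                 best_objective = objs[best],
                 trace = trace$as_df(),
                 termination_reason = terms[best],
                 ensemble = ens, counter = counter),
            class = "optimizer_result")
}

#' Powell's conjugate-direction search
#'
#' Derivative-free local minimisation: line searches (Brent) along a set
#' of directions, with the direction of largest decrease replaced by the
#' net cycle displacement.  Never returns a point worse than the start.
#'
#' @param objective_fn scalar function.
#' @param x0 start point.
#' @param tol relative improvement tolerance per cycle.
#' @param lower,upper box constraints.
#' @param max_cycles cap on direction cycles.
#' @param line_tol absolute tolerance of the Brent line searches.
#' @return list with `x` and `objective`.
#' @export
powell_search <- function(objective_fn, x0, tol = 1e-8,
                          lower = rep(-Inf, length(x0)),
                          upper = rep(Inf, length(x0)),
                          max_cycles = 20L, line_tol = 1e-9) {
  clamp <- function(x) pmin(pmax(x, lower), upper)
  p <- length(x0)
  x <- clamp(x0)
  f <- objective_fn(x)
  dirs <- diag(p)
  span <- if (all(is.finite(lower)) && all(is.finite(upper)))
    max(upper - lower) else 4
  step_mem <- rep(0.1 * span, p + 1L)  # last successful scale per direction
  # bracket outward from the previous step scale, then refine with Brent;
  # far cheaper than searching the whole box when steps have become small
  line_min <- function(x, d, f_at_x, mem_i) {
    phi <- function(a) objective_fn(clamp(x + a * d))
    s <- max(min(step_mem[mem_i], span), 1e2 * line_tol)
    fp <- phi(s); fm <- phi(-s)
    if (fp < f_at_x || fm < f_at_x) {
      sgn <- if (fp <= fm) 1 else -1
      a1 <- sgn * s; f1 <- if (sgn > 0) fp else fm
      a2 <- a1 * 2.618
      f2 <- phi(a2)
      while (f2 < f1 && abs(a2) < 2 * span) {
        a1 <- a2; f1 <- f2
        a2 <- a2 * 2.618
        f2 <- phi(a2)
      }
      iv <- sort(c(-0.25 * a1, a2))
    } else {
      # both probes uphill: minimum (if any) lies between them
      iv <- c(-s, s)
    }
    opt <- stats::optimize(phi, interval = iv, tol = line_tol)
    if (opt$objective < f_at_x) {
      step_mem[mem_i] <<- max(abs(opt$minimum), 1e2 * line_tol)
      list(x = clamp(x + opt$minimum * d), f = opt$objective)
    } else {
      step_mem[mem_i] <<- max(s / 4, 1e2 * line_tol)
      list(x = x, f = f_at_x)
    }
  }
  for (cyc in seq_len(max_cycles)) {
    x_old <- x; f_old <- f
    biggest_drop <- 0; biggest_i <- 1L
    for (i in seq_len(p)) {
      lm <- line_min(x, dirs[, i], f, i)
      if (f - lm$f > biggest_drop) { biggest_drop <- f - lm$f; biggest_i <- i }
      x <- lm$x; f <- lm$f
    }
    d_net <- x - x_old
    nrm <- sqrt(sum(d_net^2))
    if (nrm > 1e-14) {
      # replace a direction only when the extrapolation test says the net
      # displacement is a genuinely new descent direction; replacing
      # unconditionally degenerates the set on curved valleys
      f_ex <- objective_fn(clamp(2 * x - x_old))
      if (f_ex < f_old) {
        t_crit <- 2 * (f_old - 2 * f + f_ex) *
          (f_old - f - biggest_drop)^2 - biggest_drop * (f_old - f_ex)^2
        if (t_crit < 0) {
          lm <- line_min(x, d_net, f, p + 1L)
          x <- lm$x; f <- lm$f
          step_mem[biggest_i] <- step_mem[p]
          dirs[, biggest_i] <- dirs[, p]
          dirs[, p] <- d_net / nrm
        }
      }
    }
    if (f_old - f <= tol * max(abs(f_old), 1e-300)) break
  }
  list(x = x, objective = f)
}

#' GLSDC: genetic global search with diversity control plus Powell
#'
#' Alternates a real-coded genetic phase with Powell local refinement.
#' The search lives in coordinates normalised to the unit box of the
#' log10-transformed bounds.  Diversity control: after each generation,
#' candidates (parents and offspring, best first) enter the next
#' population only if they are at least `delta` away (Euclidean distance
#' in the normalised log space) from the individuals already retained;
#' remaining slots are filled with the best rejected candidates, which
#' prevents population collapse onto one basin.  Powell's method then
#' refines the top `n_local` mutually distinct individuals.  No gradient
#' is ever requested.
#'
#' @param objective_fn scalar function of the natural-scale parameter
#'   vector (counted by the caller's closure).
#' @param bounds `p x 2` positive bounds matrix.
#' @param config an [optimizer_config()] with algorithm `"glsdc"`.
#' @param counter shared [evaluation_counter()].
#' @param delta diversity distance threshold in normalised log space.
#' @param n_local individuals refined by Powell per cycle.
#' @return an `optimizer_result`.
#' @export
glsdc_run <- function(objective_fn, bounds, config,
                      counter = evaluation_counter(), delta = 0.1,
                      n_local = 3L) {
  p <- nrow(bounds)
  lo <- log10(bounds[, 1]); hi <- log10(bounds[, 2])
  to_nat <- function(z) 10^(lo + z * (hi - lo))
  f_z <- function(z) objective_fn(to_nat(pmin(pmax(z, 0), 1)))
  N <- config$population_size %||% min(10L * p, 200L)
  if (N < 4L) stop("population_size must be >= 4", call. = FALSE)
  set.seed(config$seed)
  Z <- lhs::randomLHS(N, p)
  fv <- apply(Z, 1L, f_z)
  trace <- make_trace(counter)
  trace$record(min(fv))
  mut_rate <- 1 / p
  termination <- "budget"
  # reserve the tail of the budget for one deep polish of the incumbent
  polish_due <- function()
    counter$objective_calls >= 0.7 * config$max_evals ||
      counter_elapsed(counter) >= 0.7 * config$max_seconds
  deep_polish <- function() {
    j <- which.min(fv)
    ps <- powell_search(f_z, Z[j, ], tol = config$ftol,
                        lower = rep(0, p), upper = rep(1, p),
                        max_cycles = 2L * p, line_tol = 1e-9)
    if (ps$objective < fv[j]) { Z[j, ] <<- ps$x; fv[j] <<- ps$objective }
    trace$record(min(fv))
  }
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    if (cycle > config$max_iter) { termination <- "max_iter"; break }
    if (budget_exhausted(counter, config)) break
    if (min(fv) <= config$target_objective) { termination <- "target"; break }
    if (polish_due()) { deep_polish(); termination <- "budget"; break }
    # --- genetic generation: tournament parents, BLX-0.5, mutation ---
    off <- matrix(0, N, p)
    for (i in seq_len(N)) {
      c1 <- sample.int(N, 2L); c2 <- sample.int(N, 2L)
      p1 <- Z[c1[which.min(fv[c1])], ]
      p2 <- Z[c2[which.min(fv[c2])], ]
      lo_g <- pmin(p1, p2); hi_g <- pmax(p1, p2)
      d <- hi_g - lo_g
      child <- stats::runif(p, lo_g - 0.5 * d, hi_g + 0.5 * d)
      mut <- stats::runif(p) < mut_rate
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1)
      off[i, ] <- pmin(pmax(child, 0), 1)
    }
    f_off <- numeric(N)
    for (i in seq_len(N)) {
      if (budget_exhausted(counter, config)) { f_off[i:N] <- Inf; break }
      f_off[i] <- f_z(off[i, ])
    }
    # --- diversity control: distance-gated elitist survival ---
    pool <- rbind(Z, off)
    f_pool <- c(fv, f_off)
    ord <- order(f_pool)  # ties broken by lower index
    keep <- integer(0)
    for (j in ord) {
      if (length(keep) >= N) break
      if (length(keep) == 0L) { keep <- j; next }
      dmin <- min(sqrt(rowSums(
        (pool[keep, , drop = FALSE] -
           matrix(pool[j, ], length(keep), p, byrow = TRUE))^2)))
      if (dmin >= delta) keep <- c(keep, j)
    }
    if (length(keep) < N)
      keep <- c(keep, setdiff(ord, keep)[seq_len(N - length(keep))])
    Z <- pool[keep, , drop = FALSE]
    fv <- f_pool[keep]
    trace$record(min(fv))
    if (budget_exhausted(counter, config)) break
    # --- local phase: Powell on the top distinct individuals ---
    ord2 <- order(fv)
    chosen <- integer(0)
    for (j in ord2) {
      if (length(chosen) >= n_local) break
      if (length(chosen) == 0L ||
          min(sqrt(rowSums((Z[chosen, , drop = FALSE] -
                              matrix(Z[j, ], length(chosen), p,
                                     byrow = TRUE))^2))) >= delta)
        chosen <- c(chosen, j)
    }
    for (j in chosen) {
      if (budget_exhausted(counter, config)) break
      ps <- powell_search(f_z, Z[j, ], tol = config$ftol,
                          lower = rep(0, p), upper = rep(1, p),
                          max_cycles = 2L, line_tol = 1e-6)
      if (ps$objective < fv[j]) { Z[j, ] <- ps$x; fv[j] <- ps$objective }
      trace$record(min(fv))
      if (min(fv) <= config$target_objective) break
    }
  }
  if (min(fv) > config$target_objective && !polish_due() &&
      termination != "target") deep_polish()
  best <- which.min(fv)
  x_best <- to_nat(Z[best, ])
  names(x_best) <- rownames(bounds)
  trace$record(fv[best], force = TRUE)
  structure(list(best_values = x_best, best_objective = fv[best],
                 trace = trace$as_df(), termination_reason = termination,
                 counter = counter),
            class = "optimizer_result")
}

#' Fit a problem with one algorithm / scheme / objective combination
#'
#' Dispatches to [multistart_levmar()] or [glsdc_run()] on the objective
#' built by [build_objective()].
#'
#' @inheritParams multistart_levmar
#' @export
fit_model <- function(problem, spec, config,
                      counter = evaluation_counter()) {
  if (config$algorithm %in% c("levmar_fd", "levmar_se"))
    return(multistart_levmar(problem, spec, config, counter))
  ob <- build_objective(problem, spec, counter)
  res <- glsdc_run(ob$objective_fn, ob$free$bounds, config, counter)
  res
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat("<optimizer_result> best objective ", format(x$best_objective),
      " (", x$termination_reason, "), ",
      x$counter$objective_calls, " objective calls\n", sep = "")
  invisible(x)
}

#' Estimate ensemble from repeated runs
#'
#' @param estimates `n_runs x p` matrix of estimates (natural scale),
#'   columns named by parameter.
#' @param objectives objective value per run.
#' @param algorithm,spec,seeds metadata.
#' @param layout layout of the free vector (used to restrict
#'   identifiability analysis to the kinetic segment).
#' @export
estimate_ensemble <- function(estimates, objectives, algorithm = NA,
                              spec = NULL, seeds = NULL, layout = NULL) {
  estimates <- as.matrix(estimates)
  if (is.null(colnames(estimates)))
    stop("estimate columns must be named by parameter", call. = FALSE)
  structure(list(estimates = estimates, objectives = objectives,
                 algorithm = algorithm, spec = spec, seeds = seeds,
                 layout = layout),
            class = "estimate_ensemble")
}

#' @export
print.estimate_ensemble <- function(x, ...) {
  cat("<estimate_ensemble> ", nrow(x$estimates), " runs x ",
      ncol(x$estimates), " parameters (", x$algorithm, ")\n", sep = "")
  invisible(x)
}

#' Run an ensemble of independent fits
#'
#' `n_runs` independent, seeded runs of one algorithm/scheme/objective
#' cell; run `r` uses seed `base_seed + r`.  Each run contributes its
#' best estimate to the ensemble.
#'
#' @inheritParams multistart_levmar
#' @param n_runs number of independent runs.
#' @param base_seed base seed; per-run seed is `base_seed + run index`.
#' @return list with `ensemble`, `traces` (one per run) and `counters`.
#' @export
run_ensemble <- function(problem, spec, config, n_runs = 96L,
                         base_seed = config$seed) {
  est <- list(); objs <- numeric(0); traces <- list(); counters <- list()
  layout <- NULL
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    counter <- evaluation_counter()
    fit <- fit_model(problem, spec, cfg, counter)
    est[[r]] <- fit$best_values
    objs <- c(objs, fit$best_objective)
    traces[[r]] <- fit$trace
    counters[[r]] <- list(objective_calls = counter$objective_calls,
                          gradient_calls = counter$gradient_calls,
                          fd_equivalent_evals = counter$fd_equivalent_evals,
                          elapsed_seconds = counter_elapsed(counter))
    if (is.null(layout) && !is.null(fit$ensemble))
      layout <- fit$ensemble$layout
  }
  if (is.null(layout))
    layout <- assemble_free_vector(problem, spec)$layout
  estimates <- do.call(rbind, est)
  list(ensemble = estimate_ensemble(estimates, objs,
                                    algorithm = config$algorithm,
                                    spec = spec, seeds = base_seed,
                                    layout = layout),
       traces = traces, counters = counters)
}

#' Percentile summary of convergence traces at time cutoffs
#'
#' At each cutoff, takes every trace's best objective at or before that
#' time (traces whose first record is later contribute their first
#' value; traces that ended earlier contribute their final value) and
#' summarises the 25th/50th/75th percentiles across traces.
#'
#' @param traces list of trace data.frames (columns `elapsed_seconds`,
#'   `best_objective`).
#' @param cutoffs numeric vector of cutoff times in seconds.
#' @return data.frame with columns `cutoff`, `q25`, `median`, `q75`.
#' @export
convergence_summary <- function(traces, cutoffs) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  vals_at <- function(tr, cut) {
    if (nrow(tr) == 0L) stop("empty trace", call. = FALSE)
    at <- tr$best_objective[tr$elapsed_seconds <= cut]
    if (length(at) == 0L) tr$best_objective[1L] else at[length(at)]
  }
  out <- lapply(cutoffs, function(cut) {
    v <- vapply(traces, vals_at, numeric(1L), cut = cut)
    data.frame(cutoff = cut,
               q25 = unname(stats::quantile(v, 0.25)),
               median = unname(stats::median(v)),
               q75 = unname(stats::quantile(v, 0.75)))
  })
  do.call(rbind, out)
}
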
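# An estimation problem: model + conditions + data + free-parameter space.

#' Bind a model, conditions and data into an estimation problem
#'
#' @param model an [ode_model()].
#' @param conditions list of [condition()] objects covering every
#'   condition that appears in the data.
#' @param data a `sysbio_dataset` of measurements (raw or normalised).
#' @param free character vector of free kinetic parameter names; the
#'   remaining parameters stay fixed at the model's nominal values.
#' @param bounds optional `p_free x 2` matrix (columns lower, upper;
#'   rownames = free names).  Default: three decades either side of the
#'   nominal value.
#' @param rtol,atol solver tolerances used for every simulation of this
#'   problem.
#' @return an object of class `ode_problem`.
#' @export
ode_problem <- function(model, conditions, data, free, bounds = NULL,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "ode_model"), inherits(data, "sysbio_dataset"))
  if (length(free) < 1L) stop("no free parameters", call. = FALSE)
  bad <- setdiff(free, model$param_names)
  if (length(bad))
    stop("free parameters not declared in model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cond_names <- vapply(conditions, `[[`, character(1L), "name")
  names(conditions) <- cond_names
  missing_conds <- setdiff(unique(data$condition), cond_names)
  if (length(missing_conds))
    stop("data reference undeclared conditions: ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  bad_obs <- setdiff(unique(data$observable), names(model$obs_exprs))
  if (length(bad_obs))
    stop("data reference undeclared observables: ",
         paste(bad_obs, collapse = ", "), call. = FALSE)
  if (is.null(bounds)) {
    nom <- model$params[free]
    if (any(nom <= 0))
      stop("default log-space bounds need positive nominal values; ",
           "supply bounds explicitly", call. = FALSE)
    bounds <- cbind(lower = nom / 1e3, upper = nom * 1e3)
    rownames(bounds) <- free
  }
  stopifnot(nrow(bounds) == length(free), all(bounds[, 1] < bounds[, 2]))
  structure(list(model = model, conditions = conditions, data = data,
                 free = free, bounds = bounds, rtol = rtol, atol = atol),
            class = "ode_problem")
}

#' @export
print.ode_problem <- function(x, ...) {
  cat("<ode_problem> ", x$model$name, ": ", length(x$free),
      " free kinetic parameters, ",
      length(unique(x$data$observable)), " observables, ",
      length(x$conditions), " conditions, ", nrow(x$data),
      " data points\n", sep = "")
  invisible(x)
}

n_observables <- function(problem) length(unique(problem$data$observable))

#' Write a problem specification to YAML
#'
#' Serialises states, parameters (value, free flag, bounds), rhs
#' expressions, observables, conditions and the normalisation directive.
#' The measurement table is written separately with [write_dataset()];
#' `data` records its relative path.
#'
#' @param problem an [ode_problem()].
#' @param path output YAML file.
#' @param data_path relative path recorded for the data CSV.
#' @export
write_problem_yaml <- function(problem, path, data_path = "data.csv") {
  m <- problem$model
  # free parameters first, in their estimation order, so a round trip
  # preserves the free-vector layout
  p_order <- c(problem$free, setdiff(m$param_names, problem$free))
  params <- lapply(p_order, function(p) {
    fr <- p %in% problem$free
    entry <- list(name = p, value = unname(m$params[[p]]), free = fr)
    if (fr) {
      entry$lower <- unname(problem$bounds[p, 1])
      entry$upper <- unname(problem$bounds[p, 2])
    }
    entry
  })
  ns <- attr(problem$data, "normalization")
  spec <- list(
    name = m$name,
    states = as.list(m$x0),
    parameters = params,
    rhs = as.list(m$rhs_src),
    observables = as.list(m$obs_src),
    conditions = lapply(problem$conditions, function(cn)
      list(name = cn$name, overrides = as.list(cn$overrides))),
    normalization = Filter(Negate(is.null), list(
      scheme = ns$scheme,
      reference_condition = ns$reference_condition,
      reference_time = ns$reference_time)),
    data = data_path,
    solver = list(rtol = problem$rtol, atol = problem$atol)
  )
  yaml::write_yaml(spec, path, precision = 15L)
  invisible(path)
}

#' Read a problem specification from YAML
#'
#' @param path YAML file written by [write_problem_yaml()] (or by hand in
#'   the same layout).
#' @param data_path optional override for the data CSV location; default
#'   is the `data` entry resolved relative to the YAML file.
#' @return an [ode_problem()].
#' @export
read_problem_yaml <- function(path, data_path = NULL) {
  spec <- yaml::read_yaml(path)
  states <- unlist(spec$states)
  pvals <- vapply(spec$parameters, function(p) as.numeric(p$value),
                  numeric(1L))
  names(pvals) <- vapply(spec$parameters, `[[`, character(1L), "name")
  model <- ode_model(states = states, params = pvals,
                     rhs = unlist(spec$rhs),
                     observables = unlist(spec$observables),
                     name = spec$name %||% "model")
  conds <- lapply(spec$conditions, function(cn)
    condition(cn$name, unlist(cn$overrides) %||% numeric(0)))
  ns <- spec$normalization
  nspec <- normalization_spec(ns$scheme %||% "average",
                              reference_condition = ns$reference_condition,
                              reference_time = ns$reference_time)
  if (is.null(data_path))
    data_path <- file.path(dirname(path), spec$data)
  ds <- read_dataset(data_path, normalization = nspec)
  free <- vapply(Filter(function(p) isTRUE(p$free), spec$parameters),
                 `[[`, character(1L), "name")
  bounds <- t(vapply(Filter(function(p) isTRUE(p$free), spec$parameters),
                     function(p) c(as.numeric(p$lower), as.numeric(p$upper)),
                     numeric(2L)))
  dimnames(bounds) <- list(free, c("lower", "upper"))
  rtol <- spec$solver$rtol %||% 1e-8
  atol <- spec$solver$atol %||% 1e-10
  ode_problem(model, conds, ds, free, bounds, rtol = rtol, atol = atol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
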
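# Arbitrary-unit measurement data and the shared normalisation rule.
#
# Relative assays (western blots, multiplexed ELISA, RT-qPCR) report
# intensities in arbitrary units that are comparable only within a
# replicate.  Data are made comparable across replicates by dividing each
# value by a reference (the average, maximum, or a designated control
# point of that observable in that replicate).  The DNS contract is that
# the *same* rule, over the same (condition, time) points, is applied to
# the simulated observables, so data and simulation live on one scale
# without introducing estimated scaling factors.

#' Normalisation rule for a dataset
#'
#' @param scheme one of `"average"`, `"max"`, `"reference_point"`,
#'   `"none"`.
#' @param reference_condition,reference_time the (condition, time) pair
#'   selecting the reference data point; required iff
#'   `scheme == "reference_point"`.
#' @return an object of class `normalization_spec`.
#' @export
normalization_spec <- function(scheme = c("average", "max",
                                          "reference_point", "none"),
                               reference_condition = NULL,
                               reference_time = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "reference_point" &&
      (is.null(reference_condition) || is.null(reference_time)))
    stop("reference_point normalisation needs reference_condition and ",
         "reference_time", call. = FALSE)
  structure(list(scheme = scheme,
                 reference_condition = reference_condition,
                 reference_time = reference_time),
            class = "normalization_spec")
}

#' Construct a dataset of arbitrary-unit measurements
#'
#' @param points data.frame with columns `condition`, `observable`,
#'   `time`, `replicate`, `value`.
#' @param normalization a [normalization_spec()].
#' @param normalized logical; whether `value` has already been divided by
#'   its group reference.
#' @return an object of class `sysbio_dataset` (a data.frame with the
#'   normalisation rule attached).
#' @export
dataset <- function(points, normalization = normalization_spec("average"),
                    normalized = FALSE) {
  req <- c("condition", "observable", "time", "replicate", "value")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("dataset is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  points <- as.data.frame(points)[req]
  if (!is.numeric(points$value) || any(!is.finite(points$value)))
    stop("values must be finite numerics", call. = FALSE)
  if (any(points$time < 0)) stop("times must be >= 0", call. = FALSE)
  key <- do.call(paste, c(points[c("condition", "observable", "time",
                                   "replicate")], sep = "\r"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (condition, observable, time, replicate) key: ",
         gsub("\r", ", ", d), call. = FALSE)
  }
  structure(points, class = c("sysbio_dataset", "data.frame"),
            normalization = normalization, normalized = normalized)
}

#' Read a measurement table from CSV
#'
#' Expects a header `condition,observable,time,replicate,value`; one
#' record per measurement; values in arbitrary units.  The returned
#' dataset is un-normalised; apply [normalize_data()] to divide by the
#' group references.
#'
#' @param path CSV file path.
#' @param normalization a [normalization_spec()].
#' @return a `sysbio_dataset`.
#' @export
read_dataset <- function(path, normalization = normalization_spec("average")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("condition", "observable", "time", "replicate", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("file '", path, "' is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$value))))[1L]
    stop("unparsable value in row ", bad, " of '", path, "'",
         call. = FALSE)
  }
  dataset(df, normalization = normalization, normalized = FALSE)
}

#' Write a dataset to CSV
#' @param ds a `sysbio_dataset`.
#' @param path output file.
#' @export
write_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

# Normalisation groups: all measured values for one observable in one
# replicate, pooling conditions and times.
group_key <- function(ds) paste(ds$observable, ds$replicate, sep = "\r")

#' Reference value of a measurement group
#'
#' The reference a group of values is divided by: their arithmetic mean
#' (`average`), their maximum (`max`), the value at a designated
#' (condition, time) point (`reference_point`), or 1 (`none`).
#'
#' @param values numeric vector of a group's values.
#' @param spec a [normalization_spec()].
#' @param conditions,times vectors parallel to `values`, required for
#'   `reference_point`.
#' @return scalar reference (> 0).
#' @export
reference_value <- function(values, spec, conditions = NULL, times = NULL) {
  if (length(values) == 0L)
    stop("empty normalisation group", call. = FALSE)
  ref <- switch(spec$scheme,
    average = mean(values),
    max = max(values),
    none = 1,
    reference_point = {
      hit <- which(conditions == spec$reference_condition &
                   times == spec$reference_time)
      if (length(hit) != 1L)
        stop("reference point (", spec$reference_condition, ", t=",
             spec$reference_time, ") not found exactly once in group",
             call. = FALSE)
      values[hit]
    })
  if (!is.finite(ref) || ref <= 0)
    stop("normalisation reference must be > 0 (got ", ref, ")",
         call. = FALSE)
  ref
}

#' Normalise a dataset by its group references
#'
#' Divides every value by the reference of its (observable, replicate)
#' group, pooling all conditions and times.  After average normalisation,
#' each group has mean exactly 1.
#'
#' @param ds an un-normalised `sysbio_dataset`.
#' @return the dataset with normalised values and `normalized = TRUE`.
#' @export
normalize_data <- function(ds) {
  stopifnot(inherits(ds, "sysbio_dataset"))
  if (isTRUE(attr(ds, "normalized")))
    stop("dataset is already normalised", call. = FALSE)
  spec <- attr(ds, "normalization")
  if (spec$scheme == "none") {
    attr(ds, "normalized") <- TRUE
    return(ds)
  }
  key <- group_key(ds)
  out <- ds
  for (k in unique(key)) {
    idx <- which(key == k)
    ref <- reference_value(ds$value[idx], spec,
                           conditions = ds$condition[idx],
                           times = ds$time[idx])
    out$value[idx] <- ds$value[idx] / ref
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Normalise simulated values by the data's rule (DNS)
#'
#' For each (observable, replicate) group of the dataset, computes the
#' simulated reference from the simulated values at exactly the
#' (condition, time) points that define the data reference for that
#' group, and divides.  This is the data-driven normalisation of the
#' simulations: the reference cannot be fixed a priori because it depends
#' on the simulation itself.
#'
#' @param sim_values numeric vector of simulated observable values, one
#'   per dataset row (same order).
#' @param ds the `sysbio_dataset` defining groups and the rule.
#' @return numeric vector of normalised simulated values, one per row.
#'   A non-positive simulated reference signals an error of class
#'   `scalefit_normalization_error` (the objective layer maps it to a
#'   large finite penalty).
#' @export
normalize_simulation_like_data <- function(sim_values, ds) {
  stopifnot(length(sim_values) == nrow(ds))
  spec <- attr(ds, "normalization")
  if (spec$scheme == "none") return(sim_values)
  key <- group_key(ds)
  out <- numeric(length(sim_values))
  for (k in unique(key)) {
    idx <- which(key == k)
    ref <- switch(spec$scheme,
      average = mean(sim_values[idx]),
      max = max(sim_values[idx]),
      reference_point = {
        hit <- idx[ds$condition[idx] == spec$reference_condition &
                   ds$time[idx] == spec$reference_time]
        if (length(hit) != 1L)
          stop("reference point not found exactly once in simulated group",
               call. = FALSE)
        sim_values[hit]
      })
    if (!is.finite(ref) || ref <= 0)
      stop(structure(class = c("scalefit_normalization_error", "error",
                               "condition"),
                     list(message = paste0("simulated reference <= 0 for ",
                                           "group ", gsub("\r", "/", k)),
                          call = NULL)))
    out[idx] <- sim_values[idx] / ref
  }
  out
}
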
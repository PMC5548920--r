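# Practical (a posteriori) identifiability from estimate ensembles:
# log2 normalisation against the per-parameter minimum, PCA, and the
# variance > 1 counting rule.

#' Log-normalise an estimate ensemble
#'
#' Per parameter i and run j: `log2(theta_ij / min_j theta_ij)`, so the
#' best (smallest) estimate of each parameter maps to 0 and a value of 1
#' indicates a two-fold change.  By default only the kinetic segment of
#' the free vector is kept: scaling factors and error-model parameters
#' are dropped, since the analysis targets the identifiability of the
#' kinetic parameters.
#'
#' @param ens an [estimate_ensemble()] (or a plain matrix, runs in rows).
#' @param kinetic_only drop scaling-factor / error-model columns (needs
#'   the ensemble's layout; ignored for plain matrices).
#' @return matrix, runs in rows, parameters in columns; each column
#'   minimum is exactly 0.
#' @export
log_normalize_estimates <- function(ens, kinetic_only = TRUE) {
  if (inherits(ens, "estimate_ensemble")) {
    m <- ens$estimates
    if (kinetic_only && !is.null(ens$layout))
      m <- m[, ens$layout$kinetic, drop = FALSE]
  } else {
    m <- as.matrix(ens)
  }
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0)
    stop("non-positive estimate at run ", bad[1L, 1L], ", parameter '",
         colnames(m)[bad[1L, 2L]] %||% bad[1L, 2L], "'", call. = FALSE)
  mins <- apply(m, 2L, min)
  log2(sweep(m, 2L, mins, `/`))
}

#' Principal-component variances of a normalised ensemble
#'
#' Eigen-decomposition of the column-centred covariance of the
#' log-normalised estimates (columns are centred but not rescaled: the
#' log2 normalisation is the scaling step).  Variances are returned in
#' descending order and sum to the total column variance.
#'
#' @param norm_matrix matrix from [log_normalize_estimates()], runs in
#'   rows.
#' @return list with `variances` (descending) and `loadings` (columns =
#'   principal directions).
#' @export
pca_variances <- function(norm_matrix) {
  norm_matrix <- as.matrix(norm_matrix)
  if (nrow(norm_matrix) < 2L)
    stop("need at least 2 runs for PCA", call. = FALSE)
  pc <- stats::prcomp(norm_matrix, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  # prcomp returns at most min(n-1, p) components; pad with exact zeros
  if (length(v) < ncol(norm_matrix))
    v <- c(v, rep(0, ncol(norm_matrix) - length(v)))
  list(variances = v, loadings = pc$rotation)
}

#' Degree of practical non-identifiability
#'
#' The number of principal directions with variance strictly greater
#' than 1 (i.e. more than a two-fold spread on the log2 scale).
#'
#' @param variances descending variance vector from [pca_variances()].
#' @return integer count.
#' @export
degree_of_nonidentifiability <- function(variances) {
  if (is.unsorted(rev(variances)))
    stop("variances must be sorted in descending order", call. = FALSE)
  sum(variances > 1)
}

#' Full identifiability report for an ensemble
#'
#' Runs the pipeline [log_normalize_estimates()] -> [pca_variances()] ->
#' [degree_of_nonidentifiability()].
#'
#' @inheritParams log_normalize_estimates
#' @return an `identifiability_report`: list with `pc_variances`,
#'   `pc_loadings`, `degree`, `n_runs`, `p` and the per-parameter
#'   `normalisation_baseline` (the column minima).
#' @export
identifiability_report <- function(ens, kinetic_only = TRUE) {
  m_raw <- if (inherits(ens, "estimate_ensemble")) {
    mm <- ens$estimates
    if (kinetic_only && !is.null(ens$layout))
      mm[, ens$layout$kinetic, drop = FALSE] else mm
  } else as.matrix(ens)
  nm <- log_normalize_estimates(ens, kinetic_only)
  pc <- pca_variances(nm)
  structure(list(pc_variances = pc$variances,
                 pc_loadings = pc$loadings,
                 degree = degree_of_nonidentifiability(pc$variances),
                 n_runs = nrow(nm), p = ncol(nm),
                 normalisation_baseline = apply(m_raw, 2L, min)),
            class = "identifiability_report")
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat("<identifiability_report> degree of practical non-identifiability: ",
      x$degree, " (", x$n_runs, " runs, ", x$p, " parameters)\n", sep = "")
  cat("  PC variances: ",
      paste(signif(utils::head(x$pc_variances, 8), 3), collapse = ", "),
      if (length(x$pc_variances) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Write an identifiability report to CSV
#' @param report an `identifiability_report`.
#' @param path output file (variances and loadings); a `# degree=` header
#'   line summarises the count.
#' @export
write_identifiability_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# degree=%d n_runs=%d p=%d", report$degree,
                     report$n_runs, report$p), con)
  df <- data.frame(component = seq_along(report$pc_variances),
                   variance = report$pc_variances)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
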
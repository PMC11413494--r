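# Allometric size correction: residuals of log(metric) on log(body mass),
# pooled across species, form the "overall performance" variables for the
# multivariate comparison.

#' Size-correct a performance metric against body mass
#'
#' Regresses `log(metric)` on `log(mass_g)` by ordinary least squares over
#' the pooled individuals and returns the residuals. The residuals are the
#' size-corrected performance values: what remains of (log) performance
#' after removing the shared allometric trend. Natural logarithms are used;
#' the base is immaterial to residual-based inference.
#'
#' If log mass has zero variance the slope is unidentifiable and the
#' function falls back to intercept-only centering of the log metric,
#' signalled by the `"degenerate_mass"` attribute.
#'
#' @param metric positive metric values
#' @param mass_g positive body masses, grams, same length
#' @return numeric residual vector (mean zero); attributes `"coef"`
#'   (intercept, slope) and `"degenerate_mass"`
#' @export
size_correct <- function(metric, mass_g) {
  if (length(metric) != length(mass_g))
    stop("metric and mass_g must have the same length")
  if (length(metric) < 3)
    stop("size correction needs at least 3 individuals")
  if (any(!is.finite(metric)) || any(!is.finite(mass_g)))
    stop("metric and mass_g must be finite (exclude missing mass upstream)")
  if (any(metric <= 0) || any(mass_g <= 0))
    stop("metric and mass_g must be strictly positive for the log transform")
  y <- log(metric)
  x <- log(mass_g)
  degenerate <- stats::var(x) < .Machine$double.eps
  if (degenerate) {
    res <- y - mean(y)
    coefs <- c(intercept = mean(y), slope = 0)
  } else {
    fit <- stats::lm(y ~ x)
    res <- as.numeric(stats::residuals(fit))
    coefs <- c(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]))
  }
  structure(res, coef = coefs, degenerate_mass = degenerate)
}

#' Scale matrix columns to unit standard deviation
#'
#' Rescales every column of a residual matrix to sample SD 1 (mean stays
#' 0 for centered input), the standardization used before computing
#' Euclidean distances so no metric dominates by scale alone.
#'
#' @param m numeric matrix with >= 2 rows
#' @return matrix of the same shape, each column with SD 1
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to standardize")
  sds <- apply(m, 2, stats::sd)
  zero <- sds < .Machine$double.eps
  if (any(zero)) {
    nm <- colnames(m)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("zero-SD column(s): ", paste(nm, collapse = ", "))
  }
  out <- sweep(m, 2, sds, "/")
  attr(out, "standardized") <- TRUE
  out
}

#' Build the size-corrected multivariate performance matrix
#'
#' For each requested metric, takes the residuals of log metric on log body
#' mass over all rows (pooled species), then optionally scales each
#' residual column to unit SD. Rows must already be restricted to
#' individuals with complete mass and metric records.
#'
#' @param df data.frame holding the metric columns and a mass column
#' @param metrics character vector of metric column names
#' @param mass_col name of the body-mass column (grams)
#' @param standardize scale columns to SD 1 (default `TRUE`)
#' @return numeric matrix, one column per metric, rownames from `df`
#' @export
performance_matrix <- function(df, metrics, mass_col = "mass_g",
                               standardize = TRUE) {
  missing_cols <- setdiff(c(metrics, mass_col), names(df))
  if (length(missing_cols))
    stop("unknown metric column(s): ", paste(missing_cols, collapse = ", "))
  complete <- stats::complete.cases(df[, c(metrics, mass_col)])
  if (!all(complete))
    stop("performance_matrix requires complete rows; filter upstream")
  m <- vapply(metrics, function(cl) size_correct(df[[cl]], df[[mass_col]]),
              numeric(nrow(df)))
  colnames(m) <- metrics
  rownames(m) <- rownames(df)
  if (standardize) m <- standardize_columns(m)
  m
}
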
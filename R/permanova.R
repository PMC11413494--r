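# One-factor PERMANOVA on Euclidean distances, implemented directly from
# the partition of squared inter-point distances, with a label-permutation
# null distribution.

#' Permutational multivariate analysis of variance (one factor)
#'
#' Tests whether multivariate observations differ among groups using the
#' pseudo-F ratio on Euclidean distances. Total sum of squares is
#' \eqn{\sum_{i<j} d_{ij}^2 / n} over all pairs; the within-group sum is
#' the analogous quantity within each group; pseudo-F is
#' \eqn{(SS_B/df_B)/(SS_W/df_W)} with \eqn{df_B = a-1}, \eqn{df_W = n-a}.
#' The null distribution is obtained by permuting group labels;
#' \eqn{p = (\#\{F^* \ge F_{obs}\} + 1)/(n_{perm}+1)}, which counts the
#' observed statistic among the permutations so p can never be 0 and is
#' bounded below by \eqn{1/(n_{perm}+1)}.
#'
#' Rows are internally sorted into a canonical order before permuting, so
#' the permutation p-value is invariant to the input row order for a fixed
#' seed. On univariate input the pseudo-F equals the classical one-way
#' ANOVA F.
#'
#' @param x numeric matrix (rows = individuals) of, e.g., unit-standardized
#'   size-corrected performance variables
#' @param groups group labels, one per row; >= 2 groups of >= 2 rows
#' @param n_perm number of label permutations (default 999)
#' @param seed integer seed for the permutations
#' @return object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`, `ss_total`,
#'   `n_permutations`, `seed`, `n`
#' @export
permanova <- function(x, groups, n_perm = 999, seed = 1L) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x))
    stop("groups must have one label per row of x")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 rows")

  # canonical row order: permutations then do not depend on input row order
  ord <- do.call(order, c(unname(as.data.frame(x)), list(groups)))
  x <- x[ord, , drop = FALSE]
  groups <- groups[ord]

  n <- nrow(x)
  a <- length(tab)
  D2 <- as.matrix(stats::dist(x))^2
  ss_total <- sum(D2) / (2 * n)
  ss_within_of <- function(labels) {
    s <- 0
    for (g in unique(labels)) {
      idx <- which(labels == g)
      s <- s + sum(D2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ss_w <- ss_within_of(groups)
  ss_b <- ss_total - ss_w
  df_b <- a - 1L
  df_w <- n - a
  # guard degenerate geometries: no within-group spread at all
  f_stat <- function(ss_b, ss_w) {
    if (ss_w <= .Machine$double.eps * max(ss_total, 1)) {
      if (ss_b <= .Machine$double.eps * max(ss_total, 1)) return(0)
      return(Inf)
    }
    (ss_b / df_b) / (ss_w / df_w)
  }
  f_obs <- f_stat(ss_b, ss_w)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    lab <- groups[sample.int(n)]
    ss_w_p <- ss_within_of(lab)
    f_p <- f_stat(ss_total - ss_w_p, ss_w_p)
    if (f_p >= f_obs) n_ge <- n_ge + 1L
  }
  p <- (n_ge + 1) / (n_perm + 1)

  structure(list(pseudo_F = f_obs, p_value = p,
                 df_between = df_b, df_within = df_w,
                 ss_between = ss_b, ss_within = ss_w, ss_total = ss_total,
                 n_permutations = as.integer(n_perm), seed = seed, n = n),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (Euclidean, %d permutations)\n  pseudo-F(%d, %d) = %.4g, p = %.4g\n",
    x$n_permutations, x$df_between, x$df_within, x$pseudo_F, x$p_value))
  invisible(x)
}
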
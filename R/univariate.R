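# Univariate inference: one-way linear models, Tukey HSD pairwise
# comparisons with a compact letter display, logistic regression of escape
# mode on reaction time, and mean +/- SE group summaries.

drop_na_pairs <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  list(values = values[keep], groups = as.character(groups[keep]))
}

#' One-way linear model (classical ANOVA F test)
#'
#' Fits `values ~ groups` and returns the overall F test for group
#' differences. Missing values are dropped pairwise.
#'
#' @param values numeric response
#' @param groups group labels
#' @return list with `F`, `p`, `df_between`, `df_within`, `n`,
#'   `group_means`
#' @export
oneway_lm <- function(values, groups) {
  d <- drop_na_pairs(values, groups)
  tab <- table(d$groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (length(d$values) <= length(tab))
    stop("need more observations than groups")
  fit <- stats::lm(d$values ~ factor(d$groups))
  means <- tapply(d$values, d$groups, mean)
  ssw <- sum((d$values - means[d$groups])^2)
  if (ssw < 1e-12 * max(stats::var(d$values) * (length(d$values) - 1), 1))
    stop("zero within-group variance; F is undefined")
  an <- stats::anova(fit)
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       df_between = an$Df[1], df_within = an$Df[2],
       n = length(d$values),
       group_means = tapply(d$values, d$groups, mean))
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All pairwise group comparisons using the studentized-range distribution
#' with the Tukey-Kramer unequal-n correction:
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}} referred
#' to the studentized range with `k` means and the ANOVA residual degrees
#' of freedom. Groups are then labelled with letters by the
#' insert-and-absorb algorithm so that two groups share no letter exactly
#' when their adjusted p falls below `alpha`.
#'
#' @param values numeric response
#' @param groups group labels (>= 2 groups, each >= 2 observations)
#' @param alpha significance level for the letter display
#' @return object of class `tukey_result`: `table` (group_i, group_j,
#'   diff, se, p_adj, significant), `letters` (named character vector),
#'   `means`, `n`, `alpha`, `df`
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  d <- drop_na_pairs(values, groups)
  tab <- table(d$groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("every group needs at least 2 observations")
  k <- length(tab)
  n_tot <- length(d$values)
  means <- tapply(d$values, d$groups, mean)
  ns <- as.numeric(tab)[match(names(means), names(tab))]
  names(ns) <- names(means)
  sse <- sum((d$values - means[d$groups])^2)
  df <- n_tot - k
  mse <- sse / df
  if (mse < .Machine$double.eps)
    stop("zero residual mean square; Tukey HSD is undefined")

  pairs <- utils::combn(names(means), 2)
  res <- data.frame(
    group_i = pairs[1, ], group_j = pairs[2, ],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE)
  res$se <- sqrt(mse / 2 * (1 / ns[res$group_i] + 1 / ns[res$group_j]))
  q <- abs(res$diff) / res$se
  res$p_adj <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  res$significant <- res$p_adj < alpha
  rownames(res) <- NULL

  letters_vec <- letter_display(names(means), means,
                                res[res$significant, c("group_i", "group_j")])
  structure(list(table = res, letters = letters_vec, means = means,
                 n = ns, alpha = alpha, df = df, mse = mse),
            class = "tukey_result")
}

# Insert-and-absorb compact letter display. `sig_pairs` is a data.frame of
# significantly different group pairs. Groups sharing no letter differ.
letter_display <- function(group_names, group_means, sig_pairs) {
  ord <- order(group_means, group_names)
  groups <- group_names[ord]
  cols <- list(groups)  # each column = set of groups sharing one letter
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      gi <- sig_pairs$group_i[r]
      gj <- sig_pairs$group_j[r]
      new_cols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) {
          new_cols <- c(new_cols, list(setdiff(col, gi)),
                        list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[i] && keep[j] &&
              all(new_cols[[i]] %in% new_cols[[j]]) &&
              !(all(new_cols[[j]] %in% new_cols[[i]]) && i < j)) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- unique(new_cols[keep])
    }
  }
  # order letter columns by the smallest group mean they contain
  col_key <- vapply(cols, function(col)
    min(group_means[match(col, group_names)]), numeric(1))
  cols <- cols[order(col_key)]
  out <- stats::setNames(rep("", length(group_names)), groups)
  for (i in seq_along(cols)) {
    lett <- letters[i]
    for (g in cols[[i]]) out[g] <- paste0(out[g], lett)
  }
  out[group_names]
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (Tukey-Kramer, alpha = %g, df = %d)\n",
              x$alpha, x$df))
  print(x$table, digits = 4)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Logistic regression of jump probability on reaction time
#'
#' Maximum-likelihood logistic regression of a binary jumped/scrambled
#' outcome on reaction time (ms). The odds ratio is `exp(slope)`, the
#' multiplicative change in jump odds per millisecond of reaction time.
#'
#' @param reaction_ms reaction times in ms
#' @param jumped logical (or 0/1) outcome, TRUE for a jump
#' @return list with `odds_ratio`, `p` (Wald test on the slope), `slope`,
#'   `intercept`, `n`
#' @export
logistic_jump <- function(reaction_ms, jumped) {
  jumped <- as.logical(jumped)
  keep <- !is.na(reaction_ms) & !is.na(jumped)
  x <- reaction_ms[keep]
  y <- jumped[keep]
  if (length(unique(y)) < 2)
    stop("both outcome classes (jump and scramble) must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || abs(stats::coef(fit)[2]) > 20)
    stop("complete or quasi-complete separation; logistic fit diverges")
  sm <- summary(fit)$coefficients
  slope <- unname(stats::coef(fit)[2])
  list(odds_ratio = exp(slope), p = sm[2, 4], slope = slope,
       intercept = unname(stats::coef(fit)[1]), n = length(y))
}

#' Compare take-off time between scramble and jump maneuvers
#'
#' One-way linear model of take-off time with escape mode (jump vs
#' scramble) as the factor — algebraically the pooled-variance two-sample
#' t test (F = t^2).
#'
#' @param takeoff_ms take-off times in ms
#' @param mode character vector of `"jump"` / `"scramble"`
#' @return list with `F`, `p`, `df_between`, `df_within`, `n`,
#'   `mean_jump`, `mean_scramble`
#' @export
scramble_vs_jump <- function(takeoff_ms, mode) {
  d <- drop_na_pairs(takeoff_ms, mode)
  bad <- setdiff(unique(d$groups), c("jump", "scramble"))
  if (length(bad))
    stop("mode must be 'jump' or 'scramble'; found: ",
         paste(bad, collapse = ", "))
  if (!all(c("jump", "scramble") %in% d$groups))
    stop("both jump and scramble maneuvers must be present")
  fit <- oneway_lm(d$values, d$groups)
  c(fit[c("F", "p", "df_between", "df_within", "n")],
    list(mean_jump = unname(fit$group_means["jump"]),
         mean_scramble = unname(fit$group_means["scramble"])))
}

#' Per-species summary table of trial metrics
#'
#' Mean, standard error (SD/sqrt(n)) and n per species for body mass,
#' reaction time, take-off time, overall response time (their per-trial
#' sum) and — for jumps with measured displacement and airborne time — the
#' reconstructed take-off speed, jump height (cm) and take-off angle.
#' Censored trials are excluded metric-wise: cork hits, premature
#' reactions and poor video for reaction time; cork hits and poor video
#' for take-off time; off-screen landings and poor video for the jump
#' performance metrics.
#'
#' @param trials trial data.frame (fixed trial columns)
#' @return data.frame with columns `species`, `metric`, `mean`, `se`, `n`;
#'   `se` is `NA` when n < 2, and species-metric cells with no usable
#'   trials have n = 0 and `NA` moments
#' @export
summarize_trials <- function(trials) {
  validate_trials(trials)
  ok_re <- !trials$hit_by_cork & !trials$premature & !trials$poor_video
  ok_to <- !trials$hit_by_cork & !trials$poor_video
  ok_perf <- trials$mode == "jump" & !trials$offscreen & !trials$poor_video &
    !is.na(trials$displacement_m) & !is.na(trials$airborne_s)
  kin <- data.frame(takeoff_speed = rep(NA_real_, nrow(trials)),
                    jump_height_cm = NA_real_, takeoff_angle_deg = NA_real_)
  if (any(ok_perf)) {
    k <- compute_kinematics(trials$displacement_m[ok_perf],
                            trials$airborne_s[ok_perf])
    kin$takeoff_speed[ok_perf] <- k$takeoff_speed
    kin$jump_height_cm[ok_perf] <- k$jump_height_m * 100
    kin$takeoff_angle_deg[ok_perf] <- k$takeoff_angle_deg
  }
  overall <- ifelse(ok_re & ok_to, trials$reaction_ms + trials$takeoff_ms,
                    NA_real_)
  cols <- list(
    mass_g = trials$mass_g,
    reaction_ms = ifelse(ok_re, trials$reaction_ms, NA_real_),
    takeoff_ms = ifelse(ok_to, trials$takeoff_ms, NA_real_),
    overall_ms = overall,
    takeoff_speed = kin$takeoff_speed,
    jump_height_cm = kin$jump_height_cm,
    takeoff_angle_deg = kin$takeoff_angle_deg)
  species <- sort(unique(trials$species))
  out <- do.call(rbind, lapply(species, function(sp) {
    sel <- trials$species == sp
    do.call(rbind, lapply(names(cols), function(metric) {
      v <- cols[[metric]][sel]
      v <- v[!is.na(v)]
      n <- length(v)
      data.frame(species = sp, metric = metric,
                 mean = if (n) mean(v) else NA_real_,
                 se = if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_,
                 n = n, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
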
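# Independent oracles and toy-data builders used across the suite.

# Projectile landing by numerical integration of the vertical velocity
# (trapezoid rule) - independent of the closed-form ballistics under test.
projectile_landing <- function(vx, vy, g = 9.8, n_steps = 200000) {
  tmax <- 2 * vy / g * 1.5
  tt <- seq(0, tmax, length.out = n_steps + 1)
  vels <- vy - g * tt
  y <- cumsum(c(0, diff(tt) * (head(vels, -1) + vels[-1]) / 2))
  i <- which(y < 0 & tt > 0)[1]
  t0 <- tt[i - 1]; t1 <- tt[i]
  tl <- t0 + (0 - y[i - 1]) / (y[i] - y[i - 1]) * (t1 - t0)
  list(airborne_s = tl, displacement_m = vx * tl)
}

# OLS residuals from the normal equations, written out by hand.
ols_residuals_normal_eq <- function(y, x) {
  n <- length(y)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  y - (a + b * x)
}

# Logistic MLE by iterated grid refinement of the log-likelihood. A slow
# shrink factor lets the search travel along the correlated
# intercept/slope ridge instead of collapsing onto it prematurely.
logistic_grid_mle <- function(x, y, rounds = 30, width0 = c(10, 2)) {
  nll <- function(a, b) {
    eta <- a + b * x
    sum(log1p(exp(eta))) - sum(eta[y])
  }
  center <- c(0, 0); width <- width0
  for (r in seq_len(rounds)) {
    as <- seq(center[1] - width[1], center[1] + width[1], length.out = 41)
    bs <- seq(center[2] - width[2], center[2] + width[2], length.out = 41)
    grid <- expand.grid(a = as, b = bs)
    vals <- mapply(nll, grid$a, grid$b)
    best <- grid[which.min(vals), ]
    center <- c(best$a, best$b)
    width <- width / 2
  }
  list(intercept = center[1], slope = center[2])
}

# Minimal hand-built trial table with the fixed schema.
make_trials <- function(species, mode = "jump", mass_g = 50, fps = 240,
                        reaction_ms = 20, takeoff_ms = 90,
                        displacement_m = ifelse(mode == "jump", 0.4, NA),
                        airborne_s = ifelse(mode == "jump", 0.25, NA),
                        hit_by_cork = FALSE, premature = FALSE,
                        offscreen = FALSE, poor_video = FALSE,
                        id = NULL) {
  n <- length(species)
  if (is.null(id)) id <- sprintf("ID_%03d", seq_len(n))
  data.frame(species = species, individual_id = id,
             mass_g = rep_len(mass_g, n), fps = rep_len(fps, n),
             mode = rep_len(mode, n),
             reaction_ms = rep_len(reaction_ms, n),
             takeoff_ms = rep_len(takeoff_ms, n),
             displacement_m = rep_len(displacement_m, n),
             airborne_s = rep_len(airborne_s, n),
             hit_by_cork = rep_len(hit_by_cork, n),
             premature = rep_len(premature, n),
             offscreen = rep_len(offscreen, n),
             poor_video = rep_len(poor_video, n),
             stringsAsFactors = FALSE)
}

# A realistic mixed table: two jumping species and one scrambler, fully
# measured, built deterministically from forward ballistics.
make_jumping_table <- function(n_per = 10, seed = 99) {
  set.seed(seed)
  spp <- rep(c("AAAA", "BBBB"), each = n_per)
  speed <- c(seq(1.8, 2.4, length.out = n_per),
             seq(2.2, 2.9, length.out = n_per))
  angle <- c(seq(30, 50, length.out = n_per),
             seq(25, 45, length.out = n_per))
  fb <- forward_ballistics(speed, angle)
  tr <- make_trials(spp, mode = "jump",
                    mass_g = round(c(seq(35, 45, length.out = n_per),
                                     seq(80, 100, length.out = n_per))),
                    reaction_ms = round(c(rnorm(n_per, 22, 4),
                                          rnorm(n_per, 19, 4)), 1),
                    takeoff_ms = round(c(rnorm(n_per, 100, 15),
                                         rnorm(n_per, 80, 15)), 1),
                    displacement_m = fb$displacement_m,
                    airborne_s = fb$airborne_s)
  scr <- make_trials(rep("CCCC", n_per), mode = "scramble",
                     mass_g = 180, reaction_ms = round(rnorm(n_per, 20, 3), 1),
                     takeoff_ms = round(rnorm(n_per, 150, 20), 1),
                     id = sprintf("CC_%03d", seq_len(n_per)))
  rbind(tr, scr)
}

# Exhaustive PERMANOVA p-value over all distinct label assignments for a
# two-group design (enumeration oracle, independent SS bookkeeping).
permanova_p_exact_2groups <- function(x, groups) {
  x <- as.matrix(x)
  n <- nrow(x)
  g1 <- which(groups == unique(groups)[1])
  k <- length(g1)
  D2 <- as.matrix(dist(x))^2
  f_of <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    ssw <- sum(D2[idx1, idx1]) / (2 * length(idx1)) +
      sum(D2[idx2, idx2]) / (2 * length(idx2))
    sst <- sum(D2) / (2 * n)
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  f_obs <- f_of(g1)
  combos <- combn(n, k)
  fs <- apply(combos, 2, f_of)
  list(f_obs = f_obs, p_exact = mean(fs >= f_obs - 1e-12))
}
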
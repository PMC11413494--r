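test_that("one-way ANOVA F matches hand-computed sums of squares", {
  v <- c(1, 2, 3, 4, 5, 6, 8, 9, 10)
  g <- rep(c("a", "b", "c"), each = 3)
  r <- oneway_lm(v, g)
  gm <- mean(v)
  ssb <- sum(3 * (tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 3))^2)
  expect_equal(r$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(r$df_between, 2L)
  expect_equal(r$df_within, 6L)
  expect_equal(r$p, pf((ssb / 2) / (ssw / 6), 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("identical groups give F = 0 and degenerate designs are rejected", {
  r <- oneway_lm(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$F, 0, tolerance = 1e-12)
  expect_error(oneway_lm(1:5, rep("a", 5)), "2 groups")
  expect_error(oneway_lm(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero within-group variance")
})

test_that("Tukey-Kramer adjusted p matches the reference implementation", {
  set.seed(14)
  v <- c(rnorm(8, 0), rnorm(12, 1.0), rnorm(6, 2.5))  # unbalanced
  g <- rep(c("a", "b", "c"), c(8, 12, 6))
  r <- tukey_hsd(v, g)
  ref <- TukeyHSD(aov(v ~ factor(g)))[[1]]
  key <- paste(r$table$group_j, r$table$group_i, sep = "-")
  expect_equal(r$table$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(r$table$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
})

test_that("letter display separates distinct groups and joins similar ones", {
  v <- c(1, 2, 3, 2, 3, 4, 10, 11, 12)
  g <- rep(c("A", "B", "C"), each = 3)
  r <- tukey_hsd(v, g)
  shared_ab <- intersect(strsplit(r$letters["A"], "")[[1]],
                         strsplit(r$letters["B"], "")[[1]])
  expect_gt(length(shared_ab), 0)
  shared_ac <- intersect(strsplit(r$letters["A"], "")[[1]],
                         strsplit(r$letters["C"], "")[[1]])
  expect_length(shared_ac, 0)
  # sharing no letter <=> adjusted p below alpha, for every pair
  for (i in seq_len(nrow(r$table))) {
    li <- strsplit(r$letters[r$table$group_i[i]], "")[[1]]
    lj <- strsplit(r$letters[r$table$group_j[i]], "")[[1]]
    expect_identical(length(intersect(li, lj)) == 0, r$table$significant[i])
  }
})

test_that("null data share one letter and two-group letters mirror the single test", {
  set.seed(3)
  v <- rnorm(30, 5)
  g <- rep(c("a", "b", "c"), 10)
  r <- tukey_hsd(v, g)
  expect_true(all(r$letters == "a"))
  v2 <- c(rnorm(10, 0), rnorm(10, 6))
  g2 <- rep(c("a", "b"), each = 10)
  r2 <- tukey_hsd(v2, g2)
  expect_identical(unname(r2$letters["a"] != r2$letters["b"]),
                   r2$table$significant[1])
  expect_error(tukey_hsd(rep(1, 6), rep(c("a", "b"), 3)), "zero residual")
})

test_that("Tukey p decreases as the mean difference grows", {
  set.seed(5)
  base <- rnorm(10)
  ps <- vapply(c(0.5, 1, 2, 4), function(delta) {
    v <- c(base, base + delta)
    tukey_hsd(v, rep(c("a", "b"), each = 10))$table$p_adj
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("logistic regression is exact under forced symmetry and matches a grid-search MLE", {
  # one jump and one scramble at each predictor value -> slope exactly 0
  x <- rep(c(10, 20, 30, 40), each = 2)
  y <- rep(c(TRUE, FALSE), 4)
  r <- logistic_jump(x, y)
  expect_equal(r$slope, 0, tolerance = 1e-8)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-8)
  # 8-point data set against iterated grid refinement of the likelihood
  x8 <- c(12, 15, 18, 22, 26, 30, 34, 40)
  y8 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r8 <- logistic_jump(x8, y8)
  oracle <- logistic_grid_mle(x8, y8)
  expect_equal(r8$slope, oracle$slope, tolerance = 1e-4)
  expect_equal(r8$intercept, oracle$intercept, tolerance = 1e-3)
})

test_that("single-class outcomes and complete separation are flagged", {
  expect_error(logistic_jump(c(10, 20, 30), c(TRUE, TRUE, TRUE)),
               "both outcome classes")
  expect_error(logistic_jump(c(1, 2, 3, 4, 10, 11, 12, 13),
                             c(rep(FALSE, 4), rep(TRUE, 4))),
               "separation")
})

test_that("scramble-vs-jump F equals the squared pooled t statistic", {
  set.seed(7)
  to <- c(rnorm(12, 88, 20), rnorm(9, 126, 20))
  mode <- rep(c("jump", "scramble"), c(12, 9))
  r <- scramble_vs_jump(to, mode)
  tt <- t.test(to[mode == "jump"], to[mode == "scramble"], var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
  expect_equal(r$mean_jump, mean(to[mode == "jump"]))
  expect_equal(r$mean_scramble, mean(to[mode == "scramble"]))
  # matched samples from one distribution give F near 0
  same <- c(rnorm(50, 100, 1))
  r0 <- scramble_vs_jump(c(same, same),
                         rep(c("jump", "scramble"), each = 50))
  expect_equal(r0$F, 0, tolerance = 1e-9)
  expect_error(scramble_vs_jump(to, rep("jump", 21)), "both")
  expect_error(scramble_vs_jump(to, rep(c("jump", "hop"), c(12, 9))), "mode")
})

test_that("group summaries report mean, SD/sqrt(n) and metric-wise n", {
  tr <- make_trials(rep("AAAA", 3), mode = "scramble",
                    reaction_ms = c(1, 2, 3), takeoff_ms = c(1, 2, 3),
                    displacement_m = NA, airborne_s = NA)
  s <- summarize_trials(tr)
  row <- s[s$metric == "reaction_ms", ]
  expect_equal(row$mean, 2)
  expect_equal(row$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(row$n, 3L)
  # single usable value: SE undefined
  tr1 <- make_trials("BBBB", mode = "scramble", reaction_ms = 10,
                     takeoff_ms = 50, displacement_m = NA, airborne_s = NA)
  s1 <- summarize_trials(tr1)
  expect_true(is.na(s1$se[s1$metric == "reaction_ms"]))
  expect_equal(s1$n[s1$metric == "reaction_ms"], 1L)
  # censored trials drop out of the right metrics
  tr$hit_by_cork[1] <- TRUE
  s2 <- summarize_trials(tr)
  expect_equal(s2$n[s2$metric == "reaction_ms"], 2L)
  expect_equal(s2$n[s2$metric == "takeoff_ms"], 2L)
  expect_equal(s2$n[s2$metric == "mass_g"], 3L)
})
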
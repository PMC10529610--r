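test_that("two-sample t matches the hand formula and degenerates sanely", {
  g1 <- c(1.1, 2.3, 3.0)
  g2 <- c(2.0, 2.5, 4.1)
  res <- two_sample_tests(c(g1, g2), rep(c("a", "b"), each = 3), "student")
  sp2 <- (2 * var(g1) + 2 * var(g2)) / 4
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$effect, (mean(g1) - mean(g2)) / sqrt(sp2),
               tolerance = 1e-10)
  # identical groups: t = 0, d = 0, p = 1
  same <- two_sample_tests(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3),
                           "student")
  expect_equal(same$statistic, 0)
  expect_equal(same$effect, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_tests(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero pooled variance")
})

test_that("Student and Welch agree under equal variances", {
  x <- with_seed(1, rnorm(20))
  y <- x + 0.3          # same spread, shifted
  st <- two_sample_tests(c(x, y), rep(c("a", "b"), each = 20), "student")
  we <- two_sample_tests(c(x, y), rep(c("a", "b"), each = 20), "welch")
  expect_equal(st$statistic, we$statistic, tolerance = 1e-3)
  expect_lte(we$df, st$df + 1e-9)
  # the auto rule switches to Welch for a large variance ratio
  y2 <- with_seed(2, rnorm(20, 0, 4))
  expect_equal(two_sample_tests(c(x, y2), rep(c("a", "b"), each = 20))$test,
               "welch_t")
})

test_that("mixed ANOVA matches the hand-worked partition and invariances", {
  set.seed(42)
  n1 <- 6; n2 <- 8
  subj <- rep(sprintf("s%02d", 1:(n1 + n2)), each = 2)
  grp <- rep(rep(c("g1", "g2"), c(n1, n2)), each = 2)
  cond <- rep(c("c1", "c2"), n1 + n2)
  val <- rnorm(2 * (n1 + n2)) + (grp == "g1") * 0.5 +
    (cond == "c2") * 0.3 + (grp == "g1" & cond == "c2") * 0.4
  res <- mixed_anova_2x2(val, grp, cond, subj)
  orc <- mixed_anova_oracle(val, grp, cond, subj)
  expect_equal(res$F[res$effect == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "condition"], orc$F_cond,
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:condition"], orc$F_int,
               tolerance = 1e-8)
  expect_equal(res$df2, rep(orc$df2, 3))
  expect_true(all(res$pes >= 0 & res$pes <= 1))
  # location invariance
  res2 <- mixed_anova_2x2(val + 100, grp, cond, subj)
  expect_equal(res2$F, res$F, tolerance = 1e-8)
  # scale invariance
  res3 <- mixed_anova_2x2(val * 3, grp, cond, subj)
  expect_equal(res3$F, res$F, tolerance = 1e-8)
  expect_error(mixed_anova_2x2(val[-1], grp[-1], cond[-1], subj[-1]),
               "exactly one value")
})

test_that("a null interaction yields a near-zero F", {
  set.seed(7)
  subj <- rep(sprintf("s%02d", 1:40), each = 2)
  grp <- rep(rep(c("g1", "g2"), each = 20), each = 2)
  cond <- rep(c("c1", "c2"), 40)
  base <- rep(rnorm(40, 0, 0.3), each = 2)
  val <- base + (grp == "g1") * 1.0       # pure group effect
  val <- val + rnorm(80, 0, 1e-6)
  res <- mixed_anova_2x2(val, grp, cond, subj)
  expect_lt(res$F[res$effect == "group:condition"], 1)
  expect_gt(res$F[res$effect == "group"], 20)
})

test_that("rank tests match brute-force computations", {
  # complete separation: U = 0, rank-biserial = 1
  mw <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                   "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$effect, 1)
  # tied data against first-principles U and H
  v <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 6)
  lab <- rep(c("a", "b"), 5)
  g1 <- v[lab == "a"]; g2 <- v[lab == "b"]
  mw2 <- rank_tests(v, lab, "mann_whitney")
  expect_equal(mw2$statistic, brute_U(g1, g2))
  kw <- rank_tests(v, lab, "kruskal")
  expect_equal(kw$statistic, brute_H(v, lab), tolerance = 1e-10)
  # identical paired conditions: Friedman chi-square = 0
  fr <- rank_tests(rep(c(5, 3, 4, 6), 2), rep(c("c1", "c2"), each = 4),
                   "friedman", subject = rep(1:4, 2))
  expect_equal(fr$statistic, 0)
  expect_error(rank_tests(rep(1, 6), rep(c("a", "b"), 3), "kruskal"),
               "tied")
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("power is exact in the noncentral-t design", {
  # d = 0 gives power alpha
  pc <- sensitivity_power("t", c(29, 26), effect = c(0, 0.5, 0.8, 1.2))
  expect_equal(pc$power[1], 0.05, tolerance = 1e-10)
  expect_true(all(diff(pc$power) > 0))
  # simulation oracle at d = 0.8
  hits <- with_seed(99, mean(replicate(4000, {
    t.test(rnorm(29, 0.8), rnorm(26), var.equal = TRUE)$p.value < 0.05
  })))
  expect_lt(abs(hits - pc$power[pc$effect == 0.8]), 0.025)
  # inversion round-trip
  d85 <- sensitivity_power("t", c(29, 26), target_power = 0.85)
  expect_equal(sensitivity_power("t", c(29, 26), effect = d85)$power, 0.85,
               tolerance = 1e-6)
})

test_that("ANOVA-interaction power rises with effect size and correlation", {
  pc <- sensitivity_power("anova_interaction", c(17, 42),
                          effect = c(0, 0.25, 0.4))
  expect_equal(pc$power[1], 0.05, tolerance = 1e-10)
  expect_true(all(diff(pc$power) > 0))
  hi_rho <- sensitivity_power("anova_interaction", c(17, 42), effect = 0.25,
                              rho = 0.8)
  expect_gt(hi_rho$power, pc$power[2])
  spss <- sensitivity_power("anova_interaction", c(17, 42), effect = 0.4,
                            convention = "spss")
  expect_lt(spss$power, pc$power[3])
})

test_that("a planted f = 0.4 interaction is detected reliably", {
  # 17 vs 42 subjects, repeated-measures correlation 0.5; cell effects
  # +/- 0.4 SD in the crossed pattern
  detect <- with_seed(2024, replicate(200, {
    n <- c(17, 42)
    rho <- 0.5
    subj <- sprintf("s%02d", 1:sum(n))
    grp <- rep(c("aut", "nt"), n)
    b <- rnorm(sum(n), 0, sqrt(rho))
    eff <- ifelse(grp == "aut", 0.4, -0.4)
    y1 <- b + eff + rnorm(sum(n), 0, sqrt(1 - rho))
    y2 <- b - eff + rnorm(sum(n), 0, sqrt(1 - rho))
    res <- mixed_anova_2x2(c(y1, y2), rep(grp, 2),
                           rep(c("c1", "c2"), each = sum(n)),
                           rep(subj, 2))
    res$p[res$effect == "group:condition"] < 0.05
  }))
  expect_gte(mean(detect), 0.75)
})
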
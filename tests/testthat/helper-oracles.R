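# Independent oracles used across the test files. These are deliberately
# separate transcriptions / brute-force computations, not calls into the
# package internals.

# local seeded evaluation, independent of package internals
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# One step of the 3-level binary HGF variational updates, transcribed by
# hand (unit couplings). Used to guard the compiled filter.
hgf3_step_oracle <- function(u, om2, th, mu2, sa2, mu3, sa3) {
  muhat1 <- 1 / (1 + exp(-mu2))
  da1 <- u - muhat1
  v2 <- exp(mu3 + om2)
  pihat2 <- 1 / (sa2 + v2)
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2n <- mu2 + da1 / pi2
  da2 <- (1 / pi2 + (mu2n - mu2)^2) * pihat2 - 1
  pihat3 <- 1 / (sa3 + th)
  w2 <- v2 * pihat2
  pi3 <- pihat3 + 0.5 * w2 * (w2 + (2 * w2 - 1) * da2)
  mu3n <- mu3 + 0.5 / pi3 * w2 * da2
  list(muhat1 = muhat1, da1 = da1, mu2 = mu2n, sa2 = 1 / pi2,
       mu3 = mu3n, sa3 = 1 / pi3, da2 = da2)
}

# iterate the one-step oracle over a whole series
hgf3_oracle_filter <- function(u, om2, th, mu2 = 0, sa2 = 0.1,
                               mu3 = 1, sa3 = 1) {
  out <- lapply(u, function(uk) {
    st <- hgf3_step_oracle(uk, om2, th, mu2, sa2, mu3, sa3)
    mu2 <<- st$mu2; sa2 <<- st$sa2; mu3 <<- st$mu3; sa3 <<- st$sa3
    st
  })
  list(mu2 = vapply(out, `[[`, 0, "mu2"),
       sa2 = vapply(out, `[[`, 0, "sa2"),
       mu3 = vapply(out, `[[`, 0, "mu3"),
       muhat1 = vapply(out, `[[`, 0, "muhat1"))
}

# direct Dirichlet Monte-Carlo exceedance probabilities (independent of
# the package's sampler)
dirichlet_ep_oracle <- function(alpha, nsamp = 2e5) {
  K <- length(alpha)
  x <- matrix(rgamma(nsamp * K, shape = rep(alpha, each = nsamp)),
              nsamp, K)
  tabulate(max.col(x), K) / nsamp
}

# brute-force Mann-Whitney U and Kruskal-Wallis H from first principles
brute_U <- function(g1, g2) {
  sum(outer(g1, g2, function(a, b) (a > b) + 0.5 * (a == b)))
}
brute_H <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  groups <- split(r, labels)
  H <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(g) length(g) * mean(g)^2, 0)) -
    3 * (n + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# balanced 2x2 mixed-design sums-of-squares partition worked directly
# from cell/subject means
mixed_anova_oracle <- function(values, group, condition, subject) {
  d <- data.frame(y = values, g = factor(group), c = factor(condition),
                  s = factor(subject))
  N <- nlevels(d$s)
  gm <- mean(d$y)
  subj_mean <- tapply(d$y, d$s, mean)
  subj_group <- tapply(as.character(d$g), d$s, `[`, 1)
  grp_mean <- tapply(d$y, d$g, mean)
  cond_mean <- tapply(d$y, d$c, mean)
  cell_mean <- matrix(tapply(d$y, list(d$g, d$c), mean), 2, 2)
  ng <- as.numeric(table(subj_group)[names(grp_mean)])
  ss_group <- sum(2 * ng * (as.numeric(grp_mean) - gm)^2)
  ss_subj <- 2 * sum((subj_mean - grp_mean[subj_group])^2)
  ss_cond <- sum(N * (as.numeric(cond_mean) - gm)^2)
  int_eff <- t(t(cell_mean - as.numeric(grp_mean)) -
                 as.numeric(cond_mean)) + gm
  ss_int <- sum(rep(ng, 2) * int_eff^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_cond - ss_int
  list(F_group = (ss_group / 1) / (ss_subj / (N - 2)),
       F_cond = (ss_cond / 1) / (ss_err / (N - 2)),
       F_int = (ss_int / 1) / (ss_err / (N - 2)),
       df2 = N - 2)
}
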
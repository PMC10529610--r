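# Group-level statistics on extracted model parameters: t-tests, 2x2
# mixed ANOVA, rank tests, Holm correction, and power sensitivity
# analyses via noncentral distributions.

#' Two-sample comparison with Cohen's d
#'
#' Student or Welch t-test on two independent groups. With
#' `variance_rule = "auto"` Welch is used when the larger group variance
#' exceeds twice the smaller (the comparisons can also be forced either
#' way, since test variants are often chosen by inspection).
#'
#' @param values numeric outcomes.
#' @param group two-level factor / character vector.
#' @param variance_rule `"auto"`, `"student"` or `"welch"`.
#' @return A one-row data.frame: test, statistic, df, p, effect size
#'   (pooled-SD Cohen's d) and its type.
#' @export
two_sample_tests <- function(values, group,
                             variance_rule = c("auto", "student", "welch")) {
  variance_rule <- match.arg(variance_rule)
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, all(table(group) >= 2))
  g1 <- values[group == levels(group)[1]]
  g2 <- values[group == levels(group)[2]]
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  sp2 <- ((length(g1) - 1) * v1 + (length(g2) - 1) * v2) /
    (length(g1) + length(g2) - 2)
  if (sp2 == 0) stop("zero pooled variance: groups are constant")
  welch <- switch(variance_rule, welch = TRUE, student = FALSE,
                  auto = max(v1, v2) / max(min(v1, v2), 1e-300) > 2)
  tt <- stats::t.test(g1, g2, var.equal = !welch)
  data.frame(test = if (welch) "welch_t" else "student_t",
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             effect = (mean(g1) - mean(g2)) / sqrt(sp2),
             effect_type = "cohens_d", stringsAsFactors = FALSE)
}

#' 2x2 mixed-model ANOVA
#'
#' One between-subject factor (group) crossed with one within-subject
#' factor (condition), each subject measured at both condition levels.
#' F ratios come from the standard sums-of-squares partitioning (via
#' `aov` with a subject error stratum; the SS types coincide in this
#' balanced-within design) and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` per effect.
#'
#' @param values numeric outcomes, one per subject x condition cell.
#' @param group between-subject factor (constant within subject).
#' @param condition within-subject factor with two levels.
#' @param subject subject identifier.
#' @return A data.frame with rows `group`, `condition`,
#'   `group:condition`: F, dfs, p, partial eta squared.
#' @export
mixed_anova_2x2 <- function(values, group, condition, subject) {
  d <- data.frame(y = values, g = as.factor(group), c = as.factor(condition),
                  s = as.factor(subject))
  stopifnot(nlevels(d$g) == 2, nlevels(d$c) == 2)
  cnt <- table(d$s, d$c)
  if (any(cnt != 1)) {
    bad <- rownames(cnt)[rowSums(cnt != 1) > 0]
    stop("subjects without exactly one value per condition: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::aov(y ~ g * c + Error(s / c), data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: s"]][[1]])
  within <- as.data.frame(sm[["Error: s:c"]][[1]])
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab)  # residual row is last
    ss_e <- tab[i, "Sum Sq"]; ss_r <- tab[err, "Sum Sq"]
    data.frame(effect = term, F = tab[i, "F value"],
               df1 = tab[i, "Df"], df2 = tab[err, "Df"],
               p = tab[i, "Pr(>F)"],
               pes = ss_e / (ss_e + ss_r), stringsAsFactors = FALSE)
  }
  out <- rbind(pick(between, "g"), pick(within, "c"), pick(within, "g:c"))
  out$effect <- c("group", "condition", "group:condition")
  out
}

#' Rank-based group and condition tests
#'
#' Friedman test across paired conditions, Kruskal-Wallis across groups,
#' or Mann-Whitney between two groups with the normal-approximation z and
#' the rank-biserial effect size, tie-corrected throughout.
#'
#' @param values numeric outcomes.
#' @param labels condition (friedman) or group labels.
#' @param design `"friedman"` (requires `subject`), `"kruskal"` or
#'   `"mann_whitney"`.
#' @param subject subject ids for the paired design.
#' @return A one-row data.frame: test, statistic, df (where defined), p
#'   and effect size.
#' @export
rank_tests <- function(values, labels,
                       design = c("friedman", "kruskal", "mann_whitney"),
                       subject = NULL) {
  design <- match.arg(design)
  labels <- as.factor(labels)
  if (length(unique(values)) == 1) stop("all observations are tied")
  if (design == "friedman") {
    if (is.null(subject)) stop("friedman design needs subject ids")
    ft <- stats::friedman.test(values, labels, as.factor(subject))
    stat <- unname(ft$statistic)
    pval <- ft$p.value
    if (!is.finite(stat)) { stat <- 0; pval <- 1 }  # fully tied ranks
    data.frame(test = "friedman", statistic = stat,
               df = unname(ft$parameter), p = pval,
               effect = NA_real_, effect_type = NA_character_,
               stringsAsFactors = FALSE)
  } else if (design == "kruskal") {
    kt <- stats::kruskal.test(values, labels)
    data.frame(test = "kruskal_wallis", statistic = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value,
               effect = NA_real_, effect_type = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(nlevels(labels) == 2)
    g1 <- values[labels == levels(labels)[1]]
    g2 <- values[labels == levels(labels)[2]]
    n1 <- length(g1); n2 <- length(g2)
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                              correct = FALSE))
    U <- unname(wt$statistic)
    # tie-corrected normal approximation
    r <- rank(c(g1, g2))
    ties <- table(r)
    sigma <- sqrt(n1 * n2 / 12 *
                    (n1 + n2 + 1 - sum(ties^3 - ties) /
                       ((n1 + n2) * (n1 + n2 - 1))))
    z <- (U - n1 * n2 / 2) / sigma
    data.frame(test = "mann_whitney", statistic = U, df = NA_real_,
               p = wt$p.value, effect = 1 - 2 * U / (n1 * n2),
               effect_type = "rank_biserial", z = z,
               stringsAsFactors = FALSE)
  }
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm correction with monotonicity enforcement (as in
#' `p.adjust`).
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Power sensitivity analysis
#'
#' Exact power for a two-sample two-tailed t-test via the noncentral t
#' distribution, or for the group-by-condition interaction of a 2x2
#' mixed ANOVA via the noncentral F distribution. Given `target_power`,
#' the detectable effect size is returned by numerical inversion.
#'
#' For the mixed-ANOVA interaction the noncentrality depends on the
#' repeated-measures correlation rho: `lambda = N * f^2 * m / (1 - rho)`
#' with m = 2 repeated measures (`convention = "gpower"`), or
#' `lambda = N * f^2` when the correlation is taken as absorbed into f
#' (`convention = "spss"`).
#'
#' @param design `"t"` or `"anova_interaction"`.
#' @param n per-group sample sizes, length 2.
#' @param alpha two-tailed significance level.
#' @param effect effect-size grid (d, or f) at which to evaluate power;
#'   ignored when `target_power` is given.
#' @param target_power if supplied, return the effect size whose power
#'   equals it.
#' @param rho repeated-measures correlation (ANOVA design only).
#' @param convention noncentrality convention for the ANOVA design.
#' @return If `target_power` is given, the effect size (scalar);
#'   otherwise a `power_curve` data.frame of effect sizes and power.
#' @examples
#' sensitivity_power("t", n = c(29, 26), target_power = 0.85)  # ~0.82
#' @export
sensitivity_power <- function(design = c("t", "anova_interaction"),
                              n, alpha = 0.05, effect = seq(0, 2, 0.05),
                              target_power = NULL, rho = 0.5,
                              convention = c("gpower", "spss")) {
  design <- match.arg(design)
  convention <- match.arg(convention)
  stopifnot(length(n) == 2, all(n >= 2), alpha > 0, alpha < 1)
  power_fn <- if (design == "t") {
    df <- sum(n) - 2
    tc <- stats::qt(1 - alpha / 2, df)
    function(es) {
      ncp <- es * sqrt(prod(n) / sum(n))
      stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
    }
  } else {
    N <- sum(n); df2 <- N - 2
    fc <- stats::qf(1 - alpha, 1, df2)
    mult <- if (convention == "gpower") 2 / (1 - rho) else 1
    function(es) stats::pf(fc, 1, df2, ncp = N * es^2 * mult,
                           lower.tail = FALSE)
  }
  if (!is.null(target_power)) {
    stopifnot(target_power > alpha, target_power < 1)
    return(stats::uniroot(function(es) power_fn(es) - target_power,
                          c(1e-6, 10), tol = 1e-8)$root)
  }
  structure(data.frame(effect = effect,
                       power = vapply(effect, power_fn, numeric(1))),
            class = c("power_curve", "data.frame"),
            design = design, n = n, alpha = alpha)
}
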
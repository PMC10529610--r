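#' Random-effects Bayesian model selection
#'
#' Treats the generative model as a random variable with unknown
#' population frequencies and infers their Dirichlet posterior from a
#' subjects x models matrix of log model evidences, by the standard
#' variational scheme: subject-wise model responsibilities (softmax of the
#' evidences plus digamma terms) and Dirichlet concentrations are iterated
#' to convergence. Reports expected frequencies, exceedance probabilities
#' (EP), the Bayes omnibus risk (BOR: posterior probability that all
#' models are equally frequent, from the free-energy comparison against
#' the equal-frequency null) and protected exceedance probabilities
#' `PXP = EP * (1 - BOR) + BOR / K`.
#'
#' @param lme numeric matrix, subjects in rows, models in columns; column
#'   names label the models. All entries must be finite. Only within-row
#'   differences matter: adding a subject-specific constant changes
#'   nothing.
#' @param alpha0 prior Dirichlet concentration (scalar or per model);
#'   default 1 (uniform).
#' @param nsamp Monte-Carlo draws for the exceedance probabilities.
#' @param seed seed for the Monte-Carlo step.
#' @param ep_method `"auto"` uses the exact Beta comparison when `K = 2`
#'   and Monte Carlo otherwise; `"exact"` / `"mc"` force a path.
#' @param tol convergence tolerance on the concentration updates.
#' @return A `bms` object: `alpha` (posterior concentrations), `r`
#'   (expected frequencies), `ep`, `bor`, `pxp`, `g` (subject
#'   responsibilities), free energies `F1`/`F0`, and bookkeeping.
#' @examples
#' lme <- cbind(m1 = c(-20, -21, -19), m2 = c(-25, -24, -26))
#' rfx_bms(lme)
#' @export
rfx_bms <- function(lme, alpha0 = 1, nsamp = 1e5, seed = 1L,
                    ep_method = c("auto", "exact", "mc"), tol = 1e-6) {
  ep_method <- match.arg(ep_method)
  lme <- as.matrix(lme)
  if (ncol(lme) < 2) stop("need at least two models")
  if (any(!is.finite(lme))) {
    bad <- which(!is.finite(lme), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log evidence for subject %d, model %d",
                 bad[1], bad[2]))
  }
  n <- nrow(lme); K <- ncol(lme)
  if (is.null(colnames(lme))) colnames(lme) <- paste0("model", seq_len(K))
  a0 <- rep_len(alpha0, K)

  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  for (it in seq_len(500)) {
    lw <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw) / rowSums(exp(lw))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  r <- alpha / sum(alpha)

  ep <- if ((ep_method == "auto" && K == 2) || ep_method == "exact") {
    if (K != 2) stop("exact exceedance path requires K = 2")
    p1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    c(p1, 1 - p1)
  } else {
    with_seed(seed, {
      x <- matrix(stats::rgamma(nsamp * K, shape = rep(alpha, each = nsamp)),
                  nsamp, K)
      tabulate(max.col(x), K) / nsamp
    })
  }

  # free energy of the random-effects model vs the equal-frequency null
  elr <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(g * sweep(lme, 2, elr, `+`)) - sum(g * log(pmax(g, 1e-300))) +
    dirichlet_neg_kl(alpha, a0)
  F0 <- sum(apply(lme, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- ep * (1 - bor) + bor / K

  structure(list(alpha = stats::setNames(alpha, colnames(lme)),
                 r = stats::setNames(r, colnames(lme)),
                 ep = stats::setNames(ep, colnames(lme)),
                 bor = bor,
                 pxp = stats::setNames(pxp, colnames(lme)),
                 g = g, F1 = F1, F0 = F0, n_subjects = n, alpha0 = a0,
                 nsamp = nsamp, seed = seed, iterations = it),
            class = "bms")
}

# -KL(Dir(alpha) || Dir(alpha0)): the Dirichlet part of the free energy
dirichlet_neg_kl <- function(alpha, a0) {
  elr <- digamma(alpha) - digamma(sum(alpha))
  (lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elr)) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elr))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.bms <- function(x, ...) {
  cat(sprintf("Random-effects BMS over %d subjects, %d models\n",
              x$n_subjects, length(x$r)))
  tab <- rbind(`expected frequency` = x$r, `exceedance prob.` = x$ep,
               `protected EP` = x$pxp)
  print(round(tab, 4))
  cat(sprintf("Bayes omnibus risk: %.4f\n", x$bor))
  invisible(x)
}

#' @export
summary.bms <- function(object, ...) {
  data.frame(model = names(object$r), alpha = as.numeric(object$alpha),
             r = as.numeric(object$r), ep = as.numeric(object$ep),
             pxp = as.numeric(object$pxp), bor = object$bor,
             row.names = NULL)
}

#' @export
plot.bms <- function(x, ...) {
  graphics::barplot(rbind(x$r, x$pxp), beside = TRUE,
                    names.arg = names(x$r),
                    legend.text = c("expected frequency", "protected EP"),
                    ylim = c(0, 1), ...)
  invisible(x)
}

#' Family-level Bayesian model selection
#'
#' Collapses a subjects x models evidence matrix onto model families
#' (uniform within-family prior: the family evidence of a subject is the
#' log mean of the member evidences) and runs random-effects selection
#' over the families.
#'
#' @param lme subjects x models matrix of log model evidences.
#' @param families named list mapping family name to member column names
#'   or indices.
#' @param ... passed to [rfx_bms()].
#' @return A `bms` object over families.
#' @export
family_bms <- function(lme, families, ...) {
  lme <- as.matrix(lme)
  fam <- vapply(families, function(members) {
    sub <- lme[, members, drop = FALSE]
    apply(sub, 1, logsumexp) - log(ncol(sub))
  }, numeric(nrow(lme)))
  if (nrow(lme) == 1L) fam <- matrix(fam, nrow = 1,
                                     dimnames = list(NULL, names(families)))
  colnames(fam) <- names(families)
  rfx_bms(fam, ...)
}
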
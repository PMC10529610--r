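# Parameter- and model-recovery harnesses: simulate agents with known
# ground truth, re-fit, and report how well truth is recovered.

#' Parameter recovery study
#'
#' Draws true parameters from dispersed ranges, simulates one agent per
#' subject, fits the same model back by MAP, and reports per-parameter
#' true-vs-recovered correlation, bias and RMSE plus the identifiability
#' matrix (pairwise correlations among recovered parameters).
#'
#' @param model model name.
#' @param n_subjects number of simulated subjects (>= 10).
#' @param design a design object, binary input vector, or
#'   function(subject, seed) producing one per subject.
#' @param seed master seed.
#' @param n_restarts optimisation restarts per fit.
#' @param ranges optional named list of `c(lo, hi)` uniform draw ranges in
#'   native space, overriding the defaults.
#' @return A `recovery_report`: `stats` (data.frame: parameter, cor, bias,
#'   rmse), `identifiability` (correlation matrix of recovered
#'   parameters), `true`, `recovered`, and the number of failed fits.
#' @export
parameter_recovery <- function(model, n_subjects, design, seed = 1L,
                               n_restarts = 5, ranges = NULL) {
  stopifnot(n_subjects >= 10)
  defaults <- switch(model,
    hgf3 = list(om2 = c(-4, -1.5), th = c(0.1, 1), zeta = c(2, 8)),
    hgf4 = list(om2 = c(-4, -1.5), om3 = c(-7, -4), th = c(0.3, 0.8),
                zeta = c(2, 8)),
    rw  = list(alpha = c(0.05, 0.7), v0 = c(0.3, 0.7), zeta = c(4, 16)),
    k1  = list(alpha0 = c(0.05, 0.6), mu_meta = c(0.01, 0.5),
               v0 = c(0.3, 0.7), zeta = c(4, 16)))
  if (!is.null(ranges)) defaults <- utils::modifyList(defaults, ranges)
  draw <- function() lapply(defaults, function(r) stats::runif(1, r[1], r[2]))
  true <- recov <- list()
  failed <- 0L
  for (i in seq_len(n_subjects)) {
    s_i <- seed * 1000L + i
    tp <- with_seed(s_i, draw())
    des <- if (is.function(design)) design(i, s_i) else design
    ag <- simulate_agent(des, model,
                         tp[setdiff(names(tp), "zeta")],
                         zeta = tp$zeta, seed = s_i)
    fit <- fit_learner(ag$u, ag$y, model, n_restarts = n_restarts,
                       seed = s_i)
    if (isTRUE(fit$failed)) { failed <- failed + 1L; next }
    true[[length(true) + 1L]] <- unlist(tp)
    recov[[length(recov) + 1L]] <- coef(fit)[names(unlist(tp))]
  }
  tm <- do.call(rbind, true)
  rm_ <- do.call(rbind, recov)
  stats_df <- data.frame(
    parameter = colnames(tm),
    cor = vapply(seq_len(ncol(tm)), function(j)
      stats::cor(tm[, j], rm_[, j]), numeric(1)),
    bias = colMeans(rm_ - tm),
    rmse = sqrt(colMeans((rm_ - tm)^2)), row.names = NULL)
  ident <- stats::cor(rm_)
  structure(list(model = model, stats = stats_df, identifiability = ident,
                 true = tm, recovered = rm_, n_failed = failed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery for %s (%d subjects, %d failed fits)\n",
              toupper(x$model), nrow(x$true), x$n_failed))
  print(transform(x$stats, cor = round(cor, 3), bias = round(bias, 3),
                  rmse = round(rmse, 3)), row.names = FALSE)
  invisible(x)
}

#' Model recovery study
#'
#' For each generating model, simulates a cohort, fits all candidate
#' models to every subject, runs random-effects model selection, and
#' records which model wins by protected exceedance probability.
#'
#' @param models candidate model names (all are simulated and fitted).
#' @param n_subjects cohort size per generating model.
#' @param design design object / vector / function(subject, seed).
#' @param seed master seed.
#' @param n_restarts optimisation restarts per fit.
#' @return A list with `confusion` (truth x selected counts), `pxp`
#'   (truth x candidate PXP matrix) and `n_failed`.
#' @export
model_recovery <- function(models = learner_models(), n_subjects = 10,
                           design, seed = 1L, n_restarts = 3) {
  confusion <- matrix(0L, length(models), length(models),
                      dimnames = list(truth = models, selected = models))
  pxp <- matrix(NA_real_, length(models), length(models),
                dimnames = list(truth = models, candidate = models))
  failed <- 0L
  for (ti in seq_along(models)) {
    truth <- models[ti]
    lmes <- matrix(NA_real_, n_subjects, length(models),
                   dimnames = list(NULL, models))
    for (i in seq_len(n_subjects)) {
      s_i <- seed * 100000L + ti * 1000L + i
      des <- if (is.function(design)) design(i, s_i) else design
      tp <- with_seed(s_i, switch(truth,
        hgf3 = list(om2 = stats::runif(1, -4, -2), th = 0.5),
        hgf4 = list(om2 = stats::runif(1, -4, -2),
                    om3 = stats::runif(1, -7, -5), th = 0.5),
        rw = list(alpha = stats::runif(1, 0.1, 0.5), v0 = 0.5),
        k1 = list(alpha0 = stats::runif(1, 0.1, 0.5),
                  mu_meta = stats::runif(1, 0.05, 0.3), v0 = 0.5)))
      ag <- simulate_agent(des, truth, tp,
                           zeta = with_seed(s_i + 1L, stats::runif(1, 2, 6)),
                           seed = s_i)
      for (m in models) {
        fit <- fit_learner(ag$u, ag$y, m, n_restarts = n_restarts,
                           seed = s_i)
        if (isTRUE(fit$failed)) failed <- failed + 1L
        lmes[i, m] <- if (isTRUE(fit$failed)) NA_real_ else fit$lme
      }
    }
    keep <- stats::complete.cases(lmes)
    bms <- rfx_bms(lmes[keep, , drop = FALSE], seed = seed)
    pxp[ti, ] <- bms$pxp
    win <- names(which.max(bms$pxp))
    confusion[ti, win] <- confusion[ti, win] + 1L
  }
  list(confusion = confusion, pxp = pxp, n_failed = failed)
}
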
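# Model registry: transformed parameterisations used by the inverter.
# Transforms keep the quasi-Newton search unconstrained: log for variances
# and the decision temperature, logit for rates/values bounded to [0, 1],
# identity for tonic log-volatilities (already unbounded).

learner_models <- function() c("hgf3", "hgf4", "rw", "k1")

model_info <- function(model) {
  switch(model,
    hgf3 = list(
      tpar = c("om2", "log_th", "log_ze"),
      to_native = function(p) list(om2 = p[["om2"]], th = exp(p[["log_th"]]),
                                   zeta = exp(p[["log_ze"]])),
      run = function(u, nat) hgf_filter(u, levels = 3, om2 = nat$om2,
                                        th = nat$th),
      prior_mean = c(om2 = -3, log_th = log(0.5), log_ze = log(2)),
      prior_var  = c(om2 = 4, log_th = 4, log_ze = 4)),
    hgf4 = list(
      # om4 = log top-level variance; kept nearly fixed by a tight prior,
      # which reproduces the degeneracy of the fourth-level volatility
      # parameter on short series while leaving it formally estimable
      tpar = c("om2", "om3", "om4", "log_ze"),
      to_native = function(p) list(om2 = p[["om2"]], om3 = p[["om3"]],
                                   th = exp(p[["om4"]]),
                                   zeta = exp(p[["log_ze"]])),
      run = function(u, nat) hgf_filter(u, levels = 4, om2 = nat$om2,
                                        om3 = nat$om3, th = nat$th),
      prior_mean = c(om2 = -3, om3 = -6, om4 = log(0.5), log_ze = log(2)),
      prior_var  = c(om2 = 4, om3 = 4, om4 = 0.05, log_ze = 4)),
    rw = list(
      tpar = c("logit_al", "logit_v0", "log_ze"),
      to_native = function(p) list(alpha = plogis(p[["logit_al"]]),
                                   v0 = plogis(p[["logit_v0"]]),
                                   zeta = exp(p[["log_ze"]])),
      run = function(u, nat) rw_filter(u, alpha = nat$alpha, v0 = nat$v0),
      prior_mean = c(logit_al = 0, logit_v0 = 0, log_ze = log(2)),
      prior_var  = c(logit_al = 4, logit_v0 = 4, log_ze = 4)),
    k1 = list(
      tpar = c("logit_al0", "log_mu", "logit_v0", "log_ze"),
      to_native = function(p) list(alpha0 = plogis(p[["logit_al0"]]),
                                   mu_meta = exp(p[["log_mu"]]),
                                   v0 = plogis(p[["logit_v0"]]),
                                   zeta = exp(p[["log_ze"]])),
      run = function(u, nat) k1_filter(u, alpha0 = nat$alpha0,
                                       mu_meta = nat$mu_meta, v0 = nat$v0),
      prior_mean = c(logit_al0 = 0, log_mu = log(0.1), logit_v0 = 0,
                     log_ze = log(2)),
      prior_var  = c(logit_al0 = 4, log_mu = 4, logit_v0 = 4, log_ze = 4)),
    stop("unknown model: ", model))
}

#' Default prior specification for a learning model
#'
#' Gaussian priors on the transformed parameters of a model. Variances
#' default to 4, wide enough to be only weakly informative on the scales
#' involved; the fourth-level volatility parameter of the 4-level HGF gets
#' a tight prior (variance 0.05) so that it is pinned near its prior mean.
#'
#' @param model one of `"hgf3"`, `"hgf4"`, `"rw"`, `"k1"`.
#' @return An object of class `prior_spec`: a list with named numeric
#'   vectors `mean` and `var` over the model's transformed parameters.
#' @export
default_priors <- function(model) {
  mi <- model_info(model)
  structure(list(model = model, mean = mi$prior_mean, var = mi$prior_var),
            class = "prior_spec")
}

#' Elicit perceptual prior means from experiment designs
#'
#' Sets the prior means of a model's perceptual parameters to the values
#' under which an ideal observer would experience the least surprise about
#' the input sequences it will face: a grid search minimising the mean
#' Bernoulli surprise of the model's own one-step-ahead predictions over
#' the supplied designs. Response-model parameters keep their defaults and
#' prior variances stay wide.
#'
#' @param designs a list of binary input vectors, or of design objects
#'   accepted by [design_inputs()].
#' @param model model name.
#' @param grid_n grid resolution per parameter.
#' @return A `prior_spec` whose perceptual means minimise input surprise.
#' @export
elicit_priors <- function(designs, model, grid_n = 13) {
  if (!length(designs)) stop("at least one design sequence is required")
  us <- lapply(designs, function(d)
    if (is.numeric(d) || is.integer(d)) check_binary(d, "design") else
      design_inputs(d))
  mi <- model_info(model)
  pr <- default_priors(model)
  surprise <- function(tp) {
    nat <- mi$to_native(tp)
    s <- vapply(us, function(u) {
      tr <- tryCatch(mi$run(u, nat), error = function(e) NULL)
      if (is.null(tr)) return(Inf)
      p <- pmin(pmax(tr$pred, 1e-12), 1 - 1e-12)
      -mean(u * log(p) + (1 - u) * log1p(-p))
    }, numeric(1))
    mean(s)
  }
  grids <- switch(model,
    hgf3 = list(om2 = seq(-8, 0, length.out = grid_n),
                log_th = seq(log(0.05), log(2), length.out = 7)),
    hgf4 = list(om2 = seq(-8, 0, length.out = grid_n),
                om3 = seq(-8, -2, length.out = 7)),
    rw  = list(logit_al = qlogis(seq(0.02, 0.98, length.out = grid_n)),
               logit_v0 = qlogis(c(0.2, 0.35, 0.5, 0.65, 0.8))),
    k1  = list(logit_al0 = qlogis(seq(0.02, 0.98, length.out = grid_n)),
               log_mu = log(c(0.01, 0.05, 0.1, 0.3, 1))))
  gg <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  vals <- vapply(seq_len(nrow(gg)), function(i) {
    tp <- pr$mean
    tp[names(gg)] <- as.numeric(gg[i, ])
    surprise(tp)
  }, numeric(1))
  if (!any(is.finite(vals))) {
    warning("surprise surface degenerate; keeping default prior means")
    return(pr)
  }
  if (diff(range(vals[is.finite(vals)])) < 1e-10)
    warning("flat surprise surface; prior means weakly identified")
  best <- gg[which.min(vals), , drop = FALSE]
  pr$mean[names(best)] <- as.numeric(best)
  pr
}

#' Laplace approximation to a log model evidence
#'
#' Approximates `log int exp(log_joint(theta)) dtheta` around a mode:
#' `LME = log_joint(mode) + d/2 * log(2*pi) - 1/2 * log det H`, with `H`
#' the negative Hessian of the log joint at the mode. The Hessian is
#' obtained by symmetrised finite differences; if it is not positive
#' definite its eigenvalues are floored at `1e-8` (flagged as a repair).
#'
#' @param neg_log_joint function of the parameter vector returning the
#'   *negative* log joint.
#' @param par the mode (MAP estimate) in the same space.
#' @param hessian optional precomputed Hessian of `neg_log_joint` at `par`.
#' @return A list: `lme`, `log_joint`, `hessian`, `logdet`, `repaired`.
#' @examples
#' # 1-parameter quadratic log joint: exact Gaussian integral
#' nlj <- function(x) 0.5 * (x - 2)^2 / 0.3^2
#' laplace_evidence(nlj, 2)$lme  # log(sqrt(2*pi) * 0.3)
#' @export
laplace_evidence <- function(neg_log_joint, par, hessian = NULL) {
  d <- length(par)
  if (d == 0L)
    return(list(lme = -neg_log_joint(par), log_joint = -neg_log_joint(par),
                hessian = matrix(0, 0, 0), logdet = 0, repaired = FALSE))
  H <- if (is.null(hessian))
    stats::optimHess(par, neg_log_joint) else hessian
  H <- (H + t(H)) / 2
  ee <- eigen(H, symmetric = TRUE)
  repaired <- any(ee$values < 1e-8)
  ev <- pmax(ee$values, 1e-8)
  lj <- -neg_log_joint(par)
  list(lme = lj + d / 2 * log(2 * pi) - 0.5 * sum(log(ev)),
       log_joint = lj, hessian = H, logdet = sum(log(ev)),
       repaired = repaired)
}

#' Fit a learning model to one subject's series by MAP estimation
#'
#' The workhorse estimator: maximises log-likelihood plus log-prior in the
#' model's transformed parameter space by quasi-Newton (BFGS) search from
#' the prior mean and `n_restarts - 1` jittered starts, then attaches the
#' Laplace approximation to the log model evidence. Divergent belief
#' trajectories (possible for HGF parameter proposals) score as infinitely
#' bad and are thereby rejected during the search.
#'
#' @param u binary input series (0/1).
#' @param y binary response series, same length; `NA` marks masked trials.
#' @param model `"hgf3"`, `"hgf4"`, `"rw"` or `"k1"`.
#' @param priors a `prior_spec` (see [default_priors()], [elicit_priors()]).
#' @param n_restarts number of optimisation starts (first is the prior
#'   mean).
#' @param seed integer seed controlling the start jitter; fits are
#'   bit-reproducible given `(u, y, priors, n_restarts, seed)`.
#' @param subject,condition optional identifiers carried into the result.
#' @return A `learnfit` object: MAP estimates in native (`coef()`) and
#'   transformed space, the maximised log-likelihood (`logLik()`), the
#'   Laplace log model evidence (`$lme`), the belief trajectory at the MAP
#'   (`$trajectory`), and optimisation diagnostics.
#' @seealso [rfx_bms()] for population-level model comparison over the
#'   resulting evidences.
#' @examples
#' u <- rbinom(60, 1, 0.8)
#' ag <- rw_filter(u, alpha = 0.3)
#' y <- rbinom(60, 1, response_probability(pmin(pmax(ag$pred, 1e-6), 1 - 1e-6), 8))
#' fit <- fit_learner(u, y, "rw", n_restarts = 3, seed = 1)
#' coef(fit)
#' @export
fit_learner <- function(u, y, model = c("hgf3", "hgf4", "rw", "k1"),
                        priors = NULL, n_restarts = 10, seed = 1L,
                        subject = NA_character_, condition = NA_character_) {
  model <- match.arg(model)
  u <- check_binary(u, "u")
  if (length(u) != length(y)) stop("`u` and `y` have different lengths")
  if (!all(y[!is.na(y)] %in% c(0, 1))) stop("`y` must be binary (0/1 or NA)")
  mi <- model_info(model)
  if (is.null(priors)) priors <- default_priors(model)
  stopifnot(inherits(priors, "prior_spec"),
            setequal(names(priors$mean), mi$tpar), all(priors$var > 0))
  pm <- priors$mean[mi$tpar]
  pv <- priors$var[mi$tpar]
  d <- length(pm)

  nlj <- function(tp) {
    names(tp) <- mi$tpar
    nat <- mi$to_native(tp)
    tr <- tryCatch(mi$run(u, nat), error = function(e) NULL)
    if (is.null(tr)) return(1e10)
    ll <- response_loglik(tr, y, nat$zeta)
    val <- -(as.numeric(ll) + sum(stats::dnorm(tp, pm, sqrt(pv), log = TRUE)))
    if (!is.finite(val)) 1e10 else val
  }

  starts <- with_seed(seed, {
    jit <- pmin(sqrt(pv), 2)
    rbind(pm, if (n_restarts > 1)
      t(replicate(n_restarts - 1, pm + stats::rnorm(d, 0, jit))))
  })
  best <- NULL
  conv <- integer(0)
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(
      stats::optim(starts[i, ], nlj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(op) || !is.finite(op$value) || op$value >= 1e10) next
    conv <- c(conv, op$convergence)
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) {
    return(structure(list(model = model, subject = subject,
                          condition = condition, failed = TRUE,
                          lme = NA_real_, priors = priors, seed = seed),
                     class = "learnfit"))
  }
  # never worse than the prior mean
  if (nlj(pm) < best$value) best <- list(par = pm, value = nlj(pm),
                                         convergence = 0L)
  tp <- best$par
  names(tp) <- mi$tpar
  nat <- mi$to_native(tp)
  traj <- mi$run(u, nat)
  ll <- response_loglik(traj, y, nat$zeta)
  lap <- laplace_evidence(nlj, tp)
  structure(list(
    model = model, subject = subject, condition = condition,
    u = u, y = y, failed = FALSE,
    par = nat, tpar = tp, priors = priors,
    loglik = as.numeric(ll), log_joint = -best$value, lme = lap$lme,
    hessian = lap$hessian, trajectory = traj,
    diagnostics = list(n_restarts = n_restarts, n_converged = sum(conv == 0),
                       hessian_repaired = lap$repaired,
                       clamped_trials = attr(ll, "clamped"), seed = seed),
    nobs = sum(!is.na(y)), df = d), class = "learnfit")
}

#' @export
print.learnfit <- function(x, ...) {
  cat("MAP fit of", toupper(x$model), "learning model\n")
  if (isTRUE(x$failed)) {
    cat("  <all optimisation restarts failed>\n")
    return(invisible(x))
  }
  cat(sprintf("  %d trials (%d used), %d free parameters\n",
              length(x$y), x$nobs, x$df))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(unlist(x$par)), unlist(x$par)),
            collapse = ", "), "\n")
  cat(sprintf("  log-likelihood %.3f, Laplace LME %.3f\n", x$loglik, x$lme))
  invisible(x)
}

#' @export
summary.learnfit <- function(object, ...) {
  out <- object[c("model", "subject", "condition", "par", "tpar",
                  "loglik", "lme", "diagnostics", "nobs", "df", "failed")]
  if (!isTRUE(object$failed))
    out$learning_rates <- compute_learning_rates(object$trajectory)
  class(out) <- "summary.learnfit"
  out
}

#' @export
print.summary.learnfit <- function(x, ...) {
  cat("Model:", x$model, " subject:", x$subject, "\n")
  cat("MAP estimates (native):\n")
  print(unlist(x$par))
  cat(sprintf("logLik %.3f  LME %.3f  (%d/%d restarts converged%s)\n",
              x$loglik, x$lme, x$diagnostics$n_converged,
              x$diagnostics$n_restarts,
              if (x$diagnostics$hessian_repaired) ", Hessian repaired" else ""))
  if (!is.null(x$learning_rates)) {
    lr <- x$learning_rates
    cat("mean learning rates:",
        paste(sprintf("%s = %.3f",
                      sub("mean_", "", grep("^mean_", names(lr), value = TRUE)),
                      unlist(lr[grep("^mean_", names(lr))])),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.learnfit <- function(object, transformed = FALSE, ...) {
  if (isTRUE(object$failed)) return(NULL)
  if (transformed) object$tpar else unlist(object$par)
}

#' @export
logLik.learnfit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
predict.learnfit <- function(object, type = c("response", "belief"), ...) {
  type <- match.arg(type)
  pred <- pmin(pmax(object$trajectory$pred, 1e-12), 1 - 1e-12)
  if (type == "belief") pred else
    response_probability(pred, object$par$zeta)
}

#' @export
residuals.learnfit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
simulate.learnfit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  n <- length(p)
  draw <- function() stats::rbinom(n, 1, p)
  if (is.null(seed)) replicate(nsim, draw()) else
    with_seed(seed, replicate(nsim, draw()))
}

#' @export
plot.learnfit <- function(x, ...) {
  tr <- x$trajectory
  k <- seq_along(tr$u)
  if (x$model %in% c("hgf3", "hgf4")) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
    on.exit(graphics::par(op))
    graphics::plot(k, tr$u, pch = 3, col = "darkgreen", ylim = c(0, 1),
                   xlab = "trial", ylab = "p(input = 1)",
                   main = paste(toupper(x$model), "belief trajectory"))
    graphics::lines(k, plogis(tr$mu[, 2]), col = "red", lwd = 2)
    graphics::points(k, x$y, pch = 1, col = "purple")
    graphics::lines(k, tr$alpha2, col = "black", lty = 3)
    graphics::plot(k, tr$mu[, 3], type = "l", col = "blue", xlab = "trial",
                   ylab = expression(mu[3]))
  } else {
    graphics::plot(k, tr$u, pch = 3, col = "darkgreen", ylim = c(0, 1),
                   xlab = "trial", ylab = "value",
                   main = paste(toupper(x$model), "value trajectory"))
    graphics::lines(k, tr$v, col = "red", lwd = 2)
    graphics::points(k, x$y, pch = 1, col = "purple")
  }
  invisible(x)
}

# evaluate an expression under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
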
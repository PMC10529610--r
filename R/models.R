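#' Binary hierarchical Gaussian filter
#'
#' Runs the forward (filtering) pass of the binary hierarchical Gaussian
#' filter (HGF) over a sequence of binary inputs. The model represents the
#' environment as a hierarchy of coupled Gaussian random walks: level 1 is
#' the binary outcome, level 2 its logit-space tendency, level 3 the
#' log-volatility of level 2 and, for `levels = 4`, level 4 the
#' log-volatility of level 3. The step variance of level *j* is
#' `exp(kappa_j * mu_{j+1} + omega_j)`, and the top level performs a plain
#' random walk with variance `th`. Beliefs are updated trial by trial with
#' precision-weighted prediction errors.
#'
#' @param u integer vector of binary inputs (0/1).
#' @param levels number of levels, 3 or 4.
#' @param om2,om3 tonic log-volatility of levels 2 and 3 (`om3` is used
#'   only when `levels = 4`).
#' @param th variance of the top-level random walk (must be positive). For
#'   reporting symmetry this is also exposed as `omega_L = log(th)`.
#' @param kappa inter-level coupling strengths for levels 2..L-1 (recycled);
#'   the level-1 logit coupling is fixed at 1.
#' @param mu0,sa0 initial means and variances for levels 2..L (recycled).
#'
#' @return A `belief_trajectory` object: a list with per-trial vectors
#'   `muhat1` (first-level prediction, in (0,1)), `da1` (binary prediction
#'   error), matrices `mu`, `sa`, `muhat`, `da` (columns = levels), the
#'   per-trial learning rates `alpha2`, `alpha3` (and `alpha4`), and the
#'   prediction series `pred = muhat1` consumed by the response model.
#'
#' @details A trajectory on which any posterior precision becomes
#'   non-positive or non-finite is rejected with an error of class
#'   `hgf_divergence` carrying the offending trial index; the model
#'   inverter uses this signal to discard parameter proposals.
#'
#' @examples
#' u <- rbinom(40, 1, 0.7)
#' tr <- hgf_filter(u, levels = 3, om2 = -3, th = 0.5)
#' head(tr$muhat1)
#' @export
hgf_filter <- function(u, levels = 3, om2 = -3, om3 = -6, th = 0.5,
                       kappa = 1, mu0 = c(0, 1, 1), sa0 = c(0.1, 1, 1)) {
  u <- check_binary(u, "u")
  stopifnot(levels %in% c(3L, 4L))
  if (!is.finite(th) || th <= 0) stop("`th` must be a positive variance")
  L <- as.integer(levels)
  om <- numeric(L)                       # slot j-1 holds omega_j
  om[2] <- om2
  if (L == 4L) om[3] <- om3
  ka <- numeric(L)
  ka[1] <- 1
  ka[2:(L - 1)] <- rep_len(kappa, L - 2L)
  mu0 <- rep_len(mu0, L - 1L)
  sa0 <- rep_len(sa0, L - 1L)
  if (any(sa0 <= 0)) stop("initial variances `sa0` must be positive")

  res <- .hgf_filter_cpp(u, L, om, ka, th, mu0, sa0)
  if (res$error_trial > 0) {
    cond <- structure(
      class = c("hgf_divergence", "error", "condition"),
      list(message = sprintf(
             "HGF trajectory diverged (non-positive precision) at trial %d",
             res$error_trial),
           call = sys.call(-1), trial = res$error_trial))
    stop(cond)
  }
  traj <- list(
    model = if (L == 3L) "hgf3" else "hgf4",
    u = u, levels = L,
    muhat1 = res$muhat[, 2], da1 = res$da[, 2],
    mu = res$mu[, -1, drop = FALSE], sa = res$sa[, -1, drop = FALSE],
    muhat = res$muhat[, -1, drop = FALSE], da = res$da[, -1, drop = FALSE],
    pred = res$muhat[, 2],
    params = list(levels = L, om2 = om2, om3 = if (L == 4L) om3,
                  th = th, kappa = ka[2:(L - 1)], mu0 = mu0, sa0 = sa0))
  # per-trial learning rates: effective weight on the prediction error
  traj$alpha2 <- (plogis(res$mu[, 3]) - res$muhat[, 2]) / res$da[, 2]
  traj$alpha3 <- (res$mu[, 4] - res$muhat[, 4]) / res$da[, 3]
  if (L == 4L) traj$alpha4 <- (res$mu[, 5] - res$muhat[, 5]) / res$da[, 4]
  class(traj) <- "belief_trajectory"
  traj
}

#' Rescorla-Wagner filter
#'
#' Delta-rule value updating `v_k = v_{k-1} + alpha * (u_k - v_{k-1})` with
#' a fixed learning rate. With binary inputs and `v0` in \[0, 1\] the value
#' stays in \[0, 1\] (a convex combination of `v0` and the inputs).
#'
#' @param u binary input vector (0/1).
#' @param alpha learning rate in \[0, 1\].
#' @param v0 initial value in \[0, 1\].
#' @return A `belief_trajectory` with `v`, `pred` (= value before seeing
#'   `u_k`), prediction errors `da1` and the constant `alpha` series.
#' @export
rw_filter <- function(u, alpha, v0 = 0.5) {
  u <- check_binary(u, "u")
  stopifnot(alpha >= 0, alpha <= 1, v0 >= 0, v0 <= 1)
  res <- .rw_filter_cpp(u, alpha, v0)
  structure(list(model = "rw", u = u, v = res$v, pred = res$v_prev,
                 da1 = res$da, alpha = rep(alpha, length(u)),
                 params = list(alpha = alpha, v0 = v0)),
            class = "belief_trajectory")
}

#' Sutton K1 filter
#'
#' Gain-adaptation variant of the delta rule: the log learning rate is
#' itself adjusted by the correlation between the current prediction error
#' and a decaying trace of recent updates, so that runs of same-sign errors
#' accelerate learning. With `mu_meta = 0` the filter is exactly
#' Rescorla-Wagner with `alpha = alpha0`.
#'
#' @param u binary input vector (0/1).
#' @param alpha0 initial learning rate in (0, 1\].
#' @param mu_meta meta-learning rate (>= 0) scaling the gain adaptation.
#' @param v0 initial value in \[0, 1\].
#' @return A `belief_trajectory` with `v`, `pred`, `da1` and the per-trial
#'   learning-rate series `alpha` (each element in (0, 1\]).
#' @export
k1_filter <- function(u, alpha0, mu_meta = 0.1, v0 = 0.5) {
  u <- check_binary(u, "u")
  stopifnot(alpha0 > 0, alpha0 <= 1, mu_meta >= 0, v0 >= 0, v0 <= 1)
  res <- .k1_filter_cpp(u, alpha0, mu_meta, v0)
  structure(list(model = "k1", u = u, v = res$v, pred = res$v_prev,
                 da1 = res$da, alpha = res$alpha,
                 params = list(alpha0 = alpha0, mu_meta = mu_meta, v0 = v0)),
            class = "belief_trajectory")
}

#' Per-trial learning rates and subject summaries
#'
#' Extracts the effective learning rates of a fitted or simulated belief
#' trajectory: the fraction of the level-*i* prediction error that was
#' incorporated into the level-*i* belief on each trial. For the HGF,
#' `alpha2` is measured in first-level prediction space
#' (`(s(mu2_k) - muhat1_k) / da1_k`), `alpha3` (and `alpha4`) as the
#' belief update divided by the volatility prediction error from below.
#' Trials with near-zero prediction error are dropped from summaries.
#'
#' @param traj a `belief_trajectory`.
#' @param eps prediction errors with absolute value below `eps` are
#'   treated as uninformative and skipped in the summary means.
#' @return A list with the per-trial series (`alpha2`, ...) and their
#'   trial means (`mean_alpha2`, ...). Associative trajectories report a
#'   single `alpha` series.
#' @export
compute_learning_rates <- function(traj, eps = 1e-8) {
  stopifnot(inherits(traj, "belief_trajectory"))
  msk <- function(a, d) mean(a[abs(d) > eps], na.rm = TRUE)
  if (traj$model %in% c("hgf3", "hgf4")) {
    out <- list(alpha2 = traj$alpha2, alpha3 = traj$alpha3,
                mean_alpha2 = msk(traj$alpha2, traj$da1),
                mean_alpha3 = msk(traj$alpha3, traj$da[, 2]))
    if (traj$model == "hgf4") {
      out$alpha4 <- traj$alpha4
      out$mean_alpha4 <- msk(traj$alpha4, traj$da[, 3])
    }
    out
  } else {
    list(alpha = traj$alpha, mean_alpha = mean(traj$alpha))
  }
}

#' Unit-square sigmoid response probability
#'
#' Maps a belief `m` in (0, 1) to a response probability through the
#' unit-square sigmoid `m^zeta / (m^zeta + (1 - m)^zeta)`. `zeta` is the
#' inverse decision temperature: `zeta = 1` is probability matching
#' (`p = m`), large `zeta` approaches a deterministic step at 0.5.
#'
#' @param m belief (vectorised), strictly inside (0, 1).
#' @param zeta inverse decision temperature, finite and positive.
#' @return Response probabilities in (0, 1).
#' @examples
#' response_probability(0.7, 1)   # 0.7
#' response_probability(0.7, 48)  # ~1
#' @export
response_probability <- function(m, zeta) {
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) ||
      zeta <= 0) stop("`zeta` must be a single positive finite number")
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= 1))
    stop("beliefs `m` must lie strictly inside (0, 1)")
  # compute in log space for numerical stability at large zeta
  lo <- zeta * (log(m) - log1p(-m))
  plogis(lo)
}

#' Bernoulli response log-likelihood
#'
#' Total log-likelihood of a binary response series under the unit-square
#' sigmoid response model. The response on trial k is driven by the belief
#' held *before* observing trial k's input, i.e. the trajectory's
#' one-step-ahead prediction series.
#'
#' @param traj a `belief_trajectory` (its `pred` series is used), or a
#'   numeric vector of per-trial predictions in (0, 1).
#' @param y binary response vector, same length as the predictions; `NA`
#'   entries are treated as masked trials and skipped.
#' @param zeta inverse decision temperature.
#' @param clamp probabilities are clamped to `[clamp, 1 - clamp]` so the
#'   log-likelihood stays finite in deterministic limits; clamped trials
#'   are reported via the `"clamped"` attribute.
#' @return The summed log-likelihood (scalar) with attribute `"clamped"`.
#' @export
response_loglik <- function(traj, y, zeta, clamp = 1e-12) {
  pred <- if (inherits(traj, "belief_trajectory")) traj$pred else traj
  if (length(pred) != length(y))
    stop("prediction and response series have different lengths")
  ok <- !is.na(y)
  y <- y[ok]
  pred <- pmin(pmax(pred[ok], clamp), 1 - clamp)
  p <- response_probability(pred, zeta)
  ncl <- sum(p < clamp | p > 1 - clamp)
  p <- pmin(pmax(p, clamp), 1 - clamp)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  attr(ll, "clamped") <- ncl
  ll
}

# validate a binary series
check_binary <- function(u, name) {
  if (anyNA(u)) stop(sprintf("`%s` contains NA", name))
  if (!all(u %in% c(0, 1)))
    stop(sprintf("`%s` must be a binary (0/1) series", name))
  as.integer(u)
}
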
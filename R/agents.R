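# Forward simulation of learning agents on experiment designs.

#' Simulate a learning agent on an experiment design
#'
#' Derives the binary input series from the design (veridical coding),
#' runs the requested perceptual model forward, and samples each response
#' `y_k` as a Bernoulli draw with probability given by the unit-square
#' sigmoid applied to the belief held before trial k (the one-step-ahead
#' prediction), with inverse decision temperature `zeta`.
#'
#' @param design a `swi_design`, `interception_design`, or a bare binary
#'   input vector.
#' @param model `"hgf3"`, `"hgf4"`, `"rw"` or `"k1"`.
#' @param params named list of perceptual parameters for the model (see
#'   [hgf_filter()], [rw_filter()], [k1_filter()]).
#' @param zeta inverse decision temperature of the response model.
#' @param seed integer seed; the record is exactly regenerable from it.
#' @param subject,group optional identifiers stored on the record.
#' @return An `agent_record`: list with `u`, `y`, the trajectory, the
#'   generating model name and parameters, and the seed.
#' @examples
#' d <- gen_interception_design("volatile", seed = 3)
#' ag <- simulate_agent(d, "hgf3", list(om2 = -2.5, th = 0.5), zeta = 4,
#'                      seed = 11)
#' mean(ag$y)
#' @export
simulate_agent <- function(design, model = c("hgf3", "hgf4", "rw", "k1"),
                           params, zeta = 4, seed = 1L,
                           subject = NA_character_, group = NA_character_) {
  model <- match.arg(model)
  u <- if (is.numeric(design) || is.integer(design))
    check_binary(design, "design") else design_inputs(design)
  mi <- model_info(model)
  base <- switch(model,
                 hgf3 = list(om2 = -3, th = 0.5),
                 hgf4 = list(om2 = -3, om3 = -6, th = 0.5),
                 rw = list(alpha = 0.3, v0 = 0.5),
                 k1 = list(alpha0 = 0.3, mu_meta = 0.1, v0 = 0.5))
  nat <- c(utils::modifyList(base, as.list(params)), list(zeta = zeta))
  traj <- tryCatch(mi$run(u, nat), error = function(e) {
    if (inherits(e, "hgf_divergence"))
      stop(sprintf("simulation diverged at trial %d for the given parameters",
                   e$trial), call. = FALSE)
    stop(e)
  })
  p <- response_probability(pmin(pmax(traj$pred, 1e-12), 1 - 1e-12), zeta)
  y <- with_seed(seed, stats::rbinom(length(u), 1, p))
  structure(list(subject = subject, group = group, model = model,
                 params = params, zeta = zeta, u = u, y = y,
                 p_response = p, trajectory = traj, seed = seed,
                 design = if (is.numeric(design)) NULL else design),
            class = "agent_record")
}

#' @export
print.agent_record <- function(x, ...) {
  cat(sprintf("Simulated %s agent (%d trials, mean y = %.2f, seed %d)\n",
              toupper(x$model), length(x$u), mean(x$y), x$seed))
  invisible(x)
}

#' Simulate a cohort of agents
#'
#' Draws each subject's generating parameters by calling `param_fn`
#' (seeded per subject), simulates the agent on its design, and returns
#' the records plus a long trial table.
#'
#' @param n_subjects number of agents.
#' @param design_fn function(subject index, seed) returning a design (or
#'   a single design object reused for everyone).
#' @param model generating model name.
#' @param param_fn function() returning a named list of perceptual
#'   parameters; called under a per-subject seed.
#' @param zeta_fn function() returning the decision temperature.
#' @param seed master integer seed.
#' @param group group label stored on every record.
#' @return A list with `agents` (list of `agent_record`) and `trials`
#'   (data.frame: subject, group, trial, u, y).
#' @export
simulate_cohort <- function(n_subjects, design_fn, model, param_fn,
                            zeta_fn = function() 4, seed = 1L,
                            group = "synthetic") {
  agents <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s_i <- seed * 10000L + i
    des <- if (is.function(design_fn)) design_fn(i, s_i) else design_fn
    par <- with_seed(s_i + 5000L, list(params = param_fn(),
                                       zeta = zeta_fn()))
    agents[[i]] <- simulate_agent(des, model, par$params, par$zeta,
                                  seed = s_i, subject = sprintf("S%03d", i),
                                  group = group)
  }
  trials <- do.call(rbind, lapply(agents, function(a)
    data.frame(subject = a$subject, group = a$group,
               trial = seq_along(a$u), u = a$u, y = a$y,
               stringsAsFactors = FALSE)))
  list(agents = agents, trials = trials)
}
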
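# End-to-end orchestration: simulate (or import) -> code series -> fit
# all models -> random-effects selection -> extract winning-model
# parameters -> group statistics.

#' Run the full modelling pipeline on a synthetic cohort
#'
#' Executes the stages in their canonical order: determine (or accept)
#' priors, simulate every subject in every condition from its group's
#' generating parameters, fit all candidate models by MAP, compare them
#' by random-effects Bayesian model selection, extract the parameters of
#' interest from the winning model's fits, and run the group-comparison
#' battery. Every stage draws its randomness from seeds derived from
#' `config$seed`, so a rerun with the same config reproduces all numbers
#' exactly.
#'
#' @param config a list (or YAML file path, read with the `yaml` package)
#'   with entries:
#'   \describe{
#'     \item{experiment}{`"swi"` or `"interception"`.}
#'     \item{groups}{named list; each group is a list with `n` (subjects),
#'       `model` (generating model), `zeta`, and `params` — either one
#'       named list of perceptual parameters, or (interception) one per
#'       condition, e.g. `list(stable = ..., volatile = ...)`.}
#'     \item{models}{candidate models to fit (default all four).}
#'     \item{n_restarts}{optimisation restarts per fit (default 5).}
#'     \item{stats_params}{parameter names to compare between groups
#'       (default: the winning model's native parameters plus mean
#'       learning rates).}
#'     \item{seed}{master integer seed.}
#'     \item{out_dir}{optional directory; stage outputs and a JSON
#'       manifest are written there as delimited text.}
#'   }
#' @return A `pipeline_result`: `trials`, `lme` (subjects x models,
#'   summed over conditions), `bms`, `winning_model`, `params`
#'   (long data.frame of extracted parameters), `stats` (group
#'   comparison table) and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(experiment = "interception", models = learner_models(),
         n_restarts = 5, seed = 1L, stats_params = NULL, out_dir = NULL),
    config)
  if (is.null(cfg$groups)) stop("config$groups is required")
  stopifnot(cfg$experiment %in% c("swi", "interception"),
            all(cfg$models %in% learner_models()))
  conditions <- if (cfg$experiment == "swi") "swi" else
    c("stable", "volatile")

  # ---- simulate ------------------------------------------------------
  agents <- list()
  sid <- 0L
  for (gname in names(cfg$groups)) {
    g <- cfg$groups[[gname]]
    for (i in seq_len(g$n)) {
      sid <- sid + 1L
      subject <- sprintf("S%03d", sid)
      for (cond in conditions) {
        s_i <- cfg$seed * 100000L + sid * 10L + match(cond, conditions)
        des <- if (cfg$experiment == "swi")
          gen_swi_design(order_id = ((sid - 1L) %% 3L) + 1L, seed = s_i)
        else gen_interception_design(cond, seed = s_i)
        par <- if (!is.null(g$params[[cond]]) && is.list(g$params[[cond]]))
          g$params[[cond]] else g$params
        agents[[paste(subject, cond)]] <-
          simulate_agent(des, g$model, par,
                         zeta = if (is.null(g$zeta)) 4 else g$zeta,
                         seed = s_i, subject = subject, group = gname)
      }
    }
  }
  trials <- do.call(rbind, lapply(names(agents), function(k) {
    a <- agents[[k]]
    data.frame(subject = a$subject, group = a$group,
               condition = sub("^\\S+ ", "", k),
               trial = seq_along(a$u), u = a$u, y = a$y,
               stringsAsFactors = FALSE)
  }))

  # ---- fit all candidate models --------------------------------------
  subjects <- unique(trials$subject)
  fits <- list()
  lme <- matrix(0, length(subjects), length(cfg$models),
                dimnames = list(subjects, cfg$models))
  for (k in names(agents)) {
    a <- agents[[k]]
    cond <- sub("^\\S+ ", "", k)
    for (m in cfg$models) {
      f <- fit_learner(a$u, a$y, m, n_restarts = cfg$n_restarts,
                       seed = cfg$seed * 1000L +
                         match(k, names(agents)) * 10L +
                         match(m, cfg$models),
                       subject = a$subject, condition = cond)
      if (isTRUE(f$failed))
        stop("fit failed for ", a$subject, " / ", m, " (", cond, ")")
      fits[[paste(k, m)]] <- f
      lme[a$subject, m] <- lme[a$subject, m] + f$lme
    }
  }

  # ---- model selection ------------------------------------------------
  bms <- if (length(cfg$models) >= 2)
    rfx_bms(lme, seed = cfg$seed) else NULL
  winning <- if (is.null(bms)) cfg$models else names(which.max(bms$pxp))

  # ---- extract winning-model parameters -------------------------------
  params <- do.call(rbind, lapply(names(agents), function(k) {
    f <- fits[[paste(k, winning)]]
    lr <- compute_learning_rates(f$trajectory)
    vals <- c(unlist(f$par),
              unlist(lr[grep("^mean_", names(lr))]))
    names(vals) <- sub("^mean_", "", names(vals))
    data.frame(subject = f$subject, group = agents[[k]]$group,
               condition = f$condition, parameter = names(vals),
               value = as.numeric(vals), stringsAsFactors = FALSE)
  }))

  # ---- group statistics ----------------------------------------------
  stats_params <- if (is.null(cfg$stats_params))
    unique(params$parameter) else cfg$stats_params
  stats_tab <- do.call(rbind, lapply(stats_params, function(pn) {
    pd <- params[params$parameter == pn, ]
    if (length(conditions) == 2) {
      res <- mixed_anova_2x2(pd$value, pd$group, pd$condition, pd$subject)
      res$parameter <- pn
      res
    } else {
      res <- two_sample_tests(pd$value, pd$group)
      res$parameter <- pn
      res
    }
  }))

  manifest <- list(config = cfg, n_subjects = length(subjects),
                   conditions = conditions,
                   winning_model = winning,
                   pxp = if (!is.null(bms)) as.list(bms$pxp),
                   exclusions = list(),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- structure(list(trials = trials, fits = fits, lme = lme, bms = bms,
                        winning_model = winning, params = params,
                        stats = stats_tab, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$manifest$n_subjects, "subjects,",
      ncol(x$lme), "models\n")
  cat("winning model by PXP:", x$winning_model, "\n")
  if (!is.null(x$bms)) print(round(x$bms$pxp, 4))
  invisible(x)
}

write_pipeline_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$trials, file.path(dir, "trials.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cbind(subject = rownames(res$lme), as.data.frame(res$lme)),
                     file.path(dir, "lme_matrix.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$params, file.path(dir, "parameters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(res$stats, file.path(dir, "group_stats.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- res$manifest
  if (!is.null(res$bms))
    manifest$bms <- list(r = as.list(res$bms$r), ep = as.list(res$bms$ep),
                         bor = res$bms$bor, pxp = as.list(res$bms$pxp))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Import a coded trial table
#'
#' Reads a delimited trial table (one row per trial) and validates it
#' against the column schema used throughout the pipeline: `subject`,
#' `group`, `condition`, `trial`, `u`, `y`. Unknown columns are
#' preserved. Subjects missing (NA) more than 15% of their responses are
#' flagged as excluded, mirroring the participant-level exclusion rule;
#' nothing is silently dropped.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param max_missing per-subject missing-response tolerance.
#' @return A list: `trials` (data.frame), `completeness` (per subject),
#'   `excluded` (subject ids over the threshold).
#' @export
import_trial_table <- function(path, dialect = c("tsv", "csv"),
                               max_missing = 0.15) {
  dialect <- match.arg(dialect)
  tab <- utils::read.table(path, header = TRUE,
                           sep = if (dialect == "tsv") "\t" else ",",
                           stringsAsFactors = FALSE)
  required <- c("subject", "group", "condition", "trial", "u", "y")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  miss <- tapply(is.na(tab$y), tab$subject, mean)
  list(trials = tab, completeness = 1 - miss,
       excluded = names(miss)[miss > max_missing])
}
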
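# Experiment designs: size-weight-illusion (SWI) lifting sequences and
# stable/volatile bounce-interception schedules.

swi_catalogue <- function() {
  data.frame(
    object = c("small_light", "small_heavy", "large_light", "large_heavy",
               "medium_control"),
    size_class = c("small", "small", "large", "large", "medium"),
    size_cm = c(5, 5, 10, 10, 7.5),
    mass_class = c("light", "heavy", "light", "heavy", "heavy"),
    mass_g = c(355, 490, 355, 490, 490),
    stringsAsFactors = FALSE)
}

# constrained shuffle: 8 lifts of each of the 4 test objects, both heavy
# objects seen before any light object
swi_test_order <- function() {
  cat4 <- swi_catalogue()[1:4, ]
  repeat {
    ord <- sample(rep(cat4$object, each = 8))
    first_light <- match(TRUE, cat4$mass_class[match(ord, cat4$object)] ==
                           "light")
    heavies <- c("small_heavy", "large_heavy")
    if (all(match(heavies, ord) < first_light)) return(ord)
  }
}

#' Generate a size-weight-illusion lifting design
#'
#' Five baseline lifts of the medium control object followed by 32 test
#' lifts of the four test objects (two diameters x two masses, eight lifts
#' each) in a pseudorandomised order constrained so that each heavy object
#' is lifted at least once before any light object. Three fixed orders are
#' shipped (regenerated deterministically from internal seeds);
#' `order_id = "random"` derives a fresh constrained order from `seed`.
#'
#' @param order_id 1, 2, 3 or `"random"`.
#' @param seed integer seed (used only for `order_id = "random"`, but the
#'   call is deterministic given `(order_id, seed)` in all cases).
#' @return A `swi_design`: list with `trials` (data.frame: trial, phase,
#'   object, size_class, size_cm, mass_class, mass_g), `order_id`, `seed`.
#' @examples
#' d <- gen_swi_design(order_id = 1, seed = 7)
#' table(subset(d$trials, phase == "test")$object)
#' @export
gen_swi_design <- function(order_id = 1, seed = 1L) {
  ok <- (is.numeric(order_id) && order_id %in% 1:3) ||
    identical(order_id, "random")
  if (!ok) stop("`order_id` must be 1, 2, 3 or \"random\"")
  cat <- swi_catalogue()
  ord <- if (identical(order_id, "random")) with_seed(seed, swi_test_order())
  else with_seed(190100 + as.integer(order_id), swi_test_order())
  objs <- c(rep("medium_control", 5), ord)
  idx <- match(objs, cat$object)
  trials <- data.frame(
    trial = seq_along(objs),
    phase = rep(c("baseline", "test"), c(5, 32)),
    object = objs,
    size_class = cat$size_class[idx], size_cm = cat$size_cm[idx],
    mass_class = cat$mass_class[idx], mass_g = cat$mass_g[idx],
    stringsAsFactors = FALSE)
  structure(list(trials = trials, order_id = order_id, seed = seed,
                 n_baseline = 5L, n_test = 32L),
            class = "swi_design")
}

#' Generate a bounce-interception trial schedule
#'
#' Forty-five trials per condition with exactly 30 expected (elasticity
#' 0.65, the "normal" ball) and 15 unexpected (0.85, "bouncy") trials. In
#' the stable condition the marginal probability of a normal ball is fixed
#' at 30/45 and there is no block structure. In the volatile condition the
#' schedule is partitioned into blocks of length 6, 9 or 12 whose
#' probability of a normal ball switches irregularly between 0.83, 0.67
#' and 0.50 (consecutive blocks always differ), with per-block outcome
#' counts adjusted so the 30/15 totals are met exactly.
#'
#' @param condition `"stable"` or `"volatile"`.
#' @param seed integer seed; the schedule is deterministic given
#'   `(condition, seed)`.
#' @return An `interception_design`: list with `trials` (data.frame:
#'   trial, elasticity, expected, block, p_normal) and, for volatile
#'   schedules, `blocks` (length and nominal p_normal per block).
#' @export
gen_interception_design <- function(condition = c("stable", "volatile"),
                                    seed = 1L) {
  condition <- match.arg(condition)
  n_total <- 45L; n_normal <- 30L
  out <- with_seed(seed, {
    if (condition == "stable") {
      expected <- sample(rep(c(TRUE, FALSE), c(n_normal, n_total - n_normal)))
      list(trials = data.frame(
        trial = 1:n_total,
        elasticity = ifelse(expected, 0.65, 0.85),
        expected = expected, block = 1L, p_normal = n_normal / n_total),
        blocks = NULL)
    } else {
      repeat {
        lens <- integer(0)
        while (sum(lens) < n_total)
          lens <- c(lens, sample(c(6L, 9L, 12L), 1))
        if (sum(lens) == n_total) break
      }
      nb <- length(lens)
      resample <- function(x) x[sample.int(length(x), 1)]
      ps <- numeric(nb)
      pool <- c(0.83, 0.67, 0.50)
      ps[1] <- resample(pool)
      for (b in seq_len(nb)[-1]) ps[b] <- resample(setdiff(pool, ps[b - 1]))
      # per-block normal-ball counts: nominal p, then adjust to total 30
      cnt <- round(ps * lens)
      while (sum(cnt) != n_normal) {
        if (sum(cnt) < n_normal) {
          b <- resample(which(cnt < lens))
          cnt[b] <- cnt[b] + 1L
        } else {
          b <- resample(which(cnt > 0L))
          cnt[b] <- cnt[b] - 1L
        }
      }
      expected <- unlist(lapply(seq_len(nb), function(b)
        sample(rep(c(TRUE, FALSE), c(cnt[b], lens[b] - cnt[b])))))
      list(trials = data.frame(
        trial = 1:n_total,
        elasticity = ifelse(expected, 0.65, 0.85),
        expected = expected,
        block = rep(seq_len(nb), lens),
        p_normal = rep(ps, lens)),
        blocks = data.frame(block = seq_len(nb), length = lens,
                            p_normal = ps))
    }
  })
  structure(c(out, list(condition = condition, seed = seed)),
            class = "interception_design")
}

#' Binary input series implied by a design
#'
#' Codes a design's trials into the binary environmental input `u`
#' consumed by the learning models. SWI designs use veridical
#' size-predicts-weight coding over the test trials (see
#' [code_swi_inputs()] for the felt-input variant); interception designs
#' code `u = 1` for an expected ("normal") ball.
#'
#' @param design a `swi_design` or `interception_design`.
#' @param ... passed on to [code_swi_inputs()] for SWI designs.
#' @return Integer 0/1 vector over the design's test trials.
#' @export
design_inputs <- function(design, ...) {
  if (inherits(design, "swi_design")) return(code_swi_inputs(design, ...))
  if (inherits(design, "interception_design"))
    return(as.integer(design$trials$expected))
  stop("unsupported design object")
}

#' @export
print.swi_design <- function(x, ...) {
  cat(sprintf("SWI lifting design (order %s): %d baseline + %d test trials\n",
              as.character(x$order_id), x$n_baseline, x$n_test))
  print(table(x$trials$object[x$trials$phase == "test"]))
  invisible(x)
}

#' @export
print.interception_design <- function(x, ...) {
  cat(sprintf("Interception design, %s condition: %d trials (%d expected / %d unexpected)\n",
              x$condition, nrow(x$trials), sum(x$trials$expected),
              sum(!x$trials$expected)))
  if (!is.null(x$blocks)) {
    cat("block structure:\n")
    print(x$blocks, row.names = FALSE)
  }
  invisible(x)
}
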
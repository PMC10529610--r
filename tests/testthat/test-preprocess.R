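test_that("five-point stencil differentiates quartics exactly", {
  h <- 0.01
  x <- seq(0, 1, by = h)
  f <- 2 - x + 3 * x^2 - 2 * x^3 + 0.5 * x^4
  fp <- -1 + 6 * x - 6 * x^2 + 2 * x^3
  d <- central_diff5(f, h)
  i <- 3:(length(x) - 2)
  expect_equal(d[i], fp[i], tolerance = 1e-10)
  expect_true(all(is.na(d[c(1, 2, length(x) - 1, length(x))])))
  expect_error(central_diff5(1:4), "5 samples")
})

test_that("pGFR is zero for constant force and exact for a cubic rise", {
  expect_equal(extract_pgfr(rep(2.5, 200), fs = 500, smooth = FALSE), 0)
  # cubic segment: f(t) = 30 t^2 - 20 t^3 on [0, 1]; f'(t) max at t = 0.5
  t <- seq(0, 1, by = 1 / 500)
  f <- 30 * t^2 - 20 * t^3
  expect_equal(extract_pgfr(f, fs = 500, smooth = FALSE),
               max(60 * t - 60 * t^2), tolerance = 1e-8)
})

test_that("the 14 Hz zero-phase filter suppresses 50 Hz noise", {
  tr <- synth_force_trace(belief = 0.8, noise_sd = 0, seed = 1)
  clean <- extract_pgfr(tr)
  noisy <- tr
  noisy$force <- tr$force + 0.05 * sin(2 * pi * 50 * tr$t)
  expect_lt(abs(extract_pgfr(noisy) - clean) / clean, 0.05)
  # and the filtered estimate is close to the analytic peak rate
  expect_lt(abs(clean - tr$peak_rate_true) / tr$peak_rate_true, 0.05)
})

test_that("zero-phase filtering leaves a symmetric pulse peak in place", {
  t <- seq(0, 1, by = 1 / 500)
  pulse <- exp(-((t - 0.5) / 0.08)^2)
  bf <- signal::butter(2, 14 / 250, "low")
  sm <- as.numeric(signal::filtfilt(bf, pulse))
  expect_equal(which.max(sm), which.max(pulse), tolerance = 1)
})

test_that("synthetic force traces are monotone in belief and seeded", {
  lo <- synth_force_trace(0, noise_sd = 0)
  hi <- synth_force_trace(1, noise_sd = 0)
  expect_gt(hi$peak_rate_true, lo$peak_rate_true)
  expect_gt(extract_pgfr(hi, smooth = FALSE), extract_pgfr(lo, smooth = FALSE))
  a <- synth_force_trace(0.5, noise_sd = 0.3, seed = 4)
  b <- synth_force_trace(0.5, noise_sd = 0.3, seed = 4)
  expect_identical(a$force, b$force)
})

test_that("baseline correction is plain subtraction", {
  expect_equal(baseline_correct(3.0, 3.0), 0.0)
  expect_equal(baseline_correct(5.5, 3.0), 2.5)
  expect_equal(baseline_correct(2.0, 3.0), -1.0)
})

test_that("rating z-scores standardise within subject, affine-invariantly", {
  z <- zscore_ratings(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  r <- c(3, 9, 1, 7, 5)
  expect_equal(zscore_ratings(r), zscore_ratings(10 + 4 * r),
               tolerance = 1e-12)
  expect_equal(zscore_ratings(c(10, 20)), c(-1, 1) / sqrt(2))
  expect_error(zscore_ratings(c(2, 2, 2)), "zero rating variance")
  z2 <- zscore_ratings(c(1, 2, 3, 10, 20, 30), subject = rep(1:2, each = 3))
  expect_equal(z2[1:3], z2[4:6], tolerance = 1e-12)
})

test_that("veridical SWI coding follows size-predicts-weight congruence", {
  d <- gen_swi_design(1, seed = 1)
  tt <- d$trials[d$trials$phase == "test", ]
  u <- code_swi_inputs(d, "veridical")
  expect_equal(u[tt$object == "large_heavy"], rep(1L, 8))
  expect_equal(u[tt$object == "small_light"], rep(1L, 8))
  expect_equal(u[tt$object == "large_light"], rep(0L, 8))
  expect_equal(u[tt$object == "small_heavy"], rep(0L, 8))
  # flipping every size label flips u
  flipped <- d
  flipped$trials$size_class <- c(small = "large", large = "small",
                                 medium = "medium")[d$trials$size_class]
  expect_equal(code_swi_inputs(flipped, "veridical"), 1L - u)
})

test_that("felt coding agrees with veridical when ratings mirror mass", {
  d <- gen_swi_design(3, seed = 2)
  tt <- d$trials[d$trials$phase == "test", ]
  ratings <- ifelse(tt$mass_class == "heavy", 8, 3) +
    with_seed(1, runif(32, -0.5, 0.5))
  expect_equal(code_swi_inputs(d, "felt", ratings),
               code_swi_inputs(d, "veridical"))
  expect_error(code_swi_inputs(d, "felt"), "ratings")
  ratings[5] <- NA
  expect_true(is.na(code_swi_inputs(d, "felt", ratings)[5]))
})

test_that("grip median split matches brute-force rule application", {
  sizes <- c("large", "large", "small", "small", "large", "small",
             "large", "small")
  pg <- c(2.0, 1.5, -1.0, 0.5, 0.9, -0.2, 1.8, 1.1)
  y <- discretize_grip_responses(pg, sizes)
  med <- median(pg)
  brute <- ifelse(sizes == "large", pg > med, pg <= med)
  expect_equal(y, as.integer(brute))
  # all large above / all small below -> all 1; sign flip -> all 0
  expect_equal(discretize_grip_responses(c(2, 3, -2, -3),
                                         c("large", "large", "small", "small")),
               rep(1L, 4))
  expect_equal(discretize_grip_responses(c(-2, -3, 2, 3),
                                         c("large", "large", "small", "small")),
               rep(0L, 4))
  # ties go to the low class
  expect_equal(discretize_grip_responses(c(1, 1, 1, 2),
                                         c("large", "small", "large", "large")),
               c(0L, 1L, 0L, 1L))
})

test_that("dispersion detector finds stationary windows per thresholds", {
  fs <- 120
  sweep_in <- seq(40, 25, by = -5)            # fast pursuit, > 3 deg/sample
  sweep_out <- seq(-5, -35, by = -5)
  # 200 ms stationary between fast sweeps -> exactly one fixation
  pitch <- c(sweep_in, rep(10, 24), sweep_out)
  fx <- detect_fixations(pitch, fs = fs, smooth = FALSE)
  expect_equal(nrow(fx$fixations), 1)
  expect_equal(fx$fixations$pitch, 10, tolerance = 0.5)
  expect_gte(fx$fixations$duration, 0.1)
  # 90 ms stationary -> none
  pitch2 <- c(sweep_in, rep(10, 11), sweep_out)
  fx2 <- detect_fixations(pitch2, fs = fs, smooth = FALSE)
  expect_equal(nrow(fx2$fixations), 0)
  # two separated clusters -> two fixations with correct centroids
  pitch3 <- c(rep(20, 30), seq(20, -5, by = -5), rep(-5, 30))
  fx3 <- detect_fixations(pitch3, fs = fs, smooth = FALSE)
  expect_equal(nrow(fx3$fixations), 2)
  expect_equal(fx3$fixations$pitch, c(20, -5), tolerance = 0.1)
})

test_that("gaze traces carry their target pitch and missing mask", {
  tr <- synth_gaze_trace(12, noise_sd = 0, missing_frac = 0, seed = 1)
  fx <- detect_fixations(tr)
  expect_equal(fx$bounce_pitch, 12, tolerance = 0.1)
  expect_true(fx$valid)
  # additivity: shifting the target shifts the detected fixation equally
  tr2 <- synth_gaze_trace(14, noise_sd = 0, missing_frac = 0, seed = 1)
  fx2 <- detect_fixations(tr2)
  expect_equal(fx2$bounce_pitch - fx$bounce_pitch, 2, tolerance = 0.05)
  # requested missingness is honoured
  tr3 <- synth_gaze_trace(12, missing_frac = 0.3, seed = 2)
  expect_lt(abs(tr3$missing_frac - 0.3), 0.02)
  fx3 <- detect_fixations(tr3)
  expect_false(fx3$valid)   # 30% > 20% missing rule
})

test_that("outlier screen applies the 3.29 SD and 15% rules", {
  vals <- with_seed(3, rnorm(200))
  vals[7] <- mean(vals[-7]) + 6 * sd(vals[-7])
  sc <- screen_outliers(vals)
  expect_true(sc$outlier[7])
  tame <- seq(-1, 1, length.out = 50)
  expect_false(any(screen_outliers(tame)$outlier))
  # subject with 20% missing trials is excluded
  subj <- rep(c("a", "b"), each = 20)
  v <- with_seed(4, rnorm(40))
  v[1:4] <- NA
  sc2 <- screen_outliers(v, subj)
  expect_equal(sc2$excluded, "a")
  # idempotence: re-screening the same table changes nothing
  expect_identical(sc2, screen_outliers(v, subj))
})

test_that("gaze discretisation uses the 1 SD change rule with carry-over", {
  pitch <- c(10, 10.1, 9.9, 15, 15.1, 9, 9.1)
  y <- discretize_gaze_responses(pitch)
  s <- sd(diff(pitch))
  expect_equal(y[1], 1L)
  expect_equal(y[4], 1L)          # +5.1 deg >> 1 SD upward
  expect_equal(y[6], 0L)          # -6.1 deg << -1 SD downward
  expect_equal(y[2], y[1])        # small change carries previous y
  expect_equal(y[5], y[4])
  expect_error(discretize_gaze_responses(c(1, NA)), "valid trials")
})
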
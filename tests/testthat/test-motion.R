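test_that("MSD closed forms: constant, ballistic, and gapped traces", {
  t <- seq(0, 100, by = 2)
  # constant position: MSD identically zero
  m0 <- compute_msd(t, rep(5, length(t)), max_lag = 10)
  expect_true(all(m0$msd == 0))

  # ballistic ramp z = v t: MSD(tau) = v^2 tau^2 exactly
  v <- 3
  mb <- compute_msd(t, v * t, max_lag = 10)
  expect_equal(mb$msd, v^2 * mb$lag^2, tolerance = 1e-10)

  # gaps: pairs spanning a gap use the true time difference
  tg <- c(0, 2, 4, 6, 12, 14, 16, 18, 20, 22, 24, 26, 28, 30)
  mg <- compute_msd(tg, v * tg, max_lag = 6)
  expect_equal(mg$msd, v^2 * mg$lag^2, tolerance = 1e-10)
  # lag 2 pairs: only those truly 2 s apart (the 6->12 jump contributes to
  # lag 6, not lag 2)
  expect_equal(mg$n_pairs[mg$lag == 2], sum(diff(tg) == 2))

  expect_error(compute_msd(t, rep(1, length(t)), max_lag = 60), "shorter")
})

test_that("diffusion coefficient is slope/2 with a free intercept", {
  msd <- data.frame(lag = 1:10, msd = 2 * 1e4 * (1:10))
  expect_equal(estimate_diffusion(msd)$D, 1e4, tolerance = 1e-9)

  # additive offset (static localisation error) changes the intercept only
  msd2 <- data.frame(lag = 1:10, msd = 2 * 1e4 * (1:10) + 500)
  est <- estimate_diffusion(msd2)
  expect_equal(est$D, 1e4, tolerance = 1e-9)
  expect_equal(est$intercept, 500, tolerance = 1e-6)

  expect_error(estimate_diffusion(msd[1:5, ]), "need >= 10")
})

test_that("windowed D estimator is unbiased on free walks", {
  for (D_true in c(1e3, 1e4, 3.5e4)) {
    Ds <- unlist(lapply(1:8, function(i) {
      z <- simulate_bounded_walk(D_true, 1e9, 2, 600, x0 = 5e8,
                                 seed = 1000 + i)
      w <- window_diffusion(2 * (seq_along(z) - 1), z, window = 50,
                            stride = 13L)
      w$D
    }))
    expect_gte(length(Ds), 200)
    se <- sd(Ds) / sqrt(length(Ds))
    expect_lt(abs(mean(Ds) - D_true), 3 * se)
  }
})

test_that("windows-per-recording arithmetic matches overlapping 50-s windows", {
  # ~700-s recordings at 2-s frames, stride one frame: ~330 windows each,
  # matching the 13,522-windows-in-41-recordings bookkeeping
  z <- simulate_bounded_walk(1e4, 1e6, 2, 350, x0 = 5e5, seed = 3)
  w <- window_diffusion(2 * (seq_along(z) - 1), z, window = 50, stride = 1L)
  expect_lt(abs(nrow(w) - 13522 / 41) / (13522 / 41), 0.1)
})

test_that("sliding is scored from the window maximum with an inclusive threshold", {
  expect_false(classify_sliding(data.frame(D = rep(0, 5))))
  expect_true(classify_sliding(data.frame(D = c(0, 2.2e4, 0))))   # inclusive
  expect_false(classify_sliding(data.frame(D = c(0, 2.2e4 - 1))))
  expect_error(classify_sliding(data.frame(D = numeric())), "no diffusion")

  # raising the threshold never increases the positive count
  set.seed(8)
  cohorts <- replicate(30, data.frame(D = runif(20, 0, 5e4)),
                       simplify = FALSE)
  thresholds <- c(1e4, 2.2e4, 3e4, 4e4)
  counts <- vapply(thresholds, function(th)
    sum(vapply(cohorts, classify_sliding, logical(1), threshold = th)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))

  # sustained sliding at the upper histogram mode is scored with high
  # probability (weak-confinement geometry)
  hits <- vapply(1:20, function(i) {
    z <- simulate_bounded_walk(3.5e4, 1e6, 2, 100, x0 = 5e5, seed = 40 + i)
    classify_sliding(window_diffusion(2 * (seq_along(z) - 1), z))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("slide/stick paths give a bimodal windowed-D distribution", {
  path <- make_slide_stick_path(D = 3.5e4, n_seg = 10, seg_frames = 80,
                                seed = 2)
  w <- window_diffusion(path$time_s, path$z, window = 50)
  expect_gt(nrow(w), 100)
  dens <- density(w$D)
  # modes: local maxima of the kernel density estimate
  dy <- diff(dens$y)
  peaks <- dens$x[which(diff(sign(dy)) == -2) + 1L]
  expect_true(any(abs(peaks - 0) < 0.15 * 3.5e4))
  expect_true(any(abs(peaks - 3.5e4) < 0.15 * 3.5e4))
})

test_that("secondary-initiation rate gate and degenerate inputs behave", {
  fit <- fit_elongation_decay(make_decay_trace(), c(0, 200))

  # flat post-termination record: no call
  t_post <- seq(202, 400, by = 2)
  flat <- intensity_trace(c(fit$time, t_post),
                          rep(0, length(fit$time) + length(t_post)),
                          c(fit$fitted, rep(394, length(t_post))),
                          rep(0, length(fit$time) + length(t_post)))
  call <- classify_secondary_initiation(flat, fit, t_T = 200)
  expect_false(call$antisense || call$sense_reinit)

  # no post-termination frames: a no-call, not an error
  none <- classify_secondary_initiation(make_decay_trace(), fit, t_T = 200)
  expect_false(none$antisense || none$sense_reinit)
  expect_identical(none$n_candidates, 0L)

  # a clean exponential rise at 0.0015 /s is below the elongation-rate
  # window and must not be scored antisense
  slow_rise <- 800 * exp(-0.0015 * rev(t_post - 202)) + 100
  tr_slow <- intensity_trace(c(fit$time, t_post),
                             rep(0, length(fit$time) + length(t_post)),
                             c(fit$fitted, slow_rise),
                             rep(0, length(fit$time) + length(t_post)))
  call_slow <- classify_secondary_initiation(tr_slow, fit, t_T = 200)
  expect_false(call_slow$antisense)

  # the same shape at 0.01 /s is inside the window: antisense (up tether)
  rise <- 800 * exp(-0.01 * rev(t_post - 202)) + 100
  tr_rise <- intensity_trace(c(fit$time, t_post),
                             rep(0, length(fit$time) + length(t_post)),
                             c(fit$fitted, rise),
                             rep(0, length(fit$time) + length(t_post)))
  call_rise <- classify_secondary_initiation(tr_rise, fit, t_T = 200)
  expect_true(call_rise$antisense)
  expect_false(call_rise$sense_reinit)
  expect_equal(call_rise$rate, 0.01, tolerance = 0.1)

  # a renewed decay episode is promoter-distal: sense re-initiation
  fall <- 800 * exp(-0.01 * (t_post - 202)) + 100
  tr_fall <- intensity_trace(c(fit$time, t_post),
                             rep(0, length(fit$time) + length(t_post)),
                             c(fit$fitted, fall),
                             rep(0, length(fit$time) + length(t_post)))
  call_fall <- classify_secondary_initiation(tr_fall, fit, t_T = 200)
  expect_true(call_fall$sense_reinit)
  expect_false(call_fall$antisense)
})

test_that("simulated antisense episodes are called with the molecule's rate", {
  cfg <- trace_sim_config(noise_sd = 8, D_slide = 0, p_retain = 1,
                          p_antisense = 1, p_sense_reinit = 0,
                          antisense_start_sd = 0, secondary_delay_mean = 10,
                          k_PB = 0, k_RNAP = 0, n_frames = 350, seed = 5)
  hits <- 0L
  for (i in 1:6) {
    sim <- simulate_trace(cfg, molecule = i)
    if (!sim$truth$secondary_completed) next
    fit <- fit_elongation_decay(sim$trace,
                                c(sim$truth$t_start, sim$truth$t_T))
    call <- classify_secondary_initiation(sim$trace, fit, sim$truth$t_T)
    if (call$antisense &&
        abs(call$rate - sim$truth$lambda) / sim$truth$lambda < 0.25)
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("cohort fractions carry binomial standard errors", {
  f <- fraction_with_se(c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(f$fraction, 0.6)
  expect_equal(f$se, sqrt(0.6 * 0.4 / 5))
  expect_error(fraction_with_se(logical()), "no observations")
})
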
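# Eye-trace processing: centering, spline resampling, velocity filtering,
# exclusion, gain.

test_that("centering removes offsets and is idempotent", {
  tr <- eye_trace(seq(0, 1, 0.005), rep(4.2, 201))
  expect_equal(center_trace(tr)$angle_deg, rep(0, 201))
  tt <- seq(0, 2, 0.005)
  sine <- eye_trace(tt, sin(2 * pi * tt) + 3)
  cen <- center_trace(sine)
  expect_equal(mean(cen$angle_deg), 0, tolerance = 1e-12)
  expect_equal(cen$angle_deg, center_trace(cen)$angle_deg)
  expect_error(center_trace(eye_trace(1:5, rep(NA_real_, 5))), "all-NA")
})

test_that("baseline centering uses the pre-stimulus window", {
  tt <- seq(0, 10, 0.01)
  a <- ifelse(tt < 5, 2, 7)
  cen <- center_trace(eye_trace(tt, a), method = "baseline", baseline_s = 4)
  expect_equal(cen$angle_deg[1], 0)
})

test_that("spline resampling reproduces cubics and preserves uniform traces", {
  # cubic polynomial sampled irregularly -> exact reconstruction
  set.seed(7)
  tt <- sort(runif(40, 0, 2))
  f <- function(t) 2 - t + 3 * t^2 - 0.5 * t^3
  out <- resample_spline(eye_trace(tt, f(tt)), target_rate = 100)
  expect_equal(out$angle_deg, f(out$time_s), tolerance = 1e-9)
  # already-uniform trace: values at original times unchanged
  tu <- seq(0, 1, 0.01)
  au <- sin(2 * pi * tu)
  ru <- resample_spline(eye_trace(tu, au), target_rate = 100)
  expect_equal(ru$angle_deg, au, tolerance = 1e-9)
})

test_that("duplicated frames are collapsed before splining", {
  tt <- seq(0, 2, 0.005)
  clean <- sin(2 * pi * 0.5 * tt)
  # duplicate 5% of frames (same timestamp and value)
  set.seed(3)
  dup <- sort(sample(2:length(tt), round(0.05 * length(tt))))
  ord <- rep(seq_along(tt), times = 1 + (seq_along(tt) %in% dup))
  tr <- eye_trace(tt[ord], clean[ord])
  out <- resample_spline(tr, target_rate = 200)
  expect_equal(diff(range(diff(out$time_s))), 0, tolerance = 1e-12)
  ref <- sin(2 * pi * 0.5 * out$time_s)
  expect_lt(max(abs(out$angle_deg - ref)), 1e-3)
})

test_that("too few unique samples error out", {
  expect_error(resample_spline(eye_trace(c(1, 1, 1, 2), c(1, 1, 1, 2))), ">= 4")
})

test_that("velocity estimator recovers a constant ramp", {
  tt <- seq(0, 5, 1 / 200)
  v <- estimate_velocity(eye_trace(tt, 10 * tt))
  mid <- v$velocity_dps[v$time_s > 1 & v$time_s < 4]
  expect_equal(mean(mid), 10, tolerance = 1e-4)
  expect_lt(max(abs(mid - 10)), 0.02)  # passband DC gain 1, small ripple
})

test_that("filter attenuates at cutoff and passes low frequencies", {
  fs <- 200
  tt <- seq(0, 30, 1 / fs)
  # 3 Hz sinusoid: power halved per pass, amplitude 0.5 after two passes
  x3 <- sin(2 * pi * 3 * tt)
  y3 <- filter_lowpass(x3, fs, cutoff_hz = 3)
  expect_equal(interior_amplitude(y3), 0.5, tolerance = 0.02)
  y3_single <- filter_lowpass(x3, fs, cutoff_hz = 3, zero_phase = FALSE)
  expect_equal(interior_amplitude(y3_single), 1 / sqrt(2), tolerance = 0.02)
  # 0.2 Hz passband: amplitude error < 1%
  x02 <- sin(2 * pi * 0.2 * tt)
  y02 <- filter_lowpass(x02, fs, cutoff_hz = 3)
  expect_lt(abs(interior_amplitude(y02) - 1), 0.01)
})

test_that("filter suppresses white noise but keeps low-frequency content", {
  set.seed(5)
  fs <- 200
  x <- rnorm(6000)
  y <- filter_lowpass(x, fs, cutoff_hz = 3)
  expect_lt(var(y), 0.1 * var(x))
  slow <- sin(2 * pi * 0.5 * seq_along(x) / fs)
  ys <- filter_lowpass(slow + x, fs, cutoff_hz = 3)
  expect_gt(cor(ys, slow), 0.9)
})

test_that("per-frequency amplitude gain never exceeds one", {
  fs <- 200
  tt <- seq(0, 20, 1 / fs)
  for (f in c(0.1, 1, 3, 10, 40)) {
    y <- filter_lowpass(sin(2 * pi * f * tt), fs, cutoff_hz = 3)
    expect_lte(interior_amplitude(y), 1 + 1e-6)
  }
})

test_that("undersampled traces are rejected by the filter", {
  expect_error(filter_lowpass(rnorm(100), fs = 5, cutoff_hz = 3), "too low")
})

test_that("saccade exclusion flags contaminated responses and spares clean ones", {
  proto <- build_protocol("behavior", config = list(cycles = 3))
  spec <- synthetic_behavior_spec(true_gain = 1, noise_sd = 0,
                                  saccade_rate = 0, missed_frame_prob = 0,
                                  seed = 1)
  gen <- generate_eye_trace(spec, proto)
  tr <- resample_spline(center_trace(gen$trace), 200)
  vel <- estimate_velocity(tr)
  resp <- segment_responses(tr, vel, gen$onsets)
  resp <- exclude_trials(resp)
  expect_true(all(vapply(resp, `[[`, TRUE, "included")))

  # inject a 5 deg instantaneous saccade into response 3
  r3 <- resp[[3]]
  k <- length(r3$angle) %/% 2
  r3$angle[k:length(r3$angle)] <- r3$angle[k:length(r3$angle)] + 5
  expect_warning(flagged_l <- exclude_trials(list(r3)), "all responses excluded")
  flagged <- flagged_l[[1]]
  expect_false(flagged$included)
  expect_equal(flagged$exclusion_reason, "saccade")
  # infinite threshold excludes nothing
  expect_true(suppressWarnings(
    exclude_trials(list(r3), saccade_threshold = Inf))[[1]]$included)
})

test_that("gain is 1 for a perfect mirror response and 0 for a flat eye", {
  proto <- build_protocol("behavior", config = list(cycles = 2))
  sampled <- sample_protocol(proto)
  # perfect mirror: eye velocity = -platform velocity (no filtering path)
  vel <- data.frame(time_s = sampled$trace$time, velocity_dps = -sampled$trace$velocity)
  tr <- eye_trace(sampled$trace$time, -sampled$trace$angle)
  resp <- segment_responses(tr, vel, sampled$onsets)
  g <- compute_gain(resp, platform_peak = 35)
  expect_equal(g$gain, 1.0, tolerance = 1e-9)

  flat <- data.frame(time_s = sampled$trace$time, velocity_dps = rep(0, nrow(sampled$trace)))
  g0 <- compute_gain(segment_responses(eye_trace(sampled$trace$time,
                                                 rep(0, nrow(sampled$trace))),
                                       flat, sampled$onsets),
                     platform_peak = 35)
  expect_equal(g0$gain, 0)
})

test_that("gain errors without included responses", {
  proto <- build_protocol("behavior", config = list(cycles = 1))
  sampled <- sample_protocol(proto)
  vel <- data.frame(time_s = sampled$trace$time, velocity_dps = rep(0, nrow(sampled$trace)))
  resp <- segment_responses(eye_trace(sampled$trace$time, rep(0, nrow(sampled$trace))),
                            vel, sampled$onsets)
  resp <- lapply(resp, function(r) { r$included <- FALSE; r })
  expect_error(compute_gain(resp), "no included")
})

test_that("gain is invariant to offsets and sign convention", {
  proto <- build_protocol("behavior", config = list(cycles = 3))
  spec <- synthetic_behavior_spec(true_gain = 0.7, noise_sd = 0,
                                  saccade_rate = 0, missed_frame_prob = 0, seed = 2)
  gen <- generate_eye_trace(spec, proto)
  g1 <- estimate_gain(gen$trace, proto)
  shifted <- eye_trace(gen$trace$time_s, gen$trace$angle_deg + 11)
  g2 <- estimate_gain(shifted, proto)
  negated <- eye_trace(gen$trace$time_s, -gen$trace$angle_deg)
  g3 <- estimate_gain(negated, proto)
  expect_equal(g1$gain, g2$gain, tolerance = 1e-9)
  expect_equal(g1$gain, g3$gain, tolerance = 1e-9)
})

test_that("estimated gain is strictly monotone in true gain (noise-free)", {
  proto <- build_protocol("behavior", config = list(cycles = 2))
  gains <- c(0.2, 0.5, 0.8, 1.1)
  est <- vapply(gains, function(tg) {
    gen <- generate_eye_trace(
      synthetic_behavior_spec(true_gain = tg, noise_sd = 0, saccade_rate = 0,
                              missed_frame_prob = 0, seed = 1), proto)
    estimate_gain(gen$trace, proto)$gain
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
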
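# TIPM scoring: dFF, directionality, sensitivity, pairing, bootstrap.

test_that("dFF matches the defining arithmetic", {
  # F0 = 100, post-return peak 150 -> dFF 0.5
  f <- c(rep(100, 45), rep(100, 15), 150, 130, 110, rep(100, 57))
  tr <- roi_trace(f, volume_rate = 3, event_frames = c(step = 46, `return` = 61))
  expect_equal(compute_dff(tr), 0.5)
  # flat trace -> 0
  flat <- roi_trace(rep(80, 130), volume_rate = 3,
                    event_frames = c(step = 46, `return` = 61))
  expect_equal(compute_dff(flat), 0)
})

test_that("dFF equals the brute-force oracle on random 20-frame traces", {
  set.seed(11)
  for (i in 1:50) {
    f <- runif(20, 50, 200)
    r <- sample(5:17, 1)
    rate <- runif(1, 2, 4)
    tr <- roi_trace(f, volume_rate = rate, event_frames = c(step = r - 1, `return` = r))
    expect_identical(suppressWarnings(compute_dff(tr, baseline_frames = 4)),
                     oracle_dff(f, r, rate, baseline_frames = 4))
  }
})

test_that("scored dFF recovers the generator's truth within discretization", {
  # slope 0.02/deg, 25 deg preferred step, no noise -> dFF_true 0.5
  spec <- synthetic_neuron_spec(response_slope = 0.02, response_intercept = 0,
                                noise_sd = 0, decay_tau = 3, seed = 1)
  gen <- generate_tipm_trace(spec, trial_timeline(), 25)
  expect_equal(gen$truth$dff_true, 0.5)
  scored <- compute_dff(gen$trace)
  bound <- 1 - exp(-(1 / 3) / 3)  # one-frame decay at 3 volumes/s, tau 3 s
  expect_lt(abs(scored - 0.5), 0.5 * bound + 1e-9)
  # non-preferred direction: no response
  gen_down <- generate_tipm_trace(spec, trial_timeline(), -19)
  expect_equal(gen_down$truth$dff_true, 0)
  expect_equal(compute_dff(gen_down$trace), 0, tolerance = 1e-12)
})

test_that("dFF is invariant to trace rescaling and ROI normalization", {
  spec <- synthetic_neuron_spec(noise_sd = 0, seed = 2)
  gen <- generate_tipm_trace(spec, trial_timeline(), 25)
  d0 <- compute_dff(gen$trace)
  doubled <- gen$trace
  doubled$fluorescence <- doubled$fluorescence * 2
  expect_equal(compute_dff(doubled), d0, tolerance = 1e-12)
  norm <- normalize_roi(gen$trace, reference_area = 37)
  expect_equal(compute_dff(norm), d0, tolerance = 1e-12)
})

test_that("ROI normalization scales fluorescence by area ratio", {
  tr <- roi_trace(rep(100, 130), roi_area = 50,
                  event_frames = c(step = 46, `return` = 61))
  out <- normalize_roi(tr, reference_area = 100)
  expect_equal(out$fluorescence, rep(200, 130))
  expect_true(out$normalized)
  expect_error(normalize_roi(tr, 0), "> 0")
})

test_that("dFF rejects degenerate baselines and short traces", {
  z <- roi_trace(c(rep(0, 12), rep(10, 8)), volume_rate = 3,
                 event_frames = c(step = 13, `return` = 14))
  expect_error(compute_dff(z), "baseline")
  short <- roi_trace(rep(10, 5), volume_rate = 3,
                     event_frames = c(step = 2, `return` = 3))
  expect_error(compute_dff(short), "shorter")
})

test_that("directionality index follows its formula on sign/magnitude grid", {
  expect_equal(directionality(1.0, 0)$di, 1.0)
  expect_true(directionality(1.0, 0)$tuned)
  r <- directionality(0.4, 0.4)
  expect_equal(r$di, 0)
  expect_false(r$tuned)
  expect_equal(directionality(0.3, 0.1)$di, 0.5)
  # hand-computed grid, antisymmetry included
  for (u in c(0, 0.05, 0.3, 1)) for (d in c(0, 0.05, 0.3, 1)) {
    if (u + d == 0) next
    expect_equal(directionality(u, d)$di, (u - d) / (u + d))
    expect_equal(directionality(u, d)$di, -directionality(d, u)$di)
    expect_gte(directionality(u, d)$di, -1)
    expect_lte(directionality(u, d)$di, 1)
  }
})

test_that("negative dFF is clipped with a warning and zero-sum is degenerate", {
  expect_warning(r <- directionality(-0.2, 0.4), "clipped")
  expect_equal(r$di, -1)
  expect_warning(r0 <- directionality(-0.1, -0.2), "clipped")
  expect_true(r0$degenerate)
  expect_equal(r0$di, 0)
  expect_false(r0$tuned)
})

test_that("sensitivity fit recovers an exact linear relation", {
  amps <- c(7.5, 15, 22.5, 30)
  fit <- suppressWarnings(fit_sensitivity(amps, 0.02 * amps))  # perfect fit
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
  expect_true(fit$sensitive)
  expect_error(fit_sensitivity(rep(15, 4), rnorm(4)), "distinct")
})

test_that("sensitivity slope estimate is unbiased under noise", {
  set.seed(21)
  amps <- rep(c(7.5, 15, 22.5, 30), each = 5)
  slopes <- replicate(100, fit_sensitivity(amps, 0.015 * amps + rnorm(20, 0, 0.1))$slope)
  se <- sd(slopes) / sqrt(100)
  expect_lt(abs(mean(slopes) - 0.015), 3 * se + 1e-4)
})

test_that("longitudinal pairing joins by the supplied id map", {
  da <- data.frame(neuron_id = c("n1", "n2", "n3"), mean_dff = c(0.1, 0.2, 0.3))
  db <- data.frame(neuron_id = c("n1", "n2", "n4"), mean_dff = c(0.1, 0.2, 0.9))
  idm <- data.frame(id_a = c("n1", "n2"), id_b = c("n1", "n2"))
  out <- pair_longitudinal(da, db, idm)
  expect_equal(out$pairs$difference, c(0, 0))
  expect_equal(out$unmapped$day_a, "n3")
  expect_equal(out$unmapped$day_b, "n4")
  # uniform shift appears in every difference
  db2 <- data.frame(neuron_id = da$neuron_id, mean_dff = da$mean_dff + 0.3)
  idm3 <- data.frame(id_a = da$neuron_id, id_b = da$neuron_id)
  expect_equal(pair_longitudinal(da, db2, idm3)$pairs$difference, rep(0.3, 3))
  expect_error(pair_longitudinal(da, db, data.frame(id_a = c("n1", "n1"),
                                                    id_b = c("n1", "n2"))),
               "duplicate")
})

test_that("plateau-shaped synthetic ontogeny yields rising then flat differences", {
  ds <- generate_ontogeny_dataset(ontogeny_config_plateau(), seed = 5)
  tip <- ds$tipm
  mk <- function(a, b) {
    da <- tip[tip$age == a, c("neuron", "dff")]; names(da) <- c("neuron_id", "mean_dff")
    db <- tip[tip$age == b, c("neuron", "dff")]; names(db) <- c("neuron_id", "mean_dff")
    pair_longitudinal(da, db, data.frame(id_a = da$neuron_id, id_b = da$neuron_id))$pairs$difference
  }
  d35 <- mk(3, 5); d57 <- mk(5, 7)
  expect_gt(mean(d35), 0.2)
  expect_lt(abs(mean(d57)), 0.15)
})

test_that("bootstrap SD is deterministic, zero for constants, calibrated for means", {
  expect_equal(bootstrap_sd(rep(3, 50), seed = 1), 0)
  set.seed(33); x <- rnorm(200)
  b1 <- bootstrap_sd(x, n_boot = 2000, seed = 4)
  b2 <- bootstrap_sd(x, n_boot = 2000, seed = 4)
  expect_identical(b1, b2)
  expect_lt(abs(b1 - 1 / sqrt(200)) / (1 / sqrt(200)), 0.15)
  expect_error(bootstrap_sd(numeric(0)), ">= 2")
})

test_that("per-bin bootstrap proportions sum to one and carry SDs", {
  set.seed(8)
  v <- rnorm(300)
  out <- bootstrap_bin_sd(v, breaks = seq(-4, 4, 0.5), n_boot = 60, seed = 2)
  expect_equal(sum(out$proportion), 1, tolerance = 1e-12)
  expect_true(all(out$boot_sd >= 0))
  expect_gt(max(out$boot_sd), 0)
})

test_that("log(dFF+1) transform is monotone and preserves test direction", {
  ds <- generate_ontogeny_dataset(ontogeny_config_plateau(), seed = 6)
  tip <- ds$tipm[ds$tipm$age %in% c(3, 5), ]
  raw_p <- t.test(dff ~ age, tip)$p.value
  log_p <- t.test(log1p(dff) ~ age, tip)$p.value
  expect_lt(raw_p, 0.05)
  expect_lt(log_p, 0.05)
  expect_identical(order(tip$dff), order(log1p(tip$dff)))
})
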
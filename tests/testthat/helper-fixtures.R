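# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

# A clean, noise-free TIPM trial trace with a known dFF step and decay.
make_tipm_trace <- function(dff_true = 0.5, baseline_F = 100, tau = 3,
                            volume_rate = 3, trial = trial_timeline()) {
  spec <- synthetic_neuron_spec(baseline_F = baseline_F,
                                response_slope = 0, response_intercept = dff_true,
                                decay_tau = tau, noise_sd = 0,
                                volume_rate = volume_rate, seed = 1)
  generate_tipm_trace(spec, trial, tilt_angle = 25)
}

# Brute-force dFF oracle: explicit enumeration of baseline frames and the
# post-return window, independent of compute_dff's internals.
oracle_dff <- function(f, return_frame, volume_rate, baseline_frames = 10,
                       peak_window_s = 1.0) {
  f0 <- sum(f[1:baseline_frames]) / baseline_frames
  t_return <- (return_frame - 1) / volume_rate
  peak <- -Inf
  for (i in seq_along(f)) {
    t_i <- (i - 1) / volume_rate
    if (i >= return_frame && t_i < t_return + peak_window_s - 1e-12) {
      if (f[i] > peak) peak <- f[i]
    }
  }
  (peak - f0) / f0
}

# A rectangular ROI polygon covering [0, w] x [0, h] in pixel coordinates.
rect_roi <- function(w, h, muscle = "SO") {
  muscle_roi(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)), muscle = muscle)
}

# Amplitude of a sinusoid estimated from the interior of a signal
# (avoiding filter edge transients).
interior_amplitude <- function(x, trim_frac = 0.2) {
  n <- length(x)
  lo <- floor(n * trim_frac); hi <- ceiling(n * (1 - trim_frac))
  max(abs(x[lo:hi]))
}
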
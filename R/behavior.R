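## Torsional eye-trace analysis: centering, spline resampling, velocity
## estimation, trial exclusion, cycle averaging and VOR gain.

#' Torsional eye-position trace
#'
#' Container for a torsional eye-angle time series. Positive platform
#' rotation is nose-up; the compensatory eye rotation counter-rotates, so a
#' gain-1 eye trace is the negated platform angle. Gain is computed on
#' magnitudes downstream, so the stored sign convention does not affect it.
#'
#' @param time_s Sample times, seconds, strictly increasing (duplicate
#'   timestamps from repeated camera frames are tolerated and collapsed by
#'   [resample_spline()]).
#' @param angle_deg Torsional eye angle, degrees.
#' @param sampling_rate Nominal acquisition rate in Hz (default 200).
#' @param fish_id,age_dpf Optional metadata.
#' @return An object of class `eye_trace` (a data frame with columns
#'   `time_s`, `angle_deg`).
#' @export
eye_trace <- function(time_s, angle_deg, sampling_rate = 200,
                      fish_id = NA_character_, age_dpf = NA_real_) {
  if (length(time_s) == 0L || length(time_s) != length(angle_deg)) {
    stop_invalid("`time_s` and `angle_deg` must be equal-length, non-empty")
  }
  if (any(diff(time_s) < 0)) stop_invalid("`time_s` must be non-decreasing")
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  structure(
    data.frame(time_s = as.numeric(time_s), angle_deg = as.numeric(angle_deg)),
    sampling_rate = sampling_rate, fish_id = fish_id, age_dpf = age_dpf,
    class = c("eye_trace", "data.frame")
  )
}

eye_trace_like <- function(template, time_s, angle_deg) {
  eye_trace(time_s, angle_deg,
            sampling_rate = attr(template, "sampling_rate"),
            fish_id = attr(template, "fish_id"),
            age_dpf = attr(template, "age_dpf"))
}

#' Center an eye trace
#'
#' Removes the constant offset introduced by the torsion-tracking pattern
#' matcher, either by subtracting the whole-trace mean (default) or the mean
#' over an initial pre-stimulus baseline window.
#'
#' @param trace An [eye_trace()].
#' @param method `"whole"` (whole-trace mean) or `"baseline"`.
#' @param baseline_s Length of the initial baseline window (seconds) when
#'   `method = "baseline"`.
#' @return The centered `eye_trace`. Idempotent.
#' @export
center_trace <- function(trace, method = c("whole", "baseline"),
                         baseline_s = 5) {
  method <- match.arg(method)
  a <- trace$angle_deg
  if (all(is.na(a))) stop_invalid("trace is all-NA; cannot center")
  offset <- if (method == "whole") {
    mean(a, na.rm = TRUE)
  } else {
    sel <- trace$time_s <= trace$time_s[1] + baseline_s
    mean(a[sel], na.rm = TRUE)
  }
  eye_trace_like(trace, trace$time_s, a - offset)
}

#' Resample an eye trace onto a uniform grid with a cubic spline
#'
#' Corrects transient camera slowdowns (missed frames appear as duplicated
#' samples): duplicate timestamps are collapsed to their first sample, a
#' cubic spline (`stats::splinefun`, method `"fmm"`, which reproduces cubic
#' polynomials exactly) is fitted through the remaining samples, and the
#' trace is evaluated on a uniform grid at `target_rate`.
#'
#' @param trace An [eye_trace()].
#' @param target_rate Output sampling rate, Hz.
#' @return A uniformly sampled `eye_trace` whose `sampling_rate` attribute is
#'   `target_rate`. The spline interpolates the original samples, so values
#'   at original timestamps are unchanged.
#' @export
resample_spline <- function(trace, target_rate = 200) {
  check_number(target_rate, "target_rate", positive = TRUE)
  keep <- !is.na(trace$angle_deg)
  tt <- trace$time_s[keep]; aa <- trace$angle_deg[keep]
  first <- !duplicated(tt)
  tt <- tt[first]; aa <- aa[first]
  if (length(tt) < 4L) stop_invalid("need >= 4 unique timestamps for cubic spline")
  f <- stats::splinefun(tt, aa, method = "fmm")
  grid <- seq(tt[1], tt[length(tt)], by = 1 / target_rate)
  out <- eye_trace(grid, f(grid),
                   sampling_rate = target_rate,
                   fish_id = attr(trace, "fish_id"),
                   age_dpf = attr(trace, "age_dpf"))
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' @param x Numeric signal on a uniform grid.
#' @param fs Sampling rate, Hz.
#' @param cutoff_hz Cutoff frequency, Hz; must satisfy `fs > 2 * cutoff_hz`.
#' @param poles Filter order per pass (default 4).
#' @param zero_phase If `TRUE` (default) the filter is applied
#'   forward-backward (`signal::filtfilt`), giving zero phase shift and
#'   squared magnitude response (power at the cutoff is attenuated by 0.5
#'   per pass, -6 dB total in amplitude); if `FALSE`, a single causal pass.
#' @return Filtered signal, same length as `x`.
#' @export
filter_lowpass <- function(x, fs, cutoff_hz = 3, poles = 4, zero_phase = TRUE) {
  check_number(fs, "fs", positive = TRUE)
  check_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (fs <= 2 * cutoff_hz) {
    stop_invalid("sampling rate %g Hz too low for %g Hz cutoff", fs, cutoff_hz)
  }
  bf <- signal::butter(poles, cutoff_hz / (fs / 2), type = "low")
  if (zero_phase) signal::filtfilt(bf, x) else as.numeric(signal::filter(bf, x))
}

#' Estimate eye velocity from a uniformly sampled trace
#'
#' Velocity is the first difference of the angle scaled by the sampling
#' rate, low-pass filtered with a zero-phase 4-pole Butterworth at 3 Hz to
#' suppress differentiation noise. The returned series has one fewer sample
#' than the input; sample `i` is assigned the time of input sample `i` (left
#' edge of the difference interval).
#'
#' @param trace A uniformly resampled [eye_trace()].
#' @param cutoff_hz,poles,zero_phase Passed to [filter_lowpass()].
#' @return Data frame with columns `time_s`, `velocity_dps`.
#' @export
estimate_velocity <- function(trace, cutoff_hz = 3, poles = 4,
                              zero_phase = TRUE) {
  dts <- diff(trace$time_s)
  if (length(dts) < 8L) stop_invalid("trace too short for velocity estimation")
  if (max(abs(dts - dts[1])) > 1e-6) {
    stop_invalid("trace must be uniformly sampled; run resample_spline() first")
  }
  fs <- 1 / dts[1]
  v <- diff(trace$angle_deg) * fs
  vf <- filter_lowpass(v, fs, cutoff_hz = cutoff_hz, poles = poles,
                       zero_phase = zero_phase)
  data.frame(time_s = trace$time_s[-nrow(trace)], velocity_dps = vf)
}

#' Segment a trace into per-step responses
#'
#' Aligns the (unfiltered) angle and the estimated velocity to each step's
#' command onset. The unfiltered angle is kept for saccade screening; gain
#' uses the filtered velocity.
#'
#' @param trace The uniformly resampled, centered [eye_trace()].
#' @param velocity Velocity series from [estimate_velocity()].
#' @param onsets Data frame of step onsets from [sample_protocol()] (columns
#'   `step_id`, `step_in_cycle`, `onset_time`, `direction`, `peak_velocity`).
#' @param window_s Length of the response window after onset, seconds; must
#'   cover at least the 1 s gain window.
#' @return List of `step_response` objects, each a list with the aligned
#'   series and metadata.
#' @export
segment_responses <- function(trace, velocity, onsets, window_s = 1.5) {
  check_number(window_s, "window_s", positive = TRUE)
  fs <- attr(trace, "sampling_rate")
  tt <- trace$time_s
  vt <- velocity$time_s
  # half-open [onset, onset + window) windows located by binary search
  a_lo <- findInterval(onsets$onset_time - 1e-9, tt) + 1L
  a_hi <- findInterval(onsets$onset_time + window_s - 1e-9, tt)
  v_lo <- findInterval(onsets$onset_time - 1e-9, vt) + 1L
  v_hi <- findInterval(onsets$onset_time + window_s - 1e-9, vt)
  lapply(seq_len(nrow(onsets)), function(i) {
    t0 <- onsets$onset_time[i]
    ia <- seq.int(a_lo[i], max(a_lo[i] - 1L, a_hi[i]))
    iv <- seq.int(v_lo[i], max(v_lo[i] - 1L, v_hi[i]))
    structure(
      list(step_id = onsets$step_id[i],
           step_in_cycle = onsets$step_in_cycle[i],
           direction = onsets$direction[i],
           peak_platform_velocity = onsets$peak_velocity[i],
           t_rel = tt[ia] - t0,
           angle = trace$angle_deg[ia],
           v_rel = vt[iv] - t0,
           velocity = velocity$velocity_dps[iv],
           sampling_rate = fs,
           included = TRUE, exclusion_reason = "none"),
      class = "step_response"
    )
  })
}

#' Flag step responses contaminated by saccades or tracking failure
#'
#' A response is excluded when any consecutive-sample displacement of the
#' unfiltered angle exceeds `saccade_threshold` (degrees per sample; the
#' default 1.5 corresponds to 300 deg/s at 200 Hz, far above compensatory
#' velocities) or when more than `max_nan_frac` of its samples are missing.
#' This automates the manual screening of trials with rapid position
#' deviations; the threshold is exposed and recorded.
#'
#' @param responses List of `step_response` objects.
#' @param saccade_threshold Degrees per sample; `Inf` disables.
#' @param max_nan_frac Maximum tolerated fraction of missing samples.
#' @return The responses with `included` / `exclusion_reason` set.
#' @export
exclude_trials <- function(responses, saccade_threshold = 1.5,
                           max_nan_frac = 0.2) {
  out <- lapply(responses, function(r) {
    nan_frac <- mean(is.na(r$angle))
    if (nan_frac > max_nan_frac) {
      r$included <- FALSE
      r$exclusion_reason <- "missing_data"
    } else {
      jumps <- abs(diff(r$angle))
      if (any(jumps > saccade_threshold, na.rm = TRUE)) {
        r$included <- FALSE
        r$exclusion_reason <- "saccade"
      }
    }
    r
  })
  if (!any(vapply(out, `[[`, TRUE, "included"))) {
    warning("all responses excluded", call. = FALSE)
  }
  out
}

#' VOR gain from included step responses
#'
#' For each within-cycle step position, the included velocity responses are
#' averaged across cycles (the response to that step is the mean across all
#' its repetitions); the peak |eye velocity| within the first `window_s`
#' after onset is read off the averaged trace, and gain is that peak divided
#' by the peak platform velocity (commanded peak by default).
#'
#' @param responses List of `step_response` objects (after
#'   [exclude_trials()]).
#' @param platform_peak Peak platform velocity in deg/s used as the gain
#'   denominator; default takes the commanded peak stored in the responses.
#' @param window_s Gain measurement window after step onset, seconds.
#' @return An object of class `gain_result`: overall `gain` (mean across
#'   step positions), `per_step` data frame, `peak_eye_velocity`,
#'   `peak_platform_velocity`, inclusion counts.
#' @export
compute_gain <- function(responses, platform_peak = NULL, window_s = 1.0) {
  check_number(window_s, "window_s", positive = TRUE)
  inc <- Filter(function(r) r$included, responses)
  if (!length(inc)) stop_invalid("no included responses; cannot compute gain")
  if (is.null(platform_peak)) {
    platform_peak <- max(vapply(inc, `[[`, numeric(1), "peak_platform_velocity"))
  }
  check_number(platform_peak, "platform_peak", positive = TRUE)

  by_pos <- split(inc, vapply(inc, `[[`, integer(1), "step_in_cycle"))
  per_step <- do.call(rbind, lapply(by_pos, function(group) {
    n <- min(vapply(group, function(r) length(r$velocity), integer(1)))
    vmat <- vapply(group, function(r) r$velocity[seq_len(n)], numeric(n))
    vbar <- rowMeans(vmat)
    t_rel <- group[[1]]$v_rel[seq_len(n)]
    in_win <- t_rel <= window_s
    peak_signed <- vbar[in_win][which.max(abs(vbar[in_win]))]
    data.frame(step_in_cycle = group[[1]]$step_in_cycle,
               direction = group[[1]]$direction,
               n_responses = length(group),
               peak_eye_velocity = abs(peak_signed),
               peak_eye_velocity_signed = peak_signed,
               gain = abs(peak_signed) / platform_peak)
  }))
  rownames(per_step) <- NULL
  structure(
    list(gain = mean(per_step$gain),
         per_step = per_step,
         peak_eye_velocity = max(per_step$peak_eye_velocity),
         peak_platform_velocity = platform_peak,
         n_steps_included = length(inc),
         n_steps_excluded = length(responses) - length(inc),
         window_s = window_s),
    class = "gain_result"
  )
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("<gain_result> gain = %.3f (peak eye %.1f / platform %.1f deg/s); %d steps included, %d excluded\n",
              x$gain, x$peak_eye_velocity, x$peak_platform_velocity,
              x$n_steps_included, x$n_steps_excluded))
  invisible(x)
}

#' End-to-end VOR gain estimation for one fish
#'
#' Runs the full pipeline: centering, cubic-spline resampling to a uniform
#' grid, differentiation + zero-phase Butterworth filtering, alignment to
#' step onsets, saccade exclusion, cycle averaging and gain.
#'
#' @param trace Raw [eye_trace()].
#' @param protocol A behavior protocol from [build_protocol()].
#' @param cutoff_hz,poles Velocity filter settings.
#' @param window_s Gain window after step onset, seconds.
#' @param saccade_threshold Degrees/sample for trial exclusion.
#' @param center_method Passed to [center_trace()].
#' @param platform_peak Gain denominator override (deg/s); default is the
#'   protocol's commanded peak velocity.
#' @return A `gain_result`.
#' @export
estimate_gain <- function(trace, protocol, cutoff_hz = 3, poles = 4,
                          window_s = 1.0, saccade_threshold = 1.5,
                          center_method = "whole", platform_peak = NULL) {
  sampled <- sample_protocol(protocol)
  tr <- center_trace(trace, method = center_method)
  tr <- resample_spline(tr, target_rate = attr(trace, "sampling_rate"))
  vel <- estimate_velocity(tr, cutoff_hz = cutoff_hz, poles = poles)
  resp <- segment_responses(tr, vel, sampled$onsets,
                            window_s = max(1.5, window_s + 0.5))
  resp <- exclude_trials(resp, saccade_threshold = saccade_threshold)
  compute_gain(resp, platform_peak = platform_peak, window_s = window_s)
}
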
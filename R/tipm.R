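## Tilt-in-place microscopy (TIPM) scoring: dF/F, directionality index,
## sensitivity slopes, longitudinal pairing, bootstrap SDs.
##
## TIPM tilts the animal eccentrically, holds, then returns it to the
## imaging plane within ~5 ms — much faster than the GCaMP6s decay — so the
## fluorescence recorded after the return reflects the decaying response to
## the tilt. Scoring therefore reads the peak in the first second after the
## return.

#' Per-ROI fluorescence trace for one TIPM trial
#'
#' @param fluorescence Non-negative fluorescence values, one per imaging
#'   volume (frame).
#' @param volume_rate Volumes per second (~3).
#' @param roi_area ROI area in pixels (> 0).
#' @param event_frames Named integer vector with elements `step` and
#'   `return`: the first frame at/after the eccentric step and at/after the
#'   return to horizontal.
#' @param roi_id,fish_id,age_dpf,trial_id Metadata.
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(fluorescence, volume_rate = 3, roi_area = 100,
                      event_frames, roi_id = NA, fish_id = NA,
                      age_dpf = NA_real_, trial_id = NA) {
  if (!length(fluorescence) || any(fluorescence < 0, na.rm = TRUE)) {
    stop_invalid("`fluorescence` must be non-empty and non-negative")
  }
  check_number(volume_rate, "volume_rate", positive = TRUE)
  check_number(roi_area, "roi_area", positive = TRUE)
  if (!all(c("step", "return") %in% names(event_frames))) {
    stop_invalid("`event_frames` needs named elements `step` and `return`")
  }
  ev <- as.integer(event_frames[c("step", "return")])
  if (any(ev < 1L) || any(ev > length(fluorescence)) || ev[2] < ev[1]) {
    stop_invalid("event frames must lie within the trace, return after step")
  }
  structure(
    list(fluorescence = as.numeric(fluorescence), volume_rate = volume_rate,
         roi_area = roi_area, event_frames = c(step = ev[1], return = ev[2]),
         roi_id = roi_id, fish_id = fish_id, age_dpf = age_dpf,
         trial_id = trial_id, normalized = FALSE),
    class = "roi_trace"
  )
}

#' Normalize a trace by ROI size
#'
#' Compensates for different pixel sizes when imaging zoom varied across
#' sessions by scaling fluorescence by `reference_area / roi_area`. dF/F is
#' a ratio and is therefore unchanged by this (or any) multiplicative
#' rescaling; normalization matters only when raw fluorescence values are
#' compared across sessions.
#'
#' @param trace An [roi_trace()].
#' @param reference_area Reference ROI area in pixels.
#' @return The rescaled `roi_trace`, flagged `normalized`.
#' @export
normalize_roi <- function(trace, reference_area) {
  check_number(reference_area, "reference_area", positive = TRUE)
  if (trace$roi_area <= 0) stop_invalid("zero ROI area")
  trace$fluorescence <- trace$fluorescence * reference_area / trace$roi_area
  trace$normalized <- TRUE
  trace
}

#' dF/F for one TIPM trial
#'
#' Baseline F0 is the mean of the first `baseline_frames` frames of the
#' trial; the response is the peak fluorescence among the frames acquired in
#' the first `peak_window_s` seconds after the return to horizontal
#' (half-open window: frames with times in `[t_return, t_return +
#' peak_window_s)`; at ~3 volumes/s and a 1 s window this is 3 frames);
#' dF/F = (peak - F0) / F0.
#'
#' @param trace An [roi_trace()].
#' @param baseline_frames Number of initial frames averaged for F0.
#' @param peak_window_s Post-return window, seconds.
#' @return A single dF/F value.
#' @export
compute_dff <- function(trace, baseline_frames = 10, peak_window_s = 1.0) {
  check_number(baseline_frames, "baseline_frames", positive = TRUE)
  check_number(peak_window_s, "peak_window_s", positive = TRUE)
  f <- trace$fluorescence
  if (length(f) < baseline_frames) {
    stop_invalid("trace shorter than baseline window (%d frames)", baseline_frames)
  }
  f0 <- mean(f[seq_len(baseline_frames)])
  if (!is.finite(f0) || f0 <= 0) stop_invalid("baseline fluorescence must be > 0")
  r <- trace$event_frames[["return"]]
  # frames at/after the return whose acquisition time precedes t_return + window
  n_win <- ceiling(peak_window_s * trace$volume_rate - 1e-9)
  idx <- r:min(length(f), r + n_win - 1L)
  if (r + n_win - 1L > length(f)) {
    warning("peak window truncated by end of trace", call. = FALSE)
  }
  (max(f[idx]) - f0) / f0
}

#' Summarize trials into a neuron's response for one condition
#'
#' The per-neuron response to a stimulus condition is the mean dF/F over its
#' 4–5 stimulus repeats; `log_dff = log(mean_dff + 1)` (natural log) is kept
#' alongside for statistics on the compressed scale.
#'
#' @param dff_per_trial Numeric vector of per-trial dF/F values.
#' @param direction `"nose-up"` or `"nose-down"`.
#' @param tilt_angle Stimulus amplitude, degrees (unsigned).
#' @param neuron_id,fish_id,age_dpf Metadata.
#' @return An object of class `neuron_response`.
#' @export
neuron_response <- function(dff_per_trial, direction = c("nose-up", "nose-down"),
                            tilt_angle = NA_real_, neuron_id = NA,
                            fish_id = NA, age_dpf = NA_real_) {
  direction <- match.arg(direction)
  if (!length(dff_per_trial)) stop_invalid("no trials supplied")
  m <- mean(dff_per_trial)
  if (m <= -1) stop_invalid("mean dFF <= -1; log(dFF + 1) undefined")
  structure(
    list(dff_per_trial = as.numeric(dff_per_trial), mean_dff = m,
         log_dff = log1p(m), direction = direction, tilt_angle = tilt_angle,
         neuron_id = neuron_id, fish_id = fish_id, age_dpf = age_dpf),
    class = "neuron_response"
  )
}

#' Directionality index of a neuron
#'
#' DI = (up - down) / (up + down) on dF/F, in \[-1, 1\]; +1 is purely
#' nose-up selective, -1 purely nose-down. A neuron is "tuned" when
#' |DI| > `threshold` (default 0.1). Negative dF/F values (noise below
#' baseline) are clipped to 0 for the DI only, keeping it bounded for noisy
#' non-responders; when the clipped sum is 0 the index is degenerate and
#' reported as DI = 0, untuned.
#'
#' @param up,down [neuron_response()] objects (or bare dF/F numbers) for the
#'   nose-up and nose-down conditions of the same neuron at the same
#'   amplitude.
#' @param threshold Tuned classification threshold on |DI|.
#' @return An object of class `directionality_result`: `di`, `tuned`,
#'   `up_dff`, `down_dff`, `degenerate`.
#' @export
directionality <- function(up, down, threshold = 0.1) {
  get_dff <- function(x) if (inherits(x, "neuron_response")) x$mean_dff else as.numeric(x)
  u <- get_dff(up); d <- get_dff(down)
  if (inherits(up, "neuron_response") && inherits(down, "neuron_response")) {
    if (!is.na(up$tilt_angle) && !is.na(down$tilt_angle) &&
        abs(up$tilt_angle) != abs(down$tilt_angle)) {
      stop_invalid("up/down responses must share the same |tilt angle|")
    }
  }
  if (u < 0 || d < 0) {
    warning("negative dFF clipped to 0 for directionality index", call. = FALSE)
    u <- max(0, u); d <- max(0, d)
  }
  if ((u + d) <= 0) {
    return(structure(list(di = 0, tuned = FALSE, up_dff = u, down_dff = d,
                          degenerate = TRUE, threshold = threshold),
                     class = "directionality_result"))
  }
  di <- (u - d) / (u + d)
  structure(list(di = di, tuned = abs(di) > threshold, up_dff = u,
                 down_dff = d, degenerate = FALSE, threshold = threshold),
            class = "directionality_result")
}

#' Sensitivity of a neuron to tilt amplitude
#'
#' Ordinary least-squares line of dF/F against stimulus amplitude over the
#' sensitivity-mapping gradient (7.5, 15, 22.5, 30 deg), with the two-sided
#' p-value for a non-zero slope. A neuron is classified "sensitive" when the
#' slope is positive and p < `alpha`.
#'
#' @param amplitudes Stimulus amplitudes, degrees (>= 3 distinct values).
#' @param dff dF/F responses, same length.
#' @param alpha Significance level for the sensitive classification.
#' @return An object of class `sensitivity_fit`: `slope`, `intercept`,
#'   `p_value`, `n_points`, `sensitive`.
#' @export
fit_sensitivity <- function(amplitudes, dff, alpha = 0.05) {
  if (length(amplitudes) != length(dff)) stop_invalid("length mismatch")
  if (length(unique(amplitudes)) < 3L) {
    stop_invalid("need >= 3 distinct amplitudes for a sensitivity fit")
  }
  fit <- stats::lm(dff ~ amplitudes)
  sm <- summary(fit)$coefficients
  slope <- sm["amplitudes", "Estimate"]
  p <- sm["amplitudes", "Pr(>|t|)"]
  structure(
    list(slope = unname(slope), intercept = unname(sm["(Intercept)", "Estimate"]),
         p_value = unname(p), n_points = length(dff),
         sensitive = slope > 0 && p < alpha),
    class = "sensitivity_fit"
  )
}

#' Pair neuron responses across two imaging days
#'
#' Joins two per-day response tables through a supplied identity map (the
#' map encodes neurons tracked and agreed by both raters; it is never
#' inferred). Differences are later minus earlier day.
#'
#' @param day_a,day_b Data frames with columns `neuron_id`, `mean_dff` and
#'   optionally `age_dpf`.
#' @param id_map Data frame with columns `id_a`, `id_b` linking neuron ids
#'   between days; ids must be unique within each column.
#' @return A list with `pairs` (data frame `neuron_id_a`, `neuron_id_b`,
#'   `dff_a`, `dff_b`, `difference`) and `unmapped` (ids present in a table
#'   but absent from the map).
#' @export
pair_longitudinal <- function(day_a, day_b, id_map) {
  for (nm in c("id_a", "id_b")) {
    if (anyDuplicated(id_map[[nm]])) stop_invalid("duplicate ids in `%s`", nm)
  }
  need <- function(df, lbl) {
    if (!all(c("neuron_id", "mean_dff") %in% names(df))) {
      stop_invalid("`%s` needs columns neuron_id, mean_dff", lbl)
    }
  }
  need(day_a, "day_a"); need(day_b, "day_b")
  ia <- match(id_map$id_a, day_a$neuron_id)
  ib <- match(id_map$id_b, day_b$neuron_id)
  ok <- !is.na(ia) & !is.na(ib)
  pairs <- data.frame(
    neuron_id_a = id_map$id_a[ok],
    neuron_id_b = id_map$id_b[ok],
    dff_a = day_a$mean_dff[ia[ok]],
    dff_b = day_b$mean_dff[ib[ok]]
  )
  pairs$difference <- pairs$dff_b - pairs$dff_a
  unmapped <- list(
    day_a = setdiff(day_a$neuron_id, id_map$id_a),
    day_b = setdiff(day_b$neuron_id, id_map$id_b)
  )
  list(pairs = pairs, unmapped = unmapped)
}

#' Bootstrap standard deviation of a statistic
#'
#' Resamples the data with replacement `n_boot` times (study default 60),
#' recomputes `statistic` on each resample, and returns the standard
#' deviation of the bootstrap replicates — the bootstrap estimate of the
#' statistic's sampling SD.
#'
#' @param values Numeric data (length >= 2).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return The bootstrap SD (single number).
#' @export
bootstrap_sd <- function(values, statistic = mean, n_boot = 60, seed = 1L) {
  if (length(values) < 2L) stop_invalid("need >= 2 values to bootstrap")
  check_number(n_boot, "n_boot", positive = TRUE)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      statistic(sample(values, replace = TRUE))
    }, numeric(1))
  })
  stats::sd(reps)
}

#' Bootstrap SDs of per-bin histogram proportions
#'
#' For presenting a distribution (e.g. of pairwise dF/F differences) with
#' bootstrapped error bars per bin: the data are resampled with replacement
#' and the proportion falling in each bin recomputed.
#'
#' @param values Numeric data.
#' @param breaks Bin edges (as in `cut`); values outside are dropped.
#' @param n_boot Number of bootstrap replicates (default 60).
#' @param seed Integer seed.
#' @return Data frame with `bin_lo`, `bin_hi`, `proportion`, `boot_sd`.
#' @export
bootstrap_bin_sd <- function(values, breaks, n_boot = 60, seed = 1L) {
  if (length(values) < 2L) stop_invalid("need >= 2 values to bootstrap")
  bin_of <- function(v) {
    tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                          all.inside = FALSE),
             nbins = length(breaks) - 1L) / length(v)
  }
  props <- bin_of(values[values >= breaks[1] & values <= breaks[length(breaks)]])
  mat <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      v <- sample(values, replace = TRUE)
      bin_of(v[v >= breaks[1] & v <= breaks[length(breaks)]])
    }, numeric(length(breaks) - 1L))
  })
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             proportion = props, boot_sd = apply(mat, 1, stats::sd))
}
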
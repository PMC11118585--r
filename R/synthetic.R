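## Synthetic-data generators with ground truth for every pipeline arm.
## All generators are pure functions of (spec, seed): identical inputs give
## identical outputs, and every output carries its truth record.

#' Specification for a synthetic behavioral recording
#'
#' @param true_gain Compensatory gain (0–1.5 typical; >= 0).
#' @param noise_sd Gaussian measurement noise on the eye angle, degrees.
#' @param saccade_rate Saccadic artifact rate, events/min.
#' @param saccade_amplitude Saccade step size, degrees.
#' @param missed_frame_prob Per-frame probability that the camera re-emits
#'   the previous frame (a duplicated sample, as transient slowdowns do).
#' @param sampling_rate Acquisition rate, Hz (default 200).
#' @param seed Integer seed.
#' @return An object of class `synthetic_behavior_spec`.
#' @export
synthetic_behavior_spec <- function(true_gain = 1, noise_sd = 0.2,
                                    saccade_rate = 1, saccade_amplitude = 5,
                                    missed_frame_prob = 0.02,
                                    sampling_rate = 200, seed = 1L) {
  check_number(true_gain, "true_gain", nonneg = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(saccade_rate, "saccade_rate", nonneg = TRUE)
  check_number(saccade_amplitude, "saccade_amplitude", nonneg = TRUE)
  check_number(missed_frame_prob, "missed_frame_prob", nonneg = TRUE)
  if (missed_frame_prob >= 1) stop_invalid("`missed_frame_prob` must be < 1")
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  structure(as.list(environment()), class = "synthetic_behavior_spec")
}

#' Generate a synthetic torsional eye trace for a step-tilt experiment
#'
#' The eye counter-rotates against the platform: the noiseless eye angle is
#' `-true_gain` times the platform angle (nose-up platform positive, so a
#' gain-1 eye peaks at -35 deg/s when the platform peaks at +35 deg/s).
#' Saccadic artifacts are step offsets with an exponential return (tau 0.5
#' s) at Poisson times; missed frames duplicate the previous sample (same
#' timestamp and value), which [resample_spline()] later corrects.
#'
#' @param spec A [synthetic_behavior_spec()].
#' @param protocol A behavior protocol from [build_protocol()].
#' @return List with `trace` (an [eye_trace()]), `platform` (sampled
#'   platform trace), `onsets`, and `truth` (gain, saccade times, duplicated
#'   sample indices).
#' @export
generate_eye_trace <- function(spec, protocol) {
  if (!inherits(spec, "synthetic_behavior_spec")) {
    stop_invalid("`spec` must be a synthetic_behavior_spec")
  }
  sampled <- sample_protocol(protocol, dt = 1 / spec$sampling_rate)
  plat <- sampled$trace
  n <- nrow(plat)
  dur_min <- plat$time[n] / 60
  with_seed(spec$seed, {
    eye <- -spec$true_gain * plat$angle
    # saccadic artifacts: instantaneous offset, exponential return
    n_sac <- stats::rpois(1, spec$saccade_rate * dur_min)
    sac_times <- sort(stats::runif(n_sac, 0, plat$time[n]))
    if (n_sac > 0) {
      signs <- sample(c(-1, 1), n_sac, replace = TRUE)
      for (k in seq_len(n_sac)) {
        after <- plat$time >= sac_times[k]
        eye[after] <- eye[after] +
          signs[k] * spec$saccade_amplitude *
          exp(-(plat$time[after] - sac_times[k]) / 0.5)
      }
    }
    eye <- eye + stats::rnorm(n, 0, spec$noise_sd)
    # duplicated samples emulating transient camera slowdowns
    dup <- which(stats::runif(n) < spec$missed_frame_prob)
    dup <- dup[dup > 1L]
    tt <- plat$time; aa <- eye
    if (length(dup)) {
      ord <- rep(seq_len(n), times = 1 + (seq_len(n) %in% dup))
      # a duplicated frame repeats the previous frame's timestamp and value
      tt <- tt[ord]; aa <- aa[ord]
      rep_idx <- which(duplicated(ord))
      tt[rep_idx] <- tt[rep_idx - 1L]
      aa[rep_idx] <- aa[rep_idx - 1L]
    }
    list(
      trace = eye_trace(tt, aa, sampling_rate = spec$sampling_rate),
      platform = plat,
      onsets = sampled$onsets,
      truth = list(gain = spec$true_gain, saccade_times = sac_times,
                   duplicated_frames = dup, seed = spec$seed)
    )
  })
}

#' Specification for a synthetic tilt-responsive neuron
#'
#' @param preferred_direction `"nose-up"` or `"nose-down"`.
#' @param baseline_F Baseline fluorescence, arbitrary units (> 0).
#' @param response_slope dF/F per degree of eccentricity.
#' @param response_intercept dF/F at zero eccentricity.
#' @param decay_tau Indicator decay constant, seconds (default 3, the order
#'   of GCaMP6s; scoring uses the early peak so the exact value is not
#'   critical).
#' @param noise_sd Gaussian fluorescence noise, same units as `baseline_F`.
#' @param volume_rate Imaging rate, volumes/s (default 3).
#' @param seed Integer seed.
#' @return An object of class `synthetic_neuron_spec`.
#' @export
synthetic_neuron_spec <- function(preferred_direction = c("nose-up", "nose-down"),
                                  baseline_F = 100, response_slope = 0.02,
                                  response_intercept = 0, decay_tau = 3,
                                  noise_sd = 1, volume_rate = 3, seed = 1L) {
  preferred_direction <- match.arg(preferred_direction)
  check_number(baseline_F, "baseline_F", positive = TRUE)
  check_number(decay_tau, "decay_tau", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(volume_rate, "volume_rate", positive = TRUE)
  structure(as.list(environment()), class = "synthetic_neuron_spec")
}

#' Generate a synthetic TIPM fluorescence trace for one trial
#'
#' Fluorescence sits at `baseline_F` through the baseline and eccentric
#' hold. If the tilt direction matches the neuron's preferred direction, the
#' trace on return starts at `baseline_F * (1 + dff_true)` and decays
#' exponentially with `decay_tau`, where `dff_true = max(0, intercept +
#' slope * |tilt_angle|)` — the recorded signal is the decay of the response
#' built up while tilted. Non-preferred tilts give no response
#' (unidirectional tuning). Gaussian noise is added throughout.
#'
#' @param spec A [synthetic_neuron_spec()].
#' @param trial A [trial_timeline()].
#' @param tilt_angle Signed tilt, degrees (positive nose-up; |angle| <= 30).
#' @return List with `trace` (an [roi_trace()]) and `truth` (`dff_true`,
#'   direction match, frame indices).
#' @export
generate_tipm_trace <- function(spec, trial = trial_timeline(), tilt_angle) {
  if (!inherits(spec, "synthetic_neuron_spec")) {
    stop_invalid("`spec` must be a synthetic_neuron_spec")
  }
  check_number(tilt_angle, "tilt_angle")
  if (abs(tilt_angle) > 30) stop_invalid("|tilt_angle| must be <= 30 deg")
  dt <- 1 / spec$volume_rate
  total <- trial_duration(trial)
  times <- seq(0, total, by = dt)
  n <- length(times)
  t_step <- trial$baseline_s
  t_return <- trial$baseline_s + trial$step_duration_s + trial$hold_s
  step_frame <- which(times >= t_step)[1]
  return_frame <- which(times >= t_return)[1]

  dir_of_tilt <- if (tilt_angle >= 0) "nose-up" else "nose-down"
  matches <- dir_of_tilt == spec$preferred_direction
  dff_true <- if (matches) {
    max(0, spec$response_intercept + spec$response_slope * abs(tilt_angle))
  } else 0

  f <- rep(spec$baseline_F, n)
  post <- times >= times[return_frame]
  f[post] <- spec$baseline_F *
    (1 + dff_true * exp(-(times[post] - times[return_frame]) / spec$decay_tau))
  f <- with_seed(spec$seed, pmax(0, f + stats::rnorm(n, 0, spec$noise_sd)))
  list(
    trace = roi_trace(f, volume_rate = spec$volume_rate,
                      event_frames = c(step = step_frame, return = return_frame)),
    truth = list(dff_true = dff_true, preferred_match = matches,
                 step_frame = step_frame, return_frame = return_frame,
                 tilt_angle = tilt_angle, seed = spec$seed)
  )
}

#' Specification for a synthetic NMJ image
#'
#' Emulates an alpha-bungarotoxin-style label: an elongated muscle fiber at
#' moderate intensity with bright synaptic puncta (disks) scattered on it.
#' Default noise gives contrast-to-noise (puncta - fiber)/noise = 5.
#'
#' @param image_shape `c(nrow, ncol)` pixels.
#' @param pixel_size_um um/pixel.
#' @param target_fraction Fraction of the ROI to cover with puncta
#'   (0 <= f < 1).
#' @param particle_radius_px `c(mean, sd)` of puncta radii in pixels.
#' @param fiber_intensity,puncta_intensity Grayscale levels in (0, 1];
#'   puncta must be brighter than fiber.
#' @param noise_sd Gaussian pixel noise.
#' @param seed Integer seed.
#' @return An object of class `synthetic_nmj_spec`.
#' @export
synthetic_nmj_spec <- function(image_shape = c(256, 256), pixel_size_um = 0.31,
                               target_fraction = 0.05,
                               particle_radius_px = c(3, 0.5),
                               fiber_intensity = 0.1, puncta_intensity = 0.5,
                               noise_sd = 0.08, seed = 1L) {
  check_number(target_fraction, "target_fraction", nonneg = TRUE)
  if (target_fraction >= 1) stop_invalid("`target_fraction` must be < 1")
  check_number(fiber_intensity, "fiber_intensity", positive = TRUE)
  check_number(puncta_intensity, "puncta_intensity", positive = TRUE)
  if (puncta_intensity <= fiber_intensity) {
    stop_invalid("`puncta_intensity` must exceed `fiber_intensity`")
  }
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  structure(as.list(environment()), class = "synthetic_nmj_spec")
}

#' Generate a synthetic NMJ image with known labeled fraction
#'
#' Builds an elongated elliptical muscle ROI filled at `fiber_intensity`,
#' then drops puncta disks (radius ~ Normal, clipped >= 1 px) at uniform
#' positions inside the ROI until the true mask fraction reaches
#' `target_fraction`, and finally adds Gaussian noise. The returned truth
#' mask and fraction are computed before noise.
#'
#' @param spec A [synthetic_nmj_spec()].
#' @param max_attempts Upper bound on placement attempts before giving up
#'   (guards an unreachable `target_fraction`).
#' @return List with `image` (matrix in \[0, 1\]), `roi` (a
#'   [muscle_roi()]), and `truth` (binary mask, true fraction, puncta count
#'   and radii).
#' @export
generate_nmj_image <- function(spec, max_attempts = 20000L) {
  if (!inherits(spec, "synthetic_nmj_spec")) {
    stop_invalid("`spec` must be a synthetic_nmj_spec")
  }
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  # elongated ellipse polygon as the muscle outline
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  cx0 <- nc / 2; cy0 <- nr / 2
  poly <- cbind(cx0 + 0.42 * nc * cos(th), cy0 + 0.16 * nr * sin(th))
  roi <- muscle_roi(poly, muscle = "SO")
  rmask <- roi_mask(roi, c(nr, nc))
  roi_idx <- which(rmask)
  n_roi <- length(roi_idx)

  img <- matrix(0, nr, nc)
  img[rmask] <- spec$fiber_intensity
  truth <- matrix(FALSE, nr, nc)
  radii <- numeric(0)

  with_seed(spec$seed, {
    attempts <- 0L
    # pixel center coordinates for disk rasterization
    rowpos <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)
    colpos <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
    while (sum(truth) / n_roi < spec$target_fraction) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_invalid("target_fraction %.3f unreachable after %d attempts",
                     spec$target_fraction, max_attempts)
      }
      ctr <- roi_idx[sample.int(n_roi, 1)]
      cy <- ((ctr - 1) %% nr) + 0.5
      cx <- ((ctr - 1) %/% nr) + 0.5
      r <- max(1, stats::rnorm(1, spec$particle_radius_px[1],
                               spec$particle_radius_px[2]))
      disk <- ((rowpos - cy)^2 + (colpos - cx)^2) <= r^2 & rmask
      truth <- truth | disk
      radii <- c(radii, r)
    }
    img[truth] <- spec$puncta_intensity
    true_fraction <- sum(truth) / n_roi
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- matrix(pmin(1, pmax(0, img)), nr, nc)
    list(image = img, roi = roi,
         truth = list(mask = truth, true_fraction = true_fraction,
                      n_puncta = length(radii), radii_px = radii,
                      seed = spec$seed))
  })
}

#' Default plateau-shaped ontogeny configuration
#'
#' Study-scale defaults for the synthetic ontogeny experiment: ages 3, 5, 7,
#' 9 and 15 dpf with gains rising to a plateau at 9 dpf (means 0.30, 0.55,
#' 0.70, 0.80, 0.80, SD 0.10, N = 8 fish/age), dF/F means rising 3–5 dpf
#' then flat, and NMJ % area labeled rising across the same span.
#'
#' @param flat If `TRUE`, all age means are set to their 3 dpf value
#'   (null configuration for type-I-error checks).
#' @return Config list for [generate_ontogeny_dataset()].
#' @export
ontogeny_config_plateau <- function(flat = FALSE) {
  cfg <- list(
    ages = c(3, 5, 7, 9, 15),
    n_fish = 8,
    n_neurons_per_fish = 12,
    gain = list(mean = c(0.30, 0.55, 0.70, 0.80, 0.80), sd = 0.10),
    dff = list(mean = c(0.35, 0.80, 0.85, 0.85, 0.85), sd = 0.25),
    nmj = list(mean = c(2.0, 4.0, 5.5, 6.5, 6.5), sd = 1.0)
  )
  if (flat) {
    cfg$gain$mean[] <- cfg$gain$mean[1]
    cfg$dff$mean[] <- cfg$dff$mean[1]
    cfg$nmj$mean[] <- cfg$nmj$mean[1]
  }
  cfg
}

#' Generate a multi-age, multi-fish synthetic ontogeny dataset
#'
#' Draws per-fish VOR gains, per-neuron dF/F responses (longitudinally
#' correlated within neuron across ages) and per-fish NMJ % area labeled
#' from the per-age means/SDs in `config`, emitting tidy long-format tables
#' keyed by fish, age and neuron. Deterministic per seed.
#'
#' @param config Config list as from [ontogeny_config_plateau()]: `ages`,
#'   `n_fish` (>= 2), `n_neurons_per_fish`, and per-arm `mean` (one per age)
#'   and `sd`.
#' @param seed Integer seed.
#' @return List of data frames `behavior` (fish, age, gain), `tipm` (fish,
#'   neuron, age, dff), `nmj` (fish, age, percent_area), plus the `config`
#'   echo.
#' @export
generate_ontogeny_dataset <- function(config = ontogeny_config_plateau(),
                                      seed = 1L) {
  ages <- config$ages
  nf <- config$n_fish
  if (nf < 2) stop_invalid("need >= 2 fish per group")
  for (arm in c("gain", "dff", "nmj")) {
    if (length(config[[arm]]$mean) != length(ages)) {
      stop_invalid("`%s$mean` must have one value per age", arm)
    }
  }
  nn <- config$n_neurons_per_fish
  with_seed(seed, {
    behavior <- do.call(rbind, lapply(seq_along(ages), function(i) {
      data.frame(fish = paste0("f", seq_len(nf), "_a", ages[i]),
                 age = ages[i],
                 gain = pmax(0, stats::rnorm(nf, config$gain$mean[i],
                                             config$gain$sd)))
    }))
    # longitudinal neurons: per-neuron random offset shared across ages
    tipm <- do.call(rbind, lapply(seq_len(nf), function(fi) {
      offs <- stats::rnorm(nn, 0, config$dff$sd / 2)
      do.call(rbind, lapply(seq_along(ages), function(i) {
        data.frame(fish = paste0("f", fi),
                   neuron = paste0("f", fi, "_n", seq_len(nn)),
                   age = ages[i],
                   dff = pmax(0, config$dff$mean[i] + offs +
                                stats::rnorm(nn, 0, config$dff$sd)))
      }))
    }))
    nmj <- do.call(rbind, lapply(seq_along(ages), function(i) {
      data.frame(fish = paste0("f", seq_len(nf), "_a", ages[i]),
                 age = ages[i],
                 percent_area = pmax(0, stats::rnorm(nf, config$nmj$mean[i],
                                                     config$nmj$sd)))
    }))
    rownames(behavior) <- rownames(tipm) <- rownames(nmj) <- NULL
    list(behavior = behavior, tipm = tipm, nmj = nmj, config = config,
         seed = seed)
  })
}
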
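## Stimulus construction: trapezoidal tilt steps, trial timelines, protocols.

#' Define a trapezoidal tilt step
#'
#' A single platform rotation following a trapezoidal velocity profile:
#' constant acceleration up to `peak_velocity`, a constant-velocity plateau,
#' and symmetric deceleration back to rest. When
#' `peak_velocity^2 / peak_acceleration > |amplitude|` the commanded plateau
#' is unreachable and [trapezoid_profile()] degrades gracefully to a
#' triangular profile (with a warning), peaking at
#' `sqrt(|amplitude| * peak_acceleration)`.
#'
#' @param amplitude Signed step amplitude in degrees (positive = nose-up).
#' @param peak_velocity Peak angular velocity in deg/s (> 0).
#' @param peak_acceleration Peak angular acceleration in deg/s^2 (> 0).
#' @param start_angle Platform angle at step onset, degrees.
#' @return An object of class `trapezoid_step`.
#' @examples
#' step <- trapezoid_step(15, 35, 150)
#' prof <- trapezoid_profile(step, dt = 1 / 200)
#' max(prof$velocity) # 35 deg/s plateau
#' @export
trapezoid_step <- function(amplitude, peak_velocity, peak_acceleration,
                           start_angle = 0) {
  check_number(amplitude, "amplitude")
  if (amplitude == 0) stop_invalid("`amplitude` must be non-zero")
  check_number(peak_velocity, "peak_velocity", positive = TRUE)
  check_number(peak_acceleration, "peak_acceleration", positive = TRUE)
  check_number(start_angle, "start_angle")
  structure(
    list(amplitude = amplitude, peak_velocity = peak_velocity,
         peak_acceleration = peak_acceleration, start_angle = start_angle),
    class = "trapezoid_step"
  )
}

#' @export
print.trapezoid_step <- function(x, ...) {
  cat(sprintf("<trapezoid_step> %+g deg at %g deg/s, %g deg/s^2 (from %g deg)\n",
              x$amplitude, x$peak_velocity, x$peak_acceleration, x$start_angle))
  invisible(x)
}

# Closed-form phase durations for a (possibly triangular) trapezoid step.
trapezoid_phases <- function(step) {
  A <- abs(step$amplitude)
  v <- step$peak_velocity
  a <- step$peak_acceleration
  triangular <- (v^2 / a) > A + 1e-12
  if (triangular) {
    v_max <- sqrt(A * a)
    t_ramp <- v_max / a
    t_plateau <- 0
  } else {
    v_max <- v
    t_ramp <- v / a
    t_plateau <- (A - v^2 / a) / v
  }
  list(v_max = v_max, t_ramp = t_ramp, t_plateau = t_plateau,
       t_total = 2 * t_ramp + t_plateau, triangular = triangular)
}

#' Sample a trapezoidal velocity profile
#'
#' Evaluates the step's angle and velocity analytically on a uniform time
#' grid (the exact end time is appended so the sampled angle terminates at
#' `start_angle + amplitude`). The angle column is the exact integral of the
#' velocity column, so the sampled profile integrates to the amplitude to
#' machine precision.
#'
#' @param step A [trapezoid_step()].
#' @param dt Sampling interval in seconds (> 0).
#' @return A data frame with columns `time` (s), `angle` (deg), `velocity`
#'   (deg/s).
#' @export
trapezoid_profile <- function(step, dt) {
  if (!inherits(step, "trapezoid_step")) stop_invalid("`step` must be a trapezoid_step")
  check_number(dt, "dt", positive = TRUE)
  ph <- trapezoid_phases(step)
  if (ph$triangular) {
    warning(sprintf(
      "peak velocity %g deg/s unreachable over %g deg at %g deg/s^2; emitting triangular profile (peak %g deg/s)",
      step$peak_velocity, abs(step$amplitude), step$peak_acceleration, ph$v_max),
      call. = FALSE)
  }
  tt <- seq(0, ph$t_total, by = dt)
  # the exact end time and phase breakpoints (ramp apex, plateau end) are
  # inserted so sampled extrema and the final angle are exact
  tt <- sort(unique(c(tt, ph$t_ramp, ph$t_ramp + ph$t_plateau, ph$t_total)))
  trapezoid_eval(step, tt)
}

# Analytic angle/velocity of a trapezoid step at arbitrary times.
trapezoid_eval <- function(step, tt) {
  ph <- trapezoid_phases(step)
  s <- sign(step$amplitude)
  a <- step$peak_acceleration
  v <- ph$v_max
  t1 <- ph$t_ramp
  t2 <- ph$t_ramp + ph$t_plateau
  tot <- ph$t_total
  A <- abs(step$amplitude)

  vel <- numeric(length(tt))
  ang <- numeric(length(tt))
  i1 <- tt < t1
  i2 <- tt >= t1 & tt < t2
  i3 <- tt >= t2
  vel[i1] <- a * tt[i1]
  vel[i2] <- v
  vel[i3] <- pmax(0, v - a * (tt[i3] - t2))
  ang[i1] <- 0.5 * a * tt[i1]^2
  ang[i2] <- 0.5 * a * t1^2 + v * (tt[i2] - t1)
  ang[i3] <- A - 0.5 * a * pmax(0, tot - tt[i3])^2
  ang[tt >= tot] <- A
  vel[tt >= tot] <- 0
  data.frame(time = tt, angle = step$start_angle + s * ang, velocity = s * vel)
}

#' Microstep schedule for a sampled motion profile
#'
#' Converts a monotone angle profile into the ordered times at which a
#' stepper motor emitting fixed-size microsteps must fire so that the
#' cumulative microstep count tracks the profile. The count is
#' `floor(|total excursion| / microstep_deg)`; the sub-microstep residual is
#' dropped (hardware cannot emit fractional steps). Inter-step intervals
#' shrink as velocity rises.
#'
#' @param profile Data frame with `time` and `angle` columns (as returned by
#'   [trapezoid_profile()]); the angle must be monotone.
#' @param microstep_deg Microstep size in degrees (> 0); the hardware default
#'   is 0.0072.
#' @return Numeric vector of step times (seconds).
#' @export
microstep_schedule <- function(profile, microstep_deg = 0.0072) {
  check_number(microstep_deg, "microstep_deg", positive = TRUE)
  if (!all(c("time", "angle") %in% names(profile))) {
    stop_invalid("`profile` needs `time` and `angle` columns")
  }
  rel <- profile$angle - profile$angle[1]
  d <- diff(rel)
  if (any(d > 1e-9) && any(d < -1e-9)) {
    stop_invalid("angle profile is not monotone during motion")
  }
  excursion <- abs(rel[length(rel)])
  n <- floor(excursion / microstep_deg + 1e-9)
  if (n == 0) return(numeric(0))
  targets <- (seq_len(n)) * microstep_deg
  # cumulative |angle| is non-decreasing; interpolate crossing times
  ar <- abs(rel)
  keep <- c(TRUE, diff(ar) > 0)  # drop flat segments for interpolation
  stats::approx(ar[keep], profile$time[keep], xout = targets,
                ties = "ordered", rule = 2)$y
}

#' Trial timeline for tilt-in-place imaging
#'
#' The canonical trial: a pre-stimulus baseline at horizontal, a rapid
#' eccentric step, a hold at the eccentric angle, a rapid return, and a
#' post-return period at horizontal during which the decaying response is
#' imaged. Defaults follow the imaging paradigm: 15 s baseline, ~5 ms step,
#' 5 s hold, ~5 ms return, 20 s post.
#'
#' @param baseline_s,step_duration_s,hold_s,return_duration_s,post_s Phase
#'   durations in seconds (all >= 0).
#' @param eccentric_angle Signed tilt angle in degrees (positive = nose-up).
#' @return An object of class `trial_timeline`.
#' @export
trial_timeline <- function(baseline_s = 15, step_duration_s = 0.005,
                           hold_s = 5, return_duration_s = 0.005,
                           post_s = 20, eccentric_angle = 15) {
  for (nm in c("baseline_s", "step_duration_s", "hold_s",
               "return_duration_s", "post_s")) {
    check_number(get(nm), nm, nonneg = TRUE)
  }
  check_number(eccentric_angle, "eccentric_angle")
  structure(
    list(baseline_s = baseline_s, step_duration_s = step_duration_s,
         hold_s = hold_s, return_duration_s = return_duration_s,
         post_s = post_s, eccentric_angle = eccentric_angle),
    class = "trial_timeline"
  )
}

trial_duration <- function(tl) {
  tl$baseline_s + tl$step_duration_s + tl$hold_s + tl$return_duration_s + tl$post_s
}

#' Step-train protocol
#'
#' An ordered train of trapezoid steps separated by stationary holds,
#' repeated over cycles, as used for behavioral step-tilt experiments.
#'
#' @param steps List of [trapezoid_step()] objects making up one cycle.
#' @param cycles Number of cycles (>= 1).
#' @param sampling_rate Nominal acquisition rate in Hz.
#' @param inter_step_s Stationary hold after each step, seconds.
#' @return An object of class `step_train`.
#' @export
step_train <- function(steps, cycles = 50, sampling_rate = 200,
                       inter_step_s = 7.5) {
  if (!length(steps) || !all(vapply(steps, inherits, TRUE, "trapezoid_step"))) {
    stop_invalid("`steps` must be a non-empty list of trapezoid_step objects")
  }
  check_number(cycles, "cycles", positive = TRUE)
  check_number(sampling_rate, "sampling_rate", positive = TRUE)
  check_number(inter_step_s, "inter_step_s", nonneg = TRUE)
  structure(
    list(steps = steps, cycles = as.integer(cycles),
         steps_per_cycle = length(steps),
         sampling_rate = sampling_rate, inter_step_s = inter_step_s),
    class = "step_train"
  )
}

#' @export
print.step_train <- function(x, ...) {
  cat(sprintf("<step_train> %d cycles x %d steps at %g Hz (hold %g s)\n",
              x$cycles, x$steps_per_cycle, x$sampling_rate, x$inter_step_s))
  invisible(x)
}

#' Build a named stimulation protocol
#'
#' Three protocol kinds are supported:
#' \describe{
#'   \item{`behavior`}{50 cycles of four +/-15 deg steps toward and away from
#'     the horizon (0 to +15 to 0 to -15 to 0) at 35 deg/s peak velocity and
#'     150 deg/s^2 peak acceleration; `fast = TRUE` switches to the 90 deg/s,
#'     600 deg/s^2 control.}
#'   \item{`tipm_gradient`}{Sensitivity-mapping trials: each amplitude of
#'     `amplitudes` (default 7.5, 15, 22.5, 30 deg) presented `repeats` times
#'     in one pitch `direction`, trial order randomized under `seed`.}
#'   \item{`tipm_longitudinal`}{A single 25 deg step presented `repeats`
#'     times.}
#' }
#' The randomized order is a seeded permutation recorded in the returned
#' trial table, so the same seed reproduces the same protocol exactly.
#'
#' @param kind One of `"behavior"`, `"tipm_gradient"`, `"tipm_longitudinal"`.
#' @param config Named list of overrides (`amplitudes`, `repeats`,
#'   `direction`, `cycles`, `fast`, `peak_velocity`, `peak_acceleration`,
#'   `inter_step_s`, `sampling_rate`).
#' @param seed Integer seed controlling trial-order randomization.
#' @return For `behavior`, a list with the `step_train` and per-cycle step
#'   description; for the TIPM kinds, a list with a `trials` data frame and
#'   the `trial_timeline` template.
#' @export
build_protocol <- function(kind = c("behavior", "tipm_gradient", "tipm_longitudinal"),
                           config = list(), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  if (kind == "behavior") {
    fast <- isTRUE(cfg("fast", FALSE))
    v <- cfg("peak_velocity", if (fast) 90 else 35)
    a <- cfg("peak_acceleration", if (fast) 600 else 150)
    amp <- cfg("amplitude", 15)
    steps <- list(
      trapezoid_step(+amp, v, a, start_angle = 0),
      trapezoid_step(-amp, v, a, start_angle = +amp),
      trapezoid_step(-amp, v, a, start_angle = 0),
      trapezoid_step(+amp, v, a, start_angle = -amp)
    )
    train <- step_train(steps, cycles = cfg("cycles", 50),
                        sampling_rate = cfg("sampling_rate", 200),
                        inter_step_s = cfg("inter_step_s", 7.5))
    return(structure(list(kind = kind, train = train, seed = seed),
                     class = "vor_protocol"))
  }
  timeline <- trial_timeline()
  if (kind == "tipm_gradient") {
    amplitudes <- cfg("amplitudes", c(7.5, 15, 22.5, 30))
    repeats <- cfg("repeats", 5)
    direction <- match.arg(cfg("direction", "nose-up"), c("nose-up", "nose-down"))
    amps <- rep(amplitudes, each = repeats)
    ord <- with_seed(seed, sample.int(length(amps)))
    trials <- data.frame(
      trial = seq_along(amps),
      amplitude_deg = amps[ord],
      direction = direction,
      stringsAsFactors = FALSE
    )
  } else {
    repeats <- cfg("repeats", 5)
    direction <- match.arg(cfg("direction", "nose-up"), c("nose-up", "nose-down"))
    trials <- data.frame(
      trial = seq_len(repeats),
      amplitude_deg = cfg("amplitude", 25),
      direction = direction,
      stringsAsFactors = FALSE
    )
  }
  structure(list(kind = kind, trials = trials, timeline = timeline, seed = seed),
            class = "vor_protocol")
}

#' Sample a behavior protocol into a continuous platform trace
#'
#' Concatenates the cycle's trapezoid steps and stationary holds into one
#' uniformly sampled platform angle/velocity trace, and returns the command
#' onset time, direction and within-cycle position of every step.
#'
#' @param protocol A `behavior` protocol from [build_protocol()].
#' @param dt Sampling interval in seconds; defaults to the train's rate.
#' @return List with `trace` (data frame `time`, `angle`, `velocity`) and
#'   `onsets` (data frame `step_id`, `cycle`, `step_in_cycle`, `onset_time`,
#'   `direction`, `peak_velocity`).
#' @export
sample_protocol <- function(protocol, dt = NULL) {
  if (!inherits(protocol, "vor_protocol") || protocol$kind != "behavior") {
    stop_invalid("`protocol` must be a behavior protocol")
  }
  train <- protocol$train
  if (is.null(dt)) dt <- 1 / train$sampling_rate
  hold_n <- round(train$inter_step_s / dt)

  onset <- numeric(0); direction <- numeric(0); step_in_cycle <- integer(0)
  t_cursor <- 0
  one_cycle_angle <- list(); one_cycle_vel <- list()
  for (k in seq_along(train$steps)) {
    stp <- train$steps[[k]]
    tot <- trapezoid_phases(stp)$t_total
    # uniform samples covering the motion (the hold then sits at the end angle)
    n_step <- ceiling(tot / dt - 1e-9)
    p <- trapezoid_eval(stp, (seq_len(n_step) - 1) * dt)
    onset <- c(onset, t_cursor)
    step_in_cycle <- c(step_in_cycle, k)
    direction <- c(direction, sign(stp$amplitude))
    one_cycle_angle[[2 * k - 1]] <- p$angle
    one_cycle_vel[[2 * k - 1]] <- p$velocity
    t_cursor <- t_cursor + n_step * dt
    end_angle <- stp$start_angle + stp$amplitude
    one_cycle_angle[[2 * k]] <- rep(end_angle, hold_n)
    one_cycle_vel[[2 * k]] <- rep(0, hold_n)
    t_cursor <- t_cursor + hold_n * dt
  }
  cyc_angle <- unlist(one_cycle_angle)
  cyc_vel <- unlist(one_cycle_vel)
  cycle_dur <- t_cursor

  n_cyc <- train$cycles
  angle <- rep(cyc_angle, n_cyc)
  vel <- rep(cyc_vel, n_cyc)
  time <- seq_along(angle) * dt - dt
  onsets <- data.frame(
    step_id = seq_len(n_cyc * train$steps_per_cycle),
    cycle = rep(seq_len(n_cyc), each = train$steps_per_cycle),
    step_in_cycle = rep(step_in_cycle, n_cyc),
    onset_time = rep(onset, n_cyc) + rep((seq_len(n_cyc) - 1) * cycle_dur,
                                         each = train$steps_per_cycle),
    direction = rep(direction, n_cyc),
    peak_velocity = rep(vapply(train$steps, function(s) trapezoid_phases(s)$v_max,
                               numeric(1)), n_cyc)
  )
  list(trace = data.frame(time = time, angle = angle, velocity = vel),
       onsets = onsets)
}
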
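#' Modified raised-cosine velocity profile
#'
#' Raised-cosine ramp up to `peak`, a held plateau, then a raised-cosine
#' ramp back down. With the defaults (0.8 s rise, 0.4 s hold, 0.8 s fall
#' at 60 Hz) this reproduces the 2-s inertial stimulus with its
#' 8.5 deg/s plateau.
#'
#' @param peak Plateau velocity (deg/s).
#' @param rise,fall Ramp durations (s); a zero ramp is allowed.
#' @param hold Plateau duration (s).
#' @param rate Sampling rate (Hz).
#' @param baseline Velocity at the start and end of the profile (deg/s);
#'   the ramps interpolate between `baseline` and `peak`.
#' @return A tibble of class `velocity_profile` with columns `time` (s)
#'   and `velocity` (deg/s).
#' @examples
#' prof <- raised_cosine_profile()
#' max(prof$velocity)  # 8.5
#' @export
raised_cosine_profile <- function(peak = 8.5, rise = 0.8, hold = 0.4,
                                  fall = 0.8, rate = 60, baseline = 0) {
  if (rate <= 0 || rise < 0 || fall < 0 || hold < 0) {
    abort("durations must be non-negative and `rate` positive")
  }
  total <- rise + hold + fall
  if (total <= 0) abort("profile must have positive total duration")
  t <- seq(0, total, by = 1 / rate)
  ramp <- function(u) (1 - cos(pi * u)) / 2  # 0 -> 1, C1-smooth
  v <- numeric(length(t))
  in_rise <- t < rise
  in_hold <- t >= rise & t <= rise + hold
  in_fall <- t > rise + hold
  v[in_rise] <- baseline + (peak - baseline) * ramp(t[in_rise] / rise)
  v[in_hold] <- peak
  if (fall > 0) {
    v[in_fall] <- baseline + (peak - baseline) *
      ramp((total - t[in_fall]) / fall)
  } else {
    v[in_fall] <- baseline
  }
  out <- tibble(time = t, velocity = v)
  attr(out, "profile_meta") <- list(peak = peak, rise = rise, hold = hold,
                                    fall = fall, rate = rate,
                                    baseline = baseline)
  class(out) <- c("velocity_profile", class(out))
  out
}

#' Per-condition visual velocity schedule
#'
#' Builds the pre-motion and during-motion visual velocity profiles for
#' one trial. Before self-motion the visual velocity is constant at the
#' condition's initial value (0 for `Acceleration`, the desired velocity
#' for `Constant`, twice the desired velocity for `Deceleration`). At
#' self-motion onset the velocity ramps to the desired value following
#' the raised-cosine shape, is held for 0.4 s, and ramps back to the
#' initial value over 0.8 s; in `Constant` the schedule is flat
#' throughout.
#'
#' @param condition One of `"Acceleration"`, `"Constant"`,
#'   `"Deceleration"`.
#' @param desired_velocity Visual velocity during self-motion (deg/s,
#'   signed).
#' @param pre_duration Duration of the pre-motion epoch (s).
#' @param rise,hold,fall Ramp/plateau durations of the during-motion
#'   epoch (s).
#' @param rate Sampling rate (Hz).
#' @return A list with `velocity_profile` tibbles `pre` and `during`.
#' @export
condition_schedule <- function(condition, desired_velocity,
                               pre_duration = 2, rise = 0.8, hold = 0.4,
                               fall = 0.8, rate = 60) {
  condition <- match.arg(condition,
                         c("Acceleration", "Constant", "Deceleration"))
  v0 <- switch(condition,
               Acceleration = 0,
               Constant = desired_velocity,
               Deceleration = 2 * desired_velocity)
  t_pre <- seq(0, pre_duration, by = 1 / rate)
  pre <- tibble(time = t_pre, velocity = rep(v0, length(t_pre)))
  class(pre) <- c("velocity_profile", class(pre))
  during <- if (condition == "Constant") {
    t_dur <- seq(0, rise + hold + fall, by = 1 / rate)
    flat <- tibble(time = t_dur, velocity = rep(desired_velocity, length(t_dur)))
    class(flat) <- c("velocity_profile", class(flat))
    flat
  } else {
    raised_cosine_profile(peak = desired_velocity, rise = rise, hold = hold,
                          fall = fall, rate = rate, baseline = v0)
  }
  list(condition = condition, pre = pre, during = during)
}
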
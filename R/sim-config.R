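#' Simulation configuration for the synthetic walking cohort
#'
#' Bundles the acquisition constants and cohort design of the emulated
#' experiment: treadmill walking at three speeds with a smartphone-sized IMU
#' carried in the hand, trouser pocket or jacket pocket, recorded at 1259 Hz
#' alongside 100 Hz optical marker data, for trials lasting 80--110 s
#' (about 80 +/- 5 strides).
#'
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param speeds Treadmill speeds in m/s.
#' @param placements Carry placements; artifact level increases from hand to
#'   trouser to jacket.
#' @param trial_duration Length-2 numeric: admissible trial duration range in
#'   seconds. Actual durations are set so that roughly `stride_target` strides
#'   fit, then clamped to this range.
#' @param fs_imu IMU sampling rate in Hz.
#' @param fs_mocap Marker sampling rate in Hz.
#' @param placement_noise Named numeric: broadband accelerometer artifact
#'   standard deviation in g per placement. The default ordering
#'   (jacket > trouser > hand) reflects the loosest coupling in the jacket.
#' @param marker_noise Marker measurement noise SD in mm.
#' @param stride_target,stride_target_sd Target stride count per trial and its
#'   between-trial SD.
#' @param speed_ref,speed_exponent Stride time scales as
#'   `base_stride_time * (speed_ref/speed)^speed_exponent`.
#' @param seed Integer master seed for cohort generation.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       speeds = c(1.0, 1.25, 1.5),
                       placements = c("hand", "trouser", "jacket"),
                       trial_duration = c(80, 110),
                       fs_imu = 1259,
                       fs_mocap = 100,
                       placement_noise = c(hand = 0.04, trouser = 0.07,
                                           jacket = 0.13),
                       marker_noise = 0.5,
                       stride_target = 80,
                       stride_target_sd = 2.5,
                       speed_ref = 1.25,
                       speed_exponent = 0.35,
                       seed = 20201L) {
  check_scalar(n_subjects, "n_subjects")
  if (!is.numeric(speeds) || length(speeds) < 1 || any(speeds <= 0)) {
    abort("`speeds` must be positive.")
  }
  placements <- match.arg(placements, c("hand", "trouser", "jacket"),
                          several.ok = TRUE)
  if (length(trial_duration) != 2 || any(trial_duration <= 0) ||
      diff(trial_duration) < 0) {
    abort("`trial_duration` must be an increasing positive range.")
  }
  check_scalar(fs_imu, "fs_imu")
  check_scalar(fs_mocap, "fs_mocap")
  if (fs_imu < fs_mocap) abort("`fs_imu` must be >= `fs_mocap`.")
  if (is.null(names(placement_noise)) ||
      !all(placements %in% names(placement_noise))) {
    abort("`placement_noise` must be named for every placement.")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), speeds = speeds,
         placements = placements, trial_duration = trial_duration,
         fs_imu = fs_imu, fs_mocap = fs_mocap,
         placement_noise = placement_noise, marker_noise = marker_noise,
         stride_target = stride_target, stride_target_sd = stride_target_sd,
         speed_ref = speed_ref, speed_exponent = speed_exponent,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw subject profiles for the synthetic cohort
#'
#' Each subject carries a random gait signature: a base stride time, stance and
#' double-support fractions, cycle-to-cycle stride variability, heel-strike
#' impact amplitude and a mild left/right asymmetry ratio. Double-support
#' fractions are drawn so that the per-cycle double-support duration stays in
#' the physiological 0.1--0.2 s range across all configured speeds.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param n Number of profiles to draw.
#' @param config A [sim_config()].
#' @return A tibble with one row per subject.
#' @export
draw_subject_profiles <- function(n, config = sim_config()) {
  check_scalar(n, "n")
  n <- as.integer(n)
  base <- pmin(pmax(rnorm(n, 1.10, 0.08), 0.90), 1.40)
  cv <- runif(n, 0.015, 0.030)
  # stride time extremes across speeds and cycle noise (z truncated at +/-3)
  mult <- (config$speed_ref / config$speeds)^config$speed_exponent
  t_lo <- base * min(mult) * (1 - 4 * cv)
  t_hi <- base * max(mult) * (1 + 4 * cv)
  ds_lo <- pmax(0.06, 0.105 / t_lo)
  ds_hi <- pmin(0.19, 0.195 / t_hi)
  ds_frac <- ds_lo + runif(n) * pmax(ds_hi - ds_lo, 0)
  tibble(
    subject_id = sprintf("S%02d", seq_len(n)),
    base_stride_time = base,
    stance_fraction = 0.5 + ds_frac / 2,
    double_support_fraction = ds_frac,
    stride_cv = cv,
    impact_amplitude = runif(n, 1.5, 3.0),
    asymmetry_ratio = runif(n, 0.985, 1.015)
  )
}

#' Validate a subject profile
#'
#' Checks the structural constraints a profile must satisfy: stance fraction in
#' (0.5, 0.7) (double support is impossible at or below 0.5), double-support
#' fraction no larger than twice the stance excess over 0.5, and a base stride
#' time in the 0.8--1.6 s range seen at the simulated treadmill speeds.
#'
#' @param profile A one-row tibble or named list.
#' @return `profile`, invisibly; aborts if any constraint fails.
#' @export
validate_profile <- function(profile) {
  p <- as.list(profile)
  ok <- p$stance_fraction > 0.5 && p$stance_fraction < 0.7 &&
    p$double_support_fraction <= 2 * (p$stance_fraction - 0.5) + 1e-9 &&
    p$double_support_fraction > 0.05 && p$double_support_fraction < 0.2 &&
    p$base_stride_time >= 0.8 && p$base_stride_time <= 1.6
  if (!isTRUE(ok)) abort("Subject profile violates its constraints.")
  invisible(profile)
}
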
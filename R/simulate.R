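# Synthetic single-IMU treadmill walking trials with exact ground truth.
#
# The generative model is event-first: a stride-time sequence is drawn for the
# right side, contralateral events are placed half a cycle later, and stance /
# double-support durations follow the subject's phase fractions. Marker
# trajectories and IMU channels are then rendered around those event times, so
# every downstream stage can be scored against exact truth.

# smooth rise/fall bump: 0 with zero slope at both ends, apex at `t_apex`
raised_bump <- function(t, t_on, t_apex, t_off, amp) {
  y <- numeric(length(t))
  r <- t >= t_on & t <= t_apex
  f <- t > t_apex & t <= t_off
  y[r] <- amp * 0.5 * (1 - cos(pi * (t[r] - t_on) / (t_apex - t_on)))
  y[f] <- amp * 0.5 * (1 + cos(pi * (t[f] - t_apex) / (t_off - t_apex)))
  y
}

# symmetric raised-cosine valley centred at t0 (depth > 0 dips downwards)
cosine_valley <- function(t, t0, half_width, depth) {
  y <- numeric(length(t))
  i <- abs(t - t0) <= half_width
  y[i] <- -depth * 0.5 * (1 + cos(pi * (t[i] - t0) / half_width))
  y
}

# exponentially damped sinusoid transient starting at t0; broadband impact:
# a high-frequency ring plus a lower-frequency component that survives the
# 10 Hz analysis filter
impact_transient <- function(t, t0, amp, f_hf = 18, tau_hf = 0.05,
                             f_lf = 6, tau_lf = 0.12) {
  y <- numeric(length(t))
  i <- t >= t0 & t <= t0 + 0.35
  tau <- t[i] - t0
  y[i] <- amp * exp(-tau / tau_hf) * sin(2 * pi * f_hf * tau) +
    0.4 * amp * exp(-tau / tau_lf) * sin(2 * pi * f_lf * tau)
  y
}

# Draw the event skeleton of one trial. Returns event streams, per-cycle truth
# parameters and the realised duration.
sim_events <- function(profile, speed, config, duration = NULL,
                       transitions_at = NULL) {
  p <- as.list(profile)
  t_mean <- p$base_stride_time *
    (config$speed_ref / speed)^config$speed_exponent
  f <- p$stance_fraction
  f_r <- 0.5 + (f - 0.5) * p$asymmetry_ratio
  f_l <- 0.5 + (f - 0.5) / p$asymmetry_ratio
  t0 <- 1.0

  if (is.null(duration)) {
    n_target <- max(20, round(rnorm(1, config$stride_target,
                                    config$stride_target_sd)))
    duration <- t0 + n_target * t_mean + 1.5
    duration <- min(max(duration, config$trial_duration[1]),
                    config$trial_duration[2])
  }
  check_scalar(duration, "duration")

  trans <- sort(transitions_at)
  trans_mult <- if (length(trans)) runif(length(trans), 0.92, 1.08) else numeric(0)

  strides <- numeric(0)
  t_cur <- t0
  k_trans <- 0L
  mult <- 1
  repeat {
    while (k_trans < length(trans) && t_cur >= trans[k_trans + 1L]) {
      k_trans <- k_trans + 1L
      mult <- mult * trans_mult[k_trans]
    }
    z <- max(-3, min(3, rnorm(1)))
    t_i <- t_mean * mult * (1 + p$stride_cv * z)
    if (t_cur + t_i > duration - 0.8) break
    strides <- c(strides, t_i)
    t_cur <- t_cur + t_i
  }
  n <- length(strides)
  if (n < 3) abort("Trial too short for a usable stride sequence.")

  r_hs <- t0 + cumsum(c(0, strides))            # n + 1 heel strikes
  r_to <- r_hs[seq_len(n)] + f_r * strides      # n toe-offs
  l_hs <- r_hs[seq_len(n)] + 0.5 * strides      # n heel strikes
  l_stride <- diff(l_hs)                        # n - 1 strides
  l_to <- l_hs[seq_len(n - 1)] + f_l * l_stride # n - 1 toe-offs
  # leading left toe-off (its heel strike precedes the recording) so the first
  # right cycle has a complete double-support phase
  l_to0 <- r_hs[1] + (f_l - 0.5) * strides[1]

  events <- bind_rows(
    tibble(time = r_hs, type = "HS", side = "R"),
    tibble(time = r_to, type = "TO", side = "R"),
    tibble(time = l_hs, type = "HS", side = "L"),
    tibble(time = c(l_to0, l_to), type = "TO", side = "L")
  ) %>%
    mutate(source = "truth") %>%
    arrange(.data$time)

  # analytic per-cycle truth (independent of the generic cycle computation)
  r_ds2 <- r_to[seq_len(n)] - l_hs[seq_len(n)]
  r_ds1 <- c(l_to0, l_to) - r_hs[seq_len(n)]
  right <- tibble(
    side = "R", t_start = r_hs[seq_len(n)], stride = strides,
    stance = f_r * strides, swing = (1 - f_r) * strides,
    double_support = r_ds1 + r_ds2
  )
  m <- n - 1
  l_ds1 <- r_to[seq_len(m)] - l_hs[seq_len(m)]
  l_ds2 <- l_to - r_hs[2:(m + 1)]
  left <- tibble(
    side = "L", t_start = l_hs[seq_len(m)], stride = l_stride,
    stance = f_l * l_stride, swing = (1 - f_l) * l_stride,
    double_support = l_ds1 + l_ds2
  )

  list(events = events, truth_cycles = bind_rows(right, left),
       duration = duration, stride_mean = t_mean,
       transitions = trans, r_hs = r_hs, r_to = r_to,
       l_hs = l_hs, l_to = l_to, l_to0 = l_to0)
}

# Render vertical marker trajectories (mm) around the event skeleton.
# Calcaneus: flat stance baseline, one smooth swing bump per stride whose apex
# is the "foot motion peak", and a symmetric valley at each heel strike so the
# local minimum falls exactly on the event. Metatarsal: analogous with the
# valley at toe-off.
sim_markers <- function(ev, config) {
  nm <- floor(ev$duration * config$fs_mocap)
  t <- (seq_len(nm) - 1) / config$fs_mocap
  hw <- 0.075

  render_side <- function(hs, to) {
    # if no recorded toe-off precedes the first heel strike, start a virtual
    # initial swing so that heel strike still has a preceding motion peak
    sw_on <- if (to[1] < hs[1]) to else c(hs[1] - 0.42 * (hs[2] - hs[1]), to)
    sw_off <- hs[seq_along(sw_on)]
    calc <- rep(30, nm)
    meta <- rep(20, nm)
    for (i in seq_along(sw_on)) {
      a <- sw_on[i]; b <- sw_off[i]
      if (b - a < 4 * hw) next
      apex <- a + 0.6 * (b - a)
      # The calcaneus bump must stay small enough that its descent cannot
      # displace the heel-strike valley minimum after zero-phase filtering.
      # At the shortest cohort swing (~0.31 s) the descent lasts only
      # 0.4*swing - hw ~ 49 ms; the filter's undershoot then reaches ~5.5% of
      # the bump height on the valley flank while the rebound lifts the
      # valley floor ~1.4%. Against the 8 mm valley (filter gain 0.96) the
      # minimum provably stays on the event only for heights below ~60 mm,
      # and the residual ringing slope shifts it by < 10 ms (one sample)
      # only below ~70 mm; 40 mm leaves both bounds a wide margin. The apex
      # cannot move earlier to slow the descent instead: toe-off must stay
      # inside the detector's 40-80% inter-peak band, which pins it late.
      calc <- calc + raised_bump(t, a, apex, b - hw, 40 * runif(1, 0.95, 1.05))
      meta <- meta + raised_bump(t, a + hw, a + hw + 0.5 * (b - a - hw),
                                 b, 45 * runif(1, 0.95, 1.05))
    }
    for (h in hs) calc <- calc + cosine_valley(t, h, hw, 8)
    for (d in to) meta <- meta + cosine_valley(t, d, hw, 6)
    list(calc = calc, meta = meta)
  }

  r <- render_side(ev$r_hs, ev$r_to)
  l <- render_side(ev$l_hs, c(ev$l_to0, ev$l_to))
  sn <- config$marker_noise
  noise <- function() if (sn > 0) rnorm(nm, 0, sn) else numeric(nm)
  tibble(t = t,
         calc_L_z = l$calc + noise(), calc_R_z = r$calc + noise(),
         meta_L_z = l$meta + noise(), meta_R_z = r$meta + noise())
}

# Render the six IMU channels (acc in g, angular rate in deg/s) at fs_imu:
# slowly drifting gravity projection, periodic gait motion at stride and step
# frequency, damped-oscillation transients at each gait event, placement-graded
# broadband artifact noise, and a low-frequency pendulum artifact for the
# jacket placement.
sim_imu <- function(ev, placement, profile, config) {
  p <- as.list(profile)
  ni <- floor(ev$duration * config$fs_imu)
  t <- (seq_len(ni) - 1) / config$fs_imu

  # gravity projection with slow orientation drift
  th_x <- runif(1, 0.03, 0.10) * sin(2 * pi * runif(1, 0.03, 0.08) * t +
                                       runif(1, 0, 2 * pi))
  th_y <- runif(1, 0.03, 0.10) * sin(2 * pi * runif(1, 0.03, 0.08) * t +
                                       runif(1, 0, 2 * pi))
  acc <- rbind(sin(th_y), -sin(th_x), cos(th_x) * cos(th_y))

  # periodic gait motion, phase-locked to the actual stride cycle: the
  # stride and step harmonics are produced by the same legs as the impacts,
  # so their phase must follow the (variable) heel-strike sequence rather
  # than a fixed-frequency clock -- otherwise the event-local waveform
  # slowly morphs as true stride times wander around the mean.
  hs <- ev$r_hs
  cyc <- seq_along(hs) - 1
  ph <- stats::approx(hs, cyc, xout = t, rule = 2)$y
  ph[t < hs[1]] <- (t[t < hs[1]] - hs[1]) / (hs[2] - hs[1])
  n_hs <- length(hs)
  last_stride <- hs[n_hs] - hs[n_hs - 1]
  ph[t > hs[n_hs]] <- cyc[n_hs] + (t[t > hs[n_hs]] - hs[n_hs]) / last_stride
  phi <- 2 * pi * ph

  gyr <- matrix(0, 3, ni)
  for (ax in 1:3) {
    acc[ax, ] <- acc[ax, ] +
      runif(1, 0.10, 0.30) * sin(phi + runif(1, 0, 2 * pi)) +
      runif(1, 0.10, 0.30) * sin(2 * phi + runif(1, 0, 2 * pi))
    gyr[ax, ] <- runif(1, 20, 80) * sin(phi + runif(1, 0, 2 * pi)) +
      runif(1, 20, 80) * sin(2 * phi + runif(1, 0, 2 * pi))
  }

  # event transients: each stream has a fixed propagation direction (a body
  # property: how a left vs right impact reaches the device), and the whole
  # set is rotated by one shared per-trial rotation -- the device has a single
  # orientation per trial, so stream directions cannot vary independently.
  # Ipsilateral (right-side) events hit harder than contralateral ones,
  # toe-offs are weaker than heel strikes.
  base_dir <- list(HS_R = c(0.25, 0.30, 0.90), HS_L = c(0.85, 0.35, 0.40),
                   TO_R = c(0.40, 0.80, 0.45), TO_L = c(0.70, 0.20, 0.70))
  gyr_dir <- list(HS_R = c(0.90, 0.10, 0.42), HS_L = c(0.15, 0.85, 0.50),
                  TO_R = c(0.45, 0.60, 0.66), TO_L = c(0.70, 0.65, 0.30))
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- rnorm(1, 0, 0.25)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  amp0 <- p$impact_amplitude
  stream_events <- list(HS_R = ev$r_hs, HS_L = ev$l_hs,
                        TO_R = ev$r_to, TO_L = c(ev$l_to0, ev$l_to))
  for (s in names(stream_events)) {
    u <- as.numeric(R %*% base_dir[[s]])
    u <- u / sqrt(sum(u^2))
    v <- as.numeric(R %*% gyr_dir[[s]])
    v <- v / sqrt(sum(v^2))
    amp <- amp0 * (if (grepl("_R", s)) 1 else 0.75) *
      (if (grepl("TO", s)) 0.45 else 1)
    for (t0 in stream_events[[s]]) {
      w <- impact_transient(t, t0, amp)
      idx <- which(w != 0)
      if (!length(idx)) next
      for (ax in 1:3) {
        acc[ax, idx] <- acc[ax, idx] + u[ax] * w[idx]
        gyr[ax, idx] <- gyr[ax, idx] + 40 * v[ax] * w[idx]
      }
    }
  }

  if (placement == "jacket") {
    f_p <- runif(1, 0.7, 0.9)
    ph <- runif(2, 0, 2 * pi)
    acc[1, ] <- acc[1, ] + 0.25 * sin(2 * pi * f_p * t + ph[1])
    acc[2, ] <- acc[2, ] + 0.25 * sin(2 * pi * f_p * t + ph[2])
    gyr[3, ] <- gyr[3, ] + 30 * sin(2 * pi * f_p * t + ph[1])
  }

  sn <- unname(config$placement_noise[placement])
  if (sn > 0) {
    acc <- acc + matrix(rnorm(3 * ni, 0, sn), 3)
    gyr <- gyr + matrix(rnorm(3 * ni, 0, 250 * sn), 3)
  }
  acc <- pmin(pmax(acc, -16), 16)
  gyr <- pmin(pmax(gyr, -2000), 2000)

  tibble(t = t,
         acc_x = acc[1, ], acc_y = acc[2, ], acc_z = acc[3, ],
         gyr_x = gyr[1, ], gyr_y = gyr[2, ], gyr_z = gyr[3, ])
}

#' Simulate one walking trial
#'
#' Generates a single subject x speed x placement recording: six IMU channels
#' at `config$fs_imu`, four vertical marker trajectories at `config$fs_mocap`,
#' the exact ground-truth gait events and the analytic per-cycle parameters.
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param profile One row of [draw_subject_profiles()].
#' @param speed Treadmill speed in m/s; must be one of `config$speeds`.
#' @param placement One of `config$placements`.
#' @param config A [sim_config()].
#' @param duration Optional trial duration in seconds; by default the duration
#'   is set so that about `config$stride_target` strides fit, clamped to
#'   `config$trial_duration`.
#' @param transitions_at Optional numeric vector of condition-transition
#'   timestamps; the stride rhythm shifts at each boundary and the timestamps
#'   are recorded so downstream cycle filtering can exclude spanning cycles.
#' @return A `gait_trial` object: a list with elements `imu`, `markers`,
#'   `events`, `transitions`, `truth_cycles` plus trial metadata.
#' @export
simulate_trial <- function(profile, speed, placement, config = sim_config(),
                           duration = NULL, transitions_at = NULL) {
  check_scalar(speed, "speed")
  if (!any(abs(config$speeds - speed) < 1e-9)) {
    abort("`speed` must be one of `config$speeds`.")
  }
  placement <- match.arg(placement, config$placements)
  if (!is.null(duration)) check_scalar(duration, "duration")
  validate_profile(profile)

  ev <- sim_events(profile, speed, config, duration, transitions_at)
  markers <- sim_markers(ev, config)
  imu <- sim_imu(ev, placement, profile, config)

  structure(
    list(imu = imu, markers = markers, events = ev$events,
         transitions = ev$transitions, truth_cycles = ev$truth_cycles,
         subject = as.list(profile)$subject_id, speed = speed,
         placement = placement, duration = ev$duration,
         fs_imu = config$fs_imu, fs_mocap = config$fs_mocap),
    class = "gait_trial"
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s | %.2f m/s | %s | %.1f s | %d truth events\n",
              x$subject %||% "?", x$speed, x$placement, x$duration,
              nrow(x$events)))
  invisible(x)
}
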